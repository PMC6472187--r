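# Evaluate code under a locally-set RNG seed, restoring the caller's RNG
# state afterwards; seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build an exposure vector with driving signatures
#'
#' Assigns the given weights to the driving signatures and distributes the
#' remaining probability mass uniformly over all other signatures (the
#' construction used when simulating genomes driven by one or more
#' signatures, e.g. one driver at 0.8 with the remaining 0.2 spread over the
#' other 14 of 15 signatures).
#'
#' @param n_signatures Total number of signatures K.
#' @param driver_index Indices of the driving signatures (distinct, in 1..K).
#' @param driver_weight Exposures of the driving signatures (same length,
#'   summing to at most 1).
#' @return Numeric simplex vector of length K.
#' @export
make_exposures <- function(n_signatures, driver_index, driver_weight) {
  K <- as.integer(n_signatures)
  driver_index <- as.integer(driver_index)
  stopifnot(length(driver_index) == length(driver_weight),
            all(driver_index >= 1L), all(driver_index <= K))
  if (anyDuplicated(driver_index)) stop("driver indices must be distinct")
  if (any(driver_weight < 0)) stop("driver weights must be non-negative")
  total <- sum(driver_weight)
  if (total > 1 + 1e-12) stop("driver weights exceed 1 (sum = ", total, ")")
  rest <- K - length(driver_index)
  if (rest == 0L && abs(total - 1) > 1e-12)
    stop("all signatures are drivers but weights do not sum to 1")
  w <- rep(if (rest > 0L) (1 - total) / rest else 0, K)
  w[driver_index] <- driver_weight
  w
}

#' Simulate a tumor genome from known signature exposures
#'
#' Each of `n_mutations` mutations is assigned to a signature with
#' probability given by `exposures`, and its features are drawn from that
#' signature: one of the 96 joint categories under the Alexandrov model, or
#' each feature (base change, each flanking base, strand) independently
#' under the Shiraishi model, exactly as the independent-feature model
#' assumes. The draws are aggregated into a frequency profile.
#'
#' @param signatures List of signatures sharing one [context_spec()].
#' @param exposures Simplex vector of length `length(signatures)`.
#' @param n_mutations Number of mutations to draw.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param sample Sample name of the resulting profile.
#' @return A [genome_profile()]; the integer feature counts the profile was
#'   aggregated from are attached as attribute `"counts"`.
#' @export
simulate_genome <- function(signatures, exposures, n_mutations,
                            seed = NULL, sample = "simulated") {
  S_spec <- signatures[[1L]]$spec
  K <- length(signatures)
  stopifnot(length(exposures) == K, n_mutations >= 1)
  if (abs(sum(exposures) - 1) > 1e-8 || any(exposures < 0))
    stop("exposures must be a probability vector over the signatures")
  ok <- vapply(signatures, function(s) same_spec(s$spec, S_spec), FALSE)
  if (!all(ok)) stop("signatures have mixed context specs")
  with_seed(seed, {
    n_per_sig <- as.vector(stats::rmultinom(1L, n_mutations, exposures))
    if (S_spec$model == "alexandrov") {
      counts <- numeric(96L)
      for (s in seq_len(K)) {
        if (n_per_sig[s] > 0L)
          counts <- counts +
            as.vector(stats::rmultinom(1L, n_per_sig[s], signatures[[s]]$probs))
      }
      prof <- genome_profile(counts / n_mutations, S_spec,
                             n_mutations = n_mutations, sample = sample)
    } else {
      w <- shiraishi_row_widths(S_spec)
      counts <- matrix(0, nrow = length(w), ncol = 6L)
      for (s in seq_len(K)) {
        if (n_per_sig[s] == 0L) next
        m <- signatures[[s]]$matrix
        for (r in seq_along(w)) {
          counts[r, seq_len(w[r])] <- counts[r, seq_len(w[r])] +
            as.vector(stats::rmultinom(1L, n_per_sig[s], m[r, seq_len(w[r])]))
        }
      }
      prof <- genome_profile(counts / n_mutations, S_spec,
                             n_mutations = n_mutations, sample = sample)
    }
    attr(prof, "counts") <- counts
    prof
  })
}

#' Generate a random signature set
#'
#' Draws each feature row (or the 96-category vector) from a sparse
#' symmetric Dirichlet distribution; optionally redraws signatures until all
#' pairwise Frobenius distances exceed `min_separation`, giving
#' well-separated sets for recovery experiments.
#'
#' @param n Number of signatures.
#' @param spec A [context_spec()].
#' @param seed Optional integer seed.
#' @param min_separation If set, minimum pairwise Frobenius distance;
#'   candidates closer than this to an accepted signature are redrawn.
#' @param concentration Dirichlet concentration parameter (0.5 gives sparse,
#'   signature-like rows).
#' @param max_tries Redraw budget per signature before giving up.
#' @return List of `n` signatures named `"sig1"`, `"sig2"`, ...
#' @export
random_signature_set <- function(n, spec, seed = NULL, min_separation = NULL,
                                 concentration = 0.5, max_tries = 200L) {
  stopifnot(inherits(spec, "context_spec"), n >= 1L)
  rdirichlet <- function(k) {
    x <- stats::rgamma(k, shape = concentration)
    while (sum(x) == 0) x <- stats::rgamma(k, shape = concentration)
    x / sum(x)
  }
  draw <- function(name) {
    if (spec$model == "alexandrov") {
      alexandrov_signature(rdirichlet(96L), name = name)
    } else {
      w <- shiraishi_row_widths(spec)
      m <- t(vapply(w, function(k) c(rdirichlet(k), rep(0, 6L - k)),
                    numeric(6L)))
      shiraishi_signature(m, spec = spec, name = name)
    }
  }
  with_seed(seed, {
    sigs <- list()
    for (i in seq_len(n)) {
      for (try in seq_len(max_tries)) {
        cand <- draw(paste0("sig", i))
        if (is.null(min_separation) || length(sigs) == 0L ||
            all(vapply(sigs, function(s)
              signature_distance(s, cand), 0) > min_separation)) {
          sigs[[i]] <- cand
          break
        }
        if (try == max_tries)
          stop("could not reach min_separation = ", min_separation,
               " after ", max_tries, " redraws for signature ", i)
      }
    }
    names(sigs) <- vapply(sigs, function(s) s$name, "")
    sigs
  })
}

#' Recovery evaluation on simulated genomes
#'
#' Runs the standard simulation benchmark for signature refitting: for each
#' driver combination, simulate genomes with the driving signatures at the
#' given exposures (remainder uniform over the other signatures), refit each
#' genome against the full signature set, and tabulate the absolute
#' deviation of each fitted exposure from its simulated value, split into
#' driving and non-driving signatures.
#'
#' @param signatures The signature set.
#' @param driver_weights Exposures of the driving signatures, e.g. `0.8` for
#'   one driver or `c(0.5, 0.3)` for two.
#' @param n_mutations Mutations per simulated genome.
#' @param n_genomes Genomes per driver combination.
#' @param combinations Matrix of driver index combinations (one per column);
#'   defaults to all `choose(K, d)` combinations, subsampled to
#'   `max_combinations` if necessary.
#' @param max_combinations Cap on the number of driver combinations.
#' @param seed Integer seed; genome i of combination j uses a substream
#'   derived from it by a counter, so any genome is reproducible in
#'   isolation.
#' @return Object of class `recovery_evaluation`: list with `deviations`
#'   (long data frame: combination, genome, signature, role, true, fitted,
#'   deviation) and `summary` (median, 90th and 99th percentile of the
#'   absolute deviations by role).
#' @export
evaluate_recovery <- function(signatures, driver_weights = 0.8,
                              n_mutations = 200L, n_genomes = 100L,
                              combinations = NULL, max_combinations = 200L,
                              seed = NULL) {
  K <- length(signatures)
  d <- length(driver_weights)
  S <- signature_matrix(signatures)
  spec <- signatures[[1L]]$spec
  if (is.null(combinations)) {
    combinations <- utils::combn(K, d)
    if (ncol(combinations) > max_combinations) {
      keep <- with_seed(seed, sample.int(ncol(combinations), max_combinations))
      combinations <- combinations[, keep, drop = FALSE]
    }
  }
  combinations <- as.matrix(combinations)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  counter <- 0L
  rows <- vector("list", ncol(combinations) * n_genomes)
  ri <- 0L
  for (ci in seq_len(ncol(combinations))) {
    drv <- combinations[, ci]
    w_true <- make_exposures(K, drv, driver_weights)
    role <- ifelse(seq_len(K) %in% drv, "driving", "background")
    for (gi in seq_len(n_genomes)) {
      counter <- counter + 1L
      gseed <- if (is.null(base_seed)) NULL else (base_seed + counter) %% .Machine$integer.max
      g <- simulate_genome(signatures, w_true, n_mutations, seed = gseed)
      w_hat <- solve_exposures(g, S)$weights
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        combination = ci, genome = gi, signature = colnames(S),
        role = role, true = w_true, fitted = unname(w_hat),
        deviation = abs(unname(w_hat) - w_true),
        stringsAsFactors = FALSE)
    }
  }
  dev <- do.call(rbind, rows)
  rownames(dev) <- NULL
  summ <- do.call(rbind, lapply(split(dev$deviation, dev$role), function(x)
    data.frame(n = length(x), median = stats::median(x),
               q90 = unname(stats::quantile(x, 0.9)),
               q99 = unname(stats::quantile(x, 0.99)))))
  summ <- cbind(role = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(deviations = dev, summary = summ,
                 n_mutations = n_mutations, driver_weights = driver_weights),
            class = "recovery_evaluation")
}

#' @export
print.recovery_evaluation <- function(x, ...) {
  cat(sprintf("Recovery evaluation: %d genomes, %d mutations each, drivers at (%s)\n",
              length(unique(paste(x$deviations$combination, x$deviations$genome))),
              x$n_mutations, paste(x$driver_weights, collapse = ", ")))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generate a random reference genome
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param seed Optional integer seed.
#' @param gc Probability of G or C at each position.
#' @return A [Biostrings::DNAStringSet].
#' @export
random_reference <- function(chrom_lengths = c("1" = 10000L, "2" = 8000L),
                             seed = NULL, gc = 0.4) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(chrom_lengths, function(n)
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""), "")
    Biostrings::DNAStringSet(seqs)
  })
}

#' Generate a synthetic tumor dataset on disk
#'
#' Writes a self-contained set of fixture files for end-to-end runs without
#' any external downloads: a random reference FASTA, matching somatic SNVs
#' in both VCF and MPF encodings, and a BED6 file of stranded regions.
#' Mutated positions are drawn uniformly (away from chromosome edges), the
#' reference allele is taken from the generated FASTA, and the alternate
#' allele is drawn uniformly from the other three bases.
#'
#' @param dir Output directory (created if needed).
#' @param n_mutations SNVs per sample.
#' @param samples Character vector of sample names.
#' @param chrom_lengths Passed to [random_reference()].
#' @param region_fraction Approximate fraction of each chromosome covered by
#'   stranded regions.
#' @param seed Optional integer seed.
#' @return List with the file `paths` (fasta, vcf, mpf, bed), the reference
#'   `DNAStringSet`, and the `records` data frame of planted mutations
#'   (sample, chrom, pos, ref, alt).
#' @export
synthesize_tumor_data <- function(dir, n_mutations = 50L, samples = "TUMOR1",
                                  chrom_lengths = c("1" = 10000L, "2" = 8000L),
                                  region_fraction = 0.6, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    ref <- random_reference(chrom_lengths)
    recs <- do.call(rbind, lapply(samples, function(sm) {
      chrom <- sample(names(chrom_lengths), n_mutations, replace = TRUE)
      pos <- vapply(chrom, function(ch)
        sample(6:(chrom_lengths[[ch]] - 5L), 1L), 0L)
      refb <- vapply(seq_len(n_mutations), function(i)
        as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i], pos[i])), "")
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), "")
      data.frame(sample = sm, chrom = chrom, pos = pos, ref = refb,
                 alt = altb, stringsAsFactors = FALSE)
    }))
    recs <- recs[!duplicated(recs[c("sample", "chrom", "pos")]), ]
    rownames(recs) <- NULL

    fasta <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(ref, fasta)

    mpf <- file.path(dir, "mutations.mpf")
    utils::write.table(recs, mpf, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    vcf <- file.path(dir, "mutations.vcf")
    write_fixture_vcf(recs, samples, vcf)

    bed <- file.path(dir, "regions.bed")
    write_fixture_bed(chrom_lengths, region_fraction, bed)

    list(paths = list(fasta = fasta, vcf = vcf, mpf = mpf, bed = bed),
         reference = ref, records = recs)
  })
}

# minimal single-ALT VCF 4.2 with one GT column per sample
write_fixture_vcf <- function(recs, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  key <- paste(recs$chrom, recs$pos, recs$ref, recs$alt)
  body <- vapply(unique(key), function(k) {
    rr <- recs[key == k, ]
    gts <- ifelse(samples %in% rr$sample, "0/1", "0/0")
    paste(c(rr$chrom[1L], rr$pos[1L], ".", rr$ref[1L], rr$alt[1L], ".",
            "PASS", ".", "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
}

# alternating-strand BED6 blocks covering roughly region_fraction of each
# chromosome
write_fixture_bed <- function(chrom_lengths, region_fraction, path) {
  lines <- character()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    block <- max(200L, as.integer(len / 20L))
    starts <- seq(0L, len - block, by = as.integer(block / region_fraction))
    strands <- rep(c("+", "-"), length.out = length(starts))
    lines <- c(lines, sprintf("%s\t%d\t%d\tregion%d\t0\t%s",
                              ch, starts, pmin(starts + block, len),
                              seq_along(starts), strands))
  }
  writeLines(lines, path)
}
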