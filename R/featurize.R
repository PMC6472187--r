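COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chars <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Normalize a mutation to its pyrimidine-centered representation
#'
#' Each SNV is represented on the strand where the mutated base is a
#' pyrimidine (C or T), collapsing reverse-complement pairs: if the
#' reference base is A or G, the ref/alt bases are complemented and the
#' flanking context is reverse-complemented (so the 5' and 3' flanks swap).
#' The function records which reference strand carried the pyrimidine
#' (`"+"` if the original ref was C/T, `"-"` otherwise); this drives the
#' transcription-strand feature.
#'
#' @param ref,alt Single reference/alternate bases (vectors allowed).
#' @param context5,context3 Flanking bases 5' and 3' of the variant on the
#'   reference strand, read 5' to 3' (character vectors; may be `""` for
#'   zero flanks).
#' @return Data frame with columns `change` (e.g. `"C>T"`), `context5`,
#'   `context3` (normalized flanks), and `pyrimidine_strand` (`"+"`/`"-"`).
#'   Rows whose context contains a non-ACGT character get `NA` change.
#' @export
normalize_to_pyrimidine <- function(ref, alt, context5 = "", context3 = "") {
  n <- length(ref)
  context5 <- rep_len(context5, n)
  context3 <- rep_len(context3, n)
  out <- data.frame(change = character(n), context5 = character(n),
                    context3 = character(n), pyrimidine_strand = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    c5 <- context5[i]; c3 <- context3[i]
    if (!valid_bases(paste0(c5, r, a, c3))) {
      out$change[i] <- NA_character_
      next
    }
    if (r %in% c("C", "T")) {
      out$pyrimidine_strand[i] <- "+"
    } else {
      out$pyrimidine_strand[i] <- "-"
      tmp5 <- revcomp_chars(c3)
      c3 <- revcomp_chars(c5)
      c5 <- tmp5
      r <- COMPLEMENT[[r]]
      a <- COMPLEMENT[[a]]
    }
    out$change[i] <- paste0(r, ">", a)
    out$context5[i] <- c5
    out$context3[i] <- c3
  }
  out
}

valid_bases <- function(s) {
  !grepl("[^ACGT]", s)
}

#' Assign the transcription-strand feature to mutation positions
#'
#' A mutation's strand feature compares the reference strand that carries
#' the pyrimidine (after [normalize_to_pyrimidine()]) with the transcription
#' strand of the region covering the position: `"plus"` if they agree,
#' `"minus"` if they differ, `"undefined"` if the position is not covered by
#' any region or is covered by regions on both strands.
#'
#' @param chrom,pos Mutation coordinates (1-based).
#' @param pyrimidine_strand `"+"`/`"-"` per mutation, from
#'   [normalize_to_pyrimidine()].
#' @param regions A [GenomicRanges::GRanges] of stranded regions, as
#'   returned by [read_stranded_regions()].
#' @return Character vector in `c("plus", "minus", "undefined")`.
#' @export
assign_strand <- function(chrom, pos, pyrimidine_strand, regions) {
  stopifnot(methods::is(regions, "GRanges"))
  q <- GenomicRanges::GRanges(normalize_chrom(chrom),
                              IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, regions, ignore.strand = TRUE)
  tau <- rep(NA_character_, length(q))
  qh <- S4Vectors::queryHits(hits)
  sh <- as.character(BiocGenerics::strand(regions))[S4Vectors::subjectHits(hits)]
  for (i in unique(qh)) {
    s <- unique(sh[qh == i])
    if (length(s) == 1L && s %in% c("+", "-")) tau[i] <- s
  }
  ifelse(is.na(tau), "undefined",
         ifelse(tau == pyrimidine_strand, "plus", "minus"))
}

#' Build a genome profile from mutation records
#'
#' Featurizes somatic SNVs against a reference genome into the mutational
#' catalog of one tumor: reads the flanking context of each variant from the
#' FASTA, normalizes it to the pyrimidine-centered representation, optionally
#' assigns the transcription-strand feature from stranded regions, and
#' aggregates the usable mutations into frequencies — joint 96-category
#' frequencies for the Alexandrov model, or per-feature marginal frequencies
#' for the Shiraishi model.
#'
#' Mutations are excluded (and counted in the `"excluded"` attribute) when
#' their context contains non-ACGT bases, or when `spec$use_strand` is set
#' and their transcription strand is undefined. A mismatch between the
#' record's ref allele and the FASTA base is an error by default, since
#' silent reference mismatches corrupt signatures.
#'
#' @param records Data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt` (as returned by [read_mpf()]/[read_vcf()]); a single sample.
#' @param reference A [Biostrings::DNAStringSet] (chromosome names matched
#'   after stripping any `"chr"` prefix), or a FASTA path.
#' @param spec The [context_spec()] of the target representation.
#' @param regions Stranded regions ([read_stranded_regions()]); required
#'   when `spec$use_strand` is `TRUE`.
#' @param on_ref_mismatch `"error"` (default) or `"skip"`.
#' @param sample Profile name; defaults to the records' sample.
#' @return A [genome_profile()]; exclusion counts in `attr(, "excluded")`.
#' @export
build_profile <- function(records, reference, spec, regions = NULL,
                          on_ref_mismatch = c("error", "skip"),
                          sample = NULL) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  stopifnot(inherits(spec, "context_spec"))
  if (is.character(reference)) reference <- read_reference(reference)
  if (spec$use_strand && is.null(regions))
    stop("spec includes the transcription-strand feature; ",
         "stranded regions are required")
  if (is.null(sample))
    sample <- if (nrow(records)) records$sample[1L] else "tumor"
  if (length(unique(records$sample)) > 1L)
    stop("records contain multiple samples; build one profile per sample")

  excluded <- c(ref_mismatch = 0L, bad_context = 0L, undefined_strand = 0L)
  nmax <- max(spec$flank_left, spec$flank_right)
  chrom <- normalize_chrom(records$chrom)
  missing_chrom <- setdiff(unique(chrom), names(reference))
  if (length(missing_chrom))
    stop("chromosome(s) not in reference: ",
         paste(missing_chrom, collapse = ", "))

  n <- nrow(records)
  keep <- rep(TRUE, n)
  c5 <- c3 <- character(n)
  for (i in seq_len(n)) {
    seqlen <- length(reference[[chrom[i]]])
    pos <- records$pos[i]
    if (pos < 1L || pos > seqlen)
      stop("position ", records$chrom[i], ":", pos, " outside reference")
    fasta_ref <- as.character(Biostrings::subseq(reference[[chrom[i]]], pos, pos))
    if (fasta_ref != records$ref[i]) {
      if (on_ref_mismatch == "error")
        stop(sprintf("reference mismatch at %s:%d: record says %s, FASTA has %s",
                     records$chrom[i], pos, records$ref[i], fasta_ref))
      excluded["ref_mismatch"] <- excluded["ref_mismatch"] + 1L
      keep[i] <- FALSE
      next
    }
    lo <- pos - spec$flank_left
    hi <- pos + spec$flank_right
    if (lo < 1L || hi > seqlen) {       # context truncated at chromosome edge
      excluded["bad_context"] <- excluded["bad_context"] + 1L
      keep[i] <- FALSE
      next
    }
    c5[i] <- if (spec$flank_left > 0L)
      as.character(Biostrings::subseq(reference[[chrom[i]]], lo, pos - 1L)) else ""
    c3[i] <- if (spec$flank_right > 0L)
      as.character(Biostrings::subseq(reference[[chrom[i]]], pos + 1L, hi)) else ""
  }

  norm <- normalize_to_pyrimidine(records$ref, records$alt, c5, c3)
  bad <- keep & is.na(norm$change)
  excluded["bad_context"] <- excluded["bad_context"] + sum(bad)
  keep[bad] <- FALSE

  strand_feature <- rep("undefined", n)
  if (!is.null(regions)) {
    strand_feature <- assign_strand(records$chrom, records$pos,
                                    norm$pyrimidine_strand, regions)
  }
  if (spec$use_strand) {
    undef <- keep & strand_feature == "undefined"
    excluded["undefined_strand"] <- sum(undef)
    keep[undef] <- FALSE
  }

  usable <- which(keep)
  if (!length(usable))
    stop("no usable mutations left after exclusions (",
         paste(names(excluded), excluded, sep = "=", collapse = ", "), ")")
  nm <- length(usable)

  if (spec$model == "alexandrov") {
    labels <- paste0(norm$context5[usable], "[", norm$change[usable], "]",
                     norm$context3[usable])
    counts <- table(factor(labels, levels = alexandrov_categories()))
    prof <- genome_profile(as.numeric(counts) / nm, spec,
                           n_mutations = nm, sample = sample)
  } else {
    w <- shiraishi_row_widths(spec)
    m <- matrix(0, nrow = length(w), ncol = 6L)
    m[1L, 1:6] <- tabulate(factor(norm$change[usable], levels = CHANGES),
                           nbins = 6L)
    ctx <- paste0(norm$context5[usable], norm$context3[usable])
    for (k in seq_len(spec$flank_left + spec$flank_right)) {
      b <- substr(ctx, k, k)
      m[1L + k, 1:4] <- tabulate(factor(b, levels = BASES), nbins = 4L)
    }
    if (spec$use_strand) {
      m[nrow(m), 1:2] <- tabulate(factor(strand_feature[usable],
                                         levels = c("plus", "minus")),
                                  nbins = 2L)
    }
    prof <- genome_profile(m / nm, spec, n_mutations = nm, sample = sample)
  }
  attr(prof, "excluded") <- excluded
  prof
}
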