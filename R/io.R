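# "chr" prefixes are the dominant naming mismatch between VCF/BED/FASTA
# sources; all chromosome names are matched after stripping them.
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read an indexed or plain reference FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with chromosome names normalized
#'   (any `"chr"` prefix stripped, description after the first whitespace
#'   dropped).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- normalize_chrom(sub("\\s.*$", "", names(ref)))
  ref
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES & ref != alt
}

#' Read somatic SNVs from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) into mutation records, one per
#' sample-variant pair. If the file has genotype columns, a variant is
#' assigned to every sample whose GT carries the corresponding alt allele;
#' without genotypes the whole file is treated as a single tumor named after
#' the file. Multi-allelic sites are split into one record per alt allele;
#' non-SNV alleles are skipped and counted.
#'
#' @param path VCF file.
#' @param sample_selector Optional character vector restricting the samples
#'   kept.
#' @return Data frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`;
#'   the number of skipped non-SNV alleles in `attr(, "skipped")`.
#' @export
read_vcf <- function(path, sample_selector = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variants in ", path)
  gt <- v@gt
  has_gt <- !is.null(gt) && ncol(gt) > 1L
  default_sample <- tools::file_path_sans_ext(basename(path), compression = TRUE)

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    for (ai in seq_along(alts)) {
      if (!is_snv(fix$REF[i], alts[ai])) {
        skipped <- skipped + 1L
        next
      }
      if (has_gt) {
        fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
        gt_idx <- match("GT", fmt)
        samples <- colnames(gt)[-1L]
        for (s in samples) {
          val <- gt[i, s]
          if (is.na(val)) next
          gtf <- strsplit(val, ":", fixed = TRUE)[[1L]][gt_idx]
          alleles <- strsplit(gtf, "[/|]")[[1L]]
          if (as.character(ai) %in% alleles) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = s, chrom = fix$CHROM[i],
              pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
              stringsAsFactors = FALSE)
          }
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = default_sample, chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no SNVs retained from ", path)
  if (!is.null(sample_selector)) out <- out[out$sample %in% sample_selector, ]
  if (nrow(out) == 0L) stop("no SNVs retained from ", path)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read somatic SNVs from a Mutation Position Format (MPF) file
#'
#' MPF is a tab-separated table with columns sample, chrom, pos (1-based),
#' ref, alt and no mandatory header. A header line is tolerated and detected
#' by a non-numeric third column.
#'
#' @param path MPF file (plain or gzipped).
#' @param header `"auto"` (default), `TRUE`, or `FALSE`.
#' @return As [read_vcf()]: data frame `sample`/`chrom`/`pos`/`ref`/`alt`
#'   with skipped non-SNV count in `attr(, "skipped")`.
#' @export
read_mpf <- function(path, header = "auto") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty MPF file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 5L)
  if (length(bad))
    stop("malformed MPF line ", bad[1L], " in ", path, ": expected 5 ",
         "tab-separated columns, got ", nf[bad[1L]])
  m <- do.call(rbind, fields)
  drop_header <- identical(header, TRUE) ||
    (identical(header, "auto") && is.na(suppressWarnings(as.numeric(m[1L, 3L]))))
  if (drop_header) {
    if (nrow(m) == 1L) stop("no records in ", path)
    m <- m[-1L, , drop = FALSE]
  }
  out <- data.frame(sample = m[, 1L], chrom = m[, 2L],
                    pos = suppressWarnings(as.integer(m[, 3L])),
                    ref = toupper(m[, 4L]), alt = toupper(m[, 5L]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$pos))
    stop("non-numeric position at MPF line ",
         which(is.na(out$pos))[1L] + drop_header, " in ", path)
  snv <- is_snv(out$ref, out$alt)
  skipped <- sum(!snv)
  out <- out[snv, ]
  if (nrow(out) == 0L) stop("no SNVs retained from ", path)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Split mutation records by sample
#'
#' @param records Data frame from [read_vcf()] or [read_mpf()].
#' @return Named list of per-sample data frames.
#' @export
split_by_sample <- function(records) {
  split(records, records$sample)
}

#' Read Alexandrov signatures from a COSMIC-style table
#'
#' Expects a tab-separated table with the columns `Substitution Type`,
#' `Trinucleotide`, `Somatic Mutation Type` and one column per signature,
#' with 96 data rows (the format of the COSMIC v2 signature download).
#' Rows may be in any order; each signature is reordered into the canonical
#' category order and validated.
#'
#' @param path Signature table.
#' @param renormalize Rescale each signature to sum to exactly 1 (published
#'   tables are rounded).
#' @param tolerance Normalization tolerance when `renormalize = FALSE`.
#' @return Named list of `alexandrov_signature`s.
#' @export
read_cosmic_signatures <- function(path, renormalize = FALSE,
                                   tolerance = 1e-3) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  needed <- c("Substitution Type", "Trinucleotide", "Somatic Mutation Type")
  if (!all(needed %in% colnames(tab)))
    stop("not a COSMIC-style signature table: missing columns ",
         paste(setdiff(needed, colnames(tab)), collapse = ", "))
  labels <- tab[["Somatic Mutation Type"]]
  cats <- alexandrov_categories()
  if (anyDuplicated(labels))
    stop("duplicate category: ", labels[duplicated(labels)][1L])
  missing <- setdiff(cats, labels)
  if (length(missing))
    stop("missing category: ", missing[1L])
  sig_cols <- setdiff(colnames(tab), needed)
  sig_cols <- sig_cols[vapply(tab[sig_cols], is.numeric, FALSE)]
  if (!length(sig_cols)) stop("no signature columns in ", path)
  ord <- match(cats, labels)
  sigs <- lapply(sig_cols, function(cn)
    alexandrov_signature(stats::setNames(tab[[cn]][ord], cats), name = cn,
                         renormalize = renormalize, tolerance = tolerance))
  names(sigs) <- sig_cols
  sigs
}

#' Read Shiraishi signatures from flat files
#'
#' Each signature lives in its own whitespace-separated flat file: one line
#' per feature row, six columns with zero padding (see
#' [shiraishi_signature()] for the layout). The [context_spec()] is inferred
#' from the row count and the strand-row zero pattern.
#'
#' @param paths Character vector of files, or a single directory (all
#'   regular files inside are read, in sorted order).
#' @param renormalize,tolerance Passed to [shiraishi_signature()].
#' @return Named list of `shiraishi_signature`s; an error is raised if the
#'   inferred specs differ across the set, since a joint decomposition needs
#'   one common representation.
#' @export
read_shiraishi_signatures <- function(paths, renormalize = FALSE,
                                      tolerance = 1e-10) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, full.names = TRUE))
  if (!length(paths)) stop("no signature files given")
  sigs <- lapply(paths, function(p) {
    m <- as.matrix(utils::read.table(p, header = FALSE))
    if (ncol(m) != 6L)
      stop("signature file ", p, ": expected 6 columns, got ", ncol(m))
    shiraishi_signature(m, name = tools::file_path_sans_ext(basename(p)),
                        renormalize = renormalize, tolerance = tolerance)
  })
  names(sigs) <- vapply(sigs, function(s) s$name, "")
  specs <- unique(vapply(sigs, function(s) format(s$spec), ""))
  if (length(specs) > 1L)
    stop("inconsistent context specs across signature set: ",
         paste(specs, collapse = " vs "))
  sigs
}

#' Write a signature to a flat file
#'
#' Writes the dialect [read_shiraishi_signatures()] accepts (for Shiraishi
#' signatures: one feature row per line, 6 zero-padded columns) or, for an
#' Alexandrov signature, its 96 probabilities with category labels. The
#' round trip is safe to 10 significant digits.
#'
#' @param sig A signature.
#' @param path Output file.
#' @export
write_signature <- function(sig, path) {
  if (inherits(sig, "shiraishi_signature")) {
    utils::write.table(format(sig$matrix, digits = 10, scientific = FALSE,
                              trim = TRUE),
                       path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (inherits(sig, "alexandrov_signature")) {
    utils::write.table(data.frame(category = names(sig$probs),
                                  probability = format(sig$probs, digits = 10)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("not a signature")
  invisible(path)
}

#' Read transcription-stranded regions from a BED6 file
#'
#' BED's 0-based half-open coordinates are converted to 1-based inclusive
#' internally (via [rtracklayer::import()]). Chromosome names are normalized
#' like everywhere else ("chr" prefix stripped). Positions covered by
#' regions on both strands are treated as strand-ambiguous by
#' [assign_strand()].
#'
#' @param path BED6 file.
#' @return A [GenomicRanges::GRanges] with strand information.
#' @export
read_stranded_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr)) {
    sn <- normalize_chrom(as.character(GenomicRanges::seqnames(gr)))
    gr <- GenomicRanges::GRanges(sn, IRanges::IRanges(
      BiocGenerics::start(gr), BiocGenerics::end(gr)),
      strand = BiocGenerics::strand(gr))
    if (any(as.character(BiocGenerics::strand(gr)) == "*"))
      stop("BED file ", path, " has regions without strand")
  }
  gr
}

#' Write a table of signature exposures
#'
#' Serializes one or more [decompose_tumor()] fits into a tab-separated
#' table: one row per tumor, one column per signature (signatures outside
#' the selected subset written as 0), plus `explained_variance`, `rss`, and
#' a comma-separated `subset` annotation.
#'
#' @param results A `tumor_decomposition` or list of them (one signature
#'   set).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_exposures <- function(results, path) {
  if (inherits(results, "tumor_decomposition")) results <- list(results)
  signames <- names(results[[1L]]$exposures)
  rows <- lapply(results, function(r) {
    stopifnot(identical(names(r$exposures), signames))
    cbind(data.frame(sample = r$genome$sample, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$exposures), check.names = FALSE),
          data.frame(explained_variance = r$explained_variance, rss = r$rss,
                     subset = paste(r$subset, collapse = ",")))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
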