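#' Mutation context specification
#'
#' A `context_spec` describes the sequence context used to classify a somatic
#' single-nucleotide variant: how many flanking bases on each side of the
#' mutated base are considered, whether the transcription strand is part of
#' the model, and which of the two signature models the classification feeds.
#'
#' Under the `"alexandrov"` model all context features are modelled jointly,
#' giving `6 * 4^(flank_left + flank_right)` categories (96 for the canonical
#' one-base flanks). Under the `"shiraishi"` model the base change, each
#' flanking position, and (optionally) the transcription strand are treated as
#' independent features, giving
#' `6 + 4 * (flank_left + flank_right) + 2 * use_strand` free parameters
#' (14 for trinucleotides; 24 for two flanking bases per side plus strand).
#'
#' @param flank_left Number of 5' flanking bases (non-negative integer).
#' @param flank_right Number of 3' flanking bases (non-negative integer).
#' @param use_strand Logical; include the transcription-strand feature
#'   (Shiraishi model only).
#' @param model `"shiraishi"` or `"alexandrov"`.
#' @return An object of class `context_spec`.
#' @examples
#' n_parameters(context_spec(1, 1, FALSE, "alexandrov"))  # 96
#' n_parameters(context_spec(1, 1, FALSE, "shiraishi"))   # 14
#' n_parameters(context_spec(2, 2, TRUE, "shiraishi"))    # 24
#' @export
context_spec <- function(flank_left = 1L, flank_right = 1L,
                         use_strand = FALSE,
                         model = c("shiraishi", "alexandrov")) {
  model <- match.arg(model)
  flank_left <- as.integer(flank_left)
  flank_right <- as.integer(flank_right)
  stopifnot(length(flank_left) == 1L, length(flank_right) == 1L,
            length(use_strand) == 1L, is.logical(use_strand),
            !is.na(flank_left), !is.na(flank_right), !is.na(use_strand))
  if (flank_left < 0L || flank_right < 0L)
    stop("flank counts must be non-negative")
  if (model == "alexandrov") {
    if (use_strand)
      stop("the alexandrov model does not carry a transcription-strand feature")
    if (flank_left != 1L || flank_right != 1L)
      stop("only the canonical 96-category alexandrov model ",
           "(one flanking base on each side) is supported")
  }
  structure(list(flank_left = flank_left, flank_right = flank_right,
                 use_strand = use_strand, model = model),
            class = "context_spec")
}

#' Number of model parameters for a context specification
#'
#' @param spec A [context_spec()].
#' @return Integer: 6 * 4^(l+r) for the joint (alexandrov) model,
#'   6 + 4*(l+r) + 2*use_strand for the independent-feature (shiraishi) model.
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "context_spec"))
  nf <- spec$flank_left + spec$flank_right
  if (spec$model == "alexandrov") as.integer(6L * 4L^nf)
  else 6L + 4L * nf + 2L * as.integer(spec$use_strand)
}

#' @export
print.context_spec <- function(x, ...) {
  cat(sprintf("<context_spec> %s model: %d + %d flanking bases%s (%d parameters)\n",
              x$model, x$flank_left, x$flank_right,
              if (x$use_strand) ", transcription strand" else "",
              n_parameters(x)))
  invisible(x)
}

#' @export
format.context_spec <- function(x, ...) {
  sprintf("%s(%d,%d%s)", x$model, x$flank_left, x$flank_right,
          if (x$use_strand) ",strand" else "")
}

same_spec <- function(a, b) {
  identical(a$model, b$model) &&
    a$flank_left == b$flank_left &&
    a$flank_right == b$flank_right &&
    a$use_strand == b$use_strand
}

# row labels of the Shiraishi feature matrix, in fixed reading order:
# base change, flanking positions 5'->3', optional strand
shiraishi_row_names <- function(spec) {
  pos <- c()
  if (spec$flank_left > 0L) pos <- paste0("-", rev(seq_len(spec$flank_left)))
  if (spec$flank_right > 0L) pos <- c(pos, paste0("+", seq_len(spec$flank_right)))
  c("change", pos, if (spec$use_strand) "strand")
}

# number of valid (unpadded) entries per feature row
shiraishi_row_widths <- function(spec) {
  c(6L, rep(4L, spec$flank_left + spec$flank_right),
    if (spec$use_strand) 2L)
}

BASES <- c("A", "C", "G", "T")
CHANGES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96 trinucleotide mutation categories
#'
#' Category labels in canonical COSMIC order: substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G; within each class the 5' base and then the
#' 3' base each cycle through A, C, G, T.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`.
#' @export
alexandrov_categories <- function() {
  unlist(lapply(CHANGES, function(ch)
    unlist(lapply(BASES, function(b5)
      paste0(b5, "[", ch, "]", BASES)))))
}
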