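#' Construct an Alexandrov-type (96-category) mutational signature
#'
#' An Alexandrov signature is a probability distribution over the 96
#' pyrimidine-centered trinucleotide mutation categories.
#'
#' @param probs Numeric vector of 96 probabilities. If named, entries are
#'   reordered into the canonical category order (see
#'   [alexandrov_categories()]); unnamed vectors are assumed to already be in
#'   canonical order.
#' @param name Signature identifier.
#' @param renormalize If `TRUE`, rescale `probs` to sum to exactly 1 (useful
#'   for published tables rounded to few digits); off by default.
#' @param tolerance Normalization tolerance passed to [validate_signature()].
#' @return An object of class `alexandrov_signature`.
#' @export
alexandrov_signature <- function(probs, name = "signature",
                                 renormalize = FALSE, tolerance = 1e-10) {
  cats <- alexandrov_categories()
  probs <- as.numeric_named(probs)
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), cats))
      stop("named probability vector does not cover the 96 canonical categories")
    probs <- probs[cats]
  } else {
    if (length(probs) != 96L)
      stop("an alexandrov signature needs 96 probabilities, got ", length(probs))
    names(probs) <- cats
  }
  if (renormalize) probs <- probs / sum(probs)
  sig <- structure(list(probs = probs,
                        spec = context_spec(1L, 1L, FALSE, "alexandrov"),
                        name = name),
                   class = c("alexandrov_signature", "mutsig"))
  validate_signature(sig, tolerance = tolerance)
}

as.numeric_named <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  x
}

#' Construct a Shiraishi-type (independent-feature) mutational signature
#'
#' A Shiraishi signature is a feature-row probability matrix with 6 columns:
#' row `"change"` is the distribution over the six pyrimidine-centered base
#' changes (C>A, C>G, C>T, T>A, T>C, T>G); each flanking-position row is a
#' distribution over A, C, G, T (columns 5-6 padded with zeros), ordered
#' 5' to 3' (-flank_left ... -1, +1 ... +flank_right); an optional final
#' `"strand"` row is the distribution over (plus, minus) with columns 3-6
#' padded with zeros.
#'
#' @param matrix Numeric matrix with 6 columns and one row per feature.
#' @param spec A [context_spec()]; if `NULL`, inferred from the matrix: a last
#'   row whose columns 3-6 are all zero is taken as the strand row, and the
#'   remaining flanking rows are split evenly between the 5' and 3' side.
#' @param name Signature identifier.
#' @param renormalize If `TRUE`, rescale each feature row to sum to exactly 1.
#' @param tolerance Normalization tolerance passed to [validate_signature()].
#' @return An object of class `shiraishi_signature`.
#' @export
shiraishi_signature <- function(matrix, spec = NULL, name = "signature",
                                renormalize = FALSE, tolerance = 1e-10) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) != 6L)
    stop("a shiraishi feature matrix must have 6 columns, got ", ncol(matrix))
  if (is.null(spec)) spec <- infer_context_spec(matrix)
  stopifnot(inherits(spec, "context_spec"))
  if (spec$model != "shiraishi")
    stop("spec must describe a shiraishi model")
  nr <- 1L + spec$flank_left + spec$flank_right + as.integer(spec$use_strand)
  if (nrow(matrix) != nr)
    stop(sprintf("feature matrix has %d rows but spec %s requires %d",
                 nrow(matrix), format(spec), nr))
  dimnames(matrix) <- list(shiraishi_row_names(spec), NULL)
  if (renormalize) {
    w <- shiraishi_row_widths(spec)
    for (i in seq_len(nr)) {
      matrix[i, seq_len(w[i])] <- matrix[i, seq_len(w[i])] / sum(matrix[i, seq_len(w[i])])
      matrix[i, setdiff(1:6, seq_len(w[i]))] <- 0
    }
  }
  sig <- structure(list(matrix = matrix, spec = spec, name = name),
                   class = c("shiraishi_signature", "mutsig"))
  validate_signature(sig, tolerance = tolerance)
}

# Infer a shiraishi context_spec from a 6-column feature matrix.
# Rule: a final row with zeros in columns 3-6 is the strand row; remaining
# rows after the change row are flanking rows, split evenly 5'/3'.
infer_context_spec <- function(matrix) {
  nr <- nrow(matrix)
  if (nr < 3L)
    stop("too few feature rows (", nr, "): need at least a change row and ",
         "one flanking row per side")
  has_strand <- all(matrix[nr, 3:6] == 0)
  nflank <- nr - 1L - as.integer(has_strand)
  if (nflank < 1L) stop("too few feature rows: no flanking rows left")
  if (nflank %% 2L != 0L)
    stop("cannot infer flank split from ", nflank, " flanking rows; ",
         "pass an explicit context_spec for asymmetric flanks")
  context_spec(nflank %/% 2L, nflank %/% 2L, has_strand, "shiraishi")
}

#' Validate a signature or genome profile
#'
#' Checks the representation invariants of a signature (or genome profile in
#' the same representation): expected shape for its [context_spec()],
#' non-negative entries, probability rows (or the whole vector) summing to 1
#' within `tolerance`, and hard-zero padding entries.
#'
#' @param sig An `alexandrov_signature`, `shiraishi_signature`, or
#'   [genome_profile()].
#' @param tolerance Allowed absolute deviation of a probability sum from 1.
#' @return The validated object, invisibly unchanged; errors otherwise.
#' @export
validate_signature <- function(sig, tolerance = 1e-10) {
  UseMethod("validate_signature")
}

#' @export
validate_signature.alexandrov_signature <- function(sig, tolerance = 1e-10) {
  validate_alexandrov_vector(sig$probs, tolerance, what = sig$name)
  sig
}

#' @export
validate_signature.shiraishi_signature <- function(sig, tolerance = 1e-10) {
  validate_shiraishi_matrix(sig$matrix, sig$spec, tolerance, what = sig$name)
  sig
}

#' @export
validate_signature.genome_profile <- function(sig, tolerance = 1e-10) {
  if (sig$spec$model == "alexandrov")
    validate_alexandrov_vector(sig$data, tolerance, what = sig$sample)
  else
    validate_shiraishi_matrix(sig$data, sig$spec, tolerance, what = sig$sample)
  if (!is.na(sig$n_mutations) && sig$n_mutations < 1L)
    stop("genome profile '", sig$sample, "': n_mutations must be >= 1")
  sig
}

validate_alexandrov_vector <- function(probs, tolerance, what = "signature") {
  if (length(probs) != 96L)
    stop("'", what, "': expected 96 probabilities, got ", length(probs))
  neg <- which(probs < 0)
  if (length(neg))
    stop("'", what, "': negative probability at category ",
         alexandrov_categories()[neg[1L]])
  if (abs(sum(probs) - 1) > tolerance)
    stop(sprintf("'%s': not normalized (sum = %.12g)", what, sum(probs)))
  invisible(probs)
}

validate_shiraishi_matrix <- function(mat, spec, tolerance, what = "signature") {
  nr <- 1L + spec$flank_left + spec$flank_right + as.integer(spec$use_strand)
  if (!is.matrix(mat) || nrow(mat) != nr || ncol(mat) != 6L)
    stop(sprintf("'%s': expected a %d x 6 feature matrix for spec %s",
                 what, nr, format(spec)))
  w <- shiraishi_row_widths(spec)
  rn <- shiraishi_row_names(spec)
  for (i in seq_len(nr)) {
    valid <- seq_len(w[i])
    if (any(mat[i, valid] < 0))
      stop("'", what, "': negative entry in feature row ", rn[i])
    if (abs(sum(mat[i, valid]) - 1) > tolerance)
      stop(sprintf("'%s': feature row %s not normalized (sum = %.12g)",
                   what, rn[i], sum(mat[i, valid])))
    pad <- setdiff(1:6, valid)
    if (length(pad) && any(mat[i, pad] != 0))
      stop("'", what, "': padding entries of feature row ", rn[i],
           " must be exactly 0")
  }
  invisible(mat)
}

#' Convert an Alexandrov signature to the Shiraishi model
#'
#' Marginalizes the joint 96-category distribution into the three independent
#' features of a trinucleotide Shiraishi signature: the base-change row sums
#' the probabilities of the 16 contexts within each substitution class, and
#' the 5'/3' flanking rows sum over the 24 categories carrying each flanking
#' base. Marginals are plain sums weighted by total category probability, so
#' the overall base composition of the signature's mutations is preserved.
#'
#' @param a An `alexandrov_signature`.
#' @param renormalize If `TRUE`, renormalize the input vector before
#'   marginalizing (for tables rounded to few digits).
#' @return A `shiraishi_signature` with spec (1, 1, no strand).
#' @export
convert_alexandrov_to_shiraishi <- function(a, renormalize = FALSE) {
  stopifnot(inherits(a, "alexandrov_signature"))
  validate_signature(a)
  p <- a$probs
  if (renormalize) p <- p / sum(p)
  cats <- alexandrov_categories()
  ch <- substr(cats, 3L, 5L)            # "C>A" etc.
  b5 <- substr(cats, 1L, 1L)
  b3 <- substr(cats, 7L, 7L)
  m <- rbind(
    c(vapply(CHANGES, function(x) sum(p[ch == x]), 0)),
    c(vapply(BASES, function(x) sum(p[b5 == x]), 0), 0, 0),
    c(vapply(BASES, function(x) sum(p[b3 == x]), 0), 0, 0))
  shiraishi_signature(m, spec = context_spec(1L, 1L, FALSE, "shiraishi"),
                      name = a$name)
}

#' Downgrade a Shiraishi signature to a smaller context
#'
#' Removes outermost flanking rows and/or the transcription-strand row.
#' Because the model's features are independent, the remaining rows are
#' unchanged (no renormalization is needed).
#'
#' @param s A `shiraishi_signature`.
#' @param flank_left,flank_right Target flank counts (each at most the
#'   current count).
#' @param keep_strand Keep the strand row (only if the input has one).
#' @return A `shiraishi_signature` with the reduced [context_spec()].
#' @export
downgrade_shiraishi <- function(s, flank_left, flank_right,
                                keep_strand = FALSE) {
  stopifnot(inherits(s, "shiraishi_signature"))
  sp <- s$spec
  flank_left <- as.integer(flank_left)
  flank_right <- as.integer(flank_right)
  if (flank_left > sp$flank_left || flank_right > sp$flank_right)
    stop(sprintf("target flanks (%d,%d) exceed available flanks (%d,%d)",
                 flank_left, flank_right, sp$flank_left, sp$flank_right))
  if (keep_strand && !sp$use_strand)
    stop("input signature has no transcription-strand row to keep")
  new_spec <- context_spec(flank_left, flank_right, keep_strand, "shiraishi")
  # row indices to keep: change; inner flanks; optional strand
  left_rows <- if (flank_left > 0L)
    1L + (sp$flank_left - flank_left + 1L):sp$flank_left else integer()
  right_rows <- if (flank_right > 0L)
    1L + sp$flank_left + seq_len(flank_right) else integer()
  rows <- c(1L, left_rows, right_rows,
            if (keep_strand) nrow(s$matrix))
  shiraishi_signature(s$matrix[rows, , drop = FALSE], spec = new_spec,
                      name = s$name)
}

#' Construct a genome profile (tumor mutational catalog)
#'
#' A genome profile expresses the somatic SNVs of one tumor in the same
#' representation as a signature of the matching model: a 96-entry frequency
#' vector (alexandrov) or a feature-row frequency matrix (shiraishi).
#'
#' @param data Numeric vector (alexandrov) or 6-column matrix (shiraishi).
#' @param spec The [context_spec()] of the representation.
#' @param n_mutations Number of SNVs the profile was built from (`NA` for
#'   synthetic reference profiles such as [flat_genome()]).
#' @param sample Sample identifier.
#' @return An object of class `genome_profile`.
#' @export
genome_profile <- function(data, spec, n_mutations = NA_integer_,
                           sample = "tumor") {
  stopifnot(inherits(spec, "context_spec"))
  if (spec$model == "alexandrov") {
    data <- as.numeric_named(data)
    if (is.null(names(data))) names(data) <- alexandrov_categories()
  } else {
    data <- as.matrix(data)
    storage.mode(data) <- "double"
    dimnames(data) <- list(shiraishi_row_names(spec), NULL)
  }
  prof <- structure(list(data = data, spec = spec,
                         n_mutations = as.integer(n_mutations),
                         sample = sample),
                    class = "genome_profile")
  validate_signature(prof)
}

#' The flat (uniform) genome profile
#'
#' The reference profile of a tumor with uniform mutation frequencies: 1/96
#' per category for the joint model; for the independent-feature model 1/6
#' per base change, 1/4 per flanking base, and 1/2 per strand. Used as the
#' baseline in the explained-variance computation for Shiraishi models.
#'
#' @param spec A [context_spec()].
#' @return A [genome_profile()] named `"flat"` with `n_mutations = NA`.
#' @export
flat_genome <- function(spec) {
  stopifnot(inherits(spec, "context_spec"))
  if (spec$model == "alexandrov") {
    genome_profile(rep(1 / 96, 96L), spec, sample = "flat")
  } else {
    w <- shiraishi_row_widths(spec)
    m <- t(vapply(w, function(k) c(rep(1 / k, k), rep(0, 6L - k)), numeric(6)))
    genome_profile(m, spec, sample = "flat")
  }
}

#' Flatten a signature or profile to its parameter vector
#'
#' Shiraishi feature matrices are flattened row-major over the valid
#' (unpadded) entries into a length-P vector; Alexandrov vectors are returned
#' as-is (P = 96).
#'
#' @param x A signature or [genome_profile()].
#' @return Numeric vector of length [n_parameters()] of the object's spec.
#' @export
flatten <- function(x) UseMethod("flatten")

#' @export
flatten.alexandrov_signature <- function(x) unname(x$probs)

#' @export
flatten.shiraishi_signature <- function(x) flatten_shiraishi(x$matrix, x$spec)

#' @export
flatten.genome_profile <- function(x) {
  if (x$spec$model == "alexandrov") unname(x$data)
  else flatten_shiraishi(x$data, x$spec)
}

flatten_shiraishi <- function(mat, spec) {
  w <- shiraishi_row_widths(spec)
  unlist(lapply(seq_along(w), function(i) mat[i, seq_len(w[i])]),
         use.names = FALSE)
}

# inverse of flatten_shiraishi: parameter vector -> padded feature matrix
unflatten_shiraishi <- function(v, spec) {
  w <- shiraishi_row_widths(spec)
  stopifnot(length(v) == sum(w))
  off <- 0L
  m <- matrix(0, nrow = length(w), ncol = 6L)
  for (i in seq_along(w)) {
    m[i, seq_len(w[i])] <- v[off + seq_len(w[i])]
    off <- off + w[i]
  }
  m
}

#' @export
print.mutsig <- function(x, ...) {
  cat(sprintf("<%s> '%s' [%s]\n", class(x)[1L], x$name, format(x$spec)))
  if (inherits(x, "shiraishi_signature")) {
    print(round(x$matrix, 4))
  } else {
    top <- sort(x$probs, decreasing = TRUE)[1:5]
    cat("top categories:\n")
    print(round(top, 4))
  }
  invisible(x)
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("<genome_profile> '%s' [%s], n_mutations = %s\n",
              x$sample, format(x$spec),
              ifelse(is.na(x$n_mutations), "NA", x$n_mutations)))
  invisible(x)
}
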