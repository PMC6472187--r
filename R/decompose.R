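#' Stack a signature set into a P x K parameter matrix
#'
#' @param signatures List of signatures sharing one [context_spec()].
#' @return Numeric matrix with one flattened signature per column, columns
#'   named by signature name.
#' @export
signature_matrix <- function(signatures) {
  if (inherits(signatures, "mutsig")) signatures <- list(signatures)
  if (length(signatures) == 0L) stop("empty signature set")
  spec <- signatures[[1L]]$spec
  ok <- vapply(signatures, function(s) same_spec(s$spec, spec), FALSE)
  if (!all(ok))
    stop("signatures have mixed context specs: ",
         paste(unique(vapply(signatures, function(s) format(s$spec), "")),
               collapse = " vs "))
  S <- vapply(signatures, flatten, numeric(n_parameters(spec)))
  colnames(S) <- vapply(signatures, function(s) s$name, "")
  S
}

#' Nearest positive definite matrix
#'
#' Returns a symmetric positive definite matrix close to `M` in Frobenius
#' norm. If `M` is already positive definite (smallest eigenvalue larger than
#' `eps * ||M||_2`), it is returned unchanged; otherwise the correction of
#' [Matrix::nearPD()] (alternating projections with eigenvalue clipping) is
#' applied. Used to regularize the Gram matrix of a signature set before
#' quadratic programming; residuals and explained variance are always
#' evaluated against the uncorrected matrix.
#'
#' @param M Square symmetric numeric matrix.
#' @param eps Relative eigenvalue floor deciding whether `M` already counts
#'   as positive definite.
#' @return Symmetric positive definite matrix of the same dimension.
#' @export
nearest_positive_definite <- function(M, eps = 1e-12) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("M must be a square matrix")
  if (!isSymmetric(M, tol = 1e-8))
    stop("M must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] > 0 && ev[length(ev)] > eps * ev[1L]) return(M)
  out <- Matrix::nearPD(M, eig.tol = eps, posd.tol = eps,
                        ensureSymmetry = TRUE)
  as.matrix(out$mat)
}

# Primal active-set solver for
#   min 0.5 w'Qw - d'w   s.t.  sum(w) = 1, w >= 0
# with Q symmetric positive definite. Free variables are solved through the
# KKT system with the equality constraint; bound variables enter on negative
# multipliers, blocking variables leave along the feasible line step.
solve_simplex_qp <- function(Q, d, tol = 1e-12) {
  K <- length(d)
  if (K == 1L) return(1)
  free <- rep(TRUE, K)
  w <- rep(1 / K, K)
  scale <- max(abs(Q)) + max(abs(d))
  dtol <- 1e-10 * max(scale, 1)
  kkt <- function(free) {
    k <- sum(free)
    A <- rbind(cbind(Q[free, free, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    sol <- solve(A, c(d[free], 1))
    list(z = sol[seq_len(k)], lambda = sol[k + 1L])
  }
  for (iter in seq_len(100L * K)) {
    sol <- kkt(free)
    z <- numeric(K)
    z[free] <- sol$z
    if (all(z[free] >= -tol)) {
      w <- pmax(z, 0)
      # dual feasibility of the variables held at zero
      mu <- as.numeric(Q %*% w) - d + sol$lambda
      viol <- which(!free & mu < -dtol)
      if (!length(viol)) return(w / sum(w))
      free[viol[which.min(mu[viol])]] <- TRUE
    } else {
      # step from the current feasible point towards z until a free
      # variable hits its bound
      blocking <- which(free & z < w & z < tol)
      alpha <- (w[blocking]) / (w[blocking] - z[blocking])
      j <- blocking[which.min(alpha)]
      a <- max(0, min(1, min(alpha)))
      w <- w + a * (z - w)
      w[j] <- 0
      free[j] <- FALSE
      if (sum(free) == 0L) { # numerical corner: restart from best vertex
        free[which.max(d - diag(Q) / 2)] <- TRUE
      }
    }
  }
  stop("simplex QP solver failed to converge; Gram matrix condition number: ",
       format(kappa(Q), digits = 3))
}

#' Estimate signature exposures for one genome profile
#'
#' Solves the simplex-constrained least-squares problem at the heart of
#' signature refitting: find non-negative weights `w` summing to 1 that
#' minimize `||g - S w||^2`, equivalently the quadratic program
#' `min -g'Sw + 0.5 w'S'Sw` subject to `sum(w) = 1, w >= 0`. The Gram matrix
#' `S'S` is replaced by its nearest positive definite matrix when needed so
#' the program is strictly convex; the residual sum of squares is always
#' computed from the uncorrected `S`.
#'
#' @param g Numeric parameter vector of the genome profile (see [flatten()]),
#'   or a [genome_profile()].
#' @param S Numeric P x K matrix of flattened signatures (see
#'   [signature_matrix()]), or a list of signatures.
#' @param clamp Weights below this value are set to 0 and the rest
#'   renormalized (QP returns tiny values at active constraints).
#' @return List with `weights` (named exposure vector on the simplex) and
#'   `rss` (residual sum of squares against the uncorrected `S`).
#' @export
solve_exposures <- function(g, S, clamp = 1e-8) {
  if (inherits(g, "genome_profile")) g <- flatten(g)
  if (is.list(S)) S <- signature_matrix(S)
  if (!is.matrix(S)) S <- matrix(S, ncol = 1L)
  if (length(g) != nrow(S))
    stop("profile length ", length(g), " does not match signature length ",
         nrow(S))
  K <- ncol(S)
  Q <- nearest_positive_definite(crossprod(S))
  d <- as.numeric(crossprod(S, g))
  w <- solve_simplex_qp(Q, d)
  w[w < clamp] <- 0
  w <- w / sum(w)
  names(w) <- colnames(S)
  rss <- sum((g - as.numeric(S %*% w))^2)
  list(weights = w, rss = rss)
}

#' Fraction of variance explained by a decomposition
#'
#' Computes `R^2 = 1 - sum((g - ghat)^2) / sum((g - ref)^2)` where `ghat` is
#' the catalog predicted from the fitted exposures. The baseline `ref` is the
#' mean frequency for the joint 96-category model (equal to 1/96 for a
#' normalized catalog) and the flat genome profile for the independent-feature
#' model, whose features have different numbers of states.
#'
#' @param g Parameter vector of the observed profile, or a [genome_profile()].
#' @param ghat Parameter vector of the predicted profile `S w`.
#' @param spec The [context_spec()] of the representation (taken from `g`
#'   when `g` is a profile).
#' @return The explained-variance fraction (at most 1; can be negative for
#'   fits worse than the flat baseline).
#' @export
explained_variance <- function(g, ghat, spec = NULL) {
  if (inherits(g, "genome_profile")) {
    spec <- g$spec
    g <- flatten(g)
  }
  if (is.null(spec)) stop("spec required when g is a bare vector")
  ref <- if (spec$model == "alexandrov") mean(g) else flatten(flat_genome(spec))
  denom <- sum((g - ref)^2)
  if (denom <= 0)
    stop("degenerate input: profile equals the flat genome, ",
         "explained variance is undefined")
  1 - sum((g - ghat)^2) / denom
}

#' Decompose a tumor genome into mutational signature exposures
#'
#' The main fitting function. Given a tumor's [genome_profile()] and a
#' compatible set of signatures, estimates the exposure (contribution) of
#' each signature by simplex-constrained quadratic programming
#' ([solve_exposures()]).
#'
#' By default all signatures are used. If `min_explained_variance` is given,
#' subsets of size `min_num_signatures` to `max_num_signatures` are searched:
#' for each size k, all `choose(K, k)` subsets are fitted, and the search
#' stops at the first k at which some subset reaches the threshold, returning
#' the subset with the highest explained variance at that k. If no subset
#' reaches the threshold, the overall best fit is returned with
#' `threshold_reached = FALSE`. If `min_explained_variance` is `NULL` but
#' `max_num_signatures < K`, the exhaustively best subset of exactly that
#' size is returned. Ties are broken by lexicographic subset order.
#'
#' Exhaustive enumeration is guarded by `max_subsets`; sizes whose subset
#' count exceeds it fall back to greedy forward selection (or set
#' `greedy = TRUE` to use greedy selection throughout).
#'
#' @param genome A [genome_profile()].
#' @param signatures List of signatures sharing the profile's
#'   [context_spec()].
#' @param min_explained_variance Threshold in `[0, 1]`, or `NULL` (default)
#'   for a plain full-set (or fixed-size) decomposition.
#' @param min_num_signatures,max_num_signatures Subset size bounds (defaults
#'   2 and K).
#' @param greedy Use greedy forward selection instead of exhaustive subset
#'   enumeration.
#' @param max_subsets Cap on `choose(K, k)` above which size k is searched
#'   greedily.
#' @return An object of class `tumor_decomposition` with components
#'   `exposures` (full-length named vector, zero outside the selected
#'   subset), `subset` (names of signatures used), `rss`,
#'   `explained_variance`, `threshold_reached`, `spec`, `genome`, and the
#'   signature matrix used.
#' @seealso [explained_variance_curve()], [solve_exposures()]
#' @examples
#' spec <- context_spec(1, 1, FALSE, "shiraishi")
#' sigs <- random_signature_set(4, spec, seed = 7, min_separation = 0.5)
#' g <- simulate_genome(sigs, make_exposures(4, c(1, 2), c(0.6, 0.4)),
#'                      n_mutations = 5000, seed = 1)
#' fit <- decompose_tumor(g, sigs)
#' coef(fit)
#' @export
decompose_tumor <- function(genome, signatures,
                            min_explained_variance = NULL,
                            min_num_signatures = 2L,
                            max_num_signatures = NULL,
                            greedy = FALSE,
                            max_subsets = 2e5) {
  stopifnot(inherits(genome, "genome_profile"))
  S <- signature_matrix(signatures)
  K <- ncol(S)
  if (any(duplicated(colnames(S))))
    colnames(S) <- make.unique(colnames(S))
  if (!same_spec(genome$spec, signatures[[1L]]$spec))
    stop("genome profile and signatures have different context specs")
  g <- flatten(genome)
  if (is.null(max_num_signatures)) max_num_signatures <- K
  min_num_signatures <- min(as.integer(min_num_signatures), K)
  max_num_signatures <- min(as.integer(max_num_signatures), K)
  if (max_num_signatures < min_num_signatures)
    stop("max_num_signatures < min_num_signatures")

  fit_subset <- function(idx) {
    fit <- solve_exposures(g, S[, idx, drop = FALSE])
    ev <- explained_variance(g, as.numeric(S[, idx, drop = FALSE] %*% fit$weights),
                             genome$spec)
    list(idx = idx, weights = fit$weights, rss = fit$rss, ev = ev)
  }

  if (is.null(min_explained_variance) && max_num_signatures == K) {
    best <- fit_subset(seq_len(K))
    reached <- NA
  } else {
    threshold <- if (is.null(min_explained_variance)) Inf
                 else min_explained_variance
    sizes <- if (is.null(min_explained_variance)) max_num_signatures
             else min_num_signatures:max_num_signatures
    best <- NULL
    reached <- FALSE
    for (k in sizes) {
      best_k <- best_subset_of_size(g, S, k, genome$spec, fit_subset,
                                    greedy = greedy || choose(K, k) > max_subsets)
      if (is.null(best) || best_k$ev > best$ev) best <- best_k
      if (best_k$ev >= threshold) {
        best <- best_k
        reached <- TRUE
        break
      }
    }
    if (is.null(min_explained_variance)) reached <- NA
  }

  exposures <- numeric(K)
  names(exposures) <- colnames(S)
  exposures[best$idx] <- best$weights
  structure(list(exposures = exposures,
                 subset = colnames(S)[best$idx],
                 rss = best$rss,
                 explained_variance = best$ev,
                 threshold = min_explained_variance,
                 threshold_reached = reached,
                 spec = genome$spec,
                 genome = genome,
                 S = S,
                 call = match.call()),
            class = "tumor_decomposition")
}

# best subset of exactly k signatures: exhaustive over combn unless greedy
best_subset_of_size <- function(g, S, k, spec, fit_subset, greedy = FALSE) {
  K <- ncol(S)
  if (!greedy) {
    best <- NULL
    sets <- utils::combn(K, k)
    for (j in seq_len(ncol(sets))) {
      fit <- fit_subset(sets[, j])
      if (is.null(best) || fit$ev > best$ev) best <- fit  # ties: first wins
    }
    best
  } else {
    idx <- integer()
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(K), idx)
      fits <- lapply(cand, function(j) fit_subset(sort(c(idx, j))))
      best <- fits[[which.max(vapply(fits, `[[`, 0, "ev"))]]
      idx <- best$idx
    }
    best
  }
}

#' Best explained variance as a function of subset size
#'
#' For each subset size k = 1..K, finds the subset of signatures with the
#' highest explained variance (exhaustively, or greedily above
#' `max_subsets`). The curve is non-decreasing in k, since a larger subset
#' can always zero-out the extra signatures.
#'
#' @inheritParams decompose_tumor
#' @return A data frame with columns `k`, `explained_variance`, and `subset`
#'   (comma-separated signature names), of class `ev_curve`.
#' @export
explained_variance_curve <- function(genome, signatures, greedy = FALSE,
                                     max_subsets = 2e5) {
  stopifnot(inherits(genome, "genome_profile"))
  S <- signature_matrix(signatures)
  g <- flatten(genome)
  K <- ncol(S)
  fit_subset <- function(idx) {
    fit <- solve_exposures(g, S[, idx, drop = FALSE])
    ev <- explained_variance(g, as.numeric(S[, idx, drop = FALSE] %*% fit$weights),
                             genome$spec)
    list(idx = idx, weights = fit$weights, rss = fit$rss, ev = ev)
  }
  rows <- lapply(seq_len(K), function(k) {
    best <- best_subset_of_size(g, S, k, genome$spec, fit_subset,
                                greedy = greedy || choose(K, k) > max_subsets)
    data.frame(k = k, explained_variance = best$ev,
               subset = paste(colnames(S)[best$idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ev_curve", "data.frame")
  out
}
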