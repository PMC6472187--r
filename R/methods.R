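#' @export
print.tumor_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("Tumor decomposition of '%s' [%s]\n",
              x$genome$sample, format(x$spec)))
  cat(sprintf("  signatures: %d of %d used; rss = %.4g; explained variance = %.4f\n",
              length(x$subset), length(x$exposures), x$rss,
              x$explained_variance))
  if (!is.na(x$threshold_reached) && !is.null(x$threshold))
    cat(sprintf("  minimum explained variance %.3f %s\n", x$threshold,
                if (isTRUE(x$threshold_reached)) "reached" else "NOT reached"))
  cat("Exposures:\n")
  print(round(x$exposures[x$exposures > 0], digits))
  invisible(x)
}

#' @export
coef.tumor_decomposition <- function(object, all = TRUE, ...) {
  if (all) object$exposures else object$exposures[object$subset]
}

#' @export
fitted.tumor_decomposition <- function(object, ...) {
  as.numeric(object$S %*% object$exposures)
}

#' @export
residuals.tumor_decomposition <- function(object, ...) {
  flatten(object$genome) - fitted(object)
}

#' Predicted mutational catalog of a decomposition
#'
#' Reconstructs the catalog `S w` implied by the fitted exposures as a
#' [genome_profile()] in the model's representation. With `newdata`, the
#' fitted exposures are applied to a different signature set of the same
#' size and spec.
#'
#' @param object A `tumor_decomposition`.
#' @param newdata Optional list of signatures replacing the fitted set.
#' @param ... Unused.
#' @return A [genome_profile()] (rows renormalized exactly where the
#'   reconstruction departs from 1 by floating-point error only).
#' @export
predict.tumor_decomposition <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$S else signature_matrix(newdata)
  if (ncol(S) != length(object$exposures))
    stop("newdata must contain ", length(object$exposures), " signatures")
  v <- as.numeric(S %*% object$exposures)
  if (object$spec$model == "alexandrov")
    genome_profile(v, object$spec, sample = paste0(object$genome$sample, ".fit"))
  else
    genome_profile(unflatten_shiraishi(v, object$spec), object$spec,
                   sample = paste0(object$genome$sample, ".fit"))
}

#' @export
summary.tumor_decomposition <- function(object, ...) {
  structure(list(fit = object,
                 n_signatures = length(object$exposures),
                 n_used = sum(object$exposures > 0),
                 top = sort(object$exposures, decreasing = TRUE)),
            class = "summary.tumor_decomposition")
}

#' @export
print.summary.tumor_decomposition <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d signatures with non-zero exposure\n", x$n_used))
  invisible(x)
}

#' Plot signature exposures
#'
#' Barplot of the fitted exposures, in signature order.
#'
#' @param x A `tumor_decomposition`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.tumor_decomposition <- function(x, ...) {
  graphics::barplot(x$exposures, las = 2, ylab = "exposure",
                    main = sprintf("%s (R² = %.3f)", x$genome$sample,
                                   x$explained_variance), ...)
  invisible(x)
}

#' Simulate genomes from a fitted decomposition
#'
#' Parametric simulation: draws new genome profiles from the fitted mixture
#' of signatures, with the same number of mutations as the original genome
#' (or `n_mutations`).
#'
#' @param object A `tumor_decomposition`.
#' @param nsim Number of genomes.
#' @param seed Optional integer seed.
#' @param n_mutations Mutations per simulated genome; defaults to the fitted
#'   genome's count.
#' @param ... Unused.
#' @return List of [genome_profile()]s of length `nsim`.
#' @export
simulate.tumor_decomposition <- function(object, nsim = 1, seed = NULL,
                                         n_mutations = NULL, ...) {
  if (is.null(n_mutations)) n_mutations <- object$genome$n_mutations
  if (is.na(n_mutations))
    stop("fitted genome has no mutation count; pass n_mutations")
  sigs <- signatures_from_matrix(object$S, object$spec)
  if (!is.null(seed)) seed <- seed + seq_len(nsim) - 1L
  lapply(seq_len(nsim), function(i)
    simulate_genome(sigs, object$exposures, n_mutations,
                    seed = if (is.null(seed)) NULL else seed[i],
                    sample = sprintf("%s.sim%d", object$genome$sample, i)))
}

# rebuild signature objects from a flattened P x K matrix
signatures_from_matrix <- function(S, spec) {
  lapply(seq_len(ncol(S)), function(j) {
    if (spec$model == "alexandrov")
      alexandrov_signature(S[, j], name = colnames(S)[j])
    else
      shiraishi_signature(unflatten_shiraishi(S[, j], spec), spec = spec,
                          name = colnames(S)[j])
  })
}

#' @export
plot.ev_curve <- function(x, ...) {
  graphics::plot(x$k, x$explained_variance, type = "b", pch = 19,
                 xlab = "number of signatures",
                 ylab = "explained variance", ylim = c(0, 1), ...)
  invisible(x)
}
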