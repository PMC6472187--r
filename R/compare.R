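#' Distance between two signatures
#'
#' Both signatures must share one representation (both Alexandrov, or both
#' Shiraishi with equal [context_spec()]). The Frobenius distance is taken
#' over the full padded feature matrix; since padding entries are hard zeros
#' in both operands this equals the distance between the flattened parameter
#' vectors.
#'
#' @param s1,s2 Signatures (or [genome_profile()]s) of identical
#'   representation.
#' @param metric `"frobenius"` (default), `"l1"` (rectilinear), or
#'   `"cosine"` (1 minus cosine similarity of the flattened vectors).
#' @return Non-negative scalar distance.
#' @export
signature_distance <- function(s1, s2,
                               metric = c("frobenius", "l1", "cosine")) {
  metric <- match.arg(metric)
  check_comparable(s1, s2)
  v1 <- flatten(s1)
  v2 <- flatten(s2)
  switch(metric,
         frobenius = sqrt(sum((v1 - v2)^2)),
         l1 = sum(abs(v1 - v2)),
         cosine = 1 - sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
}

check_comparable <- function(s1, s2) {
  sp1 <- s1$spec
  sp2 <- s2$spec
  if (!same_spec(sp1, sp2))
    stop("signatures are not comparable: ", format(sp1), " vs ", format(sp2),
         "; convert or downgrade first")
  invisible(TRUE)
}

#' Map one signature set onto another
#'
#' Matches each signature in `from` with a signature in `to`. With
#' `method = "nearest"` each source signature is paired with its closest
#' target (many-to-one allowed). With `method = "one_to_one"` an injective
#' assignment minimizing the total distance is computed (optimal linear
#' assignment). `method = "greedy"` builds an injective mapping by
#' repeatedly taking the globally closest unmatched pair; provided for
#' strict reproduction of sequential-matching analyses.
#'
#' @param from,to Lists of signatures of one shared representation.
#' @param method `"nearest"`, `"one_to_one"`, or `"greedy"`.
#' @param metric Distance metric, see [signature_distance()].
#' @return Object of class `signature_mapping`: a data frame with columns
#'   `from`, `to`, `distance`, plus attributes `method` and `metric`.
#' @export
map_signature_sets <- function(from, to,
                               method = c("nearest", "one_to_one", "greedy"),
                               metric = "frobenius") {
  method <- match.arg(method)
  if (inherits(from, "mutsig")) from <- list(from)
  if (inherits(to, "mutsig")) to <- list(to)
  if (method %in% c("one_to_one", "greedy") && length(from) > length(to))
    stop("injective mapping impossible: |from| = ", length(from),
         " > |to| = ", length(to))
  D <- outer(seq_along(from), seq_along(to),
             Vectorize(function(i, j)
               signature_distance(from[[i]], to[[j]], metric)))
  assign_to <- switch(method,
    nearest = apply(D, 1L, which.min),
    one_to_one = solve_assignment(D),
    greedy = greedy_assignment(D))
  out <- data.frame(
    from = vapply(from, function(s) s$name, ""),
    to = vapply(to, function(s) s$name, "")[assign_to],
    distance = D[cbind(seq_along(from), assign_to)],
    stringsAsFactors = FALSE)
  structure(out, method = method, metric = metric,
            class = c("signature_mapping", "data.frame"))
}

#' @export
print.signature_mapping <- function(x, ...) {
  cat(sprintf("Signature mapping (%s, %s distance):\n",
              attr(x, "method"), attr(x, "metric")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# Hungarian algorithm (shortest augmenting path, O(n * m^2)) for the
# rectangular assignment problem: rows <= cols, minimize total cost.
# Returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n)                 # row potentials
  v <- numeric(m + 1L)            # column potentials (m+1 = virtual start)
  p <- integer(m + 1L)            # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(INF, m + 1L)
    fromj <- integer(m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; fromj[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- fromj[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign_to <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign_to[p[j]] <- j
  assign_to
}

greedy_assignment <- function(cost) {
  n <- nrow(cost)
  assign_to <- integer(n)
  D <- cost
  for (step in seq_len(n)) {
    k <- arrayInd(which.min(D), dim(D))
    assign_to[k[1L]] <- k[2L]
    D[k[1L], ] <- Inf
    D[, k[2L]] <- Inf
  }
  assign_to
}

#' Pairwise distance summary of a signature set
#'
#' @param signatures List of at least two signatures of one representation.
#' @param metric See [signature_distance()].
#' @return List with `mean`, `sd` (unbiased, n-1 denominator), and the full
#'   symmetric distance `matrix`.
#' @export
pairwise_distance_summary <- function(signatures, metric = "frobenius") {
  K <- length(signatures)
  if (K < 2L) stop("need at least two signatures")
  D <- matrix(0, K, K,
              dimnames = rep(list(vapply(signatures, function(s) s$name, "")), 2))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    D[i, j] <- D[j, i] <- signature_distance(signatures[[i]], signatures[[j]],
                                             metric)
  }
  d <- D[upper.tri(D)]
  list(mean = mean(d), sd = stats::sd(d), matrix = D)
}
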