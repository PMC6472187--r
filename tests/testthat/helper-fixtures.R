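# Shared fixtures and independent oracles for the test suite.

# the published 24-parameter deamination example signature shipped with the
# package (quintet context + transcription strand)
deamination_signature <- function() {
  read_shiraishi_signatures(
    system.file("extdata", "deamination_signature.txt",
                package = "sigrefit"))[[1L]]
}

triplet_spec <- context_spec(1, 1, FALSE, "shiraishi")
quintet_strand_spec <- context_spec(2, 2, TRUE, "shiraishi")
alex_spec <- context_spec(1, 1, FALSE, "alexandrov")

# brute-force minimizer of ||g - S w||^2 on the simplex by grid enumeration;
# independent of the package's active-set solver
grid_simplex_fit <- function(g, S, step = 1e-3) {
  K <- ncol(S)
  stopifnot(K %in% c(1L, 2L, 3L))
  if (K == 1L) return(1)
  s <- seq(0, 1, by = step)
  W <- if (K == 2L) rbind(s, 1 - s) else {
    gr <- expand.grid(w1 = s, w2 = s)
    gr <- gr[gr$w1 + gr$w2 <= 1 + 1e-12, ]
    rbind(gr$w1, gr$w2, pmax(0, 1 - gr$w1 - gr$w2))
  }
  Q <- crossprod(S)
  d <- as.numeric(crossprod(S, g))
  obj <- colSums(W * (Q %*% W)) - 2 * colSums(d * W)
  unname(W[, which.min(obj)])
}

# reference QP solution via pracma (Goldfarb-Idnani through an established
# implementation), with the same PD correction of the Gram matrix
pracma_simplex_fit <- function(g, S) {
  K <- ncol(S)
  Q <- nearest_positive_definite(crossprod(S))
  pracma::quadprog(Q, -as.numeric(crossprod(S, g)),
                   Aeq = matrix(1, 1, K), beq = 1, lb = rep(0, K))$xmin
}

# all permutations of a vector (for brute-force assignment checks)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# a deterministic synthetic COSMIC-style table with k signature columns
write_cosmic_fixture <- function(path, k = 2, seed = 1, shuffle = FALSE) {
  set.seed(seed)
  cats <- alexandrov_categories()
  sub <- substr(cats, 3, 5)
  tri <- paste0(substr(cats, 1, 1), substr(cats, 3, 3), substr(cats, 7, 7))
  tab <- data.frame(check.names = FALSE,
                    `Substitution Type` = sub,
                    Trinucleotide = tri,
                    `Somatic Mutation Type` = cats)
  for (i in seq_len(k)) {
    p <- stats::rgamma(96, 0.5)
    tab[[paste0("Signature ", i)]] <- p / sum(p)
  }
  if (shuffle) tab <- tab[sample.int(96), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
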