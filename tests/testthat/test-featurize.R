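test_that("purine-reference mutations are reverse-complemented", {
  # G>A with 5' T and 3' G maps to C>T with 5' C and 3' A
  n <- normalize_to_pyrimidine("G", "A", "T", "G")
  expect_identical(n$change, "C>T")
  expect_identical(n$context5, "C")
  expect_identical(n$context3, "A")
  expect_identical(n$pyrimidine_strand, "-")

  # pyrimidine references are untouched: A[C>T]G stays itself
  n <- normalize_to_pyrimidine("C", "T", "A", "G")
  expect_identical(n$change, "C>T")
  expect_identical(n$context5, "A")
  expect_identical(n$context3, "G")
  expect_identical(n$pyrimidine_strand, "+")

  # ambiguity codes exclude the mutation
  n <- normalize_to_pyrimidine("C", "T", "N", "G")
  expect_true(is.na(n$change))
})

test_that("normalization matches a brute-force reverse-complement oracle", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  bases <- c("A", "C", "G", "T")
  # all 16 flank pairs around an A>C variant must map to T>G with flanks
  # swapped and reverse-complemented
  for (b5 in bases) for (b3 in bases) {
    c5 <- paste0(b5, b5); c3 <- paste0(b3, b3)
    n <- normalize_to_pyrimidine("A", "C", c5, c3)
    expect_identical(n$change, "T>G")
    expect_identical(n$context5, rc(c3))
    expect_identical(n$context3, rc(c5))
  }
})

make_regions <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  read_stranded_regions(f)
}

test_that("strand assignment compares pyrimidine strand with transcript strand", {
  reg <- make_regions("chr1\t0\t1000\tg1\t0\t+")
  expect_identical(assign_strand("1", 100, "+", reg), "plus")
  expect_identical(assign_strand("1", 100, "-", reg), "minus")
  expect_identical(assign_strand("1", 2000, "+", reg), "undefined")

  both <- make_regions(c("chr1\t0\t1000\tg1\t0\t+", "chr1\t500\t800\tg2\t0\t-"))
  expect_identical(assign_strand("1", 600, "+", both), "undefined")
  expect_identical(assign_strand("1", 100, "+", both), "plus")
})

test_that("profiles aggregate hand-countable mutations correctly", {
  ref <- Biostrings::DNAStringSet(c("1" = "AACTGTCATT"))
  #                positions:         1234567890
  recs <- data.frame(sample = "T1",
                     chrom = c("1", "1", "1", "1"),
                     pos = c(3L, 3L, 3L, 3L),
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  pa <- build_profile(recs, ref, context_spec(1, 1, FALSE, "alexandrov"))
  expect_identical(pa$n_mutations, 4L)
  expect_identical(unname(pa$data["A[C>T]T"]), 1)
  expect_identical(sum(pa$data), 1)

  # two mutations A[C>T]G and T[C>A]T under the triplet shiraishi model
  ref2 <- Biostrings::DNAStringSet(c("1" = "ACGTTCTA"))
  recs2 <- data.frame(sample = "T1", chrom = "1", pos = c(2L, 6L),
                      ref = "C", alt = c("T", "A"), stringsAsFactors = FALSE)
  ps <- build_profile(recs2, ref2, triplet_spec)
  expect_equal(unname(ps$data["change", ]), c(0.5, 0, 0.5, 0, 0, 0))
  expect_equal(unname(ps$data["-1", ]), c(0.5, 0, 0, 0.5, 0, 0))
  expect_equal(unname(ps$data["+1", ]), c(0, 0, 0.5, 0.5, 0, 0))
})

test_that("reference-mismatching records error by default, skip on request", {
  ref <- Biostrings::DNAStringSet(c("1" = "AACTGTCATT"))
  recs <- data.frame(sample = "T1", chrom = "1", pos = c(3L, 5L),
                     ref = c("C", "C"), alt = c("T", "A"),
                     stringsAsFactors = FALSE)   # pos 5 is G, not C
  expect_error(build_profile(recs, ref, triplet_spec), "reference mismatch")
  p <- build_profile(recs, ref, triplet_spec, on_ref_mismatch = "skip")
  expect_identical(p$n_mutations, 1L)
  expect_identical(unname(attr(p, "excluded")["ref_mismatch"]), 1L)
})

test_that("strand-aware profiling excludes undefined-strand mutations", {
  fx <- synthesize_tumor_data(withr::local_tempdir(), n_mutations = 40,
                              seed = 33)
  recs <- split_by_sample(read_mpf(fx$paths$mpf))[[1]]
  reg <- read_stranded_regions(fx$paths$bed)
  p <- build_profile(recs, fx$reference, quintet_strand_spec, regions = reg)
  excl <- attr(p, "excluded")
  expect_identical(p$n_mutations + sum(excl), nrow(recs))
  expect_gt(excl[["undefined_strand"]], 0L)  # fixture leaves gaps uncovered
  # without the strand feature every context-clean mutation is usable
  p2 <- build_profile(recs, fx$reference, context_spec(2, 2, FALSE, "shiraishi"))
  expect_identical(p2$n_mutations + sum(attr(p2, "excluded")), nrow(recs))
  expect_gte(p2$n_mutations, p$n_mutations)
})

test_that("profiles are count-weighted averages under concatenation", {
  fx <- synthesize_tumor_data(withr::local_tempdir(), n_mutations = 60,
                              seed = 44)
  recs <- split_by_sample(read_mpf(fx$paths$mpf))[[1]]
  a <- recs[1:25, ]; b <- recs[26:nrow(recs), ]
  spec <- context_spec(1, 1, FALSE, "shiraishi")
  pa <- build_profile(a, fx$reference, spec)
  pb <- build_profile(b, fx$reference, spec)
  pab <- build_profile(recs, fx$reference, spec)
  na <- pa$n_mutations; nb <- pb$n_mutations
  expect_identical(pab$n_mutations, na + nb)
  expect_equal(pab$data, (na * pa$data + nb * pb$data) / (na + nb))
})

test_that("the alexandrov profile marginalizes to the shiraishi profile", {
  fx <- synthesize_tumor_data(withr::local_tempdir(), n_mutations = 80,
                              seed = 55)
  recs <- split_by_sample(read_mpf(fx$paths$mpf))[[1]]
  pa <- build_profile(recs, fx$reference, context_spec(1, 1, FALSE, "alexandrov"))
  ps <- build_profile(recs, fx$reference, triplet_spec)
  conv <- convert_alexandrov_to_shiraishi(
    alexandrov_signature(pa$data, name = "profile"))
  expect_equal(conv$matrix, ps$data, tolerance = 1e-12)
})

test_that("profiles with no usable mutations are an error", {
  ref <- Biostrings::DNAStringSet(c("1" = "NNCNN"))
  recs <- data.frame(sample = "T1", chrom = "1", pos = 3L, ref = "C",
                     alt = "T", stringsAsFactors = FALSE)
  expect_error(build_profile(recs, ref, triplet_spec), "no usable mutations")
})
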