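---
title: "Refitting mutational signatures to individual tumor genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting mutational signatures to individual tumor genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrefit)
```

## Two models of a mutational signature

A mutational signature describes the preference of one mutational process
for particular base changes in particular sequence contexts. After
collapsing reverse-complement pairs onto the pyrimidine strand, a
single-nucleotide variant falls in one of six base-change classes (C>A,
C>G, C>T, T>A, T>C, T>G), flanked by bases drawn from {A, C, G, T}.

The **joint model** enumerates every combination: with one flanking base on
each side there are 6 × 4 × 4 = 96 categories, and a signature is a
probability vector over them. The **independent-feature model** instead
factorizes the distribution: one probability row for the base change, one
row of four probabilities per flanking position, and optionally a two-entry
row for the transcription strand. A trinucleotide signature then needs only
6 + 4 + 4 = 14 parameters, and a signature with two flanking bases per side
plus strand needs 6 + 4·4 + 2 = 24 — compared with 6 · 4⁴ · 2 = 3072 joint
categories for the same context. The price is the independence assumption:
interactions between features (e.g. the CpG dependence of deamination,
which couples the base change to the +1 base) are captured only through the
marginal rows.

`sigrefit` represents both models behind one interface. Independent-feature
matrices always carry 6 columns; flanking rows use columns 1–4 and the
strand row columns 1–2, with the padding entries held at exact zeros. That
single rectangular shape makes Frobenius distances and file round-trips
well-defined. Rows are ordered base change, flanking positions 5′→3′,
strand — the natural reading order of the published parameter tables; note
that other implementations of the independent-feature model order their
internal parameters differently, so flat files from other tools should be
checked against `shiraishi_signature()`'s documented layout.

A tumor's catalog is summarized in exactly the same representation
(`genome_profile`): joint-model profiles are category frequencies, and
independent-feature profiles are the empirical marginal frequencies of each
feature across the tumor's usable SNVs.

## The refitting problem

Let `g` be the flattened profile (length P) and `S` the P × K matrix of
flattened signatures. The exposures `w` minimize

$$\lVert g - S w \rVert^2 \quad\text{s.t.}\quad \textstyle\sum_s w_s = 1,\; w_s \ge 0,$$

the classical quadratic program $\min_w -g^\top S w + \tfrac12 w^\top
S^\top S w$ on the probability simplex. The problem is strictly convex
whenever $S^\top S$ is positive definite, which holds iff the signatures
are linearly independent. `solve_exposures()` implements an exact primal
active-set method: free variables are solved through the KKT system with
the equality constraint, variables hitting zero leave the working set along
a feasible line step, and bound variables re-enter when their KKT
multiplier is negative. For strictly convex problems the method terminates
finitely at the global minimum; the test suite cross-checks it against an
established Goldfarb–Idnani implementation and against brute-force grid
enumeration of the simplex.

**Positive-definiteness correction.** When signatures are collinear (e.g. a
duplicated signature, or K > P), $S^\top S$ is only positive semidefinite.
The solver then replaces it with its nearest positive definite matrix
(`Matrix::nearPD`, alternating projections with eigenvalue clipping),
applied only if the smallest eigenvalue falls below `1e-12` times the
largest. For full-rank sets the matrix is returned bit-identical; the test
suite verifies that the Gram matrix of 15 well-separated random
24-parameter signatures changes by a relative factor below 3e−15 (i.e. not
at all). The correction is a numerical device for the solver only: residual
sums of squares and explained variance are always evaluated against the
uncorrected `S`.

**Output hygiene.** Active-set solutions carry values of order 1e−12 at
active constraints; weights below `1e-8` are clamped to zero and the rest
renormalized.

## Explained variance and subset selection

The fit quality is
$$R^2 = 1 - \frac{\sum_i (g_i - \hat g_i)^2}{\sum_i (g_i - g^*_i)^2},
\qquad \hat g = S w .$$
The baseline $g^*$ differs between the models. For the joint model the
natural "no information" genome is uniform over the 96 categories, which
equals the mean frequency $\bar g$ of a normalized catalog, so the
denominator is the ordinary total sum of squares. For the independent-feature
model the features have different numbers of states, so the flat genome has
frequency 1/6 per base change, 1/4 per flanking base and 1/2 per strand
(`flat_genome()`), and the baseline is that profile rather than the row
mean. $R^2$ can be negative when a fit is worse than the flat baseline; it
is undefined (an explicit error) when the observed profile *is* the flat
genome.

`decompose_tumor(min_explained_variance = v)` searches subsets: for each
size k from `min_num_signatures` (default 2) to `max_num_signatures`
(default K) it fits all `choose(K, k)` subsets and stops at the first k
where some subset reaches v, returning the best-explaining subset at that
k. When several subsets tie, the lexicographically first is kept, which
makes results deterministic. If no subset reaches v the overall best fit is
returned with `threshold_reached = FALSE`. Because enumeration is
exponential, sizes with more than `max_subsets` (default 200,000)
combinations fall back to greedy forward selection; `greedy = TRUE` forces
greedy search throughout. The companion `explained_variance_curve()`
reports the per-k maxima, which are non-decreasing in k since a larger
subset can always zero out its extras.

## Conversion, downgrading, distances

A joint-model signature is converted to the independent-feature model by
plain marginal summation: the base-change row sums the 16 contexts of each
class, and each flanking row sums the 24 categories carrying that base.
Summation (rather than per-class renormalization) preserves the overall
base composition of the signature's mutations. Published joint-model tables
are rounded, so columns may miss 1 by ~1e−4; readers accept a configurable
tolerance and an optional `renormalize` flag (off by default) rescales
before marginalizing. Whether a reference implementation renormalizes first
is not documented anywhere we know of; both behaviors are exposed and the
difference is far below the distances being compared.

Because the independent-feature model's features are independent,
`downgrade_shiraishi()` simply drops outer flanking rows and/or the strand
row without renormalizing anything. Distances between signatures of one
representation are Frobenius (default), L1, or cosine, computed on the
padded matrices — pads are zero in both operands, so padded and flattened
distances coincide. `map_signature_sets()` matches sets either by nearest
neighbour (many-to-one) or by optimal linear assignment (injective,
Hungarian algorithm); a greedy sequential option reproduces analyses that
matched best pairs first. Pairwise summary statistics use the unbiased
(n−1) standard deviation, and the single-pair case reports `NA` rather
than 0 since the dispersion of one observation is undefined.

## Featurization of real data

`build_profile()` turns SNV records (from VCF via `vcfR`, or the
tab-separated sample/chrom/pos/ref/alt "mutation position format") into a
profile. Flanking bases are read from the reference FASTA, never trusted
from annotation fields, and a record whose ref allele contradicts the FASTA
is an error by default (`on_ref_mismatch = "skip"` downgrades it to a
counted exclusion). Chromosome names are matched after stripping any
`"chr"` prefix, the dominant cross-convention failure. Coordinates are
1-based inclusive internally; BED input is converted on read.

The transcription-strand feature compares the strand carrying the
pyrimidine with the transcript strand at that position: `"plus"` if they
agree, `"minus"` if not. Positions outside any region, or covered by
transcripts on both strands, are `undefined` and — when the model uses the
strand feature — excluded, so strand-aware profiles are built only from
regions with an unambiguous transcription direction. The choice of which
agreement state is called "plus" is a labelling convention; it affects only
the order of the two strand entries and is fixed and documented here.

## The simulation harness

`simulate_genome()` draws each of n mutations by first sampling a signature
according to the exposures and then sampling the mutation's features from
that signature — jointly for the 96-category model, independently per
feature row for the independent-feature model, exactly as that model
assumes. `evaluate_recovery()` wraps the full benchmark: drivers at fixed
exposures, the remainder uniform, refitting against the complete set, and
the absolute deviations of fitted from simulated exposures split into
driving and background signatures.

The study conditions are fixed as defaults rather than dials: one driving
signature at exposure 0.8 (multi-driver designs use 0.5/0.3, 0.4/0.25/0.15,
0.3/0.2/0.1/0.1), K = 15 signatures, and mutation counts spanning 100, 200,
770 and 2334 — the last being the median count of breast-cancer genomes
within transcribed regions, the ones below representing sparser tumors.
Because the 15 cohort-derived signatures behind the original evaluation are
not published as tables, the harness substitutes random independent-feature
signatures with sparse Dirichlet(0.5) rows, redrawn until all pairwise
Frobenius distances exceed 0.4 — comparable in separation to real signature
sets (converted COSMIC v2 signatures average 0.83). Two consequences
matter. First, the recovery numbers are structurally comparable to the
published envelopes (driver errors within ~5 percentage points at 200
mutations and ~2 at 2334) but not numerically identical to any real-cohort
figure. Second, the generator samples features independently and ignores
genomic coordinates, chromatin context, and within-genome linkage, so
passing tests demonstrate correctness of the estimator under its own model,
not robustness to violations of the independence assumption in real
genomes.

Reproducibility: every stochastic function takes a `seed` and restores the
caller's RNG state; `evaluate_recovery()` derives one substream per genome
from the base seed by a counter, so any single genome can be regenerated in
isolation. The acceptance script runs 1000 genomes per driver at 200
mutations and 200 per driver at 2334, sizes chosen to keep the full run
within a minute on one CPU while leaving Monte-Carlo error on the reported
medians well below the tolerances they are compared at; the test suite uses
smaller slices of the same design.

## Numerical choices

* Probability rows must sum to 1 within `1e-10` on construction; readers of
  published (rounded) tables accept looser, configurable tolerances and an
  optional renormalization.
* Flat-genome entries are exact binary rationals (`1/6`, `1/4`, `1/2`,
  `1/96` as computed by division), not decimal approximations.
* The PD-correction trigger is a relative eigenvalue floor of `1e-12`; the
  KKT systems of the active set are solved directly (the working sets are
  at most K+1 ≤ 31 in practice).
* Exposure clamping at `1e-8` with renormalization; subset ties broken
  lexicographically; `choose(K, k)` enumeration capped at 200,000 with a
  greedy fallback.
* Degenerate inputs fail loudly: empty signature sets, mixed context specs,
  zero usable mutations, the flat genome as input to explained variance,
  and injective mappings onto smaller sets are all explicit errors.

## Limitations

* Only SNVs are modelled: indels, doublet substitutions and structural
  variants are skipped (and counted) on read.
* The joint model is supported in its canonical 96-category form only;
  wider joint contexts explode combinatorially and are better served by the
  independent-feature model.
* Refitting quantifies contributions of *given* signatures; it cannot
  discover new ones, and exposures of near-collinear signatures (e.g. some
  converted COSMIC pairs, Frobenius distance ≈ 0.17) are mutually
  exchangeable — the explained-variance subset machinery makes this visible
  but cannot resolve it.
* Confidence intervals on exposures are out of scope; the simulation
  harness provides empirical error envelopes instead.
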