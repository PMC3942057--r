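---
title: "Cohort-level mutational signature analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-level mutational signature analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cohortsig)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
places where the design was genuinely open and we had to decide. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The catalog and the pyrimidine collapse

A somatic SNV is classified by its substitution and its two flanking
bases. Since the two DNA strands are complementary, a G>A call at
`c-G-t` is physically the same event as C>T at `a-C-g`; every mutation
is therefore reported on the pyrimidine strand, giving 6 substitution
types (C>A, C>G, C>T, T>A, T>C, T>G) × 16 flank combinations = 96
categories. The ordering is fixed (substitutions in the order above; 5'
base then 3' base, alphabetical) and every matrix in the package uses
it. Records may arrive written on either strand: the classifier accepts
a ref allele equal to the genome base or to its complement, and the test
suite checks all 192 stranded cases against a brute-force enumerator.

Practical dirt is excluded and tallied rather than fatal: records whose
context contains an ambiguous base, records at contig edges, ref alleles
matching neither strand, and exact duplicates (counted once;
configurable). CpG-island membership is tested at the mutated base only,
with BED intervals taken 0-based half-open and mutation positions
1-based, the two formats' native conventions.

## The factorization

Counts are Poisson-like, so we minimize the generalized
Kullback–Leibler divergence `D(M||WH)` with the classical multiplicative
updates, implemented in compiled code. The objective is non-increasing
at every update; the suite asserts this numerically and checks the
converged optimum against an independent box-constrained quasi-Newton
optimizer on small matrices (agreement within 1e-4 relative).

Key numerical choices:

* **Initialization**: W, H entries i.i.d. uniform(0,1] scaled to the
  data mean; the seed fully determines them. All seeds in multi-stage
  procedures derive from one master seed through a documented counter
  hash (`derive_seed`), and derived seeds are recorded in run manifests.
* **Convergence**: relative objective change < 1e-6 between checkpoints
  or 10,000 iterations for a standalone `nmf_factorize` call. Inside
  the bootstrap, restarts run short (500 iterations, tol 1e-4) to
  locate a basin, and only the best restart is polished to tol 1e-8.
  This two-stage scheme changed no recovery outcome on pilot data but
  makes the spec-scale rank scan fit a desk-scale time budget, and it
  measurably tightens the pooled-signature clusters that rank selection
  relies on.
* **Degenerate samples**: all-zero columns are excluded from
  factorization and re-attached with flagged uniform relative loads
  (1/r), so downstream shapes never change.
* **Scale convention**: signatures are reported column-stochastic; the
  scale moves into H exactly (`W_norm %*% H_rescaled = W_raw %*% H_raw`).

## Bootstrap, consensus, and rank selection

Each bootstrap replicate resamples every sample's counts multinomially
with its total fixed — resampling mutations, the unit of observation.
Replicates are factorized best-of-restarts; the pooled replicate
signatures are partitioned into r groups by k-medoids (PAM) on cosine
distance; centroids (renormalized) are the consensus signatures and
per-cluster mean silhouette width is the stability. Exposures are refit
against the consensus signatures on the *original* catalog under the
same divergence (H-only updates from a deterministic uniform start).

For rank selection we scan candidate ranks and record reconstruction
divergence, a cophenetic correlation, mean Hoyer sparseness
(`(sqrt(n) - ||v||_1/||v||_2)/(sqrt(n) - 1)`; 0 = uniform, 1 = one-hot)
and mean stability. The chosen rank is the **largest** rank whose
cophenetic coefficient reaches 0.95 and whose mean stability reaches
0.8; if none qualifies, the rank with maximal cophenetic coefficient.
Both thresholds are arguments, and the applied rule is recorded in the
report, because rank selection in this family of methods ultimately
benefits from a manual check.

Two consensus matrices are available, and this was a genuinely open
design point:

* `"sample"`: N × N co-assignment — how often two samples share the same
  dominant signature across replicates. This is the classical
  clustering-flavored consensus. We found it reliable only when samples
  are dominated by single processes: with moderately even per-sample
  mixtures (the default world of our generator), the dominant signature
  of many samples flips under resampling, its cophenetic coefficient
  decays at the true rank, and rank selection collapses toward r = 2.
* `"signature"` (the `select_rank` default): the cosine-similarity
  matrix of all pooled replicate signatures. This measures the
  stability of the objects actually being estimated; in our experiments
  it stays above threshold at the planted rank and drops sharply one
  rank above it, in both mixture regimes.

Tie-breaks everywhere (assignment, clustering, argmax) are
lowest-index deterministic; a fixed master seed reproduces every number
bit for bit.

## Archetypes and annotation

The archetype library idealizes the signature families the package
annotates against: S spreads its mass uniformly over all 16 C>A
categories; UVA and UVB put C>A resp. C>T mass on contexts with a 5'
pyrimidine; K covers C>T and C>G at TpCpX; L covers T(C>A)T and
T(C>T)G; H covers C(C>A)X and G(C>T)X; nonCGI covers X(C>T)G; flat is
uniform. Real extracted signatures are never exactly zero off their
defining support, so each archetype leaks a configurable mass fraction
(default 5%) over non-support categories with mild seeded jitter.

The non-CGI ablation experiment removes the X(C>T)G records outside
CpG islands and re-runs the *entire* analysis, including rank
selection: removing a process's mutations legitimately changes how many
processes are detectable, and forcing the full run's rank onto the
ablated catalog would simply re-extract whatever X(C>T)G residue is
left. In the planted experiment the generator places only 5% of the
non-CGI process's mutations inside islands — the process models
deamination of methylated CpGs, and islands are predominantly
unmethylated, which is what makes the signature "non-CGI" in the first
place — while catalogs without this process use a generic 20% island
share for CpG mutations. Under that world the planted signature is
recovered at cosine ≈ 0.99 from the full catalog, and after ablation
the re-selected rank drops by one and no extracted signature resembles
the archetype (cosine ≈ 0.1), mirroring the motivating observation.

Annotation replaces visual classification with quantitative cosine
matching: an exact maximum-weight one-to-one assignment (bitmask dynamic
programming, verified against permutation enumeration), a configurable
match threshold (default 0.8), and an explicit `exclusive` flag when
more signatures than archetypes force greedy fallback. Cohort profiles
are the *set* of matched archetype names plus a count of unmatched
("private") signatures — cohorts are compared by their combination of
signatures, not by private ones. Samples contributing more than half
(configurable) of a signature's cohort-wide raw exposure are reported as
outliers, and the ablation workflow re-runs extraction without them.

## The synthetic world, and what a green test establishes

The generator is deliberately the simplest structure matching the
analysis assumptions: per-sample burdens log-normal (median 300
SNVs/sample, sdlog 0.7 — exome-scale, heavy right tail), per-sample
mixture weights Dirichlet, observed catalogs multinomial (or Poisson)
around `W_true H_true`, mutations realized on a synthetic contig in
non-overlapping trinucleotide slots (so the catalog ⇄ genome round trip
is exact by construction), on a random strand, with a configurable
fraction of X(C>T)G mutations placed in a CpG-island prefix block.
Covariates are planted by rescaling exposures: heavy smokers get the
named signature's exposure multiplied by the effect size (light smokers
by its square root), MSI-high samples likewise, and expression columns
decay exponentially in a signature's relative load.

The Dirichlet concentration default is 3. This was calibrated once,
before freezing the acceptance experiments, so that the generator's
stated power property holds — a planted 2-fold exposure effect at
n = 60/60 must reject at the 0.01 level in at least 90% of cohorts
(measured ≈ 99%; at concentration 1 the property fails at ≈ 57%) —
while mixtures stay far from one-process-per-sample. Concentration is a
plain argument for scientists who want sparser worlds.

What the generator does **not** emulate: real trinucleotide frequencies
of a genome (slots are uniform), regional mutation-rate variation and
*cis*-clustered kataegis foci, indels/CNVs/structural variants, clonal
structure, sequencing error, cohort-specific burden distributions. A
green recovery test therefore establishes that the estimator works when
its model assumptions hold — it does not certify performance on any
particular real cohort.

## Associations

"t-test" is Welch (unequal variance), two-sided, by default;
pooled-variance is a flag. Zero-variance-in-both-groups comparisons
return p = 1 with a degenerate flag instead of erroring. The
heavy/light-load split is at the median load with ties assigned to the
heavy half (documented because a 1–50%/51–100% rule is ambiguous at
ties). Expression ratios are un-logged by default (log2 by flag);
load-expression correlation defaults to Spearman, robust to expression
scale. Missing covariates are excluded and tallied; excluded + used =
input. Raw p-values are reported (no multiplicity correction by
default). Tests run on relative loads by default, raw loads by flag.

## Known limitations

* KL-NMF is non-convex and, for exactly low-rank inputs, non-unique
  beyond rank 1; recovered signatures can sit inside the feasible cone
  a small cosine distance from the planted ones even at zero divergence.
  The acceptance thresholds (cosine ≥ 0.9) account for this.
* The rank-selection thresholds (0.95 / 0.8) are conventions, not laws;
  near-threshold scans deserve a manual look at the full report table.
* Bootstrap consensus clusters are aligned within the package only;
  signatures are not matched against external catalogs (e.g. COSMIC) —
  out of scope by design.
* The CLI accepts JSON or flat key=value config files (no YAML parser in
  the supported stack).
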