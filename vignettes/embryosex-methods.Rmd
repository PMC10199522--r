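---
title: "Methods: models, parameters and design choices in embryosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in embryosex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryosex)
```

`embryosex` analyses sex-biased gene expression in stage-labelled two-sex
single-cell count data from pre-implantation embryos. This vignette
documents the statistical models behind each step, the parameters a user
may want to change, the numerical conventions, and the design decisions
taken where more than one reasonable construction existed. Everything here
is also exercised by the test suite; no result is claimed that the tests
or the acceptance script do not compute.

## The synthetic-data generator

`simulate_counts()` draws gene-by-cell counts
$y_{gc} \sim \mathrm{NB}(\mu_{gc}, \alpha_g)$ with
$\mu_{gc} = \lambda_g \, s_{g,\text{stage}(c)} \, f_{g,\text{sex}(c)} \, d_c$:

- $\lambda_g$ — log-normal baseline means, natural-log mean
  `baseline_logmean_mu = 1` and sd `baseline_logmean_sd = 1.2`, giving a
  median mean near 2.7 counts with a long right tail; most genes are
  low-expressed and produce many stochastic zeros, the regime single-cell
  normalization methods are built for. No explicit zero inflation is
  added: excess zeros arise from low NB means, which keeps the generator
  free of parameters the pipeline could not identify anyway.
- $s_{g,\text{stage}}$ — stage programs. A configurable fraction of genes
  (`frac_metagene_genes = 0.5`) belongs to one of `n_metagenes = 3`
  programs, each a smooth non-negative bump over the stage axis scaled to
  the multiplier range [0.25, 3]. Programs are multiplicative and
  non-negative so the planted structure is a recoverable NMF
  factorization.
- $f_{g,\text{sex}}$ — planted sex effects. `n_sexdeg_per_stage = 25`
  genes per stage (disjoint across stages, never markers or Y-linked
  genes) get a $2^{\pm\text{log2fc}}$ shift with `sexdeg_log2fc = 2`;
  planted X-linked effects are always female-biased, autosomal directions
  are random. Y-linked genes are zeroed in female cells by construction.
- $d_c$ — per-cell depth, log-normal with `libsize_sd = 0.3` (about
  ±30% depth variation), so size-factor estimation is a real task.
- dispersion follows the trend $\alpha(\mu) = a_0 + a_1/\mu$ with defaults
  $a_0 = 0.1$, $a_1 = 1$ — moderate biological overdispersion plus the
  Poisson-like inflation of low means typical of UMI-free single-cell
  protocols.

Marker genes: the Xist-like marker is X-linked with mean 50 in females and
0.5 in males (female expression is constitutive from the first simulated
stage — the pipeline uses it as a technical control, not a dynamic
readout); the Y-linked marker has mean 30 in males and is structurally
zero in females. At these means marker dropout is vanishingly rare, which
is what makes near-perfect sexing the expected outcome.

The default configuration — 2,000 genes, 4 stages, 30 cells per stage per
sex — mirrors the scale of published mouse pre-implantation datasets
(about a hundred cells across 2-cell to blastocyst stages). What the
generator does **not** emulate: zygotic-genome-activation dynamics, batch
effects, doublets, cell-cycle structure, and gene–gene correlation beyond
the planted programs. Tests passing on these data therefore demonstrate
algorithmic correctness and calibration under the stated model, not
robustness to every artefact of real embryo data.

`simulate_genesets()` and `simulate_ppi()` derive gene sets (one per
planted metagene plus random decoys, sizes within [15, 500]) and a
stochastic block-model interaction graph (`p_within` inside metagene
modules, `p_between` elsewhere) from the same ground truth.

## Quality control and expressed fractions

`filter_counts()` applies the conventional detection filters
`min_cells = 3` (a gene must be detected in at least 3 cells) and
`min_features = 350` (a cell must retain at least 350 detected genes).
The two passes run in a fixed order — genes first, then cells, with cell
feature counts recomputed after gene removal — because a joint filter has
no unique fixed point; the sequential rule is deterministic and
idempotent. `drop_riken()` removes mouse RIKEN cDNA genes by the
case-insensitive symbol suffix "Rik". `expressed_fraction()` calls a gene
expressed in a group when it is detected (count > 0) in at least one cell
of the group — the weakest defensible definition; no minimum-count
threshold is imposed.

## Normalization

`deconvolution_size_factors()` implements pooled deconvolution for sparse
counts. Cells are placed on a ring ordered by library size so that every
pool of consecutive cells mixes deep and shallow cells; for pool sizes
{21, 41, 61, 81, 101} (clipped to n−1) each rotation of the ring
contributes one equation: the median over retained genes
(`min_mean = 0.1` average counts) of the pooled count against an average
reference pseudo-cell estimates the sum of the pool's factors. The sparse
linear system is solved by least squares with one low-weight augmentation
row per cell tying it to its library-size factor (`augment_weight = 0.01`)
— enough to pin the scale and remove the ring system's null space without
biasing the fit. Pre-clustering before pooling is omitted: at the dataset
sizes targeted here (tens to a few hundred cells per table) clusters are
too small to pool within. Negative solutions (possible in pathological
systems) are floored at 1e−8 with a warning; factors are rescaled to mean
1 exactly.

`log_normalize()` returns $\log_2(y_{gc}/\hat{s}_c + 1)$. Base 2 and
pseudocount 1 are conventions; the pseudocount must be ≥ 1 for the output
to be non-negative.

## Cell sexing

`call_sex()` encodes the marker-ratio rule exactly: female iff the
Y-marker is zero and the X-marker positive; male iff the Y-marker is
positive with ratio < 1; ratio ≥ 1 or a double zero is ambiguous. Two
boundary conventions are ours: a ratio of exactly 1 is ambiguous (the rule
only defines < 1 and > 1), and double-zero cells are ambiguous rather than
unsexed-female, treating the X-marker as a technical control for
sufficient signal. Ratios are computed on **raw** counts: sexing feeds the
normalization-independent metadata, and using normalized values would make
sex calls depend on size factors estimated from a mixture of both sexes.

## Variance partitioning and PCA

`pca_samples()` performs sample-space PCA on per-gene-centered,
**unscaled** log-normalized values; scaling to unit variance would
up-weight noise-dominated low-expression genes. `variance_explained()`
reports per gene the one-way $R^2$ of stage over all cells, and the
one-way $R^2$ of sex within each stage's cells. A per-stage one-way model
(rather than a joint two-factor decomposition) is used deliberately: the
quantity of interest is "how much of the expression variance among this
stage's cells does sex explain", stage by stage, and one-way $R^2$ answers
exactly that without an ordering convention for sequential sums of
squares. Zero-variance genes are assigned 0; a stage observed in only one
sex yields `NA`.

Under the null, one-way $R^2$ with two groups has mean ≈ 1/(n−1), so
small per-stage cell numbers inflate the baseline; comparisons should be
made across stages at comparable n, as the tests do.

## Differential expression

Per stage, `estimate_dispersions()` computes method-of-moments
dispersions $\hat\alpha_g = \max(0, (s_g^2 - \bar\mu_g)/\bar\mu_g^2)$ on
size-factor-scaled counts, fits the trend $\alpha(\mu) = a_0 + a_1/\mu$
by robust regression (`MASS::rlm`) over genes with positive raw estimates,
and shrinks each gene toward the trend on the log scale with weight
`shrink_w = 0.5` (a geometric-mean compromise between the noisy per-gene
estimate and the stable trend). This replaces the full empirical-Bayes
machinery of dedicated DE packages with a simpler estimator whose contract
— type-I error control and power, verified by simulation — is what the
pipeline needs; bit-compatibility with any specific package is a
non-goal.

`wald_test()` fits, per gene, the NB GLM
$\log \mu_c = \beta_0 + \beta_1 \cdot \mathbb{1}[\text{female}] + \log s_c$
by iteratively reweighted least squares (closed-form 2×2 normal equations,
vectorized across genes; up to 100 iterations, convergence tolerance
1e−8, coefficients capped at ±30 on the natural-log scale to catch
separations such as a sex with all-zero counts — capped fits are flagged
non-converged and report `NA` p-values). The Wald statistic
$\beta_1/\mathrm{SE}$ gets a two-sided normal p-value; BH adjustment runs
within each stage separately, matching per-stage testing. Positive
$\beta_1$ means female-biased — the orientation is declared once and used
everywhere. Cells are treated as replicates within a stage; no
pseudo-bulking is applied.

`shrink_lfc()` computes the posterior mode of $\beta_1$ under a
zero-centered normal prior using the normal approximation of the
likelihood at the MLE, i.e. the precision-weighted estimate
$\hat\beta \,\sigma_p^2/(\sigma_p^2 + \mathrm{se}^2)$. The prior SD is
selected from a grid so that the half-normal 95th percentile of the prior
matches the empirical 95th percentile of |raw effects| — large observed
effects keep the prior wide, near-null data tighten it. Classification
uses the shrunken fold change with the thresholds `lfc_cut = 0.58`
(≈1.5-fold) and `alpha = 0.05`.

Size factors from the deconvolution module are reused as GLM offsets
rather than re-deriving median-of-ratios factors inside the DE step; one
normalization serves the whole pipeline.

## Enrichment grid and regulator census

`hypergeom_enrichment()` reports both one-tailed hypergeometric
probabilities, $P(X \ge k)$ for over- and $P(X \le k)$ for
under-enrichment — the minimal model consistent with testing "over and
under". The universe is the stage's expressed genes, not all annotated
genes, so enrichment conditions on detectability at that stage. No
multiple-testing correction is applied across grid cells; instead cells
with fewer than 5 category genes or 5 sex-biased genes carry a
low-confidence flag. `regulator_census()` ranks genes by mean normalized
expression per stage (ties broken by gene identifier) and counts
transcription-factor and epigenetic-enzyme flags among the top
`top_n = 1000`.

## NMF metagenes

`nmf_fit()` minimizes the generalized Kullback–Leibler divergence with the
classical multiplicative updates, which guarantee a non-increasing
objective; a Frobenius objective is available behind
`objective = "frobenius"`. Initialization draws W and H uniformly on
(0, 1] scaled to the data mean, per seed, so every run is reproducible. A
division guard of 1e−10 protects the updates; iteration stops at
`max_iter` or when the relative objective change drops below `tol = 1e-6`.
Because the objective is multimodal, restarts matter: consensus machinery
runs `n_runs = 10` seeds per rank by default.

`consensus_and_cophenetic()` assigns each sample to its argmax mixture
component, accumulates the co-clustering fraction matrix C, and computes
the cophenetic correlation between 1−C and the cophenetic distances of the
average-linkage dendrogram of 1−C. When the consensus dissimilarity is
constant (e.g. every run produces a single cluster) agreement is perfect
by convention and 1 is returned. `select_rank()` scans candidate ranks
(5–30 by default, matching common practice for expression tables of this
size) and picks the highest cophenetic coefficient, smallest rank on ties
— the conservative choice. `metagene_membership()` assigns genes by argmax
gene-loading; all-zero rows stay unassigned.

## Pre-ranked GSEA

`enrichment_score()` is the weighted Kolmogorov–Smirnov running sum with
exponent `p = 1`: hits add their weight normalized by the set's total
weight, misses subtract 1/(N−|set|). Under positive scoring the ES is the
maximum of the running sum (never below 0, the empty prefix). Ranking
ties are broken by gene identifier. `gsea_preranked()` filters sets to
[15, 500] members after intersection with the ranked universe, and builds
the null by drawing random gene sets of the same size
(`n_perm = 1000` by default), sharing one null per distinct set size;
$p = (1 + \#\{ES^\ast \ge ES\})/(1 + n_\text{perm})$, $NES = ES /
\overline{ES^\ast}$, BH across sets. A simple Monte-Carlo gene-permutation
null is used instead of adaptive multilevel schemes — the same estimand,
at the cost of a resolution floor of 1/(1+n_perm), which is acceptable for
collections of tens to hundreds of sets.

## PPI edge classes and hive layout

`classify_edges()` labels nodes male-biased / female-biased / unbiased and
counts the six unordered edge classes; within-class counts are normalized
by the class size, and cross-class counts by the geometric mean of the two
class sizes (the natural two-sided analogue; only within-class
normalization has an established convention). Empty classes report missing
normalized values rather than zeros. "Expressed at a stage" reuses the
detection definition above. The hive layout alternates each class's nodes
over two half-axes by degree rank (ties by identifier) — an export format
for plotting tools, with no rendering guarantees.

## Cross-species conservation

`conservation_scores()` compares ortholog pairs through mean expression
profiles over generalized stage groups (S1–S4) shared by both species.
Profiles are z-scored within species — removing species-level location and
scale so only the stage *shape* is compared — and scored by Pearson
correlation. The permutation null shuffles the ortholog pairing, making
each gene's null partner uniform over the other species' scored genes;
`exact = TRUE` enumerates all partners (the limit of all pairings), the
default draws `n_perm = 999` random pairings. This profile-correlation
statistic is a deliberately defined, testable replacement for
embedding-based conservation rankings, whose procedures are not
specifiable enough to validate; outputs are labelled accordingly.
`top_expression_mask()` marks entries strictly above a gene's
`q = 0.9` quantile — the top decile of the gene's own distribution.

## Problem sizes and runtime

The test and acceptance workloads are sized to finish in minutes on one
CPU while keeping Monte-Carlo error well inside the asserted tolerances:
2,000-gene / 240-cell sexing runs, 20 replicates of 500-gene / 100-cell
null DE for calibration, 200-gene power runs at 20 cells per sex,
exhaustive hypergeometric enumeration to universe size 12, NMF rank scans
over ranks 2–6 with 10 restarts on ~90×45 planted matrices, 1,000-instance
GSEA oracle sweeps, and 200-pair conservation contrasts. Larger inputs
simply scale these calls.

## Known limitations

- The DE model treats cells as independent replicates; embryo-of-origin
  correlation is not modelled.
- Dispersion shrinkage uses a fixed weight, not an estimated posterior
  width; calibration is verified by simulation, not derived analytically.
- The Wald p-value's normal approximation degrades for very low-count
  genes; those genes are also where the test is conservative.
- Consensus NMF clusters samples by argmax mixture weight only; soft
  co-clustering definitions would change the cophenetic curve.
- The conservation statistic compares group-mean profile shapes; it does
  not attempt cross-species integration or per-cell alignment.
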