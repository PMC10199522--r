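# embryosex

Sex-biased gene expression analysis for pre-implantation embryo
single-cell transcriptomes.

## The problem

Male (XY) and female (XX) mammalian embryos differ transcriptionally well
before gonads form: Y-linked genes, *Xist*, and dosage-sensitive X-linked
regulators are expressed within the first cleavage divisions. Detecting
those differences from single-cell RNA-seq of pre-implantation embryos
requires a chain of specialised steps — cells must be sexed from marker
expression because embryos are rarely karyotyped, counts are sparse and
need pooled normalization, per-stage differential tests need negative
binomial models with fold-change shrinkage, and the resulting sex-biased
gene sets are interrogated through enrichment grids, interaction networks,
metagene factorizations and cross-species comparisons.

`embryosex` implements that chain end-to-end for stage-labelled two-sex
count matrices, together with a synthetic-data generator that plants known
sex effects, stage programs and network modules so every stage of the
pipeline can be validated against ground truth.

## Methods at the core

- **Cell sexing** by the marker-ratio rule: with raw counts `x` of an
  Xist-like X-linked marker and `y` of a Y-linked marker, a cell is female
  iff `y = 0, x > 0`; male iff `y > 0` and `x/y < 1`; otherwise ambiguous
  and removed. A `y_presence` mode (male iff summed Y-linked counts exceed
  a threshold) covers datasets sexed that way upstream.
- **Pooled deconvolution size factors**: cells ordered on a ring by library
  size; pools of consecutive cells give robust median-ratio equations
  against an average pseudo-cell; per-cell factors are deconvolved by least
  squares and rescaled to mean 1.
- **Per-stage NB Wald tests**: per-gene GLM `log mu = b0 + b_sex + log sf`
  with method-of-moments dispersions shrunk toward the trend
  `alpha(mu) = a0 + a1/mu`; Wald p-values, within-stage BH adjustment, and
  posterior-mode log2 fold-change shrinkage under a zero-centered normal
  prior. Genes with `|log2FC| >= 0.58` and `padj < 0.05` are called
  sex-biased (female-over-male orientation).
- **Enrichment grid**: one-tailed hypergeometric over/under tests of
  sex-biased genes per stage and direction against functional classes
  (protein-coding, transcription factors, epigenetic enzymes) and
  chromosome classes (autosome/X/Y), with the per-stage expressed genes as
  universe.
- **NMF metagenes**: multiplicative-update minimization of the generalized
  Kullback-Leibler divergence `D(V || WH)`, 10 restarts per candidate rank,
  consensus co-clustering of samples, and rank selection by the highest
  cophenetic correlation coefficient.
- **Pre-ranked GSEA** on metagene gene-loadings: weighted running-sum
  enrichment scores (positive scoring), gene-permutation null,
  `p = (1 + #{ES_perm >= ES}) / (1 + n_perm)`, BH across sets.
- **PPI edge classes**: stage subgraphs over expressed genes with edges
  classified by endpoint bias (MM/FF/NN/MN/FN/MF), normalized by class
  sizes, plus hive-plot layout export.
- **Cross-species conservation**: ortholog expression profiles over
  generalized stage groups (S1–S4), z-scored within species, scored by
  Pearson correlation with a pairing-permutation p-value.

## Worked example

```r
library(embryosex)

cfg <- sim_config(n_genes = 1000, n_stages = 3, cells_per_stage_per_sex = 20,
                  n_sexdeg_per_stage = 15, seed = 42)
sim <- simulate_counts(cfg)
#> simulated embryo dataset: 1000 genes x 120 cells, 3 stages

md <- sex_dataset(sim$counts, sim$metadata)
#> sex_dataset: 0 ambiguous cell(s) removed
table(md$sex)
#> female   male
#>     60     60

sf <- deconvolution_size_factors(sim$counts[, md$cell_id])
de <- run_sexde(sim$counts[, md$cell_id], md, sf)
de$counts
#>   stage male female
#> 1    E1    4     11
#> 2    E2    6      9
#> 3    E3    6      7

grid <- enrichment_grid(de$results, sim$annotation)
subset(grid, stage == "E1" & direction == "female" & category == "X",
       select = c(n_deg, n_overlap, fold, p_over))
#>    n_deg n_overlap     fold    p_over
#> 11    11         2 3.629091 0.1013629
```

All 120 cells are sexed correctly (the generator's marker separation is
clean), and each stage yields a handful of male- and female-biased calls:
the 15 planted sex-differential genes per stage are recovered subject to
power at low expression, while the false-positive rate stays below the BH
level. The grid row shows the X chromosome over-represented (3.6-fold)
among E1 female-biased genes — the generator plants X-linked effects as
female-biased — though with 11 sex-biased genes the tail probability is
still above 0.05.

Downstream, `select_rank()` / `nmf_fit()` factor the log-normalized matrix
into metagenes, `gsea_preranked()` scores gene sets against metagene
loadings, `classify_edges()` tallies interaction classes on a PPI edge
list, and `conservation_scores()` compares ortholog stage profiles between
two species.

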