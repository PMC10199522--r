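toy_species <- function(n_genes, n_cells, groups, prefix, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
                dimnames = list(sprintf("%sg%02d", prefix, seq_len(n_genes)),
                                sprintf("%sc%02d", prefix, seq_len(n_cells))))
  })
  md <- data.frame(cell_id = colnames(x),
                   group = rep_len(groups, n_cells),
                   stringsAsFactors = FALSE)
  list(norm = x, md = md)
}

test_that("stage-to-group mapping validates coverage and merges sizes", {
  md <- data.frame(cell_id = sprintf("c%02d", 1:8),
                   stage = rep(c("2cell", "4cell", "8cell", "blast"), 2))
  map <- c(`2cell` = "S1", `4cell` = "S1", `8cell` = "S2", blast = "S3")
  out <- suppressMessages(assign_generalized_stages(md, map))
  expect_equal(sum(out$group == "S1"), 4)   # two stages merged
  expect_equal(sum(out$group == "S2"), 2)

  # identity mapping reproduces the stages
  idmap <- setNames(unique(md$stage), unique(md$stage))
  out2 <- suppressMessages(assign_generalized_stages(md, idmap))
  expect_identical(out2$group, as.character(md$stage))

  expect_error(assign_generalized_stages(md, map[-2]), "4cell")
})

test_that("conservation scores hit the correlation extremes", {
  # species A: 4 groups, profile strictly increasing; B identical or reversed
  groups <- c("S1", "S2", "S3", "S4")
  mk <- function(profiles, prefix) {
    x <- profiles[, rep(1:4, each = 2)]
    dimnames(x) <- list(rownames(profiles),
                        sprintf("%sc%02d", prefix, 1:8))
    list(norm = x,
         md = data.frame(cell_id = colnames(x), group = rep(groups, each = 2)))
  }
  pa <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1, 5, 5, 5, 5), 3, 4, byrow = TRUE,
               dimnames = list(c("up", "down", "flat"), NULL))
  A <- mk(pa, "a")
  pb <- pa; rownames(pb) <- paste0("b_", rownames(pa))
  B <- mk(pb, "b")
  orth <- data.frame(gene_a = c("up", "down", "flat"),
                     gene_b = c("b_up", "b_down", "b_flat"))
  cs <- conservation_scores(A$norm, B$norm, A$md, B$md, orth, n_perm = 49,
                            seed = 1)
  expect_equal(cs$score[cs$gene_a == "up"], 1, tolerance = 1e-12)
  expect_equal(cs$score[cs$gene_a == "down"], 1, tolerance = 1e-12)
  expect_true(is.na(cs$score[cs$gene_a == "flat"]))   # constant profile

  # reversed pairing gives perfect anticorrelation
  orth_rev <- data.frame(gene_a = c("up"), gene_b = c("b_down"))
  cs2 <- conservation_scores(A$norm, B$norm, A$md, B$md, orth_rev,
                             n_perm = 9, seed = 1)
  expect_equal(cs2$score, -1, tolerance = 1e-12)
})

test_that("pairing-permutation p-values match exhaustive enumeration", {
  A <- toy_species(5, 12, c("S1", "S2", "S3", "S4"), "a", 91)
  B <- toy_species(5, 12, c("S1", "S2", "S3", "S4"), "b", 92)
  orth <- data.frame(gene_a = rownames(A$norm), gene_b = rownames(B$norm))
  exact <- conservation_scores(A$norm, B$norm, A$md, B$md, orth, exact = TRUE)

  # brute force over all 5! pairings: pair i's null is its score under the
  # partner each permutation assigns, uniform over all partners
  prof <- function(sp) {
    g <- unique(sp$md$group)
    p <- sapply(sort(g), function(gg)
      rowMeans(sp$norm[, sp$md$cell_id[sp$md$group == gg], drop = FALSE]))
    t(scale(t(p)))
  }
  zA <- prof(A); zB <- prof(B)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ]
  for (i in 1:5) {
    obs <- sum(zA[i, ] * zB[i, ]) / 3
    nulls <- apply(perms, 1, function(pp) sum(zA[i, ] * zB[pp[i], ]) / 3)
    row <- which(exact$gene_a == rownames(A$norm)[i])
    # all-pairings enumeration reduces to the uniform-partner null
    expect_equal(exact$pvalue[row], mean(nulls >= obs), tolerance = 1e-12)
  }

  # Monte-Carlo pairing permutations converge to the exact values
  mc <- conservation_scores(A$norm, B$norm, A$md, B$md, orth, n_perm = 2000,
                            seed = 3)
  expect_equal(mc$pvalue, exact$pvalue[match(mc$gene_a, exact$gene_a)],
               tolerance = 0.15)
})

test_that("conservation scoring is symmetric in the two species", {
  A <- toy_species(8, 16, c("S1", "S2", "S3", "S4"), "a", 93)
  B <- toy_species(8, 16, c("S1", "S2", "S3", "S4"), "b", 94)
  orth <- data.frame(gene_a = rownames(A$norm), gene_b = rownames(B$norm))
  ab <- conservation_scores(A$norm, B$norm, A$md, B$md, orth, exact = TRUE)
  orth_swapped <- data.frame(gene_a = orth$gene_b, gene_b = orth$gene_a)
  ba <- conservation_scores(B$norm, A$norm, B$md, A$md, orth_swapped,
                            exact = TRUE)
  m <- match(ab$gene_a, ba$gene_b)
  expect_equal(ab$score, ba$score[m], tolerance = 1e-12)
})

test_that("shared planted programs raise true-pair scores above shuffled ones", {
  sim_a <- simulate_counts(sim_config(n_genes = 600, n_stages = 4,
                                      cells_per_stage_per_sex = 10,
                                      n_sexdeg_per_stage = 0, seed = 95))
  # species B shares the metagene stage programs but redraws everything else
  reseed <- simulate_counts(sim_config(n_genes = 600, n_stages = 4,
                                       cells_per_stage_per_sex = 10,
                                       n_sexdeg_per_stage = 0, seed = 96))
  map <- setNames(paste0("S", 1:4), paste0("E", 1:4))
  mdA <- suppressMessages(assign_generalized_stages(sim_a$metadata, map))
  mdB <- suppressMessages(assign_generalized_stages(reseed$metadata, map))
  normA <- log_normalize(sim_a$counts, library_size_factors(sim_a$counts))
  normB <- log_normalize(reseed$counts, library_size_factors(reseed$counts))
  # true pairs: genes planted in the same metagene in both datasets
  memA <- sim_a$truth$metagene_membership
  memB <- reseed$truth$metagene_membership
  shared <- names(memA)[!is.na(memA) & !is.na(memB) & memA == memB]
  shared <- head(shared, 200)
  orth_true <- data.frame(gene_a = shared, gene_b = shared)
  withr::with_seed(1, {
    orth_shuf <- data.frame(gene_a = shared, gene_b = sample(shared))
  })
  cs_true <- conservation_scores(normA, normB, mdA, mdB, orth_true,
                                 n_perm = 9, seed = 1)
  cs_shuf <- conservation_scores(normA, normB, mdA, mdB, orth_shuf,
                                 n_perm = 9, seed = 1)
  expect_gt(mean(cs_true$score, na.rm = TRUE),
            mean(cs_shuf$score, na.rm = TRUE))
})

test_that("top-expression masks select strictly-above-quantile entries", {
  x <- rbind(const = rep(2, 10), inc = 1:10)
  colnames(x) <- sprintf("s%02d", 1:10)
  m9 <- top_expression_mask(x, q = 0.9)
  expect_false(any(m9["const", ]))
  expect_equal(sum(m9["inc", ]), 1)       # only the maximum exceeds q90
  expect_true(m9["inc", "s10"])
  m_low <- top_expression_mask(x, q = 0.001)
  expect_equal(sum(m_low["inc", ]), 9)    # everything above the minimum
  expect_error(top_expression_mask(x, q = 1), "strictly")
})
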