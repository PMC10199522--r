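make_nb_stage <- function(n_genes, n_per_sex, mu, alpha, lfc = 0, seed = 1,
                          biased_frac = 0) {
  withr::with_seed(seed, {
    n <- 2 * n_per_sex
    sex <- rep(c("male", "female"), each = n_per_sex)
    mu_g <- if (length(mu) == 1) rep(mu, n_genes) else mu
    biased <- seq_len(floor(biased_frac * n_genes))
    m <- matrix(0L, n_genes, n,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n))))
    for (g in seq_len(n_genes)) {
      mm <- rep(mu_g[g], n)
      if (g %in% biased) mm[sex == "female"] <- mu_g[g] * 2^lfc
      m[g, ] <- rnbinom(n, mu = mm, size = 1 / alpha)
    }
    list(counts = m, sex = sex, biased = rownames(m)[biased])
  })
}

test_that("dispersion estimation recovers a flat trend and floors degeneracies", {
  d <- make_nb_stage(300, 250, mu = exp(runif(1)), alpha = 0.2, seed = 41)
  # genes spread over a range of means
  d2 <- withr::with_seed(42, {
    mu <- exp(runif(300, log(2), log(50)))
    m <- matrix(rnbinom(300 * 500, mu = rep(mu, 500), size = 1 / 0.2),
                300, 500, dimnames = list(sprintf("g%03d", 1:300),
                                          sprintf("c%03d", 1:500)))
    m
  })
  dm <- estimate_dispersions(d2, rep(1, 500))
  expect_equal(unname(dm$trend["a0"]), 0.2, tolerance = 0.15)
  expect_lt(abs(dm$trend["a1"]), 0.5)
  expect_true(all(dm$shrunk > 0))

  # Poisson data: dispersions shrink toward the floor
  pois <- withr::with_seed(43, {
    matrix(stats::rpois(200 * 1000, 10), 200, 1000,
           dimnames = list(sprintf("g%03d", 1:200), sprintf("c%04d", 1:1000)))
  })
  dp <- estimate_dispersions(pois, rep(1, 1000))
  expect_lt(median(dp$shrunk), 0.02)

  # constant counts: method-of-moments dispersion is zero (floored)
  const <- toy_counts(5, 1, 20)
  dc <- estimate_dispersions(const, rep(1, 20))
  expect_equal(unname(dc$raw), 0)
  expect_equal(unname(dc$shrunk), 1e-8, tolerance = 1e-6)
})

test_that("the Wald test is calibrated on null data", {
  d <- make_nb_stage(400, 50, mu = 20, alpha = 0.1, seed = 44)
  res <- wald_test(d$counts, d$sex, rep(1, ncol(d$counts)))
  expect_true(all(abs(res$log2fc_raw) < 1))
  expect_lt(median(abs(res$log2fc_raw)), 0.1)
  ks <- stats::ks.test(res$pvalue[res$converged], "punif")
  expect_gt(ks$p.value, 0.01)
  # BH monotonicity: padj within [p, 1], non-decreasing in p rank
  ord <- order(res$pvalue)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$pvalue - 1e-12 & res$padj <= 1))
})

test_that("planted effects are detected with high power", {
  d <- make_nb_stage(200, 20, mu = 20, alpha = 0.1, lfc = 2, seed = 45,
                     biased_frac = 1)
  res <- wald_test(d$counts, d$sex, rep(1, ncol(d$counts)))
  power <- mean(res$padj < 0.05 & res$log2fc_raw > 0.58, na.rm = TRUE)
  expect_gte(power, 0.9)
  expect_equal(median(res$log2fc_raw), 2, tolerance = 0.15)
})

test_that("all-zero genes are excluded and label swaps flip the contrast", {
  d <- make_nb_stage(50, 15, mu = 8, alpha = 0.2, seed = 46)
  counts <- d$counts
  counts[3, ] <- 0L
  res <- wald_test(counts, d$sex, rep(1, ncol(counts)))
  expect_false("g0003" %in% res$gene_id)

  swapped <- ifelse(d$sex == "male", "female", "male")
  res2 <- wald_test(counts, swapped, rep(1, ncol(counts)))
  expect_equal(res2$log2fc_raw, -res$log2fc_raw, tolerance = 1e-6)
  expect_equal(res2$pvalue, res$pvalue, tolerance = 1e-6)
})

test_that("fold-change shrinkage matches a 1-D posterior-mode oracle", {
  res <- data.frame(gene_id = c("a", "b", "c"), stage = "E1",
                    log2fc_raw = c(3, 0, 1) / log(2) * log(2),
                    se = c(3, 1, 0.001) / log(2) * log(2))
  res$log2fc_raw <- c(3, 0, 1); res$se <- c(3, 1, 1e-4)
  shr <- shrink_lfc(res, prior_sd_grid = 0.5)  # fixed prior SD (log scale)
  prior_sd <- attr(shr, "prior_sd")
  expect_equal(prior_sd, 0.5)
  for (i in 1:3) {
    beta_hat <- res$log2fc_raw[i] * log(2)
    se <- res$se[i] * log(2)
    oracle <- stats::optimize(function(b)
      -stats::dnorm(beta_hat, b, se, log = TRUE) -
        stats::dnorm(b, 0, prior_sd, log = TRUE),
      interval = c(-10, 10), tol = 1e-10)$minimum
    expect_equal(shr$log2fc_shrunk[i], oracle / log(2), tolerance = 1e-6)
  }
  # raw 0 stays 0; shrunken never exceeds raw in magnitude
  expect_equal(shr$log2fc_shrunk[2], 0)
  expect_true(all(abs(shr$log2fc_shrunk) <= abs(shr$log2fc_raw) + 1e-12))
  # tiny SE: likelihood dominates and shrinkage is negligible
  expect_equal(shr$log2fc_shrunk[3], shr$log2fc_raw[3], tolerance = 1e-4)
})

test_that("classification applies the fold-change and FDR thresholds by enumeration", {
  res <- data.frame(
    gene_id = sprintf("g%02d", 1:10), stage = "E1",
    log2fc_raw = 0, se = 1,
    log2fc_shrunk = c(1, -1, 0.6, -0.6, 0.5, -0.5, 2, -2, 0.58, -0.58),
    padj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.2, 0.2, 0.049, 0.051),
    pvalue = 0.001
  )
  cl <- classify_and_count(res)
  expect_equal(cl$results$bias,
               c("female", "male", "female", "male", "none", "none",
                 "none", "none", "female", "none"))
  expect_equal(cl$counts$female, 3)
  expect_equal(cl$counts$male, 2)

  res$padj <- 1
  cl2 <- classify_and_count(res)
  expect_equal(cl2$counts$male + cl2$counts$female, 0)
})

test_that("the full per-stage pipeline recovers planted sexDEGs", {
  sim <- small_sim(seed = 47)
  md <- suppressMessages(sex_dataset(sim$counts, sim$metadata))
  sf <- deconvolution_size_factors(sim$counts[, md$cell_id])
  de <- suppressMessages(run_sexde(sim$counts[, md$cell_id], md, sf))
  planted <- sim$truth$planted_sexdegs
  recall <- sapply(names(planted), function(s) {
    r <- de$results[de$results$stage == s, ]
    called <- r$bias[match(planted[[s]]$gene_id, r$gene_id)]
    mean(!is.na(called) & called == planted[[s]]$direction)
  })
  # pooled recall over stages; power is limited for low-expressed genes
  expect_gt(mean(recall), 0.5)
  null_genes <- setdiff(de$results$gene_id,
                        unlist(lapply(planted, `[[`, "gene_id")))
  fp <- mean(de$results$bias[de$results$gene_id %in% null_genes] != "none")
  expect_lt(fp, 0.05)
})

test_that("Wald fold changes agree with an established NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  d <- make_nb_stage(100, 20, mu = exp(withr::with_seed(48, runif(100, 1, 4))),
                     alpha = 0.15, lfc = 1.5, seed = 48, biased_frac = 0.3)
  sf <- rep(1, ncol(d$counts))
  mine <- wald_test(d$counts, d$sex, sf)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    d$counts, data.frame(sex = factor(d$sex, levels = c("male", "female"))),
    ~sex)
  DESeq2::sizeFactors(dds) <- sf
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  common <- intersect(mine$gene_id, rownames(ref))
  expect_gt(cor(mine$log2fc_raw[match(common, mine$gene_id)],
                ref[common, "log2FoldChange"]), 0.95)
})

test_that("intersection patterns match brute-force enumeration", {
  # disjoint sets
  di <- deg_intersections(list(A = c("x", "y"), B = c("z")))
  expect_true(all(di$degree == 1))
  # identical sets
  id <- deg_intersections(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(id$pattern, "A&B")
  expect_equal(id$size, 2)
  # three overlapping sets vs direct membership enumeration
  sets <- list(A = c("a", "b", "c", "d"), B = c("c", "d", "e"),
               C = c("d", "e", "f"))
  out <- deg_intersections(sets)
  universe <- unique(unlist(sets))
  brute <- table(vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)], collapse = "&")
  }, character(1)))
  for (i in seq_len(nrow(out)))
    expect_equal(out$size[i], unname(brute[out$pattern[i]]))
  expect_equal(sum(out$size), length(universe))
})
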