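# independent alternating-optimization oracle: minimize the generalized KL
# divergence by numerically optimizing one factor at a time (L-BFGS-B on
# log-parameters) until convergence
oracle_kl_nmf <- function(V, W, H, sweeps = 200) {
  kl <- function(W, H) {
    WH <- pmax(W %*% H, 1e-12)
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  for (s in seq_len(sweeps)) {
    before <- kl(W, H)
    oh <- stats::optim(log(as.vector(H)), function(lh)
      kl(W, matrix(exp(lh), nrow(H), ncol(H))),
      method = "L-BFGS-B", control = list(maxit = 200))
    H <- matrix(exp(oh$par), nrow(H), ncol(H))
    ow <- stats::optim(log(as.vector(W)), function(lw)
      kl(matrix(exp(lw), nrow(W), ncol(W)), H),
      method = "L-BFGS-B", control = list(maxit = 200))
    W <- matrix(exp(ow$par), nrow(W), ncol(W))
    if (abs(before - kl(W, H)) < 1e-10) break
  }
  kl(W, H)
}

test_that("multiplicative updates factor exact low-rank matrices", {
  withr::with_seed(61, {
    w <- runif(8, 0.5, 2); h <- runif(6, 0.5, 2)
  })
  V <- outer(w, h)
  dimnames(V) <- list(paste0("g", 1:8), paste0("s", 1:6))
  fit <- nmf_fit(V, 1, seed = 2, max_iter = 2000, tol = 0)
  expect_lt(fit$divergence, 1e-8)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("the objective trace never increases", {
  for (s in 1:5) {
    V <- withr::with_seed(s, matrix(runif(30 * 12), 30, 12))
    dimnames(V) <- list(paste0("g", 1:30), paste0("s", 1:12))
    fit <- nmf_fit(V, 3, seed = s, max_iter = 150)
    expect_true(all(diff(fit$objective) <= 1e-8 * max(1, abs(fit$objective[1]))))
  }
  expect_error(nmf_fit(matrix(c(-1, 1, 1, 1), 2, 2), 1), "non-negative")
})

test_that("converged divergence matches an alternating-optimization oracle", {
  # the KL objective is multimodal, so a single shared initialization can
  # end in different basins; compare the best divergence over restarts
  V <- withr::with_seed(62, matrix(runif(6 * 5, 0.1, 2), 6, 5))
  dimnames(V) <- list(paste0("g", 1:6), paste0("s", 1:5))
  mu_best <- Inf; oracle_best <- Inf
  for (s in 1:5) {
    fit <- nmf_fit(V, 2, seed = s, max_iter = 50000, tol = 0)
    mu_best <- min(mu_best, fit$divergence)
    init <- withr::with_seed(s, {
      scale <- sqrt(max(mean(V), 1e-10) / (2 / 4))
      list(W = matrix(runif(6 * 2, 1e-10, 1), 6, 2) * scale,
           H = matrix(runif(2 * 5, 1e-10, 1), 2, 5) * scale)
    })
    oracle_best <- min(oracle_best, oracle_kl_nmf(V, init$W, init$H))
  }
  expect_equal(mu_best, oracle_best, tolerance = 1e-6)
})

test_that("rescaling a factor pair leaves the reconstruction unchanged", {
  V <- withr::with_seed(63, matrix(runif(20 * 8, 0, 3), 20, 8))
  dimnames(V) <- list(paste0("g", 1:20), paste0("s", 1:8))
  fit <- nmf_fit(V, 3, seed = 1, max_iter = 100)
  W2 <- fit$W; H2 <- fit$H
  lambda <- 4.2
  W2[, 2] <- W2[, 2] * lambda
  H2[2, ] <- H2[2, ] / lambda
  expect_equal(W2 %*% H2, fit$W %*% fit$H, tolerance = 1e-10)
})

test_that("consensus matrices and cophenetic coefficients are coherent", {
  p <- planted_nmf_matrix()
  cc <- consensus_and_cophenetic(p$V, 3, n_runs = 4, seed = 5, max_iter = 200)
  # consensus reconstructed by brute-force pair counting over run labels
  S <- ncol(p$V)
  brute <- matrix(0, S, S)
  for (r in seq_len(nrow(cc$labels)))
    brute <- brute + outer(cc$labels[r, ], cc$labels[r, ], "==")
  brute <- brute / nrow(cc$labels)
  expect_equal(unname(cc$consensus), brute, tolerance = 1e-12)
  # crisp planted blocks: identical partitions across runs, cophenetic 1
  expect_true(all(cc$consensus %in% c(0, 1)))
  expect_equal(cc$cophenetic, 1)
})

test_that("random independent partitions give low cophenetic coefficients", {
  cophs <- sapply(1:10, function(s) {
    labels <- withr::with_seed(100 + s,
      matrix(sample(1:4, 10 * 60, replace = TRUE), 10, 60))
    C <- matrix(0, 60, 60)
    for (r in 1:10) C <- C + outer(labels[r, ], labels[r, ], "==")
    cophenetic_coefficient(C / 10)
  })
  expect_lt(mean(cophs), 0.8)
})

test_that("rank selection recovers planted structure and breaks ties low", {
  p <- planted_nmf_matrix()
  rs <- select_rank(p$V, ranks = 2:6, n_runs = 4, seed = 9, max_iter = 200)
  expect_equal(rs$chosen_rank, 3)
  expect_true(all(rs$curve$cophenetic >= -1 & rs$curve$cophenetic <= 1))

  # single candidate rank is chosen trivially
  rs1 <- select_rank(p$V, ranks = 4, n_runs = 2, seed = 1, max_iter = 50)
  expect_equal(rs1$chosen_rank, 4)

  # a two-block matrix scores 1 at both rank 1 (single cluster convention)
  # and rank 2; the tie resolves to the smaller rank
  two <- planted_nmf_matrix(n_per_module = 20, n_modules = 2,
                            samples_per_block = 10, noise = 0.05, seed = 11)
  rs2 <- select_rank(two$V, ranks = c(1, 2), n_runs = 3, seed = 2,
                     max_iter = 200)
  expect_equal(rs2$curve$cophenetic, c(1, 1))
  expect_equal(rs2$chosen_rank, 1)
})

test_that("metagene membership recovers planted modules", {
  p <- planted_nmf_matrix()
  fit <- nmf_fit(p$V, 3, seed = 4, max_iter = 500)
  mm <- metagene_membership(fit)
  expect_gte(adjusted_rand(mm$membership, p$membership), 0.9)

  # argmax rule and all-zero rows
  W <- rbind(c(0.1, 5, 0.2), c(0, 0, 0))
  rownames(W) <- c("gA", "gB")
  fake <- structure(list(W = W, H = matrix(1, 3, 2,
                                           dimnames = list(NULL, c("s1", "s2")))),
                    class = "nmf_fit")
  mm2 <- suppressMessages(metagene_membership(fake))
  expect_equal(unname(mm2$membership["gA"]), 2L)
  expect_true(is.na(mm2$membership["gB"]))
})

test_that("per-sex factorization at study-like sample sizes yields the planted rank", {
  # mirrors the smaller sex-specific table (dozens of samples per sex)
  p <- planted_nmf_matrix(n_per_module = 25, n_modules = 3,
                          samples_per_block = 12, noise = 0.2, seed = 13)
  female <- p$V[, 1:35]
  rs <- select_rank(p$V, ranks = 2:4, n_runs = 10, seed = 3, max_iter = 200)
  expect_equal(rs$chosen_rank, 3)
  fit <- nmf_fit(female, 3, seed = 1, max_iter = 200)
  expect_equal(dim(fit$W), c(75L, 3L))
})
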