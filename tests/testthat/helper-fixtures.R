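# small simulated dataset shared across tests
small_sim <- function(seed = 3, ...) {
  simulate_counts(sim_config(n_genes = 400, n_stages = 3,
                             cells_per_stage_per_sex = 12,
                             n_sexdeg_per_stage = 10, seed = seed, ...))
}

# toy count matrix with ids
toy_counts <- function(values, n_genes, n_cells) {
  matrix(as.integer(values), n_genes, n_cells,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("c%02d", seq_len(n_cells))))
}

# adjusted Rand index (independent of any package implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force weighted KS running sum (independent of enrichment_score)
brute_es <- function(weights, set, p = 1, pos = TRUE) {
  ord <- order(-weights, names(weights))
  w <- abs(weights[ord])^p
  ids <- names(weights)[ord]
  hit <- ids %in% set
  run <- 0
  best <- 0
  denom_hit <- sum(w[hit])
  denom_miss <- length(ids) - sum(hit)
  path <- numeric(length(ids))
  for (i in seq_along(ids)) {
    run <- run + if (hit[i]) w[i] / denom_hit else -1 / denom_miss
    path[i] <- run
  }
  if (pos) max(0, path) else path[which.max(abs(path))]
}

# deterministic planted-block non-negative matrix for NMF tests
planted_nmf_matrix <- function(n_per_module = 30, n_modules = 3,
                               samples_per_block = 15, noise = 0.3,
                               seed = 7) {
  withr::with_seed(seed, {
    G <- n_per_module * n_modules
    S <- samples_per_block * n_modules
    W0 <- matrix(0, G, n_modules)
    H0 <- matrix(0, n_modules, S)
    for (m in seq_len(n_modules)) {
      W0[(m - 1) * n_per_module + seq_len(n_per_module), m] <- runif(n_per_module, 2, 4)
      H0[m, (m - 1) * samples_per_block + seq_len(samples_per_block)] <- runif(samples_per_block, 2, 4)
    }
    V <- W0 %*% H0 + matrix(runif(G * S, 0, noise), G, S)
    dimnames(V) <- list(sprintf("g%03d", seq_len(G)), sprintf("s%03d", seq_len(S)))
    list(V = V, membership = rep(seq_len(n_modules), each = n_per_module),
         sample_block = rep(seq_len(n_modules), each = samples_per_block))
  })
}
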