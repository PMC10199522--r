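#' Configuration for the embryo-like count simulator
#'
#' Bundles every knob of the two-sex, multi-stage single-cell count
#' generator. Defaults describe a small pre-implantation-like dataset:
#' a few thousand genes split over autosomes and the sex chromosomes,
#' a handful of developmental stages with both sexes present, negative
#' binomial counts with a mean-dependent dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}, excess zeros arising from low means,
#' and planted structure (sex-differential genes per stage, non-negative
#' stage programs grouping genes into metagenes, an Xist-like female marker
#' and a Y-linked male marker) that downstream modules can be scored
#' against.
#'
#' @param n_genes number of genes.
#' @param n_stages number of ordered developmental stages.
#' @param cells_per_stage_per_sex cells simulated per stage for each sex.
#' @param frac_x_linked,frac_y_linked fractions of genes placed on the X
#'   and Y chromosomes (the rest are autosomal).
#' @param frac_tf,frac_ee fractions of genes flagged as transcription
#'   factors and epigenetic enzymes.
#' @param n_sexdeg_per_stage number of sex-differential genes planted per
#'   stage (disjoint across stages).
#' @param sexdeg_log2fc planted log2 fold change (favoured sex over the
#'   other) for each planted sex-differential gene.
#' @param n_metagenes number of planted co-expression programs.
#' @param frac_metagene_genes fraction of genes assigned to a metagene.
#' @param baseline_logmean_mu,baseline_logmean_sd natural-log mean and sd
#'   of per-gene baseline expression means.
#' @param dispersion_a0,dispersion_a1 parameters of the dispersion trend
#'   \eqn{a_0 + a_1/\mu}.
#' @param libsize_sd sd (natural-log scale) of the per-cell depth
#'   multiplier; 0 gives equal depths.
#' @param marker_ids length-2 character vector naming the Xist-like and
#'   Y-linked marker genes, in that order.
#' @param seed integer seed; identical configurations reproduce
#'   bit-identical datasets.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_stages = 4L,
                       cells_per_stage_per_sex = 30L,
                       frac_x_linked = 0.05,
                       frac_y_linked = 0.01,
                       frac_tf = 0.05,
                       frac_ee = 0.03,
                       n_sexdeg_per_stage = 25L,
                       sexdeg_log2fc = 2,
                       n_metagenes = 3L,
                       frac_metagene_genes = 0.5,
                       baseline_logmean_mu = 1,
                       baseline_logmean_sd = 1.2,
                       dispersion_a0 = 0.1,
                       dispersion_a1 = 1,
                       libsize_sd = 0.3,
                       marker_ids = c("Xist", "Eif2s3y"),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_stages = as.integer(n_stages),
    cells_per_stage_per_sex = as.integer(cells_per_stage_per_sex),
    frac_x_linked = frac_x_linked, frac_y_linked = frac_y_linked,
    frac_tf = frac_tf, frac_ee = frac_ee,
    n_sexdeg_per_stage = as.integer(n_sexdeg_per_stage),
    sexdeg_log2fc = sexdeg_log2fc,
    n_metagenes = as.integer(n_metagenes),
    frac_metagene_genes = frac_metagene_genes,
    baseline_logmean_mu = baseline_logmean_mu,
    baseline_logmean_sd = baseline_logmean_sd,
    dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
    libsize_sd = libsize_sd,
    marker_ids = as.character(marker_ids),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$frac_x_linked, cfg$frac_y_linked, cfg$frac_tf, cfg$frac_ee,
             cfg$frac_metagene_genes)
  if (any(props < 0 | props > 1))
    .stopf("all fractions must lie in [0, 1]")
  if (cfg$frac_x_linked + cfg$frac_y_linked > 1)
    .stopf("frac_x_linked + frac_y_linked must not exceed 1")
  if (cfg$n_genes < 1 || cfg$n_stages < 1 || cfg$cells_per_stage_per_sex < 1)
    .stopf("n_genes, n_stages and cells_per_stage_per_sex must be >= 1")
  if (!is.finite(cfg$sexdeg_log2fc)) .stopf("sexdeg_log2fc must be finite")
  if (length(cfg$marker_ids) != 2L || anyDuplicated(cfg$marker_ids))
    .stopf("marker_ids must name two distinct genes")
  if (cfg$n_metagenes < 0) .stopf("n_metagenes must be >= 0")
  # trend must stay positive over any attainable mean
  if (cfg$dispersion_a0 <= 0 && cfg$dispersion_a1 <= 0)
    .stopf("dispersion trend a0 + a1/mu must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("embryo count simulator configuration\n")
  cat(sprintf("  %d genes (%.0f%% X, %.0f%% Y), %d stages x 2 sexes x %d cells\n",
              x$n_genes, 100 * x$frac_x_linked, 100 * x$frac_y_linked,
              x$n_stages, x$cells_per_stage_per_sex))
  cat(sprintf("  %d sexDEGs/stage at log2FC %.2f; %d metagenes; seed %d\n",
              x$n_sexdeg_per_stage, x$sexdeg_log2fc, x$n_metagenes, x$seed))
  invisible(x)
}

# metagene stage activity: one smooth non-negative bump per program, peaks
# spread across the stage axis so programs are distinguishable
.metagene_profiles <- function(n_metagenes, n_stages) {
  if (n_metagenes == 0L) return(matrix(0, 0, n_stages))
  peaks <- seq(1, n_stages, length.out = n_metagenes)
  width <- max(n_stages / (n_metagenes + 1), 0.5)
  out <- matrix(0, n_metagenes, n_stages)
  for (m in seq_len(n_metagenes))
    out[m, ] <- exp(-((seq_len(n_stages) - peaks[m])^2) / (2 * width^2))
  out
}

#' Simulate a two-sex embryo-like single-cell count dataset
#'
#' Draws a gene-by-cell negative binomial count matrix with stage-dependent
#' means (through planted metagene programs), per-stage sex-differential
#' genes, Y-linked genes silenced in females, an Xist-like marker expressed
#' highly in females and weakly in males, and a Y-linked marker expressed
#' only in males. Dispersion follows the trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param species species label stored in the sample metadata.
#'
#' @return A list of class \code{embryo_sim} with elements
#'   \item{counts}{integer gene-by-cell matrix with gene/cell identifiers;}
#'   \item{metadata}{data.frame with \code{cell_id}, ordered \code{stage},
#'     \code{species} (sex left unassigned for the sexing module);}
#'   \item{annotation}{per-gene \code{gene_id}, \code{symbol},
#'     \code{chromosome_class}, functional flags;}
#'   \item{truth}{planted ground truth: \code{true_sex},
#'     \code{planted_sexdegs} (per-stage gene/direction tables),
#'     \code{metagene_membership}, \code{cell_depth_factor}.}
#' @export
simulate_counts <- function(config, species = "simulated") {
  validate_sim_config(config)
  .with_seed(config$seed, .simulate_counts_impl(config, species))
}

.simulate_counts_impl <- function(cfg, species) {
  G <- cfg$n_genes; S <- cfg$n_stages
  stages <- sprintf("E%d", seq_len(S))
  n_per <- cfg$cells_per_stage_per_sex
  n_cells <- 2L * S * n_per

  gene_id <- sprintf("g%05d", seq_len(G))
  n_y <- round(cfg$frac_y_linked * G)
  n_x <- round(cfg$frac_x_linked * G)
  chrom <- rep("autosome", G)
  idx <- sample.int(G, n_x + n_y)
  chrom[idx[seq_len(n_x)]] <- "X"
  if (n_y > 0) chrom[idx[n_x + seq_len(n_y)]] <- "Y"

  # dedicated marker rows: an X-linked Xist-like gene and a Y-linked gene
  x_pool <- which(chrom == "X"); y_pool <- which(chrom == "Y")
  if (length(x_pool) == 0 || length(y_pool) == 0)
    .stopf("marker genes need at least one X-linked and one Y-linked gene; raise frac_x_linked/frac_y_linked")
  marker_x <- x_pool[1L]; marker_y <- y_pool[1L]
  gene_id[marker_x] <- cfg$marker_ids[1L]
  gene_id[marker_y] <- cfg$marker_ids[2L]

  is_tf <- rbinom(G, 1, cfg$frac_tf) == 1
  is_ee <- !is_tf & rbinom(G, 1, cfg$frac_ee) == 1
  annotation <- data.frame(
    gene_id = gene_id, symbol = gene_id,
    chromosome_class = chrom,
    is_protein_coding = TRUE, is_tf = is_tf, is_ee = is_ee,
    stringsAsFactors = FALSE
  )

  # baseline means and stage programs
  base_mu <- exp(rnorm(G, cfg$baseline_logmean_mu, cfg$baseline_logmean_sd))
  membership <- rep(NA_integer_, G)
  if (cfg$n_metagenes > 0 && cfg$frac_metagene_genes > 0) {
    n_in <- round(cfg$frac_metagene_genes * G)
    picked <- sample.int(G, n_in)
    membership[picked] <- sample.int(cfg$n_metagenes, n_in, replace = TRUE)
  }
  profiles <- .metagene_profiles(cfg$n_metagenes, S)  # metagene x stage
  mu_gs <- matrix(base_mu, G, S)                       # gene x stage
  in_mg <- which(!is.na(membership))
  if (length(in_mg)) {
    act <- profiles[membership[in_mg], , drop = FALSE]
    mu_gs[in_mg, ] <- mu_gs[in_mg, ] * (0.25 + 2.75 * act)
  }

  # planted sexDEGs: disjoint across stages, never markers or Y-linked;
  # planted X-linked effects are female-biased, autosomal direction random
  pool <- setdiff(which(chrom != "Y"), c(marker_x, marker_y))
  need <- cfg$n_sexdeg_per_stage * S
  if (need > length(pool))
    .stopf("cannot plant %d sexDEGs: only %d eligible genes", need, length(pool))
  planted <- list()
  deg_idx <- if (need > 0) sample(pool, need) else integer(0)
  for (s in seq_len(S)) {
    take <- deg_idx[seq_len(cfg$n_sexdeg_per_stage) + (s - 1L) * cfg$n_sexdeg_per_stage]
    if (cfg$n_sexdeg_per_stage == 0L) take <- integer(0)
    dir <- ifelse(chrom[take] == "X", "female",
                  sample(c("female", "male"), length(take), replace = TRUE))
    planted[[stages[s]]] <- data.frame(gene_id = gene_id[take],
                                       direction = dir,
                                       stringsAsFactors = FALSE)
  }

  # cells
  cell_sex <- rep(rep(c("female", "male"), each = n_per), S)
  cell_stage <- rep(stages, each = 2L * n_per)
  cell_id <- sprintf("c%04d", seq_len(n_cells))
  depth <- exp(rnorm(n_cells, 0, cfg$libsize_sd))

  counts <- matrix(0L, G, n_cells, dimnames = list(gene_id, cell_id))
  fc <- 2^cfg$sexdeg_log2fc
  for (s in seq_len(S)) {
    for (sx in c("female", "male")) {
      cols <- which(cell_stage == stages[s] & cell_sex == sx)
      mu <- mu_gs[, s]
      pl <- planted[[stages[s]]]
      if (nrow(pl)) {
        gi <- match(pl$gene_id, gene_id)
        boost <- pl$direction == sx
        mu[gi[boost]] <- mu[gi[boost]] * fc
      }
      if (sx == "female") {
        mu[chrom == "Y"] <- 0
        mu[marker_x] <- 50
      } else {
        mu[marker_x] <- 0.5
        mu[marker_y] <- 30
      }
      mu_cells <- outer(mu, depth[cols])          # gene x cells in block
      alpha <- cfg$dispersion_a0 + cfg$dispersion_a1 / pmax(mu_cells, 1e-8)
      draw <- rnbinom(length(mu_cells), mu = as.vector(mu_cells),
                      size = 1 / as.vector(alpha))
      draw[as.vector(mu_cells) == 0] <- 0L
      counts[, cols] <- draw
    }
  }
  storage.mode(counts) <- "integer"

  metadata <- data.frame(
    cell_id = cell_id,
    stage = factor(cell_stage, levels = stages, ordered = TRUE),
    species = species,
    sex = NA_character_,
    stringsAsFactors = FALSE
  )

  truth <- list(
    gene_annotation = annotation,
    true_sex = setNames(cell_sex, cell_id),
    planted_sexdegs = planted,
    metagene_membership = setNames(membership, gene_id),
    module_edges = NULL,
    cell_depth_factor = setNames(depth, cell_id)
  )

  structure(list(counts = counts, metadata = metadata,
                 annotation = annotation, truth = truth, config = cfg),
            class = "embryo_sim")
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("simulated embryo dataset: %d genes x %d cells, %d stages\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$metadata$stage)))
  invisible(x)
}

#' Simulate gene set collections matched to planted metagenes
#'
#' Builds one gene set per planted metagene (its member genes, truncated to
#' 500) plus decoy sets of uniformly sampled genes; all set sizes fall in
#' [15, 500] by construction, matching the size window used by the
#' pre-ranked enrichment step.
#'
#' @param truth the \code{truth} element of an \code{\link{simulate_counts}}
#'   result.
#' @param n_decoy_sets number of random decoy sets to add.
#' @param seed integer seed.
#' @return Named list of character vectors (a gene set collection).
#' @export
simulate_genesets <- function(truth, n_decoy_sets = 5L, seed = 1L) {
  mem <- truth$metagene_membership
  if (all(is.na(mem))) .stopf("truth has no metagene membership")
  genes <- names(mem)
  .with_seed(seed, {
    sets <- list()
    for (m in sort(unique(mem[!is.na(mem)]))) {
      members <- genes[!is.na(mem) & mem == m]
      if (length(members) > 500L) members <- members[seq_len(500L)]
      if (length(members) < 15L) {
        pad <- sample(setdiff(genes, members), 15L - length(members))
        members <- c(members, pad)
      }
      sets[[sprintf("metagene_set_%d", m)]] <- members
    }
    if (n_decoy_sets > 0) {
      for (d in seq_len(n_decoy_sets)) {
        size <- sample(15:min(500L, length(genes)), 1L)
        sets[[sprintf("decoy_set_%d", d)]] <- sample(genes, size)
      }
    }
    sets
  })
}

# map linear upper-triangle index k (ordering (1,2),(1,3),(2,3),(1,4)...) to (i,j)
.pair_from_index <- function(k) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i, j)
}

#' Simulate a protein-protein interaction edge list over simulated genes
#'
#' Genes sharing a planted metagene are connected with probability
#' \code{p_within}; all other pairs with probability \code{p_between}.
#' Returns an undirected, deduplicated, self-loop-free edge list.
#'
#' @param truth the \code{truth} element of a simulated dataset.
#' @param p_within,p_between edge probabilities (requires
#'   \code{p_within >= p_between}).
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#'   (canonically ordered so \code{gene_a < gene_b}).
#' @export
simulate_ppi <- function(truth, p_within = 0.2, p_between = 0.01, seed = 1L) {
  if (p_within < p_between) .stopf("p_within must be >= p_between")
  mem <- truth$metagene_membership
  genes <- names(mem)
  n <- length(genes)
  .with_seed(seed, {
    # background edges over every pair, then re-decide within-module pairs
    n_pairs <- n * (n - 1) / 2
    k_bg <- rbinom(1L, n_pairs, p_between)
    edges <- if (k_bg > 0) {
      ij <- .pair_from_index(sort(sample(n_pairs, k_bg)))
      data.frame(a = ij[, 1], b = ij[, 2])
    } else data.frame(a = integer(0), b = integer(0))
    same_module <- !is.na(mem[edges$a]) & !is.na(mem[edges$b]) &
      mem[edges$a] == mem[edges$b]
    edges <- edges[!same_module, , drop = FALSE]
    for (m in unique(mem[!is.na(mem)])) {
      mg <- which(!is.na(mem) & mem == m)
      if (length(mg) >= 2) {
        prs <- t(combn(mg, 2))
        keep <- runif(nrow(prs)) < p_within
        edges <- rbind(edges, data.frame(a = prs[keep, 1], b = prs[keep, 2]))
      }
    }
    if (nrow(edges) == 0)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        stringsAsFactors = FALSE))
    ga <- genes[pmin(edges$a, edges$b)]
    gb <- genes[pmax(edges$a, edges$b)]
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    out <- unique(data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
  })
}
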