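#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative gene-by-sample matrix \eqn{V \approx WH} by
#' minimizing the generalized Kullback-Leibler divergence
#' \eqn{D(V \| WH) = \sum V \log(V/WH) - V + WH} with the classical
#' multiplicative update rules, which never increase the objective.
#' Initialization draws \eqn{W, H} uniformly on (0, 1] and rescales them to
#' the data mean; runs are deterministic given the seed. A Frobenius
#' objective is available behind \code{objective = "frobenius"}.
#'
#' @param V non-negative matrix (genes x samples).
#' @param k factorization rank.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol stop when the relative objective change drops below this.
#' @param objective \code{"kl"} (default) or \code{"frobenius"}.
#' @return Object of class \code{nmf_fit}: \code{W} (genes x k), \code{H}
#'   (k x samples), \code{objective} (per-iteration trace), \code{k},
#'   \code{seed}, \code{iterations}.
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                    objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  V <- .as_dense(V)
  if (any(V < 0)) .stopf("NMF input must be non-negative")
  if (k < 1 || k > min(dim(V))) .stopf("rank k must be in [1, min(dim(V))]")
  eps <- 1e-10
  G <- nrow(V); S <- ncol(V)
  init <- .with_seed(seed, {
    scale <- sqrt(max(mean(V), eps) / (k / 4))
    list(W = matrix(runif(G * k, eps, 1), G, k) * scale,
         H = matrix(runif(k * S, eps, 1), k, S) * scale)
  })
  W <- init$W; H <- init$H
  obj_fun <- function(W, H) {
    WH <- W %*% H
    if (objective == "kl") {
      pos <- V > 0
      sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
    } else sum((V - WH)^2) / 2
  }
  trace <- numeric(0)
  last <- obj_fun(W, H)
  trace <- last
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H), G, k, byrow = TRUE), eps)
    } else {
      H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, eps)
      W <- W * (V %*% t(H)) / pmax(W %*% H %*% t(H), eps)
    }
    cur <- obj_fun(W, H)
    trace <- c(trace, cur)
    if (abs(last - cur) < tol * max(abs(last), eps)) { last <- cur; break }
    last <- cur
  }
  rownames(W) <- rownames(V); colnames(H) <- colnames(V)
  out <- list(W = W, H = H, objective = trace, k = k, seed = seed,
              iterations = length(trace) - 1L, divergence = last,
              objective_type = objective)
  class(out) <- "nmf_fit"
  out
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: rank %d, %d x %d matrix, %d iterations, final %s divergence %.6g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations, x$objective_type,
              x$divergence))
  invisible(x)
}

#' Consensus matrix and cophenetic coefficient across NMF restarts
#'
#' Runs the factorization from \code{n_runs} random initializations,
#' assigns each sample to the metagene with the largest mixture weight
#' (argmax over the corresponding column of H), and records in the
#' consensus matrix the fraction of runs in which each sample pair
#' co-clusters. The cophenetic coefficient is the correlation between the
#' consensus dissimilarity (1 - C) and the cophenetic distances of its
#' average-linkage dendrogram; a perfectly stable block partition gives 1.
#' When the consensus dissimilarity is constant (e.g. a single cluster in
#' every run) agreement is perfect by convention and 1 is returned.
#'
#' @param V non-negative matrix.
#' @param k rank.
#' @param n_runs number of restarts (>= 2).
#' @param seeds optional integer vector of per-run seeds (length
#'   \code{n_runs}); defaults to \code{seed + 0:(n_runs-1)}.
#' @param seed base seed used when \code{seeds} is absent.
#' @param ... passed to [nmf_fit()].
#' @return List: \code{consensus} (samples x samples), \code{cophenetic},
#'   \code{labels} (runs x samples cluster assignments).
#' @export
consensus_and_cophenetic <- function(V, k, n_runs = 10L, seeds = NULL,
                                     seed = 1L, ...) {
  if (n_runs < 2) .stopf("n_runs must be >= 2")
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  if (length(seeds) != n_runs) .stopf("need one seed per run")
  V <- .as_dense(V)
  S <- ncol(V)
  labels <- matrix(NA_integer_, n_runs, S)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(V, k, seed = seeds[r], ...)
    labels[r, ] <- apply(fit$H, 2, which.max)
  }
  C <- matrix(0, S, S)
  for (r in seq_len(n_runs)) {
    same <- outer(labels[r, ], labels[r, ], "==")
    C <- C + same
  }
  C <- C / n_runs
  dimnames(C) <- list(colnames(V), colnames(V))
  list(consensus = C, cophenetic = cophenetic_coefficient(C), labels = labels)
}

#' Cophenetic correlation of a consensus matrix
#'
#' @param C consensus (co-clustering fraction) matrix.
#' @return Correlation between 1 - C and the cophenetic distances of its
#'   average-linkage hierarchical clustering; 1 when the dissimilarity is
#'   constant.
#' @export
cophenetic_coefficient <- function(C) {
  d <- as.dist(1 - C)
  if (length(d) == 0 || sd(d) == 0) return(1)
  hc <- hclust(d, method = "average")
  dc <- cophenetic(hc)
  if (sd(dc) == 0) return(if (sd(d) == 0) 1 else 0)
  cor(d, dc)
}

#' Select the NMF rank by the cophenetic criterion
#'
#' Evaluates each candidate rank with [consensus_and_cophenetic()] and
#' chooses the rank with the highest cophenetic coefficient (smallest rank
#' on ties).
#'
#' @param V non-negative matrix.
#' @param ranks candidate ranks (each within \code{[1, min(dim(V)) - 1]}).
#' @param n_runs restarts per rank.
#' @param seed base seed.
#' @param ... passed to [nmf_fit()].
#' @return Object of class \code{rank_selection}: data.frame \code{curve}
#'   (\code{rank}, \code{cophenetic}) and \code{chosen_rank}.
#' @export
select_rank <- function(V, ranks = 5:30, n_runs = 10L, seed = 1L, ...) {
  V <- .as_dense(V)
  if (any(ranks < 1 | ranks > min(dim(V)) - 1))
    .stopf("ranks must lie within [1, min(dim(V)) - 1]")
  coph <- vapply(ranks, function(k) {
    consensus_and_cophenetic(V, k, n_runs = n_runs,
                             seed = seed + 1000L * k, ...)$cophenetic
  }, numeric(1))
  curve <- data.frame(rank = ranks, cophenetic = coph)
  chosen <- ranks[which.max(coph)]   # which.max takes the first (smallest) on ties
  out <- list(curve = curve, chosen_rank = chosen)
  class(out) <- "rank_selection"
  out
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("NMF rank selection over ranks %d..%d: chosen rank %d (cophenetic %.3f)\n",
              min(x$curve$rank), max(x$curve$rank), x$chosen_rank,
              max(x$curve$cophenetic)))
  invisible(x)
}

#' @export
plot.rank_selection <- function(x, ...) {
  plot(x$curve$rank, x$curve$cophenetic, type = "b",
       xlab = "factorization rank", ylab = "cophenetic coefficient", ...)
  graphics::abline(v = x$chosen_rank, lty = 2)
  invisible(x)
}

#' Metagene membership and stage profiles from a fitted NMF model
#'
#' Assigns each gene to the metagene with its largest loading (argmax over
#' its row of W); all-zero rows are left unassigned and logged. When the
#' expression matrix and metadata are supplied, also returns per-metagene
#' mean expression per stage and sex for export/plotting.
#'
#' @param model an [nmf_fit()] result.
#' @param norm optional expression matrix (same genes) for profiles.
#' @param metadata optional metadata with \code{cell_id}, \code{stage},
#'   \code{sex} for profiles.
#' @return List: \code{membership} (named integer vector, \code{NA} for
#'   unassigned) and \code{profiles} (data.frame metagene x stage x sex
#'   mean expression; \code{NULL} without inputs).
#' @export
metagene_membership <- function(model, norm = NULL, metadata = NULL) {
  W <- model$W
  zero_row <- rowSums(W) == 0
  membership <- rep(NA_integer_, nrow(W))
  membership[!zero_row] <- apply(W[!zero_row, , drop = FALSE], 1, which.max)
  names(membership) <- rownames(W)
  if (any(zero_row))
    .msgf("metagene_membership: %d all-zero gene row(s) left unassigned",
          sum(zero_row))
  profiles <- NULL
  if (!is.null(norm) && !is.null(metadata)) {
    norm <- .as_dense(norm)
    md <- metadata[match(colnames(norm), metadata$cell_id), ]
    combos <- expand.grid(metagene = sort(unique(membership[!is.na(membership)])),
                          stage = unique(as.character(md$stage)),
                          sex = unique(md$sex[!is.na(md$sex)]),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    combos$mean_expression <- vapply(seq_len(nrow(combos)), function(r) {
      g <- names(membership)[!is.na(membership) &
                               membership == combos$metagene[r]]
      g <- intersect(g, rownames(norm))
      cells <- md$cell_id[as.character(md$stage) == combos$stage[r] &
                            !is.na(md$sex) & md$sex == combos$sex[r]]
      if (length(g) == 0 || length(cells) == 0) return(NA_real_)
      mean(norm[g, cells, drop = FALSE])
    }, numeric(1))
    profiles <- combos
  }
  list(membership = membership, profiles = profiles)
}
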