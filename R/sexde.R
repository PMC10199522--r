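#' Estimate negative binomial dispersions with a mean trend
#'
#' Per-gene method-of-moments dispersion on size-factor-scaled counts,
#' \eqn{\hat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)}, a robust fit of
#' the trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} over genes with positive
#' raw dispersion, and a geometric-mean shrink of each gene toward the
#' trend. Shrinking toward a mean trend stabilises the per-gene estimates
#' at the cell numbers typical of embryo datasets.
#'
#' @param counts_stage gene-by-cell count matrix (one stage).
#' @param sf per-cell size factors.
#' @param shrink_w weight of the trend in the log-scale shrink (0 = raw
#'   only, 1 = trend only).
#' @param alpha_floor lower bound applied to all dispersions.
#' @return Object of class \code{dispersion_model}: list with
#'   \code{mean} (per-gene scaled mean), \code{raw}, \code{trend}
#'   (coefficients \code{a0}, \code{a1}), \code{fitted} (trend value per
#'   gene), \code{shrunk}.
#' @export
estimate_dispersions <- function(counts_stage, sf, shrink_w = 0.5,
                                 alpha_floor = 1e-8) {
  counts_stage <- .check_counts(counts_stage)
  if (length(sf) != ncol(counts_stage)) .stopf("need one size factor per cell")
  q <- sweep(counts_stage, 2, sf, "/")
  mu <- rowMeans(q)
  if (all(mu == 0)) .stopf("all genes are zero; cannot estimate dispersions")
  s2 <- apply(q, 1, var)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  fit_on <- which(raw > 0 & mu > 0)
  if (length(fit_on) >= 3) {
    rf <- MASS::rlm(raw[fit_on] ~ I(1 / mu[fit_on]), maxit = 50)
    a0 <- unname(coef(rf)[1]); a1 <- unname(coef(rf)[2])
  } else {
    a0 <- max(mean(raw[fit_on]), alpha_floor, na.rm = TRUE); a1 <- 0
  }
  fitted <- pmax(a0 + a1 / pmax(mu, alpha_floor), alpha_floor)
  shrunk <- exp((1 - shrink_w) * log(pmax(raw, alpha_floor)) +
                  shrink_w * log(fitted))
  out <- list(mean = mu, raw = raw, trend = c(a0 = a0, a1 = a1),
              fitted = fitted, shrunk = pmax(shrunk, alpha_floor),
              gene_id = rownames(counts_stage))
  class(out) <- "dispersion_model"
  out
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("NB dispersion model over %d genes: trend a0 = %.4g, a1 = %.4g\n",
              length(x$raw), x$trend["a0"], x$trend["a1"]))
  cat(sprintf("  median shrunken dispersion %.4g\n", median(x$shrunk)))
  invisible(x)
}

# IRLS for the per-gene NB GLM  log mu = b0 + b1 * female + log sf,
# vectorized across genes (the 2x2 weighted normal equations are closed
# form). Returns per-gene coefficients, SE of b1 and a convergence flag.
.nb_irls <- function(y, female, log_sf, alpha, max_iter = 100L, tol = 1e-8) {
  G <- nrow(y); n <- ncol(y)
  f <- as.numeric(female)
  # moment initialisation from sex-wise scaled means
  sf <- exp(log_sf)
  ys <- sweep(y, 2, sf, "/")
  m_m <- rowMeans(ys[, f == 0, drop = FALSE])
  m_f <- rowMeans(ys[, f == 1, drop = FALSE])
  b0 <- log(pmax(m_m, 1e-3))
  b1 <- log(pmax(m_f, 1e-3)) - b0
  conv <- rep(FALSE, G)
  off <- matrix(log_sf, G, n, byrow = TRUE)
  fm <- matrix(f, G, n, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * fm + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    Sw  <- rowSums(w);        Swf <- rowSums(w * fm)
    Swz <- rowSums(w * z);    Swzf <- rowSums(w * z * fm)
    det <- Sw * rowSums(w * fm * fm) - Swf^2
    ok <- det > 1e-12 & Sw > 0
    nb0 <- ifelse(ok, (rowSums(w * fm * fm) * Swz - Swf * Swzf) / det, b0)
    nb1 <- ifelse(ok, (Sw * Swzf - Swf * Swz) / det, b1)
    # diverging effects (e.g. a sex with all-zero counts) are capped
    nb1 <- pmax(pmin(nb1, 30), -30)
    nb0 <- pmax(pmin(nb0, 30), -30)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    conv <- conv | delta < tol
    if (all(conv)) break
  }
  eta <- b0 + b1 * fm + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  Sw <- rowSums(w); Swf <- rowSums(w * fm); Swff <- rowSums(w * fm * fm)
  det <- Sw * Swff - Swf^2
  se1 <- ifelse(det > 1e-12, sqrt(Sw / det), NA_real_)
  at_cap <- abs(b1) >= 30 | abs(b0) >= 30
  list(b0 = b0, b1 = b1, se1 = se1, converged = conv & !at_cap)
}

#' Per-stage negative binomial Wald test of sex-differential expression
#'
#' Fits, per gene, the NB generalized linear model with log link,
#' design \code{~ sex} (male reference, so positive coefficients mean
#' female-biased) and per-cell \code{log(size factor)} offsets, by
#' iteratively reweighted least squares with fixed gene-wise dispersion
#' from [estimate_dispersions()]. The Wald statistic is the coefficient
#' over its standard error with a two-sided normal p-value;
#' Benjamini-Hochberg adjustment is applied across the tested genes of the
#' stage. Genes with all-zero counts are excluded from testing.
#'
#' @param counts_stage gene-by-cell counts for one stage.
#' @param sex_labels per-cell labels, \code{"male"}/\code{"female"}.
#' @param sf per-cell size factors.
#' @param disp a \code{dispersion_model} for these genes, or \code{NULL} to
#'   estimate one.
#' @param stage stage label stored in the result.
#' @param max_iter,tol IRLS controls.
#' @return data.frame (one row per tested gene): \code{gene_id},
#'   \code{stage}, \code{base_mean}, \code{log2fc_raw}, \code{se},
#'   \code{wald_stat}, \code{pvalue}, \code{padj}, \code{converged}.
#'   Non-converged fits keep their estimates but carry \code{NA} p-values.
#' @export
wald_test <- function(counts_stage, sex_labels, sf, disp = NULL,
                      stage = NA_character_, max_iter = 100L, tol = 1e-8) {
  counts_stage <- .check_counts(counts_stage)
  sex_labels <- as.character(sex_labels)
  if (!all(sex_labels %in% c("male", "female")))
    .stopf("sex labels must be 'male' or 'female'")
  if (length(unique(sex_labels)) < 2)
    .stopf("both sexes must be present in the stage")
  if (is.null(disp)) disp <- estimate_dispersions(counts_stage, sf)
  tested <- rowSums(counts_stage) > 0
  y <- counts_stage[tested, , drop = FALSE]
  if (nrow(y) == 0) .stopf("no non-zero genes to test")
  alpha <- disp$shrunk[match(rownames(y), disp$gene_id)]
  fit <- .nb_irls(y, sex_labels == "female", log(sf), alpha,
                  max_iter = max_iter, tol = tol)
  wald <- fit$b1 / fit$se1
  p <- 2 * pnorm(-abs(wald))
  p[!fit$converged] <- NA_real_
  res <- data.frame(
    gene_id = rownames(y), stage = stage,
    base_mean = rowMeans(sweep(y, 2, sf, "/")),
    log2fc_raw = fit$b1 / log(2),
    se = fit$se1 / log(2),
    wald_stat = wald, pvalue = p,
    padj = p.adjust(p, method = "BH"),
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Shrink log fold changes with a zero-centered normal prior
#'
#' Adds a \code{log2fc_shrunk} column: the posterior mode of the sex
#' coefficient under a zero-centered normal prior, using the normal
#' approximation of the likelihood at the MLE — the precision-weighted
#' estimate \eqn{\hat\beta \sigma_p^2 / (\sigma_p^2 + se^2)}. The prior SD
#' is picked from \code{prior_sd_grid} so that the half-normal 95th
#' percentile of the prior matches the empirical 95th percentile of the
#' absolute raw effects; shrunken effects never exceed the raw ones in
#' magnitude.
#'
#' @param results a [wald_test()] result.
#' @param prior_sd_grid candidate prior SDs (natural-log scale).
#' @return \code{results} with \code{log2fc_shrunk} and a
#'   \code{"prior_sd"} attribute (natural-log scale).
#' @export
shrink_lfc <- function(results, prior_sd_grid = 2^seq(-6, 4, length.out = 60)) {
  beta <- results$log2fc_raw * log(2)
  se <- results$se * log(2)
  usable <- is.finite(beta) & is.finite(se)
  target <- quantile(abs(beta[usable]), 0.95, names = FALSE)
  # half-normal 95th percentile of N(0, sd) is sd * qnorm(0.975)
  prior_sd <- prior_sd_grid[which.min(abs(prior_sd_grid * qnorm(0.975) - target))]
  shrunk <- beta * prior_sd^2 / (prior_sd^2 + se^2)
  shrunk[!usable] <- NA_real_
  results$log2fc_shrunk <- shrunk / log(2)
  attr(results, "prior_sd") <- prior_sd
  results
}

#' Classify genes as male- or female-biased and tally per stage
#'
#' A gene is female-biased when its shrunken log2 fold change (female over
#' male) is at least \code{lfc_cut} with \code{padj < alpha}; male-biased
#' symmetrically; otherwise unbiased. Returns the labelled table and
#' per-stage counts, plus expressed/sex-biased tallies.
#'
#' @param results DE rows for one or more stages, after [shrink_lfc()].
#' @param lfc_cut absolute shrunken log2 fold-change threshold.
#' @param alpha adjusted p-value threshold.
#' @return List with \code{results} (adds \code{bias}), \code{counts}
#'   (stage x direction), and \code{tallies} (per stage: tested, biased).
#' @export
classify_and_count <- function(results, lfc_cut = 0.58, alpha = 0.05) {
  lfc <- results$log2fc_shrunk
  if (is.null(lfc)) .stopf("run shrink_lfc() before classification")
  sig <- !is.na(results$padj) & results$padj < alpha & !is.na(lfc)
  bias <- rep("none", nrow(results))
  bias[sig & lfc >= lfc_cut] <- "female"
  bias[sig & lfc <= -lfc_cut] <- "male"
  results$bias <- bias
  stages <- unique(results$stage)
  in_stage <- function(s) if (is.na(s)) is.na(results$stage) else
    !is.na(results$stage) & results$stage == s
  counts <- data.frame(
    stage = stages,
    male = vapply(stages, function(s) sum(bias == "male" & in_stage(s)), 0L,
                  USE.NAMES = FALSE),
    female = vapply(stages, function(s) sum(bias == "female" & in_stage(s)), 0L,
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  tallies <- data.frame(
    stage = stages,
    n_tested = vapply(stages, function(s) sum(in_stage(s)), 0L,
                      USE.NAMES = FALSE),
    n_biased = counts$male + counts$female,
    stringsAsFactors = FALSE
  )
  rownames(counts) <- rownames(tallies) <- NULL
  list(results = results, counts = counts, tallies = tallies)
}

#' Run the per-stage sex-differential expression pipeline
#'
#' Convenience wrapper: for every stage with both sexes present, estimates
#' dispersions, runs the Wald test, shrinks fold changes (BH adjustment is
#' within-stage), and classifies genes.
#'
#' @param counts gene-by-cell counts (all stages).
#' @param metadata metadata with \code{cell_id}, \code{stage}, filled
#'   \code{sex}.
#' @param sf size factors named by cell (subset per stage).
#' @param lfc_cut,alpha classification thresholds.
#' @return A [classify_and_count()] list covering all testable stages.
#' @export
run_sexde <- function(counts, metadata, sf, lfc_cut = 0.58, alpha = 0.05) {
  counts <- .check_counts(counts)
  stages <- if (is.factor(metadata$stage)) levels(droplevels(metadata$stage))
            else unique(metadata$stage)
  res <- list()
  for (st in stages) {
    md <- metadata[metadata$stage == st & metadata$sex %in% c("male", "female"), ]
    if (length(unique(md$sex)) < 2) {
      .msgf("run_sexde: stage %s lacks both sexes; skipped", st)
      next
    }
    y <- counts[, md$cell_id, drop = FALSE]
    r <- wald_test(y, md$sex, sf[md$cell_id], stage = st)
    res[[st]] <- shrink_lfc(r)
  }
  if (length(res) == 0) .stopf("no stage had both sexes")
  classify_and_count(do.call(rbind, res), lfc_cut = lfc_cut, alpha = alpha)
}

#' Exact sizes of set-intersection patterns (upset-style)
#'
#' For named sets (e.g. sexDEGs keyed by species, stage and direction),
#' counts the elements belonging to exactly each non-empty combination of
#' sets.
#'
#' @param sets named list of character vectors.
#' @return data.frame with \code{pattern} (set names joined by \code{"&"}),
#'   \code{degree}, and \code{size}; only non-empty patterns, largest
#'   first.
#' @export
deg_intersections <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    .stopf("sets must have unique names")
  universe <- unique(unlist(sets))
  if (length(universe) == 0)
    return(data.frame(pattern = character(0), degree = integer(0),
                      size = integer(0), stringsAsFactors = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(universe, names(sets)))
  key <- apply(memb, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(key)
  out <- data.frame(pattern = names(tab),
                    degree = vapply(strsplit(names(tab), "&", fixed = TRUE),
                                    length, 0L),
                    size = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
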