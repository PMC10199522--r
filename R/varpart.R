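#' Principal component analysis of samples
#'
#' PCA of cells/samples on log-normalized expression: per-gene centered,
#' unscaled. Returns sample scores, the fraction of total variance per
#' component, and gene loadings so the extreme-loading genes of each
#' component can be reported.
#'
#' @param norm log-normalized gene-by-sample matrix.
#' @param n_components number of components to retain (clipped to what the
#'   data supports).
#' @return Object of class \code{sample_pca}: list with \code{scores}
#'   (samples x components), \code{variance_fractions} (all components),
#'   \code{loadings} (genes x components).
#' @export
pca_samples <- function(norm, n_components = 15L) {
  norm <- .as_dense(norm)
  if (ncol(norm) < 2) .stopf("PCA needs at least 2 samples")
  pc <- prcomp(t(norm), center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  out <- list(scores = pc$x[, seq_len(k), drop = FALSE],
              variance_fractions = fr,
              loadings = pc$rotation[, seq_len(k), drop = FALSE])
  class(out) <- "sample_pca"
  out
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("sample PCA: %d samples, %d retained components\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  PC1+PC2 explain %.1f%% of total variance\n",
              100 * sum(x$variance_fractions[1:min(2, length(x$variance_fractions))])))
  invisible(x)
}

#' Top and bottom loading genes per principal component
#'
#' @param pca a [pca_samples()] result.
#' @param n number of genes per extreme.
#' @return data.frame with \code{component}, \code{gene_id}, \code{loading},
#'   \code{extreme} (\code{"top"}/\code{"bottom"}).
#' @export
pca_extreme_loadings <- function(pca, n = 10L) {
  do.call(rbind, lapply(seq_len(ncol(pca$loadings)), function(k) {
    l <- sort(pca$loadings[, k])
    lo <- head(l, n); hi <- rev(head(rev(l), n))
    data.frame(component = k,
               gene_id = c(names(lo), names(hi)),
               loading = c(unname(lo), unname(hi)),
               extreme = rep(c("bottom", "top"), c(length(lo), length(hi))),
               stringsAsFactors = FALSE)
  }))
}

# one-way R^2 of a grouping factor, vectorized over genes (rows of x)
.oneway_r2 <- function(x, groups) {
  groups <- droplevels(factor(groups))
  gm <- rowMeans(x)
  sst <- rowSums((x - gm)^2)
  ssb <- rep(0, nrow(x))
  for (lev in levels(groups)) {
    cols <- which(groups == lev)
    ssb <- ssb + length(cols) * (rowMeans(x[, cols, drop = FALSE]) - gm)^2
  }
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  pmin(pmax(r2, 0), 1)
}

#' Per-gene variance explained by stage and by sex within stage
#'
#' For each gene, the fraction of expression variance explained by
#' developmental stage (one-way R-squared over all cells) and, within each
#' stage, the fraction explained by sex (one-way R-squared restricted to
#' that stage's cells). Genes with zero variance in scope are assigned 0;
#' a stage containing a single sex yields \code{NA} for that stage.
#'
#' @param norm log-normalized gene-by-cell matrix.
#' @param metadata sample metadata with \code{cell_id}, \code{stage},
#'   \code{sex}.
#' @return data.frame with \code{gene_id}, \code{frac_stage}, and one
#'   \code{frac_sex_<stage>} column per stage; all fractions in [0, 1].
#' @export
variance_explained <- function(norm, metadata) {
  norm <- .as_dense(norm)
  md <- metadata[match(colnames(norm), metadata$cell_id), ]
  if (anyNA(md$cell_id)) .stopf("metadata does not cover all cells")
  if (anyNA(md$stage) || all(is.na(md$sex)))
    .stopf("stage and sex labels are required")
  res <- data.frame(gene_id = rownames(norm),
                    frac_stage = .oneway_r2(norm, md$stage),
                    stringsAsFactors = FALSE)
  stages <- if (is.factor(md$stage)) levels(droplevels(md$stage)) else unique(md$stage)
  for (st in stages) {
    cols <- which(md$stage == st & !is.na(md$sex))
    col_name <- paste0("frac_sex_", st)
    if (length(unique(md$sex[cols])) < 2) {
      res[[col_name]] <- NA_real_
    } else {
      res[[col_name]] <- .oneway_r2(norm[, cols, drop = FALSE], md$sex[cols])
    }
  }
  res
}
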