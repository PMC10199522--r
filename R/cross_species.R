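#' Map species-specific stages onto generalized developmental groups
#'
#' Mouse and human stages do not align one-to-one; a user-supplied mapping
#' folds each species' stage labels into shared stage-adjacent groups
#' (S1..S4 by convention) so profiles become comparable.
#'
#' @param metadata per-cell metadata with \code{stage}.
#' @param mapping named character vector or two-column data.frame
#'   (\code{stage}, \code{group}) covering every stage present.
#' @return Metadata with an added \code{group} column; group sizes are
#'   logged.
#' @export
assign_generalized_stages <- function(metadata, mapping) {
  if (is.data.frame(mapping))
    mapping <- setNames(as.character(mapping$group), as.character(mapping$stage))
  stages <- as.character(metadata$stage)
  missing_map <- setdiff(unique(stages), names(mapping))
  if (length(missing_map))
    .stopf("no group mapping for stage '%s'", missing_map[1])
  metadata$group <- unname(mapping[stages])
  tab <- table(metadata$group)
  .msgf("generalized groups: %s",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  metadata
}

# gene x group matrix of mean expression over each group's cells
.group_profiles <- function(norm, metadata, groups) {
  md <- metadata[match(colnames(norm), metadata$cell_id), ]
  out <- vapply(groups, function(g) {
    cells <- md$cell_id[!is.na(md$group) & md$group == g]
    rowMeans(norm[, cells, drop = FALSE])
  }, numeric(nrow(norm)))
  matrix(out, nrow = nrow(norm), dimnames = list(rownames(norm), groups))
}

#' Conservation of ortholog expression profiles across species
#'
#' For every ortholog pair, computes each gene's mean expression profile
#' over the generalized stage groups shared by both species, z-scores the
#' profile within its species (removing species-level scale), and scores
#' the pair by the Pearson correlation of the two z-scored profiles. The
#' permutation p-value shuffles the ortholog pairing: under the null each
#' gene's partner is a uniformly random scored gene of the other species,
#' so \code{exact = TRUE} enumerates all partners while the default draws
#' \code{n_perm} random pairings. Pairs are ranked by p-value then score.
#'
#' @param normA,normB log-normalized matrices for species A and B.
#' @param metadataA,metadataB metadata with \code{cell_id} and a
#'   \code{group} column (see [assign_generalized_stages()]).
#' @param orthologs data.frame with columns \code{gene_a} (species A id)
#'   and \code{gene_b} (species B id); duplicates removed, unmapped genes
#'   ignored.
#' @param n_perm number of random pairings (ignored when
#'   \code{exact = TRUE}).
#' @param seed integer seed.
#' @param exact enumerate all partners instead of sampling pairings.
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{score},
#'   \code{pvalue}, plus the group profiles as attribute
#'   \code{"profiles"}. Pairs with a constant profile get \code{NA} score
#'   and p.
#' @export
conservation_scores <- function(normA, normB, metadataA, metadataB,
                                orthologs, n_perm = 999L, seed = 1L,
                                exact = FALSE) {
  normA <- .as_dense(normA); normB <- .as_dense(normB)
  orthologs <- unique(orthologs[, c("gene_a", "gene_b")])
  orthologs <- orthologs[orthologs$gene_a %in% rownames(normA) &
                           orthologs$gene_b %in% rownames(normB), , drop = FALSE]
  if (nrow(orthologs) == 0) .stopf("no ortholog pair maps into both matrices")
  groups <- intersect(unique(metadataA$group), unique(metadataB$group))
  groups <- sort(groups)
  if (length(groups) < 2)
    .stopf("need at least 2 generalized groups present in both species")
  profA <- .group_profiles(normA[orthologs$gene_a, , drop = FALSE], metadataA, groups)
  profB <- .group_profiles(normB[orthologs$gene_b, , drop = FALSE], metadataB, groups)
  zscore <- function(m) {
    mu <- rowMeans(m); s <- apply(m, 1, sd)
    z <- (m - mu) / ifelse(s > 0, s, NA_real_)
    z
  }
  zA <- zscore(profA); zB <- zscore(profB)
  ng <- length(groups)
  score_of <- function(ia, ib) rowSums(zA[ia, , drop = FALSE] *
                                         zB[ib, , drop = FALSE]) / (ng - 1)
  n <- nrow(orthologs)
  obs <- score_of(seq_len(n), seq_len(n))
  pvals <- rep(NA_real_, n)
  scored <- which(is.finite(obs))
  if (length(scored)) {
    if (exact) {
      # uniform-partner enumeration: equivalent to averaging over all
      # pairings, since a random pairing sends pair i to each partner
      # equiprobably; the observed pairing is itself one enumerated case,
      # so the plain exceedance fraction is already never zero
      cand <- scored
      for (i in scored) {
        nulls <- score_of(rep(i, length(cand)), cand)
        pvals[i] <- sum(nulls >= obs[i], na.rm = TRUE) /
          sum(is.finite(nulls))
      }
    } else {
      if (n_perm < 1) .stopf("n_perm must be >= 1")
      hits <- integer(n)
      .with_seed(seed, {
        for (b in seq_len(n_perm)) {
          perm <- sample(scored)
          nulls <- score_of(scored, perm)
          hits[scored] <- hits[scored] + as.integer(nulls >= obs[scored])
        }
      })
      pvals[scored] <- (1 + hits[scored]) / (1 + n_perm)
    }
  }
  out <- data.frame(gene_a = orthologs$gene_a, gene_b = orthologs$gene_b,
                    score = obs, pvalue = pvals, stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "profiles") <- list(A = profA, B = profB, groups = groups)
  out
}

#' Mask of top-quantile expression values per gene
#'
#' Marks, per gene, the samples whose expression strictly exceeds the
#' gene's \code{q}-quantile across samples — by default the top decile.
#' A constant gene yields an empty mask.
#'
#' @param norm gene-by-sample expression matrix.
#' @param q quantile in (0, 1); default 0.9.
#' @return Logical matrix of the same shape.
#' @export
top_expression_mask <- function(norm, q = 0.9) {
  if (q <= 0 || q >= 1) .stopf("q must lie strictly between 0 and 1")
  norm <- .as_dense(norm)
  thresh <- apply(norm, 1, quantile, probs = q)
  norm > thresh
}
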