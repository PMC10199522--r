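#' Hypergeometric over/under enrichment of a gene set
#'
#' Tests whether a set of differentially expressed genes overlaps a
#' category (functional class or chromosome) more or less than expected
#' under random draws from the universe. With \eqn{X} hypergeometric on
#' (universe size, category size, DEG count): \code{p_over} =
#' \eqn{P(X \ge k)} and \code{p_under} = \eqn{P(X \le k)} for observed
#' overlap \eqn{k}. Cells with fewer than 5 DEGs or 5 category genes are
#' flagged low-confidence.
#'
#' @param universe character vector of background genes.
#' @param category_set,deg_set subsets of \code{universe}.
#' @return One-row data.frame: \code{n_universe}, \code{n_category},
#'   \code{n_deg}, \code{n_overlap}, \code{fold}, \code{p_over},
#'   \code{p_under}, \code{low_confidence}.
#' @export
hypergeom_enrichment <- function(universe, category_set, deg_set) {
  universe <- unique(universe)
  if (length(universe) == 0) .stopf("empty universe")
  category_set <- intersect(unique(category_set), universe)
  deg_set <- intersect(unique(deg_set), universe)
  N <- length(universe); K <- length(category_set); n <- length(deg_set)
  k <- length(intersect(category_set, deg_set))
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  data.frame(
    n_universe = N, n_category = K, n_deg = n, n_overlap = k,
    fold = fold,
    p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_under = phyper(k, K, N - K, n),
    low_confidence = n < 5 || K < 5,
    stringsAsFactors = FALSE
  )
}

#' Enrichment grid of sex-biased genes over classes and chromosomes
#'
#' One hypergeometric test per stage, bias direction and category, with
#' categories \code{protein_coding}, \code{TF}, \code{EE}, \code{autosome},
#' \code{X}, \code{Y}. The universe of each stage is its expressed genes
#' (the tested genes of the DE results unless supplied explicitly).
#'
#' @param de_results classified DE rows (with \code{bias}) from
#'   [classify_and_count()].
#' @param annotation gene annotation with flags and
#'   \code{chromosome_class}.
#' @param expressed_by_stage optional named list (stage -> expressed gene
#'   ids) overriding the default universe.
#' @return Long data.frame: \code{stage}, \code{direction},
#'   \code{category}, plus the [hypergeom_enrichment()] columns;
#'   \code{degenerate} marks cells with no DEGs.
#' @export
enrichment_grid <- function(de_results, annotation, expressed_by_stage = NULL) {
  if (is.null(de_results$bias)) .stopf("DE results must be classified first")
  cat_members <- list(
    protein_coding = annotation$gene_id[annotation$is_protein_coding],
    TF = annotation$gene_id[annotation$is_tf],
    EE = annotation$gene_id[annotation$is_ee],
    autosome = annotation$gene_id[annotation$chromosome_class == "autosome"],
    X = annotation$gene_id[annotation$chromosome_class == "X"],
    Y = annotation$gene_id[annotation$chromosome_class == "Y"]
  )
  out <- list()
  for (st in unique(de_results$stage)) {
    rows <- de_results[de_results$stage == st, ]
    universe <- if (!is.null(expressed_by_stage)) expressed_by_stage[[st]]
                else rows$gene_id
    for (dir in c("male", "female")) {
      degs <- rows$gene_id[rows$bias == dir]
      for (cat_name in names(cat_members)) {
        cell <- hypergeom_enrichment(universe, cat_members[[cat_name]], degs)
        cell <- cbind(data.frame(stage = st, direction = dir,
                                 category = cat_name,
                                 stringsAsFactors = FALSE),
                      cell)
        cell$degenerate <- length(degs) == 0
        out[[length(out) + 1L]] <- cell
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Census of regulators among the most highly expressed genes
#'
#' Per stage, ranks genes by mean normalized expression over the stage's
#' cells (ties broken by gene identifier order) and counts transcription
#' factors and epigenetic enzymes among the top \code{top_n}.
#'
#' @param norm log-normalized gene-by-cell matrix.
#' @param annotation gene annotation with \code{is_tf}, \code{is_ee}.
#' @param metadata metadata with \code{cell_id} and \code{stage}.
#' @param top_n number of top-expressed genes to scan (uses all genes with
#'   a warning when fewer are available).
#' @return data.frame: \code{stage}, \code{n_top}, \code{n_tf},
#'   \code{n_ee}.
#' @export
regulator_census <- function(norm, annotation, metadata, top_n = 1000L) {
  norm <- .as_dense(norm)
  ann <- annotation[match(rownames(norm), annotation$gene_id), ]
  if (nrow(norm) < top_n) {
    .warnf("only %d genes available; using all of them", nrow(norm))
    top_n <- nrow(norm)
  }
  stages <- if (is.factor(metadata$stage)) levels(droplevels(metadata$stage))
            else unique(metadata$stage)
  out <- lapply(stages, function(st) {
    cells <- metadata$cell_id[metadata$stage == st]
    cells <- intersect(cells, colnames(norm))
    m <- rowMeans(norm[, cells, drop = FALSE])
    ord <- order(-m, rownames(norm))
    top <- ord[seq_len(top_n)]
    data.frame(stage = st, n_top = top_n,
               n_tf = sum(ann$is_tf[top], na.rm = TRUE),
               n_ee = sum(ann$is_ee[top], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
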