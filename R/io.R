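#' Read a gene-by-cell count matrix
#'
#' Reads either a Matrix Market sparse triplet (\code{format = "mtx"}, with
#' \code{genes.tsv} and \code{cells.tsv} identifier sidecars next to the
#' matrix file) or a dense tab-separated table with gene identifiers in the
#' first column and cell identifiers in the header. Entries must be
#' non-negative integers; violations are rejected with the offending
#' location named.
#'
#' @param path path to the \code{.mtx} file or dense TSV.
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return Integer matrix (genes x cells) with dimnames.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) .stopf("malformed Matrix Market file %s: %s",
                                             path, conditionMessage(e)))
    m <- as.matrix(m)
    side <- function(f) file.path(dirname(path), f)
    if (!file.exists(side("genes.tsv")) || !file.exists(side("cells.tsv")))
      .stopf("missing genes.tsv / cells.tsv sidecar next to %s", path)
    genes <- read.delim(side("genes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(side("cells.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      .stopf("dimension mismatch: matrix is %d x %d but sidecars list %d genes, %d cells",
             nrow(m), ncol(m), length(genes), length(cells))
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2) .stopf("dense TSV %s needs a gene id column plus >= 1 cell", path)
    genes <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("negative or non-integer entry at gene '%s', cell '%s' (value %g)",
           rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]])
  storage.mode(m) <- "integer"
  .check_counts(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: Matrix Market triplet plus \code{genes.tsv}
#' and \code{cells.tsv} sidecars, or a dense TSV. Round-trips losslessly.
#'
#' @param counts gene-by-cell integer matrix with dimnames.
#' @param path output path (\code{.mtx} file or TSV file).
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  counts <- .check_counts(counts)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                    path)
    write.table(rownames(counts), file.path(dirname(path), "genes.tsv"),
                quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    write.table(colnames(counts), file.path(dirname(path), "cells.tsv"),
                quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  } else {
    out <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Quality-control filtering of genes then cells
#'
#' Removes genes detected (count > 0) in fewer than \code{min_cells} cells,
#' then removes cells in which fewer than \code{min_features} of the
#' remaining genes are detected. The gene pass runs first and cell feature
#' counts are recomputed after it, so the two passes compose
#' deterministically; the operation is idempotent.
#'
#' @param counts gene-by-cell count matrix.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @param min_features minimum number of detected genes a cell must retain.
#' @return Filtered count matrix. Warns (does not error) when the result is
#'   empty.
#' @export
filter_counts <- function(counts, min_cells = 3L, min_features = 350L) {
  counts <- .check_counts(counts)
  keep_g <- rowSums(counts > 0) >= min_cells
  counts <- counts[keep_g, , drop = FALSE]
  keep_c <- colSums(counts > 0) >= min_features
  counts <- counts[, keep_c, drop = FALSE]
  if (nrow(counts) == 0 || ncol(counts) == 0)
    .warnf("filtering removed every %s", if (nrow(counts) == 0) "gene" else "cell")
  counts
}

#' Drop RIKEN-annotated genes
#'
#' Removes genes whose annotation symbol carries the case-insensitive
#' suffix \code{"Rik"} (RIKEN cDNA clones in mouse nomenclature) and logs
#' how many were removed.
#'
#' @param counts gene-by-cell count matrix.
#' @param annotation gene annotation with \code{gene_id} and \code{symbol}.
#' @return Count matrix without RIKEN genes.
#' @export
drop_riken <- function(counts, annotation) {
  counts <- .check_counts(counts)
  sym <- annotation$symbol[match(rownames(counts), annotation$gene_id)]
  sym[is.na(sym)] <- ""
  rik <- grepl("rik$", sym, ignore.case = TRUE)
  .msgf("drop_riken: removing %d RIKEN-annotated gene(s)", sum(rik))
  out <- counts[!rik, , drop = FALSE]
  if (nrow(out) == 0) .warnf("all genes were RIKEN-annotated; empty gene set")
  out
}

#' Fraction of annotated genes expressed per group and chromosome class
#'
#' For each group (sex or stage) and chromosome class, reports the fraction
#' of annotated genes of that class detected (count > 0) in at least one
#' cell of the group.
#'
#' @param counts gene-by-cell count matrix.
#' @param annotation gene annotation with \code{chromosome_class}.
#' @param metadata sample metadata with \code{cell_id} plus the grouping
#'   column.
#' @param group_by \code{"sex"} or \code{"stage"}.
#' @return data.frame with \code{group}, \code{chromosome_class},
#'   \code{n_annotated}, \code{n_expressed}, \code{fraction}. Groups with no
#'   cells get \code{NA} fractions.
#' @export
expressed_fraction <- function(counts, annotation, metadata,
                               group_by = c("sex", "stage")) {
  group_by <- match.arg(group_by)
  counts <- .check_counts(counts)
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (anyNA(ann$chromosome_class))
    .stopf("annotation does not cover all matrix genes")
  grp_all <- metadata[[group_by]]
  levels_ <- if (is.factor(grp_all)) levels(grp_all) else unique(grp_all)
  levels_ <- levels_[!is.na(levels_)]
  classes <- c("autosome", "X", "Y")
  res <- expand.grid(group = levels_, chromosome_class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$n_annotated <- NA_integer_; res$n_expressed <- NA_integer_
  res$fraction <- NA_real_
  for (r in seq_len(nrow(res))) {
    cells <- metadata$cell_id[!is.na(grp_all) & grp_all == res$group[r]]
    cells <- intersect(cells, colnames(counts))
    gsel <- ann$chromosome_class == res$chromosome_class[r]
    res$n_annotated[r] <- sum(gsel)
    if (length(cells) == 0 || sum(gsel) == 0) next
    expressed <- rowSums(counts[gsel, cells, drop = FALSE] > 0) > 0
    res$n_expressed[r] <- sum(expressed)
    res$fraction[r] <- mean(expressed)
  }
  res
}
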