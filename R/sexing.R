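#' Call the sex of a cell from two marker counts
#'
#' Applies the marker-ratio rule: cells that do not express the Y-linked
#' marker but do express the X-linked Xist-like marker are female; cells
#' expressing the Y-linked marker with an Xist-to-Y ratio below one are
#' male; a ratio of one or above is ambiguous (possible contamination), and
#' cells expressing neither marker are ambiguous for lack of signal.
#' The Xist-like marker doubles as a technical control: a cell with no
#' signal on either marker cannot be sexed confidently.
#'
#' @param xist,eif2s3y non-negative counts of the X-linked and Y-linked
#'   marker (vectors recycle).
#' @return data.frame with columns \code{label} (\code{"male"},
#'   \code{"female"} or \code{"ambiguous"}) and \code{ratio}
#'   (\code{xist / eif2s3y}; \code{NA} when the Y marker is zero).
#' @export
call_sex <- function(xist, eif2s3y) {
  if (any(xist < 0) || any(eif2s3y < 0)) .stopf("marker counts must be >= 0")
  n <- max(length(xist), length(eif2s3y))
  xist <- rep_len(xist, n); eif2s3y <- rep_len(eif2s3y, n)
  ratio <- ifelse(eif2s3y > 0, xist / eif2s3y, NA_real_)
  label <- rep("ambiguous", n)
  label[eif2s3y == 0 & xist > 0] <- "female"
  label[eif2s3y > 0 & ratio < 1] <- "male"
  data.frame(label = label, ratio = ratio, stringsAsFactors = FALSE)
}

#' Sex every cell of a dataset and drop ambiguous cells
#'
#' In \code{"ratio"} mode, applies [call_sex()] to each cell's raw marker
#' counts (raw counts avoid circularity with size-factor estimation). In
#' \code{"y_presence"} mode — how datasets lacking a single reliable Y
#' marker are typically sexed — a cell is male iff its summed counts over
#' all Y-linked genes exceed \code{y_threshold}, else female. Ambiguous
#' cells are removed from the returned metadata, with the removal count
#' logged and stored in the \code{"n_ambiguous"} attribute.
#'
#' @param counts gene-by-cell count matrix.
#' @param metadata sample metadata (\code{cell_id} matching the matrix).
#' @param marker_x_id,marker_y_id gene identifiers of the Xist-like and
#'   Y-linked markers (ratio mode).
#' @param mode \code{"ratio"} or \code{"y_presence"}.
#' @param annotation gene annotation (required for \code{y_presence} mode,
#'   to find Y-linked genes).
#' @param y_threshold summed Y-linked count above which a cell is male
#'   (\code{y_presence} mode, default 0).
#' @return The metadata restricted to unambiguous cells, with a filled
#'   \code{sex} column and a \code{sex_marker_ratio} column in ratio mode.
#' @export
sex_dataset <- function(counts, metadata,
                        marker_x_id = "Xist", marker_y_id = "Eif2s3y",
                        mode = c("ratio", "y_presence"),
                        annotation = NULL, y_threshold = 0) {
  mode <- match.arg(mode)
  counts <- .check_counts(counts)
  cells <- metadata$cell_id
  missing_cells <- setdiff(cells, colnames(counts))
  if (length(missing_cells))
    .stopf("metadata cell '%s' absent from count matrix", missing_cells[1])
  if (mode == "ratio") {
    for (id in c(marker_x_id, marker_y_id))
      if (!id %in% rownames(counts))
        .stopf("marker gene '%s' not found in the count matrix", id)
    calls <- call_sex(counts[marker_x_id, cells], counts[marker_y_id, cells])
    metadata$sex <- calls$label
    metadata$sex_marker_ratio <- calls$ratio
  } else {
    if (is.null(annotation)) .stopf("y_presence mode requires gene annotation")
    y_genes <- intersect(annotation$gene_id[annotation$chromosome_class == "Y"],
                         rownames(counts))
    ysum <- if (length(y_genes)) colSums(counts[y_genes, cells, drop = FALSE])
            else rep(0, length(cells))
    metadata$sex <- ifelse(ysum > y_threshold, "male", "female")
  }
  n_amb <- sum(metadata$sex == "ambiguous")
  .msgf("sex_dataset: %d ambiguous cell(s) removed", n_amb)
  out <- metadata[metadata$sex != "ambiguous", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ambiguous") <- n_amb
  out
}
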