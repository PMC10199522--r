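#' Read a protein-protein interaction edge list
#'
#' Two-column TSV of gene identifier pairs; self-loops are dropped and
#' duplicate edges collapse after canonical ordering of endpoints.
#'
#' @param path path to the TSV (header optional, first two columns used).
#' @param header whether the file has a header line.
#' @return data.frame with \code{gene_a}, \code{gene_b}.
#' @export
read_edge_list <- function(path, header = TRUE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) .stopf("edge list needs two columns")
  canonical_edges(data.frame(gene_a = as.character(tab[[1]]),
                             gene_b = as.character(tab[[2]]),
                             stringsAsFactors = FALSE))
}

#' Canonicalize an undirected edge list
#'
#' @param edges data.frame with \code{gene_a}, \code{gene_b}.
#' @return Self-loop-free, deduplicated edge list with
#'   \code{gene_a < gene_b}.
#' @export
canonical_edges <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  out <- unique(data.frame(gene_a = a[keep], gene_b = b[keep],
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage-specific interaction subgraph over expressed genes
#'
#' @param edges edge list (\code{gene_a}, \code{gene_b}).
#' @param expressed_genes genes expressed at the stage.
#' @return Edges whose both endpoints are expressed.
#' @export
stage_subgraph <- function(edges, expressed_genes) {
  keep <- edges$gene_a %in% expressed_genes & edges$gene_b %in% expressed_genes
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify interaction edges by the sex bias of their endpoints
#'
#' Labels each node male-biased (M), female-biased (F) or unbiased (N) and
#' counts the six unordered edge classes MM, FF, NN, MN, FN, MF. Counts are
#' also normalized: within-class counts by the class size (MM/|M| etc.),
#' cross-class counts by the geometric mean of the two class sizes; a class
#' with no members yields a missing (not zero) normalized value.
#'
#' @param edges stage subgraph edge list.
#' @param male_degs,female_degs disjoint character vectors of biased genes.
#' @param nodes node universe for the class sizes; defaults to the genes
#'   incident to the edges.
#' @param stage optional stage label carried into the output.
#' @return List of class \code{edge_class_counts}: \code{counts} (named,
#'   the six classes), \code{class_sizes} (|M|, |F|, |N|),
#'   \code{normalized}, \code{stage}.
#' @export
classify_edges <- function(edges, male_degs, female_degs, nodes = NULL,
                           stage = NA_character_) {
  if (length(intersect(male_degs, female_degs)) > 0)
    .stopf("male and female DEG sets overlap")
  if (is.null(nodes)) nodes <- unique(c(edges$gene_a, edges$gene_b))
  lab <- function(g) ifelse(g %in% male_degs, "M",
                            ifelse(g %in% female_degs, "F", "N"))
  la <- lab(edges$gene_a); lb <- lab(edges$gene_b)
  cls <- paste0(pmin(la, lb), pmax(la, lb))
  cls[cls == "FM"] <- "MF"   # canonical unordered labels
  classes <- c("MM", "FF", "NN", "MN", "FN", "MF")
  counts <- setNames(integer(6), classes)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  sizes <- c(M = sum(nodes %in% male_degs),
             F = sum(nodes %in% female_degs),
             N = sum(!(nodes %in% male_degs | nodes %in% female_degs)))
  geo <- function(a, b) if (a > 0 && b > 0) sqrt(a * b) else NA_real_
  normalized <- c(
    MM = if (sizes["M"] > 0) counts["MM"] / sizes["M"] else NA_real_,
    FF = if (sizes["F"] > 0) counts["FF"] / sizes["F"] else NA_real_,
    NN = if (sizes["N"] > 0) counts["NN"] / sizes["N"] else NA_real_,
    MN = counts["MN"] / geo(sizes["M"], sizes["N"]),
    FN = counts["FN"] / geo(sizes["F"], sizes["N"]),
    MF = counts["MF"] / geo(sizes["M"], sizes["F"])
  )
  out <- list(counts = counts, class_sizes = sizes,
              normalized = setNames(as.numeric(normalized), classes),
              stage = stage)
  class(out) <- "edge_class_counts"
  out
}

#' @export
print.edge_class_counts <- function(x, ...) {
  cat(sprintf("edge classes%s: |M| = %d, |F| = %d, |N| = %d\n",
              if (is.na(x$stage)) "" else paste0(" at stage ", x$stage),
              x$class_sizes["M"], x$class_sizes["F"], x$class_sizes["N"]))
  print(x$counts)
  invisible(x)
}

# pmin/pmax on the single-character labels gives alphabetical canonical
# pairs: FF < FM < FN < MM < MN < NN; only FM needs renaming to MF.

#' Hive-layout coordinates for a classified interaction network
#'
#' Assigns every node to one of six half-axes — male-biased nodes
#' alternate between axes \code{1a}/\code{1b}, female-biased between
#' \code{2a}/\code{2b}, unbiased between \code{3a}/\code{3b} — ordered by
#' degree (ties broken by gene identifier), with the position equal to the
#' 0-based degree rank within the half-axis. Export only; rendering is out
#' of scope.
#'
#' @param edges stage subgraph edge list.
#' @param male_degs,female_degs disjoint biased gene sets.
#' @param nodes node universe (defaults to genes incident to the edges).
#' @return data.frame: \code{gene_id}, \code{class}, \code{axis},
#'   \code{position}, \code{degree}.
#' @export
hive_layout_export <- function(edges, male_degs, female_degs, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(edges$gene_a, edges$gene_b))
  deg_tab <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  degree <- setNames(as.integer(deg_tab), nodes)
  cls <- ifelse(nodes %in% male_degs, "M",
                ifelse(nodes %in% female_degs, "F", "N"))
  axis_root <- c(M = "1", F = "2", N = "3")
  out <- data.frame(gene_id = nodes, class = cls, axis = NA_character_,
                    position = NA_integer_, degree = degree,
                    stringsAsFactors = FALSE)
  for (cl in c("M", "F", "N")) {
    sel <- which(cls == cl)
    if (length(sel) == 0) next
    ord <- sel[order(-degree[sel], nodes[sel])]
    half <- rep(c("a", "b"), length.out = length(ord))
    out$axis[ord] <- paste0(axis_root[cl], half)
    for (h in c("a", "b")) {
      on_axis <- ord[half == h]
      out$position[on_axis] <- seq_along(on_axis) - 1L
    }
  }
  rownames(out) <- NULL
  out
}
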