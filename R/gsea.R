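#' Read a GMT gene set file
#'
#' Tab-delimited, one set per line: name, description, member genes. A
#' missing description field is tolerated; member lists are deduplicated
#' and set names must be unique.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) .stopf("malformed GMT line: '%s'", substr(ln, 1, 60))
    name <- parts[1]
    genes <- parts[-(1:2)]
    if (length(genes) == 0) genes <- parts[-1]   # description omitted
    genes <- unique(genes[nzchar(genes)])
    if (name %in% names(sets)) .stopf("duplicate gene set name '%s'", name)
    sets[[name]] <- genes
  }
  sets
}

#' Write a gene set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) .stopf("sets must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list (decreasing weight, ties broken by gene
#' identifier): genes in the set increment the running sum by their weight
#' (to power \code{p}) normalized by the set's total weight, genes outside
#' decrement it by \code{1/(N - |set|)}. Under positive scoring the
#' enrichment score is the maximum of the running sum; under
#' \code{"std"} it is the maximum deviation from zero, signed.
#'
#' @param weights named non-negative numeric vector (gene -> ranking
#'   weight); ordering is derived internally.
#' @param set character vector of set members.
#' @param p weight exponent (1 = classical weighted statistic).
#' @param score_type \code{"pos"} or \code{"std"}.
#' @return List: \code{es}, \code{running} (profile along the ranking),
#'   \code{order} (gene ids in ranked order), \code{hit} (logical).
#' @export
enrichment_score <- function(weights, set, p = 1, score_type = c("pos", "std")) {
  score_type <- match.arg(score_type)
  if (is.null(names(weights))) .stopf("weights must be named by gene")
  if (score_type == "pos" && any(weights < 0))
    .stopf("positive scoring requires non-negative weights")
  ord <- order(-weights, names(weights))
  w <- weights[ord]; ids <- names(weights)[ord]
  hit <- ids %in% set
  if (!any(hit)) .stopf("set does not intersect the ranked list")
  N <- length(w); m <- sum(hit)
  if (m == N) .stopf("set covers the whole ranked list; miss step undefined")
  wp <- abs(w)^p
  inc <- numeric(N)
  inc[hit] <- wp[hit] / sum(wp[hit])
  inc[!hit] <- -1 / (N - m)
  running <- cumsum(inc)
  # the running sum starts at 0 (empty prefix), so the positive-mode
  # maximum is never negative
  es <- if (score_type == "pos") max(0, running)
        else running[which.max(abs(running))]
  list(es = es, running = running, order = ids, hit = hit)
}

#' Pre-ranked gene set enrichment with a gene-permutation null
#'
#' Scores every gene set of a collection against a non-negative ranking
#' weight vector (e.g. one metagene column of the NMF gene-loading
#' matrix). Sets are intersected with the ranked universe and filtered to
#' \code{[min_size, max_size]}. The null distribution of the enrichment
#' score is obtained by drawing random gene sets of the same size from the
#' universe; \eqn{p = (1 + \#\{ES_{perm} \ge ES\})/(1 + n_{perm})},
#' \eqn{NES = ES / \overline{ES}_{perm}}, and Benjamini-Hochberg adjustment
#' runs across the surviving sets. Leading-edge genes are the set members
#' at or before the running-sum peak.
#'
#' @param weights named non-negative vector of ranking weights.
#' @param collection named list of gene sets.
#' @param min_size,max_size set size window after intersection (defaults
#'   15 and 500).
#' @param n_perm number of permutations (> 0).
#' @param seed integer seed for the permutation draw.
#' @param p weight exponent.
#' @return data.frame: \code{set}, \code{size}, \code{es}, \code{nes},
#'   \code{pvalue}, \code{padj}, \code{leading_edge}
#'   (comma-separated). Empty (with a warning) when no set survives
#'   filtering.
#' @export
gsea_preranked <- function(weights, collection, min_size = 15L,
                           max_size = 500L, n_perm = 1000L, seed = 1L, p = 1) {
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (is.null(names(weights))) .stopf("weights must be named by gene")
  universe <- names(weights)
  kept <- lapply(collection, intersect, y = universe)
  sizes <- lengths(kept)
  keep <- sizes >= min_size & sizes <= max_size
  kept <- kept[keep]
  if (length(kept) == 0) {
    .warnf("no gene set survives the [%d, %d] size filter", min_size, max_size)
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), pvalue = numeric(0), padj = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  obs <- lapply(kept, function(s) enrichment_score(weights, s, p = p))
  es <- vapply(obs, `[[`, numeric(1), "es")

  # one shared null per distinct set size
  uniq_sizes <- sort(unique(lengths(kept)))
  null_es <- .with_seed(seed, {
    sapply(uniq_sizes, function(sz) {
      vapply(seq_len(n_perm), function(i) {
        enrichment_score(weights, sample(universe, sz), p = p)$es
      }, numeric(1))
    })
  })
  null_es <- matrix(null_es, nrow = n_perm,
                    dimnames = list(NULL, as.character(uniq_sizes)))

  pvals <- numeric(length(kept)); nes <- numeric(length(kept))
  for (i in seq_along(kept)) {
    nul <- null_es[, as.character(length(kept[[i]]))]
    pvals[i] <- (1 + sum(nul >= es[i])) / (1 + n_perm)
    nes[i] <- es[i] / mean(nul)
  }
  leading <- vapply(obs, function(o) {
    peak <- which.max(o$running)
    paste(o$order[seq_len(peak)][o$hit[seq_len(peak)]], collapse = ",")
  }, character(1))
  out <- data.frame(set = names(kept), size = lengths(kept), es = es,
                    nes = nes, pvalue = pvals,
                    padj = p.adjust(pvals, method = "BH"),
                    leading_edge = leading, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$pvalue, -out$es), , drop = FALSE]
}

#' Long-format concordance table of enriched pathways across analyses
#'
#' Combines per-metagene GSEA results from several analyses (e.g. species
#' by sex) into one pathway-by-analysis table of significance indicators,
#' plus per-pathway counts of enriched metagenes normalized by the number
#' of metagenes in each analysis.
#'
#' @param results named list of data.frames; each must carry \code{set},
#'   \code{metagene}, \code{padj} columns (bind per-metagene
#'   [gsea_preranked()] outputs with a \code{metagene} column).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return List: \code{indicators} (long data.frame \code{set},
#'   \code{analysis}, \code{metagene}, \code{significant}) and
#'   \code{normalized_counts} (\code{set}, \code{analysis},
#'   \code{n_enriched}, \code{n_metagenes}, \code{normalized}).
#' @export
enrichment_heatmap_table <- function(results, alpha = 0.05) {
  if (length(results) == 0) .stopf("need at least one result table")
  if (is.null(names(results))) .stopf("results must be named by analysis")
  ind <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(set = r$set, analysis = nm, metagene = r$metagene,
               significant = r$padj < alpha, stringsAsFactors = FALSE)
  }))
  counts <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    n_mg <- length(unique(r$metagene))
    sets <- unique(r$set)
    data.frame(set = sets, analysis = nm,
               n_enriched = vapply(sets, function(s)
                 sum(r$set == s & r$padj < alpha), 0L),
               n_metagenes = n_mg, stringsAsFactors = FALSE)
  }))
  counts$normalized <- counts$n_enriched / counts$n_metagenes
  rownames(ind) <- rownames(counts) <- NULL
  list(indicators = ind, normalized_counts = counts)
}
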