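#' @importFrom stats rnbinom rnorm runif rbinom quantile median var sd cor
#'   prcomp hclust cophenetic as.dist phyper p.adjust pnorm qnorm setNames
#'   coef
#' @importFrom utils read.delim write.table head combn
#' @importFrom graphics plot abline
NULL

# counts may arrive as a base matrix or a Matrix sparse matrix; work dense
# internally (the study-scale data are small) but accept both at the surface.
.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

.check_counts <- function(counts) {
  counts <- .as_dense(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("count matrix must carry gene (row) and cell (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate gene identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicate cell identifiers in count matrix")
  if (any(counts < 0)) .stopf("count matrix has negative entries")
  counts
}

# deterministic RNG scoping: run `expr` under `seed` without disturbing the
# caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
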