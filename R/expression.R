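# Expression handling: RPKM matrix input, per-gene max reduction,
# top-percentile filtering, log transform and binning.

#' Read a gene x condition RPKM expression matrix
#'
#' Expected layout: header `gene_id<TAB>cond1<TAB>cond2...`, then one row
#' per gene of numeric, non-negative RPKM values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, rows named by gene id, columns by condition.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs gene_id plus >= 1 condition")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene row: ", ids[duplicated(ids)][1L])
  }
  mat <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(mat)) stop("non-numeric expression cell in ", path)
  if (any(mat < 0)) stop("negative RPKM value in ", path)
  mat
}

#' Per-gene maximum expression over all conditions
#'
#' The highest reported value for a gene across tissues/conditions is used
#' as its expression summary (rather than the mean or median): many genes
#' are expressed only in specific tissues, so the maximum better reflects a
#' gene's importance to the organism.
#'
#' @param values Numeric gene x condition matrix from [read_expression()].
#' @return Named numeric vector of per-gene maxima.
#' @export
max_expression <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  apply(values, 1L, max)
}

#' Remove the most extreme top fraction of expression values
#'
#' A few extremely highly expressed genes can swamp category comparisons,
#' so genes in the top `percent` of per-gene maxima are filtered out before
#' any expression analysis. The threshold is the nearest-rank upper
#' percentile (no interpolation); only values strictly above it are
#' removed, so full ties remove nothing.
#'
#' @param per_gene_max Named numeric vector from [max_expression()].
#' @param percent Percentage to remove, in (0, 100); default 1.
#' @return List with `retained` (gene ids kept), `removed` (gene ids
#'   dropped) and `threshold` (the RPKM cutoff used).
#' @export
filter_top_percent <- function(per_gene_max, percent = 1) {
  stopifnot(percent > 0, percent < 100)
  n <- length(per_gene_max)
  if (n < 100 / percent) {
    warning("fewer than ", ceiling(100 / percent),
            " genes; top-", percent, "% filter removes nothing")
    return(list(retained = names(per_gene_max), removed = character(0),
                threshold = Inf))
  }
  k <- ceiling((100 - percent) / 100 * n)
  threshold <- sort(per_gene_max)[k]
  drop <- per_gene_max > threshold
  list(retained = names(per_gene_max)[!drop],
       removed = names(per_gene_max)[drop],
       threshold = unname(threshold))
}

#' Log-transform expression with a pseudocount
#'
#' `log10(RPKM + pseudocount)`; the default pseudocount of 1 keeps
#' zero-expression genes finite (at 0), so they land in the lowest bin.
#'
#' @param x Non-negative numeric vector of RPKM values.
#' @param pseudocount Added before the log; default 1.
#' @return Numeric vector, names preserved.
#' @export
log_expression <- function(x, pseudocount = 1) {
  log10(x + pseudocount)
}

#' Define an expression bin scheme
#'
#' Bins collect genes of similar log expression. Either pass explicit
#' `edges`, or pass the observed log values and get `n_bins` equal-width
#' bins spanning their range. Bin `i` covers `[edge_i, edge_{i+1})`; the
#' last bin is closed on the right.
#'
#' @param values Observed log-expression values (used when `edges` is NULL).
#' @param n_bins Number of bins; default 8.
#' @param edges Optional explicit ascending breakpoints (length
#'   `n_bins + 1`).
#' @return A `bin_scheme`: list with `n_bins` and `edges`.
#' @export
bin_scheme <- function(values = NULL, n_bins = 8L, edges = NULL) {
  if (is.null(edges)) {
    stopifnot(!is.null(values), all(is.finite(values)))
    lo <- min(values)
    hi <- max(values)
    if (hi <= lo) hi <- lo + 1 # degenerate range: one occupied bin
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(n_bins = length(edges) - 1L, edges = as.numeric(edges)),
            class = "bin_scheme")
}

#' Assign log-expression values to bins
#'
#' @param x Numeric (log-expression) values, optionally named by gene.
#' @param scheme A [bin_scheme()]. Its edges must span `x`; a value outside
#'   them is an error, since edges are built from the data and an
#'   out-of-range value indicates a pipeline bug.
#' @return Integer vector of 0-based bin indices (bin 0 is the lowest
#'   expression block), names preserved.
#' @export
assign_bins <- function(x, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  idx <- findInterval(x, scheme$edges, rightmost.closed = TRUE)
  if (any(idx == 0L | idx > scheme$n_bins)) {
    stop("log-expression value outside bin edges")
  }
  stats::setNames(idx - 1L, names(x))
}
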