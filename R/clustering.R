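# Qualitative structure check: hierarchical clustering of samples on
# abundant bait peptidoforms and agreement with condition labels.

#' Select abundantly detected peptidoforms
#'
#' Keeps rows with dataset-wide total at least `min_total` that are detected
#' (count > 0) in at least `min_samples` samples.
#'
#' @param counts Count matrix.
#' @param min_total Minimum dataset-wide total (default 10).
#' @param min_samples Minimum number of samples with a nonzero count
#'   (default 2).
#' @return The filtered matrix; a warning when no rows survive.
#' @export
select_abundant <- function(counts, min_total = 10, min_samples = 2) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total &
    rowSums(counts > 0) >= min_samples
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("No peptidoforms pass the abundance filter; clustering will be skipped",
            call. = FALSE)
  out
}

#' Log2 transform with zero fill for non-detected entries
#'
#' Positive counts become `log2(count)`; zeros (peptidoform not detected in
#' that sample) stay 0. Note `log2(1) == 0` collides with non-detection;
#' the upstream singleton filter removes most count-1 rows.
#'
#' @param counts Non-negative count matrix.
#' @return Transformed matrix of the same shape.
#' @export
log2_zero_fill <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  out <- counts
  pos <- counts > 0
  out[pos] <- log2(counts[pos])
  out
}

#' Hierarchically cluster samples and peptidoforms
#'
#' Agglomerative clustering with Euclidean distance and complete linkage on
#' both rows (peptidoforms) and columns (samples) — the `pheatmap` defaults.
#' Flat sample clusters are obtained by cutting the column dendrogram at
#' `k` (by default the number of distinct condition labels).
#'
#' @param transformed Matrix as produced by [log2_zero_fill()].
#' @param design An `experiment_design` (supplies `k` and sample order).
#' @param k Number of flat clusters; default the number of conditions among
#'   the clustered samples.
#' @return List of class `cluster_result`: `row_hclust`, `col_hclust`,
#'   `sample_order`, `clusters` (named integer vector), `k`, `matrix`.
#' @export
hcluster <- function(transformed, design = NULL, k = NULL) {
  m <- as.matrix(transformed)
  if (ncol(m) < 2L) stop("Clustering needs at least 2 samples", call. = FALSE)
  if (nrow(m) < 1L) stop("Clustering needs at least 1 feature", call. = FALSE)
  if (is.null(k)) {
    if (is.null(design)) stop("Supply either a design or k", call. = FALSE)
    conds <- design$samples$condition[design$samples$sample_id %in% colnames(m)]
    k <- length(unique(conds))
  }
  k <- min(k, ncol(m))
  col_h <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                         method = "complete")
  row_h <- if (nrow(m) >= 2L)
    stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  else NULL
  structure(list(row_hclust = row_h, col_hclust = col_h,
                 sample_order = colnames(m)[col_h$order],
                 clusters = stats::cutree(col_h, k = k), k = k, matrix = m),
            class = "cluster_result")
}

#' Agreement between flat clusters and condition labels
#'
#' Each flat cluster is assigned its majority condition (ties broken toward
#' the condition with more samples overall, then lexicographically); a
#' sample is correctly clustered when its own condition equals its
#' cluster's majority condition.
#'
#' @param cluster_result A `cluster_result` from [hcluster()].
#' @param design An `experiment_design`.
#' @return List with `n_correct`, `n_total` and per-sample logical `correct`.
#' @export
condition_agreement <- function(cluster_result, design) {
  cl <- cluster_result$clusters
  cond <- design$samples$condition[match(names(cl), design$samples$sample_id)]
  if (anyNA(cond)) stop("Clustered sample(s) missing from design", call. = FALSE)
  cond_size <- table(cond)
  majority <- vapply(split(cond, cl), function(x) {
    tab <- table(x)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) {   # ties: larger condition overall, then lexicographic
      sz <- cond_size[best]
      best <- best[sz == max(sz)]
      best <- sort(best)
    }
    best[1L]
  }, character(1L))
  correct <- cond == majority[as.character(cl)]
  names(correct) <- names(cl)
  list(n_correct = sum(correct), n_total = length(correct), correct = correct)
}

#' Cluster a bait count matrix end to end
#'
#' Convenience wrapper: abundance selection, log2 zero-fill transform,
#' clustering, and condition agreement.
#'
#' @param counts Bait count matrix (normally globally min-normalized).
#' @param design An `experiment_design`.
#' @param min_total,min_samples Passed to [select_abundant()].
#' @return A `cluster_result` with an `agreement` element, or `NULL` when no
#'   features pass the abundance filter.
#' @export
cluster_peptidoforms <- function(counts, design, min_total = 10,
                                 min_samples = 2) {
  sel <- select_abundant(counts, min_total, min_samples)
  if (nrow(sel) == 0L) return(NULL)
  res <- hcluster(log2_zero_fill(sel), design)
  res$agreement <- condition_agreement(res, design)
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (euclidean, complete): %d features x %d samples, k = %d\n",
              nrow(x$matrix), ncol(x$matrix), x$k))
  if (!is.null(x$agreement))
    cat(sprintf("Condition agreement: %d / %d samples correctly clustered\n",
                x$agreement$n_correct, x$agreement$n_total))
  invisible(x)
}
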