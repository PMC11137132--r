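# Differential presence of bait peptidoforms: min-sample normalization,
# singleton filtering, SAINTexpress-style scoring (external binary or
# internal Poisson surrogate) and Bayesian FDR.

#' Normalize bait counts to the smallest sample total within a comparison
#'
#' Each sample's counts are scaled by `min(totals) / total(sample)` so that
#' after normalization every sample in the comparison carries the total bait
#' PSM count of the sample with the fewest. The minimum-total sample is
#' unchanged; within-sample proportions are preserved.
#'
#' @param counts Bait count matrix (rows = peptidoform keys, columns =
#'   sample ids).
#' @param samples Sample ids to normalize over (the comparison members);
#'   default all columns.
#' @return The matrix restricted to `samples`, normalized, with attribute
#'   `norm_factors`.
#' @export
normalize_bait_counts <- function(counts, samples = colnames(counts)) {
  counts <- as.matrix(counts)
  absent <- setdiff(samples, colnames(counts))
  if (length(absent) > 0L) stop("Sample(s) absent from count matrix: ",
                                paste(absent, collapse = ", "), call. = FALSE)
  m <- counts[, samples, drop = FALSE]
  totals <- colSums(m)
  if (any(totals == 0)) stop("Sample(s) with zero bait PSMs: ",
                             paste(samples[totals == 0], collapse = ", "),
                             "; comparison impossible", call. = FALSE)
  factors <- min(totals) / totals
  out <- sweep(m, 2L, factors, `*`)
  attr(out, "norm_factors") <- factors
  out
}

#' Remove peptidoforms supported by a single PSM in the whole dataset
#'
#' Applied to RAW (pre-normalization) counts: rows whose dataset-wide total
#' equals 1 are unreliable identifications and are removed.
#'
#' @param counts Raw count matrix.
#' @return The filtered matrix, with attribute `removed` naming dropped rows.
#' @export
filter_singletons <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  drop <- totals == 1
  out <- counts[!drop, , drop = FALSE]
  if (nrow(out) == 0L && nrow(counts) > 0L)
    warning("All peptidoforms were singletons; matrix is empty", call. = FALSE)
  attr(out, "removed") <- rownames(counts)[drop]
  out
}

# continuous Poisson log-density for fractional counts
.dcpois_log <- function(x, lambda) x * log(lambda) - lambda - lgamma(x + 1)

#' Score a comparison with the internal SAINTexpress-style surrogate
#'
#' A two-component Poisson model per peptidoform: the background rate is the
#' mean control count plus a pseudocount, the enriched rate is the mean test
#' count plus the pseudocount, floored at the background rate (enrichment
#' only; depletion is discovered by running the reversed comparison). Each
#' test replicate's count yields a posterior probability of the enriched
#' component; `avgp` is their mean. Fractional counts (post-normalization)
#' use the continuous Poisson density with a gamma-function factorial.
#'
#' @param counts Normalized, singleton-filtered bait count matrix restricted
#'   to the comparison samples.
#' @param design An `experiment_design`.
#' @param comparison List/one-row data frame with `test` and `control`.
#' @param alpha Pseudocount added to both rates (default 0.1).
#' @param prior Prior probability of the enriched component (default 0.5).
#' @return Data frame with `peptidoform`, `test`, `control`, `avgp`,
#'   `log2fc`, `mean_test`, `mean_control`.
#' @export
score_internal <- function(counts, design, comparison, alpha = 0.1,
                           prior = 0.5) {
  counts <- as.matrix(counts)
  test_s <- design$samples$sample_id[design$samples$condition == comparison$test]
  ctrl_s <- design$samples$sample_id[design$samples$condition == comparison$control]
  if (length(test_s) == 0L) stop("Comparison has zero test replicates",
                                 call. = FALSE)
  test_s <- intersect(test_s, colnames(counts))
  ctrl_s <- intersect(ctrl_s, colnames(counts))
  if (length(test_s) == 0L) stop("No test-condition samples in count matrix",
                                 call. = FALSE)
  mt <- rowMeans(counts[, test_s, drop = FALSE])
  mc <- if (length(ctrl_s) > 0L) rowMeans(counts[, ctrl_s, drop = FALSE])
        else rep(0, nrow(counts))
  lambda0 <- mc + alpha
  lambda1 <- pmax(mt + alpha, lambda0)
  tcounts <- counts[, test_s, drop = FALSE]
  l1 <- .dcpois_log(tcounts, lambda1)
  l0 <- .dcpois_log(tcounts, lambda0)
  p <- 1 / (1 + exp(log((1 - prior) / prior) + l0 - l1))
  data.frame(peptidoform = rownames(counts),
             test = comparison$test, control = comparison$control,
             avgp = rowMeans(p),
             log2fc = log2((mt + alpha) / (mc + alpha)),
             mean_test = mt, mean_control = mc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bayesian FDR from AvgP values
#'
#' Results are ranked by `avgp` descending; the BFDR at rank k is the
#' cumulative mean of `1 - avgp` over the top k. Tied `avgp` values share
#' the value of the larger rank, which together with the cumulative
#' construction makes the BFDR non-decreasing down the ranking.
#'
#' @param results Data frame with an `avgp` column in `[0, 1]`.
#' @return `results` sorted by `avgp` descending with a `bfdr` column added.
#' @export
compute_bfdr <- function(results) {
  if (nrow(results) == 0L) { results$bfdr <- numeric(0L); return(results) }
  stopifnot(all(results$avgp >= 0 & results$avgp <= 1))
  ord <- order(-results$avgp)
  results <- results[ord, , drop = FALSE]
  bfdr <- cumsum(1 - results$avgp) / seq_len(nrow(results))
  bfdr <- stats::ave(bfdr, results$avgp, FUN = max)  # ties share larger rank
  results$bfdr <- cummax(bfdr)
  rownames(results) <- NULL
  results
}

#' Call significant peptidoforms at a BFDR threshold
#'
#' @param results Data frame with a `bfdr` column.
#' @param threshold BFDR cutoff (default 0.05); strictly `bfdr < threshold`.
#' @return `results` with a logical `significant` column.
#' @export
call_significant <- function(results, threshold = 0.05) {
  results$significant <- results$bfdr < threshold
  results
}

#' Score one comparison in both directions
#'
#' Runs the surrogate scorer (or an external SAINTexpress binary) with each
#' condition in the test role, computes the BFDR within each direction, and
#' binds the results. Counts are normalized within the comparison before
#' scoring; the singleton filter must already have been applied to the raw
#' matrix.
#'
#' @param raw_counts Raw bait count matrix (all design samples), already
#'   singleton-filtered.
#' @param design An `experiment_design`.
#' @param comparison List/one-row data frame with `test` and `control`.
#' @param scorer `"internal"` or `"saintexpress"`.
#' @param bfdr_threshold Significance cutoff (default 0.05).
#' @param both_directions Score the reversed comparison too (default TRUE).
#' @param alpha,prior Surrogate parameters, see [score_internal()].
#' @param saint_binary,saint_opts Passed to [run_saintexpress()].
#' @return Data frame of differential results with `bfdr` and `significant`.
#' @export
score_comparison <- function(raw_counts, design, comparison,
                             scorer = c("internal", "saintexpress"),
                             bfdr_threshold = 0.05, both_directions = TRUE,
                             alpha = 0.1, prior = 0.5,
                             saint_binary = "SAINTexpress-spc",
                             saint_opts = "") {
  scorer <- match.arg(scorer)
  cmp_samples <- design$samples$sample_id[
    design$samples$condition %in% c(comparison$test, comparison$control)]
  norm <- normalize_bait_counts(raw_counts, cmp_samples)
  dirs <- list(comparison)
  if (both_directions)
    dirs <- c(dirs, list(list(test = comparison$control,
                              control = comparison$test)))
  res <- lapply(dirs, function(cmp) {
    scored <- if (scorer == "saintexpress") {
      run_saintexpress(norm, design, cmp, binary = saint_binary,
                       options = saint_opts)
    } else {
      score_internal(norm, design, cmp, alpha = alpha, prior = prior)
    }
    compute_bfdr(scored)
  })
  out <- do.call(rbind, res)
  attr(out, "normalized_counts") <- norm
  call_significant(out, bfdr_threshold)
}

#' Run the external SAINTexpress binary on one comparison
#'
#' Writes the spectral-count input triple to a temporary workspace, invokes
#' the binary there, checks the exit status and parses the `list.txt`
#' output. When the binary is not on the PATH the internal surrogate scorer
#' is used instead, with a prominent warning.
#'
#' @param norm_counts Normalized bait count matrix.
#' @param design An `experiment_design`.
#' @param comparison List with `test` and `control`.
#' @param binary SAINTexpress executable name or path.
#' @param options Extra command-line options passed through verbatim.
#' @return Data frame with `peptidoform`, `test`, `control`, `avgp` (and
#'   whatever else the output provides) suitable for [compute_bfdr()].
#' @export
run_saintexpress <- function(norm_counts, design, comparison,
                             binary = "SAINTexpress-spc", options = "") {
  if (Sys.which(binary) == "" && !file.exists(binary)) {
    warning("SAINTexpress binary '", binary, "' not found; ",
            "falling back to the internal surrogate scorer", call. = FALSE)
    return(score_internal(norm_counts, design, comparison))
  }
  work <- tempfile("saint_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  paths <- write_saint_inputs(norm_counts, design, comparison, work)
  args <- c(if (nzchar(options)) strsplit(options, "[[:space:]]+")[[1L]],
            basename(paths[["interaction"]]), basename(paths[["prey"]]),
            basename(paths[["bait"]]))
  old <- setwd(work)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  status <- suppressWarnings(
    system2(binary, args, stdout = "saint_stdout.log", stderr = "saint_stderr.log"))
  if (status != 0L) {
    err <- tryCatch(readLines("saint_stderr.log"), error = function(e) character(0))
    stop("SAINTexpress exited with status ", status, ":\n",
         paste(err, collapse = "\n"), call. = FALSE)
  }
  out <- read_saint_output(file.path(work, "list.txt"))
  data.frame(peptidoform = out$peptidoform, test = comparison$test,
             control = comparison$control, avgp = out$avgp,
             stringsAsFactors = FALSE)
}
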