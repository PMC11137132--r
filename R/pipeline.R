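# End-to-end orchestration and the command-line surface.

#' Analyse an experiment held in memory
#'
#' The core pipeline on parsed objects: bait aggregation, singleton
#' filtering, per-comparison normalization and scoring, BFDR significance
#' calls, plus coverage, peptide positions, bait-vs-prey enrichment summary
#' and clustering (on globally min-normalized counts).
#'
#' @param psm_tables Named list of `psm_table`s (one per sample) or one
#'   bound `psm_table`.
#' @param design An `experiment_design`.
#' @param db A `protein_db`, or `NULL` to skip coverage/positions.
#' @param scorer `"internal"` or `"saintexpress"`.
#' @param bfdr_threshold BFDR significance cutoff (default 0.05).
#' @param min_total,min_samples Clustering abundance filter, see
#'   [select_abundant()].
#' @param digits Delta-mass rounding decimals (default 1).
#' @param alpha,prior Internal-scorer parameters.
#' @param saint_binary,saint_opts External SAINTexpress interface.
#' @return List of class `baitform_result`: `raw_counts`,
#'   `filtered_counts`, `results` (one data frame per comparison, both
#'   directions), `coverage`, `positions`, `enrichment`, `clustering`,
#'   `log` (character vector of the defaults/decisions used).
#' @export
analyze_experiment <- function(psm_tables, design, db = NULL,
                               scorer = c("internal", "saintexpress"),
                               bfdr_threshold = 0.05, min_total = 10,
                               min_samples = 2, digits = 1L, alpha = 0.1,
                               prior = 0.5,
                               saint_binary = "SAINTexpress-spc",
                               saint_opts = "") {
  scorer <- match.arg(scorer)
  records <- if (is.data.frame(psm_tables)) psm_tables
             else bind_psm_tables(psm_tables)
  log <- c(
    sprintf("delta-mass rounding: %d decimal(s), ties away from zero", digits),
    sprintf("isotopic-error spacing 1.00335 Da, k in -1..3, tolerance 0.05 Da"),
    "singleton filter applied to RAW counts, before normalization",
    "normalization: min-total within each comparison (global min for clustering)",
    sprintf("scorer: %s (alpha=%g, prior=%g); BFDR threshold %g (strict <)",
            scorer, alpha, prior, bfdr_threshold),
    sprintf("clustering: euclidean/complete, min_total=%g, min_samples=%g",
            min_total, min_samples))

  raw <- aggregate_counts(records, design, scope = "bait", digits = digits)
  filtered <- filter_singletons(raw)

  results <- list()
  for (i in seq_len(nrow(design$comparisons))) {
    cmp <- design$comparisons[i, ]
    nm <- paste0(cmp$test, "_vs_", cmp$control)
    if (nm %in% names(results) ||
        paste0(cmp$control, "_vs_", cmp$test) %in% names(results)) next
    results[[nm]] <- score_comparison(filtered, design, cmp, scorer = scorer,
                                      bfdr_threshold = bfdr_threshold,
                                      alpha = alpha, prior = prior,
                                      saint_binary = saint_binary,
                                      saint_opts = saint_opts)
  }

  coverage <- positions <- NULL
  if (!is.null(db) && design$bait_gene %in% db$gene) {
    bait_recs <- records[.is_bait_record(records, design), , drop = FALSE]
    coverage <- compute_coverage(bait_recs, db, design$bait_gene)
    positions <- peptide_relative_positions(bait_recs, db, design$bait_gene)
  }
  enrichment <- summarize_enrichment(records, design)
  clustering <- if (ncol(filtered) >= 2L && nrow(filtered) >= 1L) {
    glob <- normalize_bait_counts(filtered)
    cluster_peptidoforms(glob, design, min_total = min_total,
                         min_samples = min_samples)
  } else NULL

  structure(list(raw_counts = raw, filtered_counts = filtered,
                 results = results, coverage = coverage,
                 positions = positions, enrichment = enrichment,
                 clustering = clustering, log = log),
            class = "baitform_result")
}

#' @export
print.baitform_result <- function(x, ...) {
  cat("baitform analysis:", nrow(x$raw_counts), "bait peptidoforms (",
      nrow(x$filtered_counts), "after singleton filter ) across",
      ncol(x$raw_counts), "samples\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: %d peptidoforms scored, %d significant at BFDR\n",
                nm, nrow(r), sum(r$significant)))
  }
  if (!is.null(x$coverage)) print(x$coverage)
  if (!is.null(x$clustering)) print(x$clustering)
  invisible(x)
}

#' Run the full pipeline from files on disk
#'
#' Reads the design manifest, the per-sample PSM tables and the FASTA, runs
#' [analyze_experiment()], and writes results TSVs (one per comparison), a
#' coverage/positions TSV, the flat clusters and a run log into `out_dir`.
#'
#' @param design_path Design manifest TSV (see [read_design()]).
#' @param fasta_path Protein FASTA, or `NULL`.
#' @param out_dir Output directory.
#' @param ... Passed to [analyze_experiment()].
#' @return Invisibly, the `baitform_result`.
#' @export
run_pipeline <- function(design_path, fasta_path = NULL, out_dir, ...) {
  design <- read_design(design_path)
  tables <- lapply(seq_len(nrow(design$samples)), function(i)
    read_psm_table(design$samples$psm_path[i], design$samples$sample_id[i]))
  names(tables) <- design$samples$sample_id
  db <- if (!is.null(fasta_path)) read_fasta(fasta_path) else NULL
  res <- analyze_experiment(tables, design, db, ...)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$results)) {
    r <- res$results[[nm]]
    r$peptide <- peptidoform_peptide(r$peptidoform)
    r$delta_mass <- peptidoform_delta(r$peptidoform)
    write_results_tsv(r, attr(r, "normalized_counts"),
                      file.path(out_dir, paste0("differential_", nm, ".tsv")))
  }
  if (!is.null(res$positions))
    utils::write.table(res$positions, file.path(out_dir, "peptide_positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$coverage))
    writeLines(sprintf("%s\t%.4f", res$coverage$gene,
                       res$coverage$percent_coverage),
               file.path(out_dir, "coverage.tsv"))
  if (!is.null(res$clustering))
    utils::write.table(
      data.frame(sample_id = names(res$clustering$clusters),
                 cluster = res$clustering$clusters),
      file.path(out_dir, "sample_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `run` (full
#' pipeline) and `annotate` (explain a delta mass). Invoke from a shell as
#' `Rscript -e 'baitform::baitform_main()' <subcommand> [options]`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
baitform_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: baitform <simulate|run|annotate> [options]"
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  sub <- args[1L]; rest <- args[-1L]
  status <- tryCatch({
    switch(sub,
      simulate = {
        p <- optparse::OptionParser(option_list = list(
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--seed", type = "integer", default = 42L),
          optparse::make_option("--scenario", type = "character",
                                default = "mutation")))
        o <- optparse::parse_args(p, rest)
        if (is.null(o$out)) stop("--out is required", call. = FALSE)
        cfg <- sim_config(seed = o$seed)
        ds <- if (o$scenario == "mutation") generate_mutation_scenario(cfg)
              else generate_dataset(cfg)
        write_dataset(ds, o$out)
        message("Wrote synthetic dataset to ", o$out)
        0L
      },
      run = {
        p <- optparse::OptionParser(option_list = list(
          optparse::make_option("--design", type = "character"),
          optparse::make_option("--fasta", type = "character", default = NULL),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--scorer", type = "character",
                                default = "internal"),
          optparse::make_option("--bfdr", type = "double", default = 0.05),
          optparse::make_option("--min-total", type = "double", default = 10,
                                dest = "min_total"),
          optparse::make_option("--decimals", type = "integer", default = 1L),
          optparse::make_option("--saint-binary", type = "character",
                                default = "SAINTexpress-spc",
                                dest = "saint_binary"),
          optparse::make_option("--saint-opts", type = "character",
                                default = "", dest = "saint_opts")))
        o <- optparse::parse_args(p, rest)
        if (is.null(o$design) || is.null(o$out))
          stop("--design and --out are required", call. = FALSE)
        res <- run_pipeline(o$design, o$fasta, o$out, scorer = o$scorer,
                            bfdr_threshold = o$bfdr,
                            min_total = o$min_total, digits = o$decimals,
                            saint_binary = o$saint_binary,
                            saint_opts = o$saint_opts)
        print(res)
        0L
      },
      annotate = {
        p <- optparse::OptionParser(option_list = list(
          optparse::make_option("--delta", type = "double"),
          optparse::make_option("--residue", type = "character",
                                default = NA_character_),
          optparse::make_option("--tolerance", type = "double",
                                default = 0.05)))
        o <- optparse::parse_args(p, rest)
        if (is.null(o$delta)) stop("--delta is required", call. = FALSE)
        ann <- annotate_delta_mass(o$delta, o$residue, tolerance = o$tolerance)
        if (nrow(ann) == 0L) message("No candidate annotation within tolerance")
        else print(ann)
        0L
      },
      { message(usage); 1L })
  }, error = function(e) { message("Error: ", conditionMessage(e)); 1L })
  invisible(status)
}
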