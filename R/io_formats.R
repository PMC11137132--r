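# Readers and writers for every external format the workflow touches:
# FragPipe-style psm.tsv, protein FASTA, design manifests, SAINTexpress
# input/output triples, and the results TSV.

#' Default column mapping for the FragPipe psm.tsv dialect
#'
#' Maps canonical internal field names to the column headers found in a
#' FragPipe/MSFragger `psm.tsv`. Pass a modified copy to [read_psm_table()]
#' to consume tables from other open-search exporters.
#'
#' @return Named character vector: internal field -> expected column header.
#' @export
psm_column_map <- function() {
  c(spectrum_id            = "Spectrum",
    peptide                = "Peptide",
    modified_peptide       = "Modified Peptide",
    delta_mass             = "Delta Mass",
    assigned_protein       = "Protein",
    gene                   = "Gene",
    mapped_proteins        = "Mapped Proteins",
    localization           = "MSFragger Localization",
    observed_modifications = "Observed Modifications",
    intensity              = "Intensity")
}

# mandatory fields for any usable PSM table
.psm_mandatory <- c("peptide", "delta_mass", "assigned_protein", "gene")

#' Read a FragPipe-style PSM table
#'
#' Parses one tab-separated `psm.tsv` (one file per sample) into a
#' `psm_table` data frame with canonical column names. Optional columns that
#' are absent in the file become empty strings (or `NA` for intensity).
#'
#' @param path Path to a tab-separated PSM table with a header row.
#' @param sample_id Sample identifier attached to every row.
#' @param columns Column mapping as produced by [psm_column_map()].
#' @return A data frame of class `psm_table` with columns `spectrum_id`,
#'   `sample_id`, `peptide`, `modified_peptide`, `delta_mass`,
#'   `assigned_protein`, `gene`, `mapped_proteins`, `localization`,
#'   `observed_modifications`, `intensity`. Row count equals the number of
#'   data rows in the file.
#' @export
read_psm_table <- function(path, sample_id, columns = psm_column_map()) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(sample_id), length(sample_id) == 1L)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  missing <- setdiff(columns[.psm_mandatory], names(raw))
  if (length(missing) > 0L) {
    stop("PSM table '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  pick <- function(field, default = "") {
    col <- columns[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  dm_chr <- pick("delta_mass")
  dm <- suppressWarnings(as.numeric(dm_chr))
  bad <- which(!is.finite(dm))
  if (length(bad) > 0L) {
    stop("Unparsable delta mass in '", path, "' at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (value '", dm_chr[bad[1L]], "')", call. = FALSE)
  }
  out <- data.frame(
    spectrum_id            = pick("spectrum_id"),
    sample_id              = rep(sample_id, n),
    peptide                = pick("peptide"),
    modified_peptide       = pick("modified_peptide"),
    delta_mass             = dm,
    assigned_protein       = pick("assigned_protein"),
    gene                   = pick("gene"),
    mapped_proteins        = pick("mapped_proteins"),
    localization           = pick("localization"),
    observed_modifications = pick("observed_modifications"),
    intensity              = suppressWarnings(as.numeric(pick("intensity", NA_character_))),
    stringsAsFactors = FALSE
  )
  if (n > 0L && any(!grepl("^[A-Z]+$", out$peptide))) {
    stop("PSM table '", path, "' contains peptide(s) that are not uppercase ",
         "amino-acid strings", call. = FALSE)
  }
  class(out) <- c("psm_table", class(out))
  out
}

#' Combine per-sample PSM tables
#'
#' @param tables List of `psm_table` data frames.
#' @return One `psm_table` with all rows.
#' @export
bind_psm_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, as.data.frame))
  class(out) <- c("psm_table", class(out))
  out
}

#' Read a protein FASTA into a gene-indexed protein database
#'
#' Headers are parsed with a UniProt-style convention: accession from
#' `sp|ACC|NAME` / `tr|ACC|NAME` (otherwise the first whitespace-delimited
#' token) and gene symbol from a `GN=` tag (otherwise the `NAME` part after
#' the accession, otherwise the accession itself). Custom extraction can be
#' supplied for non-UniProt databases.
#'
#' @param path FASTA file path.
#' @param accession_fun,gene_fun Optional functions mapping a header string
#'   to accession / gene symbol.
#' @return An object of class `protein_db`: a data frame with columns
#'   `accession`, `gene`, `sequence`, `length`.
#' @export
read_fasta <- function(path, accession_fun = NULL, gene_fun = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  sequences <- as.character(seqs)
  if (is.null(accession_fun)) {
    accession_fun <- function(h) {
      tok <- sub("\\s.*$", "", h)
      if (grepl("^(sp|tr)\\|", tok)) strsplit(tok, "|", fixed = TRUE)[[1L]][2L] else tok
    }
  }
  if (is.null(gene_fun)) {
    gene_fun <- function(h) {
      m <- regmatches(h, regexpr("GN=([^ ]+)", h))
      if (length(m) == 1L) return(sub("^GN=", "", m))
      tok <- sub("\\s.*$", "", h)
      parts <- strsplit(tok, "|", fixed = TRUE)[[1L]]
      if (length(parts) >= 3L) sub("_.*$", "", parts[3L]) else tok
    }
  }
  protein_db(accession = vapply(headers, accession_fun, character(1L), USE.NAMES = FALSE),
             gene      = vapply(headers, gene_fun, character(1L), USE.NAMES = FALSE),
             sequence  = sequences)
}

#' Construct a protein database
#'
#' @param accession,gene,sequence Parallel character vectors.
#' @return A `protein_db` data frame.
#' @export
protein_db <- function(accession, gene, sequence) {
  stopifnot(length(accession) == length(gene),
            length(gene) == length(sequence))
  if (anyDuplicated(accession)) {
    stop("Duplicate accession(s) in protein database: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(sequence) > 0L && any(!grepl("^[A-Za-z]+$", sequence))) {
    stop("Protein sequence(s) contain non-alphabetic characters", call. = FALSE)
  }
  out <- data.frame(accession = as.character(accession),
                    gene = as.character(gene),
                    sequence = toupper(as.character(sequence)),
                    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  class(out) <- c("protein_db", class(out))
  out
}

#' Longest isoform sequence of a gene
#'
#' Ties on length are broken lexicographically by accession, so the result is
#' deterministic and independent of FASTA record order.
#'
#' @param db A `protein_db`.
#' @param gene Gene symbol.
#' @return The longest isoform sequence (character scalar).
#' @export
longest_isoform <- function(db, gene) {
  rows <- db[db$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0L) stop("Gene '", gene, "' not found in protein database",
                             call. = FALSE)
  rows <- rows[order(-rows$length, rows$accession), , drop = FALSE]
  rows$sequence[1L]
}

#' Construct an experiment design
#'
#' @param samples Data frame with columns `sample_id`, `condition` and
#'   optionally `replicate` and `psm_path`.
#' @param bait_gene Bait gene symbol.
#' @param bait_accessions Character vector of bait accessions (isoform
#'   suffixes such as `-2` are matched by prefix downstream).
#' @param comparisons Data frame with columns `test`, `control`; defaults to
#'   both orderings of the first two conditions when exactly two exist.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(samples, bait_gene, bait_accessions,
                              comparisons = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "condition") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  if (anyDuplicated(samples$sample_id)) stop("Duplicate sample_id in design",
                                             call. = FALSE)
  if (nrow(samples) == 0L) stop("Design has no samples", call. = FALSE)
  if (length(bait_accessions) == 0L) stop("bait_accessions must be non-empty",
                                          call. = FALSE)
  if (!"replicate" %in% names(samples)) {
    samples$replicate <- stats::ave(seq_len(nrow(samples)), samples$condition,
                                    FUN = seq_along)
  }
  conds <- unique(samples$condition)
  if (is.null(comparisons)) {
    comparisons <- if (length(conds) == 2L) {
      data.frame(test = c(conds[2L], conds[1L]), control = c(conds[1L], conds[2L]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(test = character(0L), control = character(0L))
    }
  }
  bad <- setdiff(c(comparisons$test, comparisons$control), conds)
  if (length(bad) > 0L) stop("Comparison references unknown condition(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  structure(list(samples = samples,
                 bait_gene = as.character(bait_gene),
                 bait_accessions = unique(as.character(bait_accessions)),
                 comparisons = comparisons),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design: bait", x$bait_gene,
      sprintf("(%d accession(s))", length(x$bait_accessions)), "\n")
  tab <- table(x$samples$condition)
  cat("Samples:", nrow(x$samples), "in", length(tab), "condition(s):",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (nrow(x$comparisons) > 0L)
    cat("Comparisons:",
        paste(x$comparisons$test, "vs", x$comparisons$control, collapse = "; "),
        "\n")
  invisible(x)
}

#' Read a design manifest
#'
#' A tab-separated manifest with one row per sample and columns `sample_id`,
#' `psm_path`, `condition`, `bait_gene`, `bait_accessions`
#' (semicolon-separated). `bait_gene`/`bait_accessions` must be constant
#' across rows. Relative `psm_path`s are resolved against the manifest
#' directory.
#'
#' @param path Manifest TSV path.
#' @return An `experiment_design` whose `samples` carry `psm_path`.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "psm_path", "condition", "bait_gene", "bait_accessions")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) stop("Design manifest missing column(s): ",
                                 paste(missing, collapse = ", "), call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", tab$psm_path)
  tab$psm_path[rel] <- file.path(dirname(path), tab$psm_path[rel])
  experiment_design(samples = tab[, c("sample_id", "condition", "psm_path")],
                    bait_gene = unique(tab$bait_gene)[1L],
                    bait_accessions = unlist(strsplit(tab$bait_accessions[1L], ";",
                                                      fixed = TRUE)))
}

# round half away from zero at the external SAINT interface
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Write SAINTexpress spectral-count input files
#'
#' Emits the classic SAINTexpress triple for one comparison: an interaction
#' file (IP, bait, prey, count), a prey file (prey, length, gene) and a bait
#' file (IP, bait, T/C). The peptidoform key plays the prey role; its prey
#' "length" is the peptide length. Counts are rounded half-away-from-zero to
#' integers (SAINTexpress consumes spectral counts); zero-count pairs are
#' omitted.
#'
#' @param counts Bait-peptidoform count matrix (rows = peptidoform keys,
#'   columns = sample ids), normally normalized.
#' @param design An `experiment_design`.
#' @param comparison List or one-row data frame with `test` and `control`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named paths `interaction`, `prey`, `bait`.
#' @export
write_saint_inputs <- function(counts, design, comparison, dir) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("No bait peptidoforms to write", call. = FALSE)
  test_s <- design$samples$sample_id[design$samples$condition == comparison$test]
  ctrl_s <- design$samples$sample_id[design$samples$condition == comparison$control]
  all_s <- c(test_s, ctrl_s)
  absent <- setdiff(all_s, colnames(counts))
  if (length(absent) > 0L) stop("Sample(s) absent from count matrix: ",
                                paste(absent, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bait_name <- design$bait_gene
  keys <- rownames(counts)
  peptides <- peptidoform_peptide(keys)

  inter <- do.call(rbind, lapply(all_s, function(s) {
    cnt <- .round_half_away(counts[, s])
    keep <- cnt > 0
    if (!any(keep)) return(NULL)
    data.frame(ip = s, bait = bait_name, prey = keys[keep],
               count = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  }))
  if (is.null(inter)) inter <- data.frame(ip = character(0), bait = character(0),
                                          prey = character(0), count = integer(0))
  prey <- data.frame(prey = keys, length = nchar(peptides), gene = keys,
                     stringsAsFactors = FALSE)
  bait <- data.frame(ip = all_s, bait = bait_name,
                     tc = c(rep("T", length(test_s)), rep("C", length(ctrl_s))),
                     stringsAsFactors = FALSE)
  paths <- c(interaction = file.path(dir, "interaction.txt"),
             prey = file.path(dir, "prey.txt"),
             bait = file.path(dir, "bait.txt"))
  wr <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE, col.names = FALSE)
  wr(inter, paths[["interaction"]])
  wr(prey, paths[["prey"]])
  wr(bait, paths[["bait"]])
  invisible(paths)
}

#' Read a SAINTexpress "list" output file
#'
#' @param path Tab-separated SAINTexpress output with at least `Prey`,
#'   `AvgP` and `BFDR` columns (a `Bait` column is tolerated but unused).
#' @return Data frame with `peptidoform`, `avgp`, `bfdr` and, when a
#'   `FoldChange` column is present, `fold_change`. Unparsable BFDR entries
#'   become `NA` with a warning.
#' @export
read_saint_output <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"BFDR" %in% names(tab)) stop("SAINT output '", path,
                                    "' is missing the BFDR column", call. = FALSE)
  if (!"Prey" %in% names(tab)) stop("SAINT output '", path,
                                    "' is missing the Prey column", call. = FALSE)
  bfdr <- suppressWarnings(as.numeric(tab$BFDR))
  if (nrow(tab) > 0L && anyNA(bfdr)) {
    warning("SAINT output contains ", sum(is.na(bfdr)),
            " unparsable BFDR value(s); marked as missing", call. = FALSE)
  }
  out <- data.frame(peptidoform = as.character(tab$Prey),
                    avgp = if ("AvgP" %in% names(tab))
                      suppressWarnings(as.numeric(tab$AvgP)) else NA_real_,
                    bfdr = bfdr, stringsAsFactors = FALSE)
  if ("FoldChange" %in% names(tab))
    out$fold_change <- suppressWarnings(as.numeric(tab$FoldChange))
  out
}

#' Write the differential-results TSV
#'
#' @param results Data frame of differential results (see [score_comparison()]).
#' @param counts Normalized count matrix whose per-sample columns are appended.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(results, counts = NULL, path) {
  out <- results
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    idx <- match(out$peptidoform, rownames(counts))
    for (s in colnames(counts)) out[[paste0("count_", s)]] <- counts[idx, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
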