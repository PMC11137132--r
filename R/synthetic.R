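# Seeded generator of open-search-style PSM tables with controlled
# peptidoform structure: bait peptides at high counts, prey background,
# delta-mass populations and condition-dependent peptidoform abundance.

# Synthetic 186-residue Ras-like bait sequence (NOT a real protein entry;
# constructed so tryptic digestion yields ~10 peptides of length 7-30,
# contains the LVVVGAGGVGK mutation-scenario peptide, and has C- and
# M-bearing peptides for the delta-mass menu).
.SYNTHETIC_BAIT <- paste0(
  "MTEYK", "LVVVGAGGVGK", "SALTIQLIQNHFVDEYDPTIEDSYR", "K",
  "QVVIDGETCLLDILDTAGQEEYSAMR", "DQYMR", "TGEGFLCVFAINNTK", "SFEDIHQYR",
  "EQIK", "R", "VK", "DSDDVPMVLVGNK", "CDLAAR", "TVESR", "QAQDLAR",
  "SYGIPYIETSAK", "TR", "QGVEDAFYTLVR", "EIR", "QHK", "LNPPDESGPGCMSCK",
  "CVLS")

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P; keeps peptides
#' within the length window.
#'
#' @param sequence Protein sequence (uppercase string).
#' @param min_len,max_len Peptide length window (defaults 7 and 30).
#' @return Character vector of peptides in N- to C-terminal order.
#' @export
digest_tryptic <- function(sequence, min_len = 7L, max_len = 30L) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n |
                           (cut_after < n & aa[cut_after + 1L] != "P")]
  starts <- c(1L, cut_after[cut_after < n] + 1L)
  ends <- c(cut_after[cut_after < n], n)
  peps <- substring(sequence, starts, ends)
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

#' Simulation configuration for the synthetic open-search generator
#'
#' Defaults describe a typical two-condition bait pulldown: three replicates
#' per condition, an expected 10 PSMs per unmodified bait peptidoform per
#' sample, a delta-mass menu with isotopic errors, N-terminal carbamylation,
#' methionine oxidation and a fixed-modification-displacement negative on
#' cysteine, 300 prey proteins with gamma-distributed per-protein PSM rates
#' (mean 3, so the bait dot sits far above the prey density), 20%
#' multiplicative sample-depth jitter and +/-0.01 Da sub-bin delta jitter.
#'
#' @param seed Integer RNG seed.
#' @param conditions Named integer vector: condition label -> replicate count.
#' @param bait_gene,bait_accession,bait_sequence Bait identity; the default
#'   sequence is a synthetic Ras-like 186-mer.
#' @param baseline_rate Expected PSM count of an unmodified bait peptidoform
#'   per sample.
#' @param delta_menu Data frame with `delta` (Da), `residues` (single
#'   letter required in the peptide, `"N-term"`, or `""` for any) and
#'   `rate_frac` (rate relative to `baseline_rate`).
#' @param differential Data frame with `peptide`, `delta`, `condition`,
#'   `fold_change`: multiplies that peptidoform's rate in that condition.
#' @param prey_n,prey_rate_shape,prey_rate_scale Number of prey proteins and
#'   the gamma distribution of their per-sample PSM rates.
#' @param depth_sd Standard deviation of log-normal sample-depth jitter.
#' @param delta_jitter Half-width (Da) of uniform sub-bin jitter applied to
#'   emitted delta masses.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       conditions = c(control = 3L, test = 3L),
                       bait_gene = "BAITX",
                       bait_accession = "SYNB01",
                       bait_sequence = .SYNTHETIC_BAIT,
                       baseline_rate = 10,
                       delta_menu = data.frame(
                         delta = c(1.00335, 43.0058, 15.9949, -9.0368),
                         residues = c("", "N-term", "M", "C"),
                         rate_frac = c(0.15, 0.2, 0.25, 0.15),
                         stringsAsFactors = FALSE),
                       differential = NULL,
                       prey_n = 300L,
                       prey_rate_shape = 1.5,
                       prey_rate_scale = 2,
                       depth_sd = 0.2,
                       delta_jitter = 0.01) {
  stopifnot(all(conditions >= 1L), baseline_rate >= 0,
            all(delta_menu$rate_frac >= 0), depth_sd >= 0, delta_jitter >= 0)
  if (is.null(differential))
    differential <- data.frame(peptide = character(0), delta = numeric(0),
                               condition = character(0),
                               fold_change = numeric(0),
                               stringsAsFactors = FALSE)
  stopifnot(all(differential$fold_change > 0))
  structure(list(seed = as.integer(seed), conditions = conditions,
                 bait_gene = bait_gene, bait_accession = bait_accession,
                 bait_sequence = bait_sequence, baseline_rate = baseline_rate,
                 delta_menu = delta_menu, differential = differential,
                 prey_n = as.integer(prey_n),
                 prey_rate_shape = prey_rate_shape,
                 prey_rate_scale = prey_rate_scale,
                 depth_sd = depth_sd, delta_jitter = delta_jitter),
            class = "sim_config")
}

# lowercase the first occurrence of `residue` in `peptide` (localization
# string as produced by open-search engines); "" when not applicable
.localize <- function(peptide, residue) {
  if (residue == "" || residue == "N-term") return("")
  pos <- regexpr(residue, peptide, fixed = TRUE)[[1L]]
  if (pos == -1L) return("")
  substr(peptide, pos, pos) <- tolower(residue)
  peptide
}

# bait peptidoform table (peptide, delta, localization) plus the
# per-condition Poisson rate matrix implied by a config
.bait_rate_table <- function(config) {
  peptides <- digest_tryptic(config$bait_sequence)
  if (length(peptides) == 0L)
    stop("Bait sequence yields no valid tryptic peptides", call. = FALSE)
  forms <- data.frame(peptide = peptides, delta = 0, localization = "",
                      rate = config$baseline_rate, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(config$delta_menu))) {
    d <- config$delta_menu[i, ]
    eligible <- if (d$residues == "" || d$residues == "N-term") peptides
                else peptides[grepl(d$residues, peptides, fixed = TRUE)]
    if (length(eligible) == 0L) next
    forms <- rbind(forms, data.frame(
      peptide = eligible, delta = d$delta,
      localization = vapply(eligible, .localize, character(1L),
                            residue = d$residues, USE.NAMES = FALSE),
      rate = config$baseline_rate * d$rate_frac, stringsAsFactors = FALSE))
  }
  conds <- names(config$conditions)
  rates <- matrix(forms$rate, nrow = nrow(forms), ncol = length(conds),
                  dimnames = list(NULL, conds))
  diff <- config$differential
  for (i in seq_len(nrow(diff))) {
    row <- which(forms$peptide == diff$peptide[i] &
                   abs(forms$delta - diff$delta[i]) < 1e-6)
    if (length(row) == 0L) {   # peptidoform absent at baseline: add it
      forms <- rbind(forms, data.frame(peptide = diff$peptide[i],
                                       delta = diff$delta[i],
                                       localization = "", rate = 0,
                                       stringsAsFactors = FALSE))
      rates <- rbind(rates, matrix(0, 1L, ncol(rates)))
      row <- nrow(forms)
    }
    stopifnot(diff$condition[i] %in% conds)
    rates[row, diff$condition[i]] <- rates[row, diff$condition[i]] *
      diff$fold_change[i]
  }
  forms$rate <- NULL
  list(forms = forms, rates = rates)
}

# shared sampling path: all randomness happens here, in a fixed order, so
# that a fixed seed gives byte-identical output
.sample_dataset <- function(config, forms, rates) {
  set.seed(config$seed)
  conds <- names(config$conditions)
  prey_acc <- sprintf("SYNP%03d", seq_len(config$prey_n))
  prey_gene <- sprintf("PREY%03d", seq_len(config$prey_n))
  prey_seq <- vapply(seq_len(config$prey_n), function(i) {
    paste(sample(names(.RESIDUE_MASS), sample(120:400, 1L), replace = TRUE),
          collapse = "")
  }, character(1L))
  prey_pep <- vapply(prey_seq, function(s) {
    p <- digest_tryptic(s)
    if (length(p) > 0L) p[1L] else substr(s, 1L, 12L)
  }, character(1L), USE.NAMES = FALSE)
  prey_rate <- stats::rgamma(config$prey_n, shape = config$prey_rate_shape,
                             scale = config$prey_rate_scale)

  samples <- data.frame(
    sample_id = unlist(lapply(conds, function(cn)
      paste0(cn, "_", seq_len(config$conditions[[cn]])))),
    condition = rep(conds, times = config$conditions),
    stringsAsFactors = FALSE)
  design <- experiment_design(samples, config$bait_gene,
                              config$bait_accession)

  psm <- stats::setNames(vector("list", nrow(samples)), samples$sample_id)
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]; cn <- samples$condition[i]
    depth <- exp(stats::rnorm(1L, 0, config$depth_sd))
    bait_cnt <- stats::rpois(nrow(forms), rates[, cn] * depth)
    prey_cnt <- stats::rpois(config$prey_n, prey_rate * depth)
    bi <- rep(seq_len(nrow(forms)), bait_cnt)
    pj <- rep(seq_len(config$prey_n), prey_cnt)
    n_bait <- length(bi); n_prey <- length(pj)
    jit <- stats::runif(n_bait, -config$delta_jitter, config$delta_jitter)
    tab <- data.frame(
      spectrum_id = sprintf("%s.%05d", s, seq_len(n_bait + n_prey)),
      sample_id = s,
      peptide = c(forms$peptide[bi], prey_pep[pj]),
      modified_peptide = "",
      delta_mass = c(forms$delta[bi] + jit, rep(0, n_prey)),
      assigned_protein = c(rep(config$bait_accession, n_bait), prey_acc[pj]),
      gene = c(rep(config$bait_gene, n_bait), prey_gene[pj]),
      mapped_proteins = "",
      localization = c(forms$localization[bi], rep("", n_prey)),
      observed_modifications = "",
      intensity = NA_real_,
      stringsAsFactors = FALSE)
    class(tab) <- c("psm_table", class(tab))
    psm[[s]] <- tab
  }

  db <- protein_db(accession = c(config$bait_accession, prey_acc),
                   gene = c(config$bait_gene, prey_gene),
                   sequence = c(config$bait_sequence, prey_seq))
  key <- make_peptidoform_key(forms$peptide, forms$delta)$key
  differs <- apply(rates, 1L, function(r) max(r) - min(r) > 1e-12)
  truth <- cbind(data.frame(key = key[differs],
                            peptide = forms$peptide[differs],
                            delta = forms$delta[differs],
                            stringsAsFactors = FALSE),
                 as.data.frame(rates[differs, , drop = FALSE]))
  rownames(truth) <- NULL
  structure(list(psm = psm, db = db, design = design, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Generate a synthetic open-search dataset
#'
#' Digests the bait in silico, draws per-sample peptidoform PSM counts from
#' Poisson rates (condition effect times log-normal sample depth), emits
#' delta masses with sub-bin jitter, draws prey PSMs per protein, and
#' returns everything the downstream pipeline consumes. Deterministic under
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with `psm` (named list of per-sample
#'   `psm_table`s), `db` (a `protein_db` of bait + preys), `design` (an
#'   `experiment_design`), and `truth` (data frame of peptidoforms whose
#'   rates differ between conditions, with `key`, `peptide`, `delta`, and
#'   per-condition rate columns).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bt <- .bait_rate_table(config)
  .sample_dataset(config, bt$forms, bt$rates)
}

#' Generate a genetic-mutation scenario dataset
#'
#' A paired swap emulating a point mutation detected through open search:
#' in the mutant condition, a fraction of the target peptide's unmodified
#' rate mass moves to the substituted form (+58.0055 Da, a Gly->Asp mass
#' difference, localized on the mutated glycine).
#'
#' @param config A [sim_config()] whose bait contains `target_peptide`.
#' @param target_peptide Peptide carrying the substitution (default
#'   `"LVVVGAGGVGK"`).
#' @param delta Substitution mass in Da (default 58.0055, Gly->Asp).
#' @param position Position of the substituted residue within the peptide
#'   (default 7, lowercased in the localization string).
#' @param mutant_condition Condition carrying the mutant form (default
#'   `"test"`).
#' @param swap_fraction Fraction of the unmodified rate moved to the mutant
#'   form in the mutant condition (default 1: a pure swap).
#' @return A `sim_dataset`, as [generate_dataset()].
#' @export
generate_mutation_scenario <- function(config = sim_config(),
                                       target_peptide = "LVVVGAGGVGK",
                                       delta = 58.0055, position = 7L,
                                       mutant_condition = "test",
                                       swap_fraction = 1) {
  stopifnot(inherits(config, "sim_config"),
            swap_fraction >= 0, swap_fraction <= 1,
            mutant_condition %in% names(config$conditions))
  if (!grepl(target_peptide, config$bait_sequence, fixed = TRUE))
    stop("Bait sequence does not contain the target peptide ",
         target_peptide, call. = FALSE)
  bt <- .bait_rate_table(config)
  forms <- bt$forms; rates <- bt$rates
  unmod <- which(forms$peptide == target_peptide & forms$delta == 0)
  stopifnot(length(unmod) == 1L)
  loc <- target_peptide
  substr(loc, position, position) <- tolower(substr(loc, position, position))
  forms <- rbind(forms, data.frame(peptide = target_peptide, delta = delta,
                                   localization = loc,
                                   stringsAsFactors = FALSE))
  rates <- rbind(rates, matrix(0, 1L, ncol(rates)))
  moved <- rates[unmod, mutant_condition] * swap_fraction
  rates[nrow(rates), mutant_condition] <- moved
  rates[unmod, mutant_condition] <- rates[unmod, mutant_condition] - moved
  .sample_dataset(config, forms, rates)
}

#' Write a synthetic dataset to disk in FragPipe dialect
#'
#' Emits one `psm.tsv` per sample, a FASTA of bait and prey sequences, and a
#' design manifest consumable by [read_design()].
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- psm_column_map()
  fields <- c("spectrum_id", "peptide", "modified_peptide", "delta_mass",
              "assigned_protein", "gene", "mapped_proteins", "localization",
              "observed_modifications", "intensity")
  paths <- character(0L)
  for (s in names(dataset$psm)) {
    out <- dataset$psm[[s]][fields]
    names(out) <- cols[fields]
    p <- file.path(dir, paste0(s, ".psm.tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[s] <- p
  }
  fasta <- file.path(dir, "proteins.fasta")
  headers <- sprintf("sp|%s|%s_SYNTH GN=%s", dataset$db$accession,
                     dataset$db$gene, dataset$db$gene)
  writeLines(paste0(">", headers, "\n", dataset$db$sequence), fasta)
  manifest <- data.frame(
    sample_id = dataset$design$samples$sample_id,
    psm_path = basename(paths[dataset$design$samples$sample_id]),
    condition = dataset$design$samples$condition,
    bait_gene = dataset$design$bait_gene,
    bait_accessions = paste(dataset$design$bait_accessions, collapse = ";"),
    stringsAsFactors = FALSE)
  mpath <- file.path(dir, "design.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
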