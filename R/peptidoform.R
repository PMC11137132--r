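# Peptidoform-level operations: delta-mass keying, isotopic-error handling,
# modification-state classification, count aggregation, protein coverage,
# peptide positions and delta-mass annotation.

# Spacing between isotope peaks (Da): mass difference 13C - 12C.
.ISOTOPE_SPACING <- 1.00335

# Monoisotopic residue masses (Da) of the 20 standard amino acids.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# round half away from zero to `digits` decimals
.round_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Build a peptidoform key from a peptide and a delta mass
#'
#' The delta mass is rounded to one decimal place (ties away from zero) and a
#' rounded `-0.0` is normalized to `+0.0`. The key is rendered as
#' `"<peptide>@<signed delta with one decimal>"`, e.g.
#' `"LVVVGAGGVGK@+58.0"`; the unmodified form is `"<peptide>@+0.0"`.
#'
#' @param peptide Uppercase amino-acid string(s).
#' @param delta_mass Signed delta mass(es) in Da.
#' @param localization Optional localization string(s) carried through.
#' @param digits Decimal places for the delta-mass bin (default 1).
#' @return Data frame with `peptide`, `delta_key` (numeric), `key` (the
#'   rendered identity string) and `localization`.
#' @export
make_peptidoform_key <- function(peptide, delta_mass, localization = "",
                                 digits = 1L) {
  stopifnot(all(grepl("^[A-Z]+$", peptide)), all(is.finite(delta_mass)))
  dk <- .round_away(delta_mass, digits)
  dk[dk == 0] <- 0  # -0.0 -> +0.0
  data.frame(peptide = peptide, delta_key = dk,
             key = paste0(peptide, "@", sprintf(paste0("%+.", digits, "f"), dk)),
             localization = rep_len(as.character(localization), length(peptide)),
             stringsAsFactors = FALSE)
}

#' Peptide part of a peptidoform key
#' @param key Character vector of `"<peptide>@<delta>"` keys.
#' @return Character vector of peptides.
#' @export
peptidoform_peptide <- function(key) sub("@.*$", "", key)

#' Delta-mass part of a peptidoform key
#' @param key Character vector of `"<peptide>@<delta>"` keys.
#' @return Numeric vector of rounded delta masses.
#' @export
peptidoform_delta <- function(key) as.numeric(sub("^.*@", "", key))

#' Is a delta mass an isotopic (monoisotopic-peak selection) error?
#'
#' True when the delta mass lies within `tolerance` of `k` times the isotope
#' spacing (1.00335 Da) for some integer `k` in `k_range`, including the
#' `k = 0` no-shift case.
#'
#' @param delta_mass Numeric vector of delta masses (Da).
#' @param tolerance Matching tolerance in Da (default 0.05).
#' @param k_range Integer isotope offsets considered (default -1..3).
#' @return Logical vector.
#' @export
is_isotopic_error <- function(delta_mass, tolerance = 0.05, k_range = -1:3) {
  stopifnot(tolerance > 0)
  ks <- unique(c(0L, as.integer(k_range)))
  Reduce(`|`, lapply(ks, function(k)
    abs(delta_mass - k * .ISOTOPE_SPACING) <= tolerance))
}

#' Classify the modification state of one peptide
#'
#' Delta keys that are isotopic errors (including +0.0) are collapsed into
#' the unmodified state first; the peptide is then `"unmodified"` when only
#' unmodified forms remain, `"modified"` when exactly one non-isotopic form
#' and no unmodified form was seen, and `"multiple"` otherwise.
#'
#' @param delta_keys Numeric vector of rounded delta masses observed for one
#'   peptide sequence.
#' @param tolerance,k_range Passed to [is_isotopic_error()].
#' @return One of `"unmodified"`, `"modified"`, `"multiple"`.
#' @export
classify_modification_state <- function(delta_keys, tolerance = 0.05,
                                        k_range = -1:3) {
  if (length(delta_keys) == 0L) stop("Empty peptidoform set", call. = FALSE)
  iso <- is_isotopic_error(delta_keys, tolerance, k_range)
  mods <- unique(delta_keys[!iso])
  has_unmod <- any(iso)
  if (length(mods) == 0L) return("unmodified")
  if (length(mods) == 1L && !has_unmod) return("modified")
  "multiple"
}

# does each record hit the bait? gene symbol match OR accession prefix match
# (P01116 matches P01116, P01116-2, ...)
.is_bait_record <- function(records, design) {
  acc_hit <- rep(FALSE, nrow(records))
  for (acc in design$bait_accessions) {
    acc_hit <- acc_hit | records$assigned_protein == acc |
      startsWith(records$assigned_protein, paste0(acc, "-"))
  }
  records$gene == design$bait_gene | acc_hit
}

#' Aggregate PSM records into a peptidoform-by-sample count matrix
#'
#' Each PSM contributes one count to the cell (peptidoform key, sample). At
#' `scope = "bait"` only PSMs whose gene symbol equals the bait gene or whose
#' assigned protein matches a bait accession (isoform suffixes included) are
#' counted; the matrix total then equals the number of in-scope PSMs.
#'
#' @param records A `psm_table` (possibly several samples bound together).
#' @param design An `experiment_design`; columns cover all design samples.
#' @param scope `"bait"` or `"all"`.
#' @param digits Delta-mass rounding decimals (default 1).
#' @return Numeric matrix, rows = peptidoform keys, columns = design sample
#'   ids, with attribute `scope`. Row order is lexicographic in the key.
#' @export
aggregate_counts <- function(records, design, scope = c("bait", "all"),
                             digits = 1L) {
  scope <- match.arg(scope)
  stopifnot(inherits(design, "experiment_design"))
  unknown <- setdiff(unique(records$sample_id), design$samples$sample_id)
  if (length(unknown) > 0L)
    stop("PSM sample id(s) not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (scope == "bait") records <- records[.is_bait_record(records, design), ,
                                          drop = FALSE]
  samples <- design$samples$sample_id
  if (nrow(records) == 0L) {
    warning("No PSMs in scope '", scope, "'; returning empty matrix",
            call. = FALSE)
    m <- matrix(0, nrow = 0L, ncol = length(samples),
                dimnames = list(NULL, samples))
    attr(m, "scope") <- scope
    return(m)
  }
  keys <- make_peptidoform_key(records$peptide, records$delta_mass,
                               digits = digits)$key
  tab <- table(factor(keys, levels = sort(unique(keys))),
               factor(records$sample_id, levels = samples))
  m <- matrix(as.numeric(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  attr(m, "scope") <- scope
  m
}

#' Protein sequence coverage of a gene's longest isoform
#'
#' Each distinct peptide is located by exact substring search against the
#' gene's longest isoform; every match contributes its residue positions
#' (1-based, inclusive). Peptides with no match contribute nothing and are
#' reported with a warning.
#'
#' @param peptides Character vector of peptide sequences (or a `psm_table`,
#'   from which distinct peptides are taken).
#' @param db A `protein_db`.
#' @param gene Gene symbol present in `db`.
#' @return List of class `coverage_result`: `gene`, `percent_coverage`
#'   (0-100), `covered_positions` (sorted integer vector), `isoform_length`,
#'   `unmatched` (peptides with no match).
#' @export
compute_coverage <- function(peptides, db, gene) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(peptides)
  iso <- longest_isoform(db, gene)
  len <- nchar(iso)
  covered <- logical(len)
  unmatched <- character(0L)
  for (p in peptides) {
    hits <- gregexpr(p, iso, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) { unmatched <- c(unmatched, p); next }
    for (st in hits) covered[st:(st + nchar(p) - 1L)] <- TRUE
  }
  if (length(unmatched) > 0L)
    warning(length(unmatched), " peptide(s) did not match the ", gene,
            " longest isoform and were ignored", call. = FALSE)
  structure(list(gene = gene,
                 percent_coverage = 100 * sum(covered) / len,
                 covered_positions = which(covered),
                 isoform_length = len,
                 unmatched = unmatched),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("%s coverage: %.1f%% (%d/%d residues of the longest isoform)\n",
              x$gene, x$percent_coverage, length(x$covered_positions),
              x$isoform_length))
  invisible(x)
}

#' Relative positions of peptides on a gene's longest isoform
#'
#' The first exact match of each peptide provides the plotting coordinate;
#' `relative_midpoint = ((start + end) / 2) / isoform_length`. Peptides with
#' no match are omitted with a warning.
#'
#' @inheritParams compute_coverage
#' @return Data frame with `peptide`, `start`, `end`, `relative_midpoint`.
#' @export
peptide_relative_positions <- function(peptides, db, gene) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(peptides)
  iso <- longest_isoform(db, gene)
  len <- nchar(iso)
  st <- vapply(peptides, function(p) regexpr(p, iso, fixed = TRUE)[[1L]],
               integer(1L), USE.NAMES = FALSE)
  miss <- st == -1L
  if (any(miss)) warning(sum(miss), " peptide(s) did not match the ", gene,
                         " longest isoform and were omitted", call. = FALSE)
  peptides <- peptides[!miss]; st <- st[!miss]
  en <- st + nchar(peptides) - 1L
  data.frame(peptide = peptides, start = st, end = en,
             relative_midpoint = ((st + en) / 2) / len,
             stringsAsFactors = FALSE)
}

#' Built-in known-modification table
#'
#' Shipped as a TSV resource (`extdata/known_mods.tsv`): name, monoisotopic
#' mass, residue specificity (comma-separated letters and/or `N-term`),
#' provenance. Users may extend it by row-binding their own entries.
#'
#' @return Data frame with `name`, `mono_mass`, `residues`, `provenance`.
#' @export
known_modifications <- function() {
  path <- system.file("extdata", "known_mods.tsv", package = "baitform",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Amino-acid substitution mass table
#'
#' All ordered pairs of distinct standard residues with the mass difference
#' `mass(to) - mass(from)`, generated from the 20 monoisotopic residue
#' masses.
#'
#' @return Data frame with `from`, `to`, `mass_diff`.
#' @export
substitution_table <- function() {
  aa <- names(.RESIDUE_MASS)
  grid <- expand.grid(from = aa, to = aa, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  grid$mass_diff <- .RESIDUE_MASS[grid$to] - .RESIDUE_MASS[grid$from]
  rownames(grid) <- NULL
  grid
}

#' Annotate a delta mass with candidate explanations
#'
#' Candidates are named modifications and single amino-acid substitutions
#' whose mass lies within `tolerance` of the delta, evaluated both directly
#' and after adding back the mass of any fixed modification whose residue
#' specificity matches the localized residue (the "displaces fixed mod"
#' route, e.g. cysteic acid under fixed carbamidomethyl reporting -9.04 Da).
#' Isotopic errors (including 0.0, reported as `"unmodified"`) are annotated
#' as such. Residue-specific candidates only match when the localized
#' residue is unknown or agrees with the specificity.
#'
#' @param delta_key Rounded delta mass (Da), scalar.
#' @param localized_residue One uppercase letter, `"N-term"`, or `NA` when
#'   the shift is not localized.
#' @param fixed_mods Data frame of fixed modifications in the search
#'   (defaults to carbamidomethyl-C from [known_modifications()]).
#' @param known_mods Candidate modification table (default
#'   [known_modifications()]).
#' @param tolerance Matching tolerance in Da (default 0.05).
#' @return Data frame with `annotation`, `candidate_mass`, `type` (one of
#'   `unmodified`, `isotopic_error`, `modification`, `substitution`),
#'   `displaces_fixed` (name of the displaced fixed mod or `NA`). Zero rows
#'   when nothing matches.
#' @export
annotate_delta_mass <- function(delta_key, localized_residue = NA,
                                fixed_mods = NULL,
                                known_mods = known_modifications(),
                                tolerance = 0.05) {
  stopifnot(tolerance > 0, length(delta_key) == 1L, is.finite(delta_key))
  if (is.null(fixed_mods))
    fixed_mods <- known_mods[known_mods$name == "carbamidomethyl", ,
                             drop = FALSE]
  res <- if (is.na(localized_residue)) NA_character_
         else as.character(localized_residue)
  hit <- function(annotation, mass, type, displaces = NA_character_)
    data.frame(annotation = annotation, candidate_mass = mass, type = type,
               displaces_fixed = displaces, stringsAsFactors = FALSE)
  out <- list()

  if (abs(delta_key) <= tolerance) {
    out[[length(out) + 1L]] <- hit("unmodified", 0, "unmodified")
  } else if (is_isotopic_error(delta_key, tolerance)) {
    k <- round(delta_key / .ISOTOPE_SPACING)
    out[[length(out) + 1L]] <- hit(sprintf("isotopic error (%+d Da)", k),
                                   k * .ISOTOPE_SPACING, "isotopic_error")
  }

  res_ok <- function(residues) {
    is.na(res) || res %in% strsplit(residues, ",", fixed = TRUE)[[1L]]
  }
  # effective deltas: direct, and with each matching fixed mod added back
  routes <- data.frame(shift = 0, displaces = NA_character_,
                       stringsAsFactors = FALSE)
  if (nrow(fixed_mods) > 0L) {
    for (i in seq_len(nrow(fixed_mods))) {
      if (!is.na(res) && res %in% strsplit(fixed_mods$residues[i], ",")[[1L]]) {
        routes <- rbind(routes, data.frame(shift = fixed_mods$mono_mass[i],
                                           displaces = fixed_mods$name[i]))
      }
    }
  }
  subs <- substitution_table()
  for (r in seq_len(nrow(routes))) {
    eff <- delta_key + routes$shift[r]
    disp <- routes$displaces[r]
    km <- known_mods[abs(eff - known_mods$mono_mass) <= tolerance, ,
                     drop = FALSE]
    for (i in seq_len(nrow(km))) {
      if (!res_ok(km$residues[i])) next
      if (!is.na(disp) && km$name[i] == disp) next  # fixed mod explaining itself
      out[[length(out) + 1L]] <- hit(km$name[i], km$mono_mass[i],
                                     "modification", disp)
    }
    sb <- subs[abs(eff - subs$mass_diff) <= tolerance, , drop = FALSE]
    for (i in seq_len(nrow(sb))) {
      if (!is.na(res) && res != "N-term" && res != sb$from[i]) next
      if (identical(res, "N-term")) next  # substitutions are residue events
      out[[length(out) + 1L]] <- hit(paste0(sb$from[i], "->", sb$to[i]),
                                     sb$mass_diff[i], "substitution", disp)
    }
  }
  if (length(out) == 0L)
    return(data.frame(annotation = character(0), candidate_mass = numeric(0),
                      type = character(0), displaces_fixed = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[c("annotation", "displaces_fixed")]), ,
             drop = FALSE]
  # stable, table-order-independent ordering: by |mass error| then name
  out <- out[order(abs(delta_key +
                         ifelse(is.na(out$displaces_fixed), 0,
                                fixed_mods$mono_mass[match(out$displaces_fixed,
                                                           fixed_mods$name)]) -
                         out$candidate_mass),
                   out$annotation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample bait vs prey enrichment summary
#'
#' Summarizes an all-protein PSM table into, per sample, the total bait PSM
#' count and the distribution of per-protein PSM totals for non-bait
#' proteins.
#'
#' @param records A `psm_table` covering all proteins.
#' @param design An `experiment_design`.
#' @return Named list (one entry per design sample) of lists with
#'   `bait_psm_count` and `prey_counts` (named numeric vector, one entry per
#'   prey protein observed in that sample).
#' @export
summarize_enrichment <- function(records, design) {
  bait <- .is_bait_record(records, design)
  out <- lapply(design$samples$sample_id, function(s) {
    in_s <- records$sample_id == s
    prey <- records[in_s & !bait, , drop = FALSE]
    prey_counts <- if (nrow(prey) > 0L) {
      tab <- table(prey$assigned_protein)
      stats::setNames(as.numeric(tab), names(tab))
    } else stats::setNames(numeric(0L), character(0L))
    list(bait_psm_count = sum(in_s & bait), prey_counts = prey_counts)
  })
  stats::setNames(out, design$samples$sample_id)
}
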