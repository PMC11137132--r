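# Fixtures built in code: tiny FragPipe-dialect PSM tables, FASTA files and
# designs used across the unit tests.

write_psm_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  # rows: data.frame with any of the FragPipe column names; missing
  # mandatory columns are filled with defaults
  n <- nrow(rows)
  defaults <- data.frame(
    Spectrum = sprintf("spec.%02d", seq_len(n)),
    Peptide = rep_len("PEPTIDEK", n), `Delta Mass` = rep_len(0, n),
    Protein = rep_len("P00001", n), Gene = rep_len("GENE1", n),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_fasta_fixture <- function(entries, path = tempfile(fileext = ".fasta")) {
  # entries: named list gene -> character vector of sequences (isoforms);
  # accessions are ACC_<gene>_<i>
  lines <- unlist(lapply(names(entries), function(g) {
    seqs <- entries[[g]]
    unlist(lapply(seq_along(seqs), function(i)
      c(sprintf(">sp|ACC%s%d|%s_TEST GN=%s", g, i, g, g), seqs[i])))
  }))
  writeLines(lines, path)
  path
}

make_design <- function(n_test = 2, n_control = 2, bait_gene = "BAIT",
                        bait_accessions = "B0001") {
  experiment_design(
    samples = data.frame(
      sample_id = c(paste0("c", seq_len(n_control)), paste0("t", seq_len(n_test))),
      condition = c(rep("control", n_control), rep("test", n_test)),
      stringsAsFactors = FALSE),
    bait_gene = bait_gene, bait_accessions = bait_accessions)
}

make_psm <- function(sample_id, peptide, delta_mass, protein = "B0001",
                     gene = "BAIT", localization = "") {
  n <- max(length(sample_id), length(peptide), length(delta_mass))
  out <- data.frame(
    spectrum_id = sprintf("s.%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    peptide = rep_len(peptide, n),
    modified_peptide = "",
    delta_mass = rep_len(delta_mass, n),
    assigned_protein = rep_len(protein, n),
    gene = rep_len(gene, n),
    mapped_proteins = "", localization = rep_len(localization, n),
    observed_modifications = "", intensity = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("psm_table", class(out))
  out
}

# count matrix helper: rows named by key, columns by sample
make_counts <- function(values, keys, samples) {
  matrix(values, nrow = length(keys), ncol = length(samples),
         dimnames = list(keys, samples))
}
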