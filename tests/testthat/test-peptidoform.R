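test_that("make_peptidoform_key rounds to one decimal, ties away from zero", {
  expect_equal(make_peptidoform_key("LVVVGAGGVGK", 58.0055)$key,
               "LVVVGAGGVGK@+58.0")
  expect_equal(make_peptidoform_key("PEPTIDE", 0)$key, "PEPTIDE@+0.0")
  # -0.04 rounds to -0.0, normalized to +0.0
  expect_equal(make_peptidoform_key("PEPTIDE", -0.04)$key, "PEPTIDE@+0.0")
  # ties away from zero on the 0.05 boundary, both signs
  expect_equal(make_peptidoform_key("PEP", 0.05)$delta_key, 0.1)
  expect_equal(make_peptidoform_key("PEP", -0.05)$delta_key, -0.1)
  expect_equal(make_peptidoform_key("PEP", -9.0368)$key, "PEP@-9.0")
  expect_equal(make_peptidoform_key("PEP", 43.0058)$key, "PEP@+43.0")
})

test_that("keys are stable under sub-bin jitter away from bin boundaries", {
  set.seed(5)
  for (m in c(0.2, 1.0, 15.99, 58.01, -9.04, -25.03)) {
    base <- make_peptidoform_key("PEP", m)$key
    for (eps in runif(20, -0.04, 0.04)) {
      # only assert when m is at least 0.05 from a bin boundary after jitter
      if (abs((m + eps) * 10 - round((m + eps) * 10)) < 0.499 &&
          round((m + eps) * 10) == round(m * 10))
        expect_equal(make_peptidoform_key("PEP", m + eps)$key, base)
    }
  }
})

test_that("peptidoform key accessors invert the key", {
  k <- make_peptidoform_key(c("AAK", "CCK"), c(58.0055, -9.04))$key
  expect_equal(peptidoform_peptide(k), c("AAK", "CCK"))
  expect_equal(peptidoform_delta(k), c(58.0, -9.0))
})

test_that("is_isotopic_error matches integer multiples of 1.00335 Da", {
  expect_true(is_isotopic_error(1.0033))
  expect_true(is_isotopic_error(0))
  expect_true(is_isotopic_error(-1.0))
  expect_true(is_isotopic_error(2.0067))
  expect_true(is_isotopic_error(3.01))
  expect_false(is_isotopic_error(58.0055))
  expect_false(is_isotopic_error(0.5))
  expect_false(is_isotopic_error(4.0134))        # k = 4 outside default range
  expect_true(is_isotopic_error(4.0134, k_range = -1:4))
})

test_that("classify_modification_state collapses isotopic errors first", {
  expect_equal(classify_modification_state(0), "unmodified")
  expect_equal(classify_modification_state(c(0, 43.0, 58.0)), "multiple")
  expect_equal(classify_modification_state(1.0), "unmodified")
  expect_equal(classify_modification_state(c(0, 1.0, 2.0)), "unmodified")
  expect_equal(classify_modification_state(15.99), "modified")
  expect_equal(classify_modification_state(c(16.0, 16.0)), "modified")
  expect_equal(classify_modification_state(c(0, 15.99)), "multiple")
  expect_error(classify_modification_state(numeric(0)), "Empty")
  # order invariance
  set.seed(2)
  v <- c(0, 1.0, 43.0, 58.0, 15.99)
  for (i in 1:10)
    expect_equal(classify_modification_state(sample(v)),
                 classify_modification_state(v))
})

test_that("aggregate_counts counts PSMs per peptidoform per sample", {
  design <- make_design(n_test = 1, n_control = 1)
  recs <- make_psm("c1", "PEPTIDEK", rep(0, 5))
  m <- aggregate_counts(recs, design, scope = "bait")
  expect_equal(unname(m["PEPTIDEK@+0.0", "c1"]), 5)
  expect_equal(ncol(m), 2L)  # all design samples present as columns
  expect_equal(unname(m["PEPTIDEK@+0.0", "t1"]), 0)
})

test_that("aggregate_counts bait scope matches gene or accession prefix", {
  design <- make_design(bait_gene = "KRAS", bait_accessions = "P01116")
  recs <- rbind(
    make_psm("c1", "AAAAAAAK", 0, protein = "P01116", gene = "KRAS"),
    make_psm("c1", "CCCCCCCK", 0, protein = "P01116-2", gene = ""),
    make_psm("c1", "DDDDDDDK", 0, protein = "Q99999", gene = "KRAS"),
    make_psm("c1", "EEEEEEEK", 0, protein = "P88888", gene = "PREY1"))
  m <- aggregate_counts(recs, design, scope = "bait")
  expect_equal(sum(m), 3)                    # isoform suffix + gene matches
  expect_false("EEEEEEEK@+0.0" %in% rownames(m))
  # conservation: matrix total equals in-scope record count
  m_all <- suppressWarnings(aggregate_counts(recs, design, scope = "all"))
  expect_equal(sum(m_all), nrow(recs))
})

test_that("aggregate_counts warns on empty scope and rejects foreign samples", {
  design <- make_design()
  prey_only <- make_psm("c1", "EEEEEEEK", 0, protein = "X1", gene = "PREY")
  expect_warning(m <- aggregate_counts(prey_only, design, scope = "bait"),
                 "No PSMs")
  expect_equal(nrow(m), 0L)
  foreign <- make_psm("nope", "EEEEEEEK", 0)
  expect_error(aggregate_counts(foreign, design), "not in design")
})

test_that("compute_coverage measures residues of the longest isoform", {
  db <- protein_db("A1", "G1", strrep("ACDEFGHIKL", 1))  # length 10
  cov <- compute_coverage("ACDEF", db, "G1")
  expect_equal(cov$percent_coverage, 50)
  expect_equal(cov$covered_positions, 1:5)

  # full-length peptide -> exactly 100
  cov_full <- compute_coverage("ACDEFGHIKL", db, "G1")
  expect_equal(cov_full$percent_coverage, 100)

  # non-matching peptide -> zero coverage with warning
  expect_warning(cov0 <- compute_coverage("WWWWW", db, "G1"), "did not match")
  expect_equal(cov0$percent_coverage, 0)

  # repeated substring: all matches count, positions stay a set
  db2 <- protein_db("A2", "G2", "AAKAAKAAK")
  cov2 <- compute_coverage("AAK", db2, "G2")
  expect_equal(cov2$percent_coverage, 100)
  expect_error(compute_coverage("AAK", db2, "NOPE"), "not found")
})

test_that("peptide_relative_positions uses the first match midpoint", {
  db <- protein_db("A1", "G1", paste0("LVVVGAGGVGK", strrep("A", 178)))  # 189
  pos <- peptide_relative_positions("LVVVGAGGVGK", db, "G1")
  expect_equal(pos$start, 1L)
  expect_equal(pos$end, 11L)
  expect_equal(pos$relative_midpoint, ((1 + 11) / 2) / 189)

  # whole-protein peptide: midpoint (1 + L)/2 / L, i.e. 0.5 + 1/(2L)
  db2 <- protein_db("A2", "G2", "ACDEFGHIKL")
  expect_equal(peptide_relative_positions("ACDEFGHIKL", db2, "G2")$relative_midpoint,
               ((1 + 10) / 2) / 10)
  expect_warning(
    out <- peptide_relative_positions(c("ACDEF", "WWWWW"), db2, "G2"),
    "omitted")
  expect_equal(nrow(out), 1L)
})

test_that("annotate_delta_mass reproduces the worked examples", {
  # cysteic acid displacing fixed carbamidomethyl on C
  a <- annotate_delta_mass(-9.0, "C")
  expect_true(any(a$annotation == "cysteic_acid" &
                    a$displaces_fixed == "carbamidomethyl"))
  # sulfinic acid at -25 on C
  b <- annotate_delta_mass(-25.0, "C")
  expect_true(any(b$annotation == "sulfinic_acid" &
                    b$displaces_fixed == "carbamidomethyl"))
  # Gly -> Asp substitution at +58 localized on G
  c_ <- annotate_delta_mass(58.0, "G")
  expect_true(any(c_$annotation == "G->D" & c_$type == "substitution"))
  # N-terminal carbamylation at +43
  d <- annotate_delta_mass(43.0, "N-term")
  expect_equal(d$annotation, "carbamylation")
  # zero always contains "unmodified"; isotopic errors annotated as such
  expect_true("unmodified" %in% annotate_delta_mass(0)$annotation)
  expect_true(any(annotate_delta_mass(1.0)$type == "isotopic_error"))
  # nothing within tolerance -> empty
  expect_equal(nrow(annotate_delta_mass(500.123)), 0L)
})

test_that("annotation respects residue specificity and table order", {
  # +58 on a residue that is not G must not claim G->D
  a <- annotate_delta_mass(58.0, "A")
  expect_false(any(a$annotation == "G->D"))
  # order of candidate table rows does not change the result set
  km <- known_modifications()
  ann1 <- annotate_delta_mass(-9.0, "C", known_mods = km)
  ann2 <- annotate_delta_mass(-9.0, "C", known_mods = km[rev(seq_len(nrow(km))), ])
  expect_equal(ann1, ann2)
})

test_that("summarize_enrichment separates bait dots from prey distribution", {
  design <- make_design(n_test = 0 + 1, n_control = 1)
  recs <- rbind(
    make_psm("c1", "AAAAAAAK", rep(0, 100)),                       # bait
    make_psm("c1", "CCCCCCCK", rep(0, 5), protein = "X1", gene = "P1"),
    make_psm("c1", "DDDDDDDK", rep(0, 5), protein = "X2", gene = "P2"),
    make_psm("c1", "EEEEEEEK", rep(0, 5), protein = "X3", gene = "P3"))
  s <- summarize_enrichment(recs, design)
  expect_equal(s$c1$bait_psm_count, 100)
  expect_equal(unname(s$c1$prey_counts), c(5, 5, 5))
  expect_equal(s$t1$bait_psm_count, 0)
  expect_length(s$t1$prey_counts, 0)
})

test_that("substitution table covers all ordered pairs of distinct residues", {
  st <- substitution_table()
  expect_equal(nrow(st), 20 * 19)
  expect_equal(st$mass_diff[st$from == "G" & st$to == "D"], 58.00548,
               tolerance = 1e-6)
  # antisymmetry
  expect_equal(st$mass_diff[st$from == "D" & st$to == "G"],
               -st$mass_diff[st$from == "G" & st$to == "D"])
})
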