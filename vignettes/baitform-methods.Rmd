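---
title: "Methods: differential bait peptidoforms from IP-MS open search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential bait peptidoforms from IP-MS open search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitform)
```

## The problem

Classical immunoprecipitation mass spectrometry (IP-MS) asks how the
*interactome* of a bait protein changes between conditions, and treats the
bait's own peptide-spectrum matches (PSMs) as a nuisance. baitform inverts
this: because antibody capture enriches the bait enormously, the bait's
peptides are observed at high, reproducible spectral counts, and an open
database search (wide precursor tolerance) attaches to each PSM a **delta
mass** — observed minus theoretical monoisotopic peptide mass. Point
mutations, chemical artifacts and post-translational modifications all
surface as delta-mass populations on bait peptides. Comparing the abundance
of these *peptidoforms* between conditions reveals condition-specific
protein states (a G→D substitution at +58.01 Da, N-terminal carbamylation
at +43.01 Da, cysteine oxidation states, a phosphosite at +79.97 Da, ...).

## The model and procedure

1. **Peptidoform identity.** Each PSM is keyed by
   `peptide @ delta mass rounded to one decimal` (ties away from zero;
   `-0.0` normalized to `+0.0`), e.g. `LVVVGAGGVGK@+58.0`. One decimal
   keeps isotope clusters (spaced 1.00335 Da) separable while absorbing the
   sub-0.05 Da measurement scatter of well-calibrated instruments. Where
   figure labels in the literature print integers ("+58", "+43") we regard
   that as display rounding only.
2. **Singleton filter.** Peptidoforms supported by exactly one PSM in the
   whole dataset are removed, on **raw** counts. The criterion is defined on
   raw PSM evidence; running it after normalization would let scale factors
   move totals across the threshold, so the order filter-then-normalize is
   fixed and asserted by a test.
3. **Normalization.** Within each comparison, every sample's bait counts
   are scaled by `min(totals)/total(sample)`, so all samples carry the bait
   PSM mass of the shallowest sample. This removes bait-enrichment
   differences (the dominant nuisance in IP-MS) while preserving
   within-sample proportions. For clustering, which looks across *all*
   samples, the same rule is applied with the global minimum; for scoring
   it is applied per comparison. The distinction is logged at run time.
4. **Scoring.** The spectral-count triple (interaction/prey/bait files,
   peptidoforms in the prey role) can be handed to an external SAINTexpress
   binary. Because that binary is not redistributable, the package ships a
   documented surrogate with the same output shape: per peptidoform, a
   two-component Poisson model with background rate
   `lambda0 = mean(control) + alpha` and enriched rate
   `lambda1 = max(mean(test) + alpha, lambda0)` (pseudocount
   `alpha = 0.1`, prior `pi = 0.5`). Each test replicate's count yields a
   posterior probability of the enriched component; their mean is **AvgP**.
   Normalized counts are fractional, so the continuous Poisson density
   (gamma-function factorial) is used. Flooring `lambda1` at `lambda0`
   makes each orientation an *enrichment-only* test; depletion is found by
   scoring the reversed comparison, which is done by default — mirroring
   how a mutation swap shows up as the unmodified form "up in control" and
   the mutant form "up in test".
5. **BFDR.** Down the AvgP-descending ranking, the Bayesian FDR at rank
   *k* is the cumulative mean of `1 - AvgP`; ties share the larger rank's
   value, and the cumulative construction makes it non-decreasing.
   Significance is `BFDR < 0.05`, strict.
6. **Descriptors.** Coverage is the percentage of residues of the gene's
   longest isoform (ties broken lexicographically by accession) hit by any
   exact peptide match — all match positions count, positions form a set so
   over-counting is impossible. Peptide map coordinates use the first match:
   `((start + end)/2) / length`. Delta-mass annotation searches named
   modifications plus all 380 ordered single-residue substitutions, both
   directly and after adding back a fixed modification whose specificity
   matches the localized residue — this explains the classic negative
   shifts, e.g. cysteic acid under fixed carbamidomethyl reporting
   −9.04 Da.
7. **Clustering.** Abundant peptidoforms (dataset total ≥ 10, detected in
   ≥ 2 samples) are log2-transformed with zeros kept at 0 (the convention
   used here for "not detected"; note `log2(1) = 0` collides with it,
   which the singleton filter mostly removes upstream), then clustered with
   Euclidean distance and complete linkage on rows and columns — the
   `pheatmap` defaults. Sample clusters cut at k = number of conditions are
   compared to the condition labels by majority vote (ties toward the
   larger condition, then lexicographic).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| delta-mass rounding | 1 decimal | Da | separates isotope peaks, absorbs scatter |
| isotope spacing | 1.00335, k ∈ −1..3 | Da | monoisotopic mis-selection range |
| isotope / annotation tolerance | 0.05 | Da | half a rounding bin |
| pseudocount `alpha` | 0.1 | counts | keeps rates positive at zero counts |
| prior `pi` | 0.5 | — | symmetric two-component prior |
| BFDR threshold | 0.05 | — | strict `<` |
| abundance filter | total ≥ 10 in ≥ 2 samples | counts | quantifies "highly abundant", which has no standard numeric definition |

All of these are arguments with the defaults above, and every default in
force is echoed into the run log for auditability.

## What the synthetic generator emulates — and does not

`generate_dataset()` digests a **synthetic** 186-residue Ras-like bait in
silico (cleave after K/R, not before P, peptide length 7–30), assigns each
peptidoform a Poisson rate (baseline 10 PSMs per unmodified peptide per
sample — typical for a well-enriched bait — with a delta-mass menu of
isotopic errors, N-terminal carbamylation, Met oxidation and a
fixed-mod-displacement negative on Cys), multiplies by condition effects
and log-normal sample depth (sd 0.2), and emits FragPipe-dialect tables
with ±0.01 Da sub-bin delta jitter so the rounding operator is exercised
without bin crossings. Prey background is 300 proteins with
gamma-distributed rates (mean 3), putting the bait far above the prey
median as in real pulldowns. `generate_mutation_scenario()` moves the
unmodified rate mass of `LVVVGAGGVGK` to a +58.0055 Da (Gly→Asp) form in
the mutant condition, localized on the substituted glycine.

The generator does **not** emulate: search-engine FDR and decoys, chimeric
spectra, razor-peptide ambiguity, retention-time or intensity structure,
missed cleavages, or batch effects. A green test on synthetic data
therefore establishes the *statistical pipeline's* correctness and
calibration, not the behavior of any search engine upstream.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero (R's `round()` is banker's rounding and
  would split the 0.05 boundary inconsistently); the same rule integerizes
  counts at the external SAINT interface only — internal scoring keeps
  fractional counts.
* A sample with zero bait PSMs makes its comparison impossible and is a
  named error, not a silent drop.
* Empty peptidoform sets, header-only PSM files, all-singleton matrices
  and absent preys are handled explicitly (empty results plus warnings).
* Clustering is deterministic given input order; the flat partition is
  invariant to sample/feature permutation on tie-free data.
* `longest_isoform` breaks length ties lexicographically by accession so
  coverage is reproducible across FASTA orderings.

## Open design points resolved here

* **Scoring backend.** SAINTexpress internals are not reimplemented; the
  external interface is faithful (file triple, integer counts, T/C labels,
  pass-through options) and the surrogate is documented above. The two
  never stand in for each other in tests.
* **Clustering normalization scope.** Global minimum for clustering,
  per-comparison minima for scoring (both logged), since clustering spans
  samples that belong to no single comparison.
* **Relative-midpoint convention.** `((start + end)/2)/length` in 1-based
  residue coordinates; a full-length peptide maps to `0.5 + 1/(2L)`, not
  exactly 0.5.

## Known limitations

Intensity-based normalization and the intensity SAINT model are out of
scope (spectral counting degrades when bait enrichment differs drastically
between conditions). Localization strings are propagated from upstream,
never re-inferred. Combinatorial multi-modification delta masses are
reported but rarely annotatable from a single-shift table. The 15-of-16
style clustering agreement on published pulldown datasets is not asserted
anywhere: the original feature-selection thresholds are unknown, so only
the qualitative construction (perfect separation on condition-disjoint
synthetic support) is tested.
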