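# metatrio

Stratified somatic variant analysis of matched normal / primary-tumor /
metastasis ("trio") whole-genome data.

When a primary tumor and its metastasis are sequenced against the same
matched normal, the somatic SNVs split into three strata — truncal
(shared), tumor-private and metastasis-private — whose proportions and
mutational signatures describe when mutagenic processes acted during
progression. Two artifacts bias a naive split: a clonal variant may be
called in only one sample of the pair because purity and ploidy differ
(inflating the private strata), and tumor DNA contaminating the matched
normal makes true somatic variants look germline (deleting them
entirely). `metatrio` corrects both and runs the downstream stratified
analyses:

* **MAF cross-rescue stratification** — a variant called somatic in one
  sample of the pair is counted present in the other when its mutant
  allele fraction there is above 5%, carried by at least 2 reads, and at
  least twice the matched-control MAF; presence pairs map to
  shared / tumor-private / metastasis-private.
* **Tumor-in-normal rescue (TiNDA)** — control-BAF vs sample-BAF points
  are clustered (9-component binomial-mixture EM, single pass); clusters
  with ≥ 75% of points above the identity line, centroid sample MAF > 1%
  and centroid control MAF < 45% are tumor-in-normal, and their
  germline-labelled members are reclassified as somatic.
* **Mutational signatures** — 96-context catalogs per stratum, decomposed
  by non-negative least squares `e = argmin_{e≥0} ‖C − W·e‖₂` against a
  signature matrix, with signature-specific cutoffs, cohort-level
  signature detection, paired Wilcoxon strata comparisons (BH-corrected),
  hierarchical exposure clustering, and covariate associations.
* **Kataegis** — clusters of ≥ 5 mutations within 10 kb, merged into
  maximal loci, annotated with genes within 10 kb, with cross-sample
  recurrent regions.
* **Copy number** — gain/loss when a segment's total copy number deviates
  more than 0.7 from the sample base ploidy (strict), LOH when the minor
  allele copy number is below 0.5, and arm-level recurrence proportions
  across the cohort.
* **Cohort statistics** — per-channel gene × sample mutation matrices
  (coding non-silent / ncRNA / 3′-UTR), recurrent genes,
  mutual-exclusivity calls with two-sided Fisher exact tests,
  chi-square tests, Benjamini-Hochberg correction and hypergeometric
  gene-set enrichment.
* **Synthetic cohorts** — a generator that emulates a 12-patient
  colorectal trio cohort (purity 0.35–0.85, ploidy 2–3, 36× coverage,
  5,000–17,000 SNVs per patient, 65/15/20% strata, 5% tumor-in-normal
  contamination) with full truth labels, so every stage is testable
  without access to controlled data.

## Worked example

```r
library(metatrio)

W <- synthetic_signature_matrix(12, seed = 1)
cfg <- crc_cohort_configs(n_patients = 1, n_snvs = 10000,
                            signature_ids = W$signature_ids, seed = 1)[[1]]
sim <- generate_trio(cfg, W)
sim$trio
#> Trio dataset: SIM-001
#>   12000 aligned call positions (7735 caller-somatic in tumor, 8145 in
#>   metastasis, 2327 germline-labelled)
#>   purity 0.59/0.65, ploidy 2/3 (tumor/metastasis), coverage 36x

tin <- apply_tinda(sim$trio, seed = 1)   # tumor-in-normal rescue
nrow(tin$audit)
#> [1] 326

st <- stratify_trio(tin$trio)            # MAF cross-rescue stratification
st
#> Stratified somatic catalog: SIM-001
#>   9998 somatic SNVs: 65.4% shared, 15.3% tumor-private,
#>   19.4% metastasis-private

shared <- st$calls[st$calls$stratum == "shared" & st$calls$is_snv, ]
fit <- apply_signature_cutoffs(build_catalog(shared), W, 0.06)
fit
#> Signature exposures (3 active, residual 70.15)
#>     S4     S7     S9
#> 0.3899 0.1885 0.4216
```

The trio was generated with 65/15/20% strata and truncal exposures
(S4 = 0.399, S7 = 0.185, S9 = 0.416); after contamination rescue (326 of
the 327 contaminated variants recovered), stratification and decomposition
recover both within sampling error.

An end-to-end run over a cohort directory — TiNDA, stratification,
signatures, kataegis, copy number, recurrence, mutual exclusivity — is
`run_pipeline(data_dir, out_dir)`, which writes TSV tables, a run log and
a deterministic `summary.json`. `simulate_command(dir)` writes a synthetic
cohort in the expected layout, and `inst/cli/metatrio.R` wraps simulate /
run / validate for shell use.

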