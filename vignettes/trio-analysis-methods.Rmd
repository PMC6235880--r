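---
title: "Methods: stratified somatic analysis of tumor-metastasis trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified somatic analysis of tumor-metastasis trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatrio)
```

## The problem

In a matched trio — normal tissue, primary tumor, and a metastasis from the
same patient — the somatic single-nucleotide variants (SNVs) partition into
three strata: *truncal* (shared) mutations acquired before the metastatic
lineage separated, *tumor-private* mutations, and *metastasis-private*
mutations. The stratum proportions, and the mutational signatures active
within each stratum, describe when mutagenic processes operated during
disease progression. Two systematic artifacts corrupt a naive partition:

1. **Differential detection power.** Tumor and metastasis differ in purity
   (tumor cell content) and ploidy, so a clonal variant can be confidently
   called in one sample and missed in the other, inflating the private
   strata.
2. **Tumor-in-normal contamination.** Tumor-derived DNA in the matched
   normal puts alternate reads under true somatic variants, which makes the
   upstream caller label them germline and silently deletes them from the
   somatic set.

`metatrio` implements the corrections for both artifacts, the downstream
stratified analyses (signature decomposition, kataegis, copy-number states
and recurrence, cohort statistics), and a synthetic-data generator with
known truth labels against which every stage is validated.

## MAF cross-rescue stratification

For a variant called somatic in one sample of the tumor/metastasis pair,
presence in the *other* sample is granted when, in that sample,

* the mutant allele fraction (MAF, alternate reads over depth) exceeds 5%
  (strictly), **and**
* at least 2 alternate reads support it, **and**
* its MAF is at least twice the MAF at the same position in the matched
  normal (a control MAF of zero satisfies the ratio — the rule's intent is
  to exclude germline leakage, and any positive MAF is at least twice 0).

Presence by direct somatic call is always retained; the presence pair then
maps (both → shared, tumor only → tumor-private, metastasis only →
metastasis-private). Fractions are reported over the union of somatic SNVs;
indels are stratified under the same rules but flagged as an extension and
excluded from the fractions.

The fixed 2-read floor is motivated by expected read support: at the cohort
medians — purity 0.475, coverage 36x, ploidy 3 — a single-copy clonal
variant is expected on `expected_read_support(0.475, 36, 3) = 5.7` mutant
reads, and under a Poisson model with that mean, 2-read support is well
inside the bulk of the distribution. `poisson_support_probability()`
returns the standard Poisson point mass; note that at k = 2, mu = 5.7 it
evaluates to 0.054. The floor is a fixed constant, not recomputed per
sample; `min_alt_reads_for_maf()` is provided as a diagnostic for what the
5% threshold alone would imply at a given coverage.

## Tumor-in-normal rescue (TiNDA)

For each of the tumor and the metastasis, every mutated position of the
pair (minus known common variants, which are overwhelmingly germline) is
placed on the plane of control BAF versus sample BAF. True somatic variants
sit on the left edge (control BAF near 0); contaminated somatic variants
sit slightly right of it (control BAF roughly 0.01–0.15); germline
heterozygous sites form a blob at (0.5, 0.5). Clusters are called
tumor-in-normal when at least 75% of their points lie strictly above the
identity line, the centroid sample MAF exceeds 1%, and the centroid control
MAF is below 45%. Germline-labelled members of qualifying clusters are
reclassified as somatic; somatic calls are never demoted. The two bounds
are applied to cluster centroids (they are phrased as cluster-level
properties); both the bounds and their per-centroid application are
configurable.

**Choice of clusterer.** The clustering is a nine-component binomial
mixture fitted by a single EM pass (k-means++ seeding, 100 iterations, no
model selection over the component count): each component has a control-BAF
and a sample-BAF mean, and a point's likelihood is the product of the two
binomial likelihoods of its read counts. We deliberately do not use a hard
spatial partition (k-means). A hard partition slices the germline
heterozygous blob into spatial halves, and the half above the identity
line then satisfies all three rescue rules with a control centroid just
under 0.45 — in our synthetic validation this mislabelled roughly half of
the germline het sites as rescued. Mixture components, by contrast, share
a homogeneous cloud instead of slicing it. Because binomial mixtures with
coinciding means are not identifiable, EM can still leave one cloud
covered by near-duplicate components; we therefore merge a component pair
whenever the merge costs less log-likelihood than the three parameters it
frees (a BIC comparison, `2 * dlogLik < 3 * log n`). On synthetic trios
with 5% contamination this yields rescue recall above 0.99 with a
false-rescue rate below 0.005 for germline heterozygous sites.

Points are processed in a canonical sort order, so the rescue set is
invariant to input order for a fixed seed.

## Signature decomposition

Per-stratum SNVs are binned into the 96 pyrimidine-centered trinucleotide
contexts (purine-reference SNVs are reverse-complemented). The catalog
`C` is decomposed against a signature matrix `W` (96 x S, columns sum
to 1) by non-negative least squares, `e = argmin_{e >= 0} ||C - W e||`,
solved by an in-package Lawson–Hanson active-set implementation; exposures
are in mutation counts, with normalized exposures `e / sum(e)` alongside.

A signature-specific cutoff is then applied on normalized exposure
(default 0.06 for every signature, overridable per signature): signatures
below their cutoff are removed and the NNLS re-run on the remaining
columns, iterating until all survivors meet their cutoffs. Cohort-level
detection fits the pooled cohort catalog with cutoffs, and the surviving
signatures define the restricted matrix used for all per-sample and
per-stratum fits — rare signatures must prove themselves on pooled
evidence before being offered to individual fits.

Strata are compared per signature with a two-sided paired Wilcoxon
signed-rank test across patients (exact distribution for n <= 25; the test
choice is ours — only the Benjamini–Hochberg correction across signatures
is prescribed), with the median paired difference as the direction.
Exposure profiles are clustered hierarchically (Euclidean distance,
complete linkage), and exposure–covariate associations (e.g. diploid
versus aneuploid samples) use a two-sided exact Mann–Whitney test per
signature with BH correction.

The bundled `inst/extdata/signatures_synthetic_96x12.tsv` is a *synthetic*
signature matrix produced by `synthetic_signature_matrix()`; curated
signature catalogs are supplied by the user in the same TSV layout.

## Kataegis

A kataegis locus is a cluster of at least 5 mutations spanning at most
10 kb (span = last minus first position, inclusive). Every qualifying run
of 5 consecutive mutations seeds a locus; overlapping or adjacent runs are
merged into maximal loci. Detection is validated against a brute-force
window scan. No per-strand or substitution-class refinement is applied.
Loci are annotated with genes whose span lies within 10 kb (boundary
inclusive; overlap is distance 0), and per-sample loci are intersected
across samples to report recurrent regions (>= 2 samples).

## Copy-number states and recurrence

Allele-specific segments (from an upstream caller, consumed as input) are
classified relative to the *sample base ploidy*, not 2: gain when
`tcn - ploidy > 0.7`, loss when `ploidy - tcn > 0.7`, both strict, so a
deviation of exactly 0.7 is neutral (an explicit floating-point guard
keeps 2.7 - 2.0 at the boundary). LOH is a minor-allele copy number below
0.5 (rounds to zero copies); missing minor copy number yields unknown.
Arm-level recurrence reports, per arm, the proportion of samples with at
least one overlapping gain/loss/LOH segment, with the denominator being
the samples with any segment data on that chromosome; centromere-spanning
segments count for both arms; sex chromosomes are excluded by default.
Genes inherit the state of overlapping non-neutral segments, with
gain/loss conflicts reported as "complex".

## Cohort statistics

Mutation matrices (gene x sample, binary) are built per channel — coding
non-silent, ncRNA-exonic, and 3'-UTR, kept separate because they answer
different questions. Recurrent genes use a sample-count cutoff (default
4). A gene pair is mutually exclusive when at most one sample carries
mutations in *both* genes (the alternative reading — at most one sample
mutated in either — would contradict the genes being recurrently
mutated); a two-sided Fisher exact p-value accompanies the call,
implemented by hypergeometric enumeration under the probability-mass rule
(conventions for two-sided Fisher tests differ; this is the common one).
The chi-square test is Pearson's without continuity correction.
Enrichment of a hit set against user-supplied gene sets is the upper-tail
hypergeometric probability, BH-corrected across sets.

## The synthetic cohort

The generator emulates the study conditions of a 12-patient
colorectal-cancer trio cohort: per patient, 5,000–17,000 somatic SNVs;
stratum fractions (0.65, 0.15, 0.20) — the published 65/15/19% with the
remainder rounded so the fractions sum to 1; purities uniform in
[0.35, 0.85]; ploidy 2 or 3; mean coverage 36x. A clonal variant's true
VAF is `purity * mult / (purity * CN + 2 (1 - purity))` with CN equal to
the sample ploidy and multiplicity 1 — a single dominant clone per
stratum; subclonal structure is deliberately out of scope. Read counts
are Poisson depth (truncated at 1) with binomial allele sampling; the
emulated upstream caller flags a variant somatic in a sample when it has
at least 2 alternate reads there. Contexts are assigned directly from the
per-stratum signature mixtures (no reference FASTA is needed at desk
scale). Positions are uniform over the 22 hs37d5 autosomes.

Tumor-in-normal contamination affects 5% of truncal variants by default:
their normal-sample VAF is uniform in (0.01, 0.15) and their caller flags
are cleared (the caller would have labelled them germline). The magnitude
is our choice — the study motivates the rescue step by observed
contamination but does not quantify it; 5% is a realistic mid-range level
and is exercised by the validation suite. Each trio also carries 2,000
germline heterozygous BAF positions (sample and control BAF 0.5), of
which 80% are marked as known common variants; the remaining 20% emulate
rare germline hets that survive the common-variant filter and are the
false-rescue test set. These counts are desk-scale stand-ins for the tens
of thousands of such positions in real data.

What passing tests on this generator do *not* show: robustness to
subclonal architecture, to allelic imbalance shifting germline BAF away
from 0.5 in aneuploid regions, to mapping artifacts with systematic
strand or position bias, or to purity estimation error — real-data
features the generator does not emulate.

## Numerical and design choices

* Coordinates are 1-based inclusive in memory everywhere; BED inputs are
  converted at the boundary, and chromosome names are normalized by
  stripping any "chr" prefix. Multi-allelic VCF rows are split into one
  record per alternate allele. Records with missing read counts are
  rejected outright (the MAF rules divide by depth).
* Signature matrix columns must sum to 1 within 1e-3 (then renormalized
  exactly); context rows are canonicalized to the fixed 96-label order.
* Without codon-level information, every CDS SNV is treated as
  potentially non-silent; a codon-aware `synonymous` column, when
  supplied, excludes silent SNVs. Splice sites are the 2 bp of intron
  flanking any exonic interval. 3'-UTR mutations are tracked as their own
  channel, not as mutations of interest.
* Region-class ties resolve by the fixed priority splice_site > CDS >
  UTR3 > UTR5 > ncRNA_exon > intron > intergenic; overlapping genes all
  report, and recurrence counts each gene once per sample.
* The NNLS active-set tolerance scales with the problem
  (`10 eps max(colSums|A|) max(dim)`); rank-deficient subproblems zero
  the unresolvable coordinates.
* Degenerate inputs: empty catalogs are an error at decomposition (the
  caller is told to skip); if cutoffs remove every signature the exposure
  vector is zero with a warning, while cohort-level detection treats an
  empty surviving set as an error; clustering fewer distinct BAF points
  than k reduces k with a warning; unsorted kataegis positions are sorted
  with a warning; duplicate positions keep distance 0.
* Determinism: every stochastic entry point takes a seed; identical seeds
  give bit-identical outputs, and the pipeline's JSON summary is
  byte-identical across reruns.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data:
12 trios of 10,000 SNVs for cohort-level stratification recovery, single
trios of 3,000–8,000 SNVs for rule-level checks, 10,000-mutation catalogs
for exposure recovery, 200 random catalogs for NNLS oracle equivalence,
and 500 random chromosomes for the kataegis oracle. These sizes match the
study's per-sample mutation loads while keeping a full validation run in
minutes on one CPU.

## Known limitations

* The iterative cutoff procedure is greedy; it is not guaranteed to find
  the minimum-residual subset among all cutoff-admissible signature
  subsets (they occasionally differ), but it is the procedure stated and
  validated here.
* TiNDA's specificity depends on cluster granularity; the BIC merge
  removes the dominant failure mode, but germline sites in strongly
  imbalanced copy-number regions (BAF far from 0.5) are not modelled.
* Gene-level annotation is interval-based; codon-level consequences
  require an external annotator's column.
* Arm recurrence uses a user-supplied (or midpoint-default) arm map;
  acrocentric chromosomes need a real cytoband file for meaningful p-arm
  calls.
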