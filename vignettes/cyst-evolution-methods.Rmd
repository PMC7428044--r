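---
title: "Methods: clonal evolution of neoplastic pancreatic cysts"
author: "cystevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal evolution of neoplastic pancreatic cysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystevol)
```

## The scientific problem

Intraductal papillary mucinous neoplasms (IPMNs) and mucinous cystic
neoplasms (MCNs) are noninvasive pancreatic cysts that co-occur with small
invasive carcinomas. Multi-region sequencing of such lesions — a few
whole-exome samples per patient (precursor with high-grade dysplasia, the
invasive cancer, sometimes a low-grade region, and a matched normal) plus
deep targeted sequencing of many microdissected regions in a subset of
patients — makes it possible to ask whether the cyst is the direct ancestor
of the cancer, which clones diverged when, and how long the window between
high-grade dysplasia and invasion lasts.

This package implements that analysis as a tested pipeline over read-count
tables, organized as an analysis workflow: the computation lives in the
package functions, and the numbered scripts under `analysis/` are thin
drivers that run the stages on a synthetic cohort and report what they
find. Because the real patient data are controlled-access, a first-class
simulator generates cohorts with the same design and known ground truth;
everything the pipeline claims is validated against that truth.

## Integrated mutation calling

Candidate somatic sites (discovered externally per patient) are
re-genotyped in every sample of the patient and assigned one of five
states: `present_primary`, `present_secondary`, `absent`,
`indeterminate_low_coverage`, `site_excluded`. The filters run in order:

1. *Capture-efficiency filter.* A site is analyzable only if its depth
   strictly exceeds 20% of the sample's median capture coverage in **every**
   sample of the patient; otherwise it is excluded everywhere. "Exceeds"
   is read strictly; stated minimums elsewhere ("at least 10", "a minimum
   of two") are read inclusively.
2. *Germline filter.* The matched normal must have at least 10 distinct
   reads and a variant allele fraction (VAF) below 2%.
3. *Primary calls.* Whole-exome: VAF >= 10% and >= 5 mutant reads.
   Targeted: VAF >= 5% and a coverage-scaled mutant-read minimum,
   `ceiling(5 * sample_median / mean(whole-exome medians))`, floored at 2 —
   deep panels allow a lower VAF cut but need more reads to hold the
   sequencing-error false-positive rate constant. The ceiling-and-floor
   rounding is this package's choice; only the scaling ratio itself is
   prescribed by the study design.
4. *Secondary calls.* Precursor samples are systematically less pure than
   cancers, so a mutation already primary in *any* sample of the patient is
   called present in a whole-exome sample with just 2 mutant reads.
   Secondary presence is computed in a second pass after all primary calls
   are fixed and does **not** seed further secondary calls — chaining would
   propagate single errors across the cohort.

A depth of zero yields `indeterminate_low_coverage`, never `absent`.
Targeted samples are only assessed at sites discovered in the patient's
whole-exome data or inside the 15 fully covered pancreatic driver genes
(*APC, ATM, BRAF, CDKN2A, CTNNB1, GNAS, KRAS, MAP2K4, PIK3CA, PTEN, RNF43,
SMAD4, STK11, TGFBR2, TP53*). The external homology/visual review of the
original workflow is represented by an explicit site exclusion list in the
configuration.

## Targeted-panel copy number

The ~185 kb panel is too small for conventional copy-number callers, so
gene-level log2 copy ratios are computed directly: per-interval median
depth (floored at 1 read so log ratios stay finite; an additive pseudocount
would bias every ratio, and the floor preserves the exact closed form
`log2(depth / median)` for covered intervals), normalized by the panel-wide
median, GC-corrected by dividing each interval by the median ratio of its
GC decile (deciles with fewer than 5 intervals fall back to the global
median), re-centred to a median log2 of exactly 0, and summarized per gene
by the median of interval ratios. Classification applies *after* GC
correction: log2 < -1.25 is homozygous deletion (a 0.25 margin beyond the
-1 of hemizygous loss) and log2 > 1.6 is amplification (about copy number
6+ in a pure, largely diploid genome — at lower purity the detectable copy
number rises accordingly).

Whole-exome focal copy-number aberrations are screened from
externally produced allele-specific segments: length < 3 Mb and total copy
0 (homozygous deletion) or >= 3x ploidy (amplification), then routed for
review exactly as the study triaged them (purity >= 30%: any driver-gene
hit, or cellular fraction >= 75%; purity < 30%: extended driver list and
cellular fraction >= 75%). Nothing is silently auto-passed: events carry an
explicit `needs_review`/`dropped` flag. The extended ("195-gene") list is
configuration-supplied; the package ships only the 15-gene list as a
default stand-in since no equivalent public list applies.

## Genome-wide LOH

Loss of heterozygosity is read from the minor allele frequency (mAF) of
germline heterozygous SNPs, which drops from 0.5 under allelic imbalance:
to `(1-p)/(2-p)` for a clonal hemizygous deletion at purity `p`, and to
`(1-p)/2` for copy-neutral LOH. Per sample and chromosome the mAF series is
segmented by recursive binary splitting with a permutation test (alpha
0.01, 1000 permutations, seeded): the same change-point family as circular
binary segmentation, without the circular edge wrap, which adds nothing on
linear chromosome arms at this scale. Segment mAF is the median of member
SNPs at the whole-exome stage (robust to outlier SNPs) and the mean at the
targeted extension, where the study prescribes the average.

LOH calls require a tumor-normal segment mAF decrease of at least 0.1
(inclusive). Each sample's minimum segmental mAF over segments longer than
10 Mb with at least 20 SNPs serves as a purity proxy; LOH segments are
tiered by their distance to it: < 0.1 high confidence, 0.1-0.2
intermediate, >= 0.2 low. The half-open tier edges make the three tiers a
partition. Patient-level segments take the union of breakpoints across
whole-exome tumor samples, keep segments > 10 Mb with >= 20 SNPs and a
high-confidence call in at least one sample, and are classed `uniform`
(LOH everywhere) or `differential`; differential segments additionally
need a 0.1 mAF separation between samples with and without LOH. Segments
with facing boundaries within 5 Mb and identical per-sample calls are
merged to a fixpoint (merging recomputes mAFs over pooled SNPs and never
flips a call). Targeted samples are annotated per candidate segment from
SNPs with >= 20x coverage, or marked unknown.

## Phylogenetic reconstruction

Mutations, differential/uniform LOH segments and reviewed focal CNAs form a
binary presence matrix per patient. Indeterminate entries are imputed to
the event's majority value (ties to absent) and logged — dropping them
silently would lose characters. Identical presence patterns define
*alteration clusters*; clusters with a single member go to a singleton pool
because one discordant call is as likely an error as a real branch. A
singleton differing from a cluster in exactly one sample is merged when the
discrepancy is explainable: mutant reads within a 20% margin of the
violated threshold (the declared automation of the study's manual review),
LOH/copy loss at the locus (mutation loss), or a marginal presence barely
above threshold. All corrections are logged. In patients where every
sample is whole-exome sequenced, mutations whose absences are all
explainable by copy loss at the locus are excluded as ambiguous.

Samples containing two clusters whose sample sets are non-nested cannot be
a single clone: such cluster pairs (reduced so no retained pair's member
has an ancestor paired with the same partner) split the mixed sample into
two subclone pseudo-samples, each carrying one member and lacking the
other and its descendants. Cluster membership is never altered by the
split.

Trees are found by maximum parsimony over the cluster characters
(unweighted — weighting by cluster size would let one large trunk cluster
dominate topology choices it cannot inform), with the matched normal as an
all-absent outgroup root. The search enumerates every topology up to 7
leaves and switches to branch-and-bound above (Fitch scores cannot
decrease as leaves are added, so partial trees scoring above the incumbent
are pruned); all minimum-score trees are returned in canonical order, with
branch lengths equal to the number of alterations per edge. In the
pipeline driver, samples with identical character patterns are collapsed
into one leaf first: their binary resolutions are interchangeable and
only multiply the tree list. The hard leaf cap is 25.

Ancestry of precursor-annotated samples is classified from genotypes:
`cancerization` if the sample covers every confident mutation of a cancer
sample (intraductal spread of the carcinoma, mimicking precursor
histology), `independent_clone` if it shares zero confidently called
non-hotspot mutations with every cancer sample (hotspots such as KRAS
codon 12 recur independently and are excluded as ancestry evidence), and
`precursor_lineage` otherwise. Ancestry evidence is restricted to primary
calls: at 170x and an error rate of 10^-3, a secondary call (2 reads) has
a per-site false-positive probability of 1-2%, so across ~100 candidate
sites a spurious "shared" or "cancer-private" secondary call is expected —
enough to break a superset or zero-sharing test that admits them.

## Timing of malignant progression

For each patient, `y` counts mutations present in the cancer whole-exome
sample and confidently absent (not indeterminate — a conservative
undercount beats fabricated absence) in the paired high-grade precursor.
Patients whose precursor sample is reclassified as cancerization are
excluded: they have no true precursor genotype. The model is

$$y_i \sim \mathrm{Poisson}(\mu T_i),\quad T_i \sim \mathrm{Gamma}(a, b),
\quad a = 1 + m b,\quad b = \frac{m + \sqrt{m^2 + 4 s^2}}{2 s^2},$$

with $m \sim U(0, 100)$, $s \sim U(0, 100)$: the Gamma prior on the latent
progression times has mode exactly $m$ years and standard deviation
exactly $s$ years (both identities hold to machine precision and are
tested). The mutation rate $\mu$ is not identifiable from one count per
patient, so the model is fitted on a grid (default 1-10 mutations/year)
and medians are averaged across the grid without weighting — per-rate
outputs are retained so any other aggregation can be applied.

The sampler exploits conjugacy: $T_i \mid y_i, m, s \sim
\mathrm{Gamma}(a + y_i,\, b + \mu)$ exactly (Gibbs), with random-walk
Metropolis on $m$ and $s$ reflected at the prior bounds and step sizes
adapted only during burn-in. Defaults are 4 chains of 20,000 iterations
(5,000 burn-in) with a split-chain convergence bound of 1.01;
non-convergent fits are flagged, never silently returned. Against fixed
hyperparameters the sampler is checked to reproduce the closed-form
posterior mean and variance within Monte-Carlo error, and
simulation-based calibration over replicated 17-patient cohorts holds the
90% credible-interval coverage between 0.80 and 0.98.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` plants, per patient: a trunk initiated by a hotspot
mutation (mean 45 trunk mutations), a shared precursor/cancer ancestor
(mean 8), precursor-private branches (mean 15), and a cancer branch with
$\mathrm{Poisson}(\mu T)$ private mutations, $T \sim$ Gamma(mode 3 y, sd
2 y) and $\mu = 5$/year — these defaults put per-sample totals in the
observed 26-111 range and the expected cancer-private count near 20.
Purity is drawn 0.5-0.8 for precursors and 0.3-0.6 for cancers
(noninvasive lesions are consistently purer); whole-exome coverage
averages 177x and targeted 508x. Read depths are Poisson, mutant reads
Binomial at the purity-determined VAF, non-mutant sites carry a 10^-3
error rate (chosen to exercise the 2%-normal filter and the secondary-call
tier). LOH events are 10-80 Mb on named chromosomes (spanning both sides
of the 10 Mb rule); SNP counts follow the allele-dosage formulas above.
Scenario patients add cancerization samples (genotype a strict superset of
the cancer), a second invasion branch (given a defined binary divergence
order so topology recovery is well-posed), or an independent clone reusing
a hotspot label from a fixed pool.

The simulator does *not* emulate FFPE artifacts, mapping error, subclonal
structure within a sample (beyond planted mixtures), indels,
trinucleotide context, or a real reference genome. Passing tests therefore
demonstrate the pipeline's logic and statistical calibration under the
declared noise model, not robustness to every artifact of archival tissue
sequencing.

## Numerical choices and problem sizes

Boundary comparisons on the 0.1 LOH difference and tier edges use a 1e-9
float guard so printed thresholds behave as written. Permutation tests
stop early once the significance level can no longer be reached. The test
suite and the acceptance script use reduced MCMC schedules (2 chains,
3,000-11,000 iterations) and cohort sizes (50 planted patients, 60-100
planted LOH/copy-number events, 200-500 random parsimony instances),
sizes at which every check has comfortable Monte-Carlo margin; the
pipeline defaults remain the full schedule.

## Known limitations

- The singleton-rescue margin automates a review step that was qualitative
  in the original workflow; the margin (20%) is a declared convention.
- Branch-and-bound is exact but can be slow near the 25-leaf cap on
  conflict-heavy matrices; the pipeline collapses identical leaves first.
- The timing model conditions on called mutation counts; calling errors
  propagate into `y` (the simulator shows ~95%+ agreement with planted
  counts at study purity/coverage, but degraded samples would bias `y`
  downward and the inferred times with it).
- LOH segmentation assumes ordered SNPs with roughly uniform density;
  acrocentric gaps or capture deserts are not modeled.
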