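---
title: "From TAS2R haplotypes to bitter-taste phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TAS2R haplotypes to bitter-taste phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterhap)
```

## The scientific problem

Humans carry ~25 bitter-taste receptor (TAS2R) genes in three clusters on
chromosomes 5, 7 and 12. Coding variation in these genes changes receptor
affinity and thereby perception thresholds, but the genes sit in strong
linkage disequilibrium (LD): within each haplotype block only a handful of
long-range haplotypes (LRHs) segregate, each carrying a particular
combination of alleles across several genes. A genotype–phenotype
association can therefore be driven by a causal allele, inherited by a
linked passenger allele, or — when two genes' sensitive alleles reside on
*opposite* haplotypes — masked entirely, because nearly every subject then
carries a sensitive allele of at least one gene.

`bitterhap` implements the full analysis chain that disentangles these
cases: a synthetic cohort generator with the LD structure described above;
copy-number-aware genotype handling and EM haplotype phasing; multi-allelic
LD and four-gamete block partitions; maximum-likelihood psychometric fits
to 4-AFC detection and yes/no recognition series with labeled-magnitude
(gLMS) intensity inversion and Peirce outlier rejection; mixed-model
association scans with a permutation experiment-wide threshold; a
three-step fluorescence correction with Hill dose–response fits for
calcium-imaging plates; and the integration logic that labels loci causal,
linked passengers, or phase-masked.

## The synthetic cohort generator

No subject-level data are redistributable for the original study design,
so every stage is exercised on synthetic cohorts whose structure mirrors
the study: 48 diploid subjects; 25 genes in six multi-gene blocks plus
singleton loci; an LRH pool per block with fixed frequencies (the
TAS2R31–42 block carries four LRHs at 0.30/0.22/0.20/0.16, including a
haplotype coupling the TAS2R43 whole-gene deletion to the truncated
TAS2R46 allele); whole-gene deletion alleles at TAS2R43/TAS2R45 giving
copy numbers 0–2; and six bitter compounds with per-allele receptor
pharmacology.

Key generator choices:

* **Random mating.** Each subject draws two LRHs per block i.i.d. from the
  pool; Hardy–Weinberg proportions and haplotype-frequency recovery are
  tested properties, not assumptions.
* **Rare haplotypes.** The pool frequencies sum to slightly below one; the
  remainder is drawn by mutating a pool haplotype at one random site. This
  keeps allele sets closed, and means gene-level allele frequencies sit
  slightly above the pool values.
* **Mutation-compatible block composition.** Within a block, every gene
  pair's major-vs-rest collapse leaves one of the four gametes absent from
  the pool, so four-gamete recombination evidence arises only *between*
  blocks (plus occasional rare-haplotype sampling noise at n = 48).
* **Perceptual link.** A subject's latent log10 recognition threshold is
  `offset + slope · log10(min activation threshold over carried functional
  alleles) + N(0, sd)`, with per-compound link parameters. Offsets were
  calibrated once against the published per-compound subject ranges
  (e.g. +0.7 log10 for grosheimin maps receptor thresholds of
  1–10 µM into the published 2–50 µM perceptual span). For absinthin and
  cascarillin a compressive slope (0.1) makes the two repulsion-phase
  sensitive alleles perceptually near-equivalent — which is precisely the
  published explanation for their missing association, and the reason
  perception can sit below in-vitro activation. Subjects carrying no
  functional assayed allele default to the top of the tested series
  (perception via receptors outside the assayed set).
* **Assay resolution.** Plate replicate noise is 0.001 ΔF/F and each
  allele's Hill coefficient is chosen (bounded to [0.8, 4]) so its curve
  first exceeds the statistically resolvable response (~0.005 ΔF/F with
  six replicates) exactly at its published activation threshold. This is
  the unique way to make the published threshold/EC50/amplitude triples
  mutually consistent under the statistical threshold-call rule: a
  threshold 41-fold below the EC50 (TAS2R30-H1 with amarogentin) forces a
  shallow curve and a fine resolution, while a threshold 2.3-fold below
  the EC50 (TAS2R43-H2 with grosheimin) forces a steep one.

What the generator does **not** emulate: population structure and
relatedness, cross-block ancestry correlation (blocks segregate
independently, so region-wide mean LD between blocks is near zero, lower
than in the real data), redundant tag SNPs (each haplotype split is tagged
by a single site, which also caps within-block mean r²), read-level
sequencing error, and adaptive psychophysical procedures. Passing tests
therefore validate the analysis machinery under the stated structure; they
do not certify performance on cohorts violating it.

## Genotypes, copy number and phasing

Copy number at the deletion-capable loci follows the multiplex-PCR
decision table: internal products only → two copies, both product types →
one, spanning product only → zero, neither → assay failure. Genotyping
quality control uses the exact conditional Hardy–Weinberg test (two-sided
by probability mass), appropriate at n = 48; note the exact test is
discrete and therefore slightly conservative — its nominal 5% rejection
rate realises at ~3–5%.

Phasing uses the classical multinomial EM over the haplotype pairs
compatible with each subject's unphased genotypes, with ten seeded random
restarts after a uniform start; the log-likelihood is non-decreasing
within each run (asserted in tests) and the reported phase is each
subject's maximum-posterior diplotype. This is a deterministic,
dependency-free stand-in for Bayesian coalescent-prior phasing, adequate
at the observed scale (≤ 6 haplotypes per gene). Hemizygous subjects
contribute their directly observed haplotype paired with the deletion
state `DEL`; zero-copy subjects contribute two `DEL` chromosomes; subjects
with missing genotypes are excluded from the scope and reported unphased.
Low-posterior phases are reported with their posterior rather than being
resolved by external data. Haplotypes are named `H1, H2, …` by descending
frequency (ties broken lexicographically; `DEL` keeps its name), and
long-range haplotypes `H-LR1, …` likewise. Block-scope phasing treats each
gene's haplotype as one multi-allelic marker.

## LD and haplotype blocks

Pairwise LD between multi-allelic loci uses the frequency-weighted
multi-allelic D′ (`Σ pᵢqⱼ·|D′ᵢⱼ|`) and the chi-square-based r²
(`χ²/(N·min(k−1, l−1))`, the squared Cramér's V), which reduce to the
classical quantities for biallelic pairs; p-values come from a seeded
Monte-Carlo chi-square test (10,000 draws by default), valid for sparse
multi-allelic tables.

Blocks follow the four-gamete rule with a 5% cutoff: after collapsing each
unit to major-allele-vs-rest, a pair shows recombination evidence iff all
four gametes reach 5% frequency, and blocks are maximal contiguous runs
with no within-run evidence, built greedily left-to-right. Greedy maximal
runs over a hereditary validity property give a minimum-size partition
(verified against a dynamic-programming oracle in tests), but minimum
partitions are not always unique, so exact reversal symmetry is only
guaranteed when the partition is unambiguous (as in the default scenario);
the block *count* is always reversal-invariant. Monomorphic units (genes
with no coding SNPs) can never show evidence and are excluded rather than
being glued arbitrarily to a neighbour. Manual per-unit block overrides
win over the algorithm, mirroring curated adjustments at loci whose SNPs
span several blocks.

## Psychophysics

Concentration series are geometric (12 steps, common ratio 1.5, per-
compound starts). Detection uses the 4-AFC model
`P(correct) = 0.25 + 0.75·logistic(slope·(log10 c − mu))`, recognition the
plain logistic; both are fitted per subject × compound × repetition by
Bernoulli maximum likelihood from five deterministic starts (ties broken
by likelihood then smallest slope), on log10 concentration. The reported
threshold is `10^mu`, the midpoint of the non-guessing component
(detection P = 0.625, recognition P = 0.5) — the conventional forced-
choice definition; the criterion point is configurable. All-success
series are censored `low` at the series floor, at-chance series censored
`high` at the ceiling; censored values are clamped to the boundary with
the flag retained, so downstream fold ranges compress at the series edges
exactly as bounded procedures do. The yes/no recognition question is
simulated at every step by default, with a mode restricting it to
correctly chosen samples; the fitting stage accepts both.

Intensity ratings (percent of the gLMS scale) are fitted by least squares
to a saturating logistic with floor 0, and inverted at 6, 17, 34.7 and
52.5% of scale length for the weak/moderate/strong/very-strong
concentrations; inversions beyond the tested range or above the curve's
saturation are censored. Monotonicity of the four inverted concentrations
is automatic from the shared curve.

Outliers are rejected by Peirce's criterion (Gould's iterative algorithm,
one unknown quantity), applied per compound × measure to log10 thresholds
across subject × repetition cells; deviations are measured against the
full-sample mean and standard deviation and the allowed number of doubtful
observations grows while rejections continue. The implementation is
validated against an independently computed reference table and is
idempotent on its own output.

## Association

The genotype–phenotype model is `log10(y)_ij = mu + beta_g(i) + u_i +
e_ij` with a subject random intercept, estimated by REML (`nlme::lme`);
the genotype test is the F test with containment denominator degrees of
freedom, which on balanced replicate designs coincides exactly with the
one-way ANOVA on subject means (asserted to 1e-6 in tests, and calibrated:
type-I error 0.05 ± 0.02 over 1,000 null scans). Genotype is coded
categorically; classes at sample frequency ≤ 0.05 are dropped and their
subjects excluded for that unit. Degenerate units (a single class,
constant phenotype) are flagged, not raised.

The experiment-wide threshold is the 5th percentile of the permutation
distribution of the minimum p across all SNP-level tests, permuting
subject phenotype vectors as units so the LD among tests and the
within-subject replication are preserved; with one test it returns ~0.05,
duplicated tests change nothing, and for independent tests it matches the
Šidák closed form `1 − 0.95^(1/m)` (all tested). The permutation statistic
is the vectorised subject-means F — the balanced-design equivalent of the
mixed-model F — which keeps 1,000+ permutations inexpensive. A Šidák
threshold with a user-supplied effective test count is available as a fast
alternative; both are interpretations of an experiment-wide correction,
not reproductions of a specific published recipe. Gene- and block-level
analyses use Bonferroni.

## Receptor function

Raw plates carry peak (`F`) and baseline (`F0`) fluorescence per well.
Corrections are applied in fixed order: (1) well-to-well, `ΔF/F = (F −
F0)/F0`; (2) subtraction of the matched empty-vector mean per (day,
compound, concentration), removing receptor-independent artefacts — empty
vector wells end at mean zero by construction; (3) day alignment by the
grand/day positive-control ratio, which removes day gains up to the
experiment's mean gain (so absolute amplitudes carry a ~6% scale
uncertainty at six days). The whole pipeline is invariant to detector
gain. Concentrations above a per-compound artefact-free ceiling (3×10⁻⁴ M
default, 3×10⁻⁵ M for quinine) are excluded.

The activation threshold is the lowest concentration whose corrected
response significantly exceeds the matched empty vector (one-way ANOVA
gate, then per-concentration comparisons, Bonferroni m = number of tested
concentrations, requiring a positive mean difference); `NA` when nothing
is significant up to the ceiling. Dose–response curves are fitted by
bounded nonlinear least squares to the Hill equation `A·cⁿ/(EC50ⁿ + cⁿ)`
(EC50 within one decade of the tested range, n ∈ [0.5, 4], A ≥ 0, multiple
deterministic starts); boundary-pinned or non-convergent fits are marked
not activated. Fits are checked against a dense grid-search oracle, and
the published EC50s are recovered within ±20% (median over 200 simulated
six-replicate plate sets).

## Integration

`classify_alleles` labels alleles never significantly activated
`nonfunctional`; activated alleles are classed within (compound, gene) by
the ratio of their activation threshold to the gene's best: ≤3×
`sensitive`, ≤30× `intermediate`, else `insensitive` (configurable).
Classing within gene rather than across the compound is deliberate: the
question each time is which of a gene's alleles is its high-sensitivity
form, regardless of how the gene compares to other receptors. Separately,
an allele is *phenotype-explanatory* iff it activates at or below the top
of the subjects' recognition range.

`phase_summary` annotates each common LRH with the genes whose sensitive
allele it carries and counts per subject the LRH copies bearing at least
one sensitive allele. The phase mode is `single_locus` (one gene),
`repulsion` (every common LRH carries exactly one gene's sensitive
allele), `coupling` (the carriers of one gene's sensitive alleles nest
within the other's, with co-residence), else `mixed`. In a pure
four-haplotype repulsion pool every subject carries exactly two sensitive
copies — the configuration that nullifies single-locus association.

`candidate_filter` intersects association signals (experiment-wide
significant blocks), the receptor–agonist inventory (an editable
configuration table), and functional evidence: `causal` needs all three;
blocks significant without functional support are `linked_passenger`;
inventory-responsive genes with sensitive alleles but no signal are
`phase_masked` when their sensitive alleles sit in repulsion (explanatory
status is deliberately not required here, because repulsion-phase
perception can sit below in-vitro activation), else `unexplained`. The
paired simulation property — identical allele effects arranged in coupling
fire the scan, in repulsion they stay silent — holds in ≥45 of 50
replicates and is the package's distilled version of the study's central
claim.

## Problem sizes and numerical choices

The default test and acceptance workloads use the study-scale designs: 48
subjects, 12-step series in triplicate, 6-replicate plates, 200 replicate
plate simulations for EC50 recovery, 1,000 null scans for type-I error,
1,000–3,000 permutations per threshold, 50 paired phase-contrast
replicates, and n = 10,000 cohorts for frequency-recovery checks.
Optimiser settings (L-BFGS-B bounds, five deterministic starts,
tie-breaking by likelihood then smallest slope), EM tolerance (1e-8 on
frequencies, 200 iterations, 10 restarts) and the clamping of censored
values are fixed defaults documented above; all randomness flows through a
single seeded generator with hierarchically derived sub-stream seeds, so
every result in the package is reproducible from (inputs, seed).
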