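---
title: "Methods: longitudinal sperm DNA methylome analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal sperm DNA methylome analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermethylome)
```

## The problem this package addresses

Human sperm carries a highly stereotyped DNA methylation landscape: most
CpG sites are either almost fully methylated or almost fully unmethylated,
germline imprinting control regions (ICRs) sit at parent-of-origin-specific
extremes (paternally methylated ICRs such as *H19* near 100%, maternally
methylated ICRs such as *MEST*, *KCNQ1OT1* and *SNRPN* near 0%), and a
minority of CpGs with intermediate methylation — "dynamic" sites — show
elevated inter-individual variability and environmental sensitivity.

`spermethylome` implements an analysis of this landscape for a
three-cohort longitudinal design: community controls (CC) and men treated
for Hodgkin disease (HD) or testicular cancer (TC), each sampled before
treatment (baseline, 0 months) and at roughly 6-month intervals
afterwards. The questions the pipeline answers are: Is imprinting intact?
Are samples contaminated with somatic cells? Does a cross-cohort
methylation signature exist at baseline? Where does it concentrate in the
genome (DMRs)? How much does each subject's methylome move after
treatment, relative to control drift? And are the moving sites enriched at
dynamic CpGs?

Because cohorts like this are small and rarely public, the package ships a
calibrated synthetic-cohort generator with full ground truth, so every
stage of the analysis runs, and is tested, without external data.

## Data model

All methylation is handled as beta values, fractions in $[0,1]$; percent
appears only in printed output. Coordinates are 0-based half-open (BED
convention) throughout. Missing betas stay missing and are excluded
pairwise from every statistic; nothing is imputed. The containers are
deliberately plain: a probes-by-samples matrix with an optional aligned
read-coverage matrix (`beta_matrix`), a sample manifest (subject, cohort,
timepoint in months), a probe annotation table (position, multi-mapping
flag, SNP minor allele frequency), and a named region set in which ICR
entries carry a parent of origin plus the expected sperm and somatic beta
levels.

## Quality control at imprinted regions

`summarize_icrs()` averages the non-missing betas of the probes inside
each region, per sample. The contamination estimator
(`estimate_contamination()`) models an observed ICR mean as a
two-component mixture of sperm and somatic signal,

$$\mathrm{obs}_i = (1-\alpha)\,s_i + \alpha\,m_i,$$

with $s_i$ the sperm expectation and $m_i$ the somatic expectation of ICR
$i$, and solves for $\alpha$ by least squares in closed form,

$$\hat\alpha = \frac{\sum_i (s_i-\mathrm{obs}_i)(s_i-m_i)}
                    {\sum_i (s_i-m_i)^2},$$

clipped to $[0,1]$. The verdict logic encodes the biological reasoning
that somatic contamination pulls *every* ICR toward the somatic level by a
similar fraction: the per-ICR implied alphas
$(s_i-\mathrm{obs}_i)/(s_i-m_i)$ must be uniform (coefficient of variation
below 0.5 by default) before a sample is called `contaminated`; a strong
but locus-confined deviation is a `locus_anomaly` instead. On synthetic
mixtures the estimator recovers the true mixing fraction to within 0.05
across the whole $\alpha \in [0.1, 0.9]$ range at default noise.

`flag_outlier_samples()` combines this estimate with robust z-scores
(median/MAD) of the samples' principal-component scores on the ICR-mean
table. The robust-z threshold is a design constant, not an estimated
quantity: ICR means are probe-averaged and therefore very tight, so on a
cohort of ~20 samples MAD-based z-scores of 3-4 occur by chance; the
default threshold of 6 flags only gross outliers, while genuinely
contaminated samples (mixing fraction 0.3) sit at z-scores an order of
magnitude beyond it. Flagged samples are excluded downstream by default
but retained in the QC table with their reasons.

## Baseline differential methylation

Probes are first filtered on annotation: multi-mapping probes and probes
containing a SNP at minor allele frequency *strictly greater than* 1% are
removed (a probe at exactly the cutoff is kept).

For each remaining probe, a classical one-way fixed-effects ANOVA is
computed across the cohorts on baseline samples:
$F = \frac{SSB/(k-1)}{SSW/(N-k)}$, with $p$ from the F distribution. The
implementation is a vectorised closed form over matrix rows (rows are
centred first so the sum-of-squares decomposition is stable near machine
precision); it is verified against `stats::aov` to $10^{-10}$ on random
matrices. The classical (equal-variance) form is used rather than Welch's;
with near-balanced cohorts (7/7/6) the distinction is minor, and the
equal-variance form matches the base-R default used as the oracle.
Significance defaults to raw $p < 0.05$ — deliberately, since the
workflow this package implements screens probes without multiple-testing
adjustment and then works with the resulting site lists; Benjamini-
Hochberg adjustment is available via `use_fdr = TRUE` for users who want
the stricter screen.

Pairwise contrasts use the Tukey-Kramer studentized-range test, which
handles the unequal group sizes and reduces to Tukey's HSD at equal $n$:

$$q_{ij} = \frac{|\bar\beta_i - \bar\beta_j|}
               {\sqrt{\tfrac{MSW}{2}\left(\tfrac1{n_i}+\tfrac1{n_j}\right)}},$$

with the adjusted $p$ from the studentized-range distribution with $k$
groups and $N-k$ degrees of freedom (verified against `TukeyHSD`).
Degenerate probes follow documented conventions: all values equal gives
$F=0$, $p=1$; zero within-group variance with distinct means gives
adjusted $p = 0$. Signed differences follow the pair label (HD−CC, TC−CC,
TC−HD), so "hypomethylated in TC" is a negative TC−CC difference.

The top-$k$ probes (default 500) are selected by ascending $p$ with ties
broken by larger $F$ and then probe id, making the selection invariant to
input order. Samples are clustered on those probes with Euclidean
distance and average linkage — a common default for beta-value heatmaps;
the metric and linkage are recorded in the run summary since the choice is
a convention, not a derived quantity — and the tree is cut into three
clusters. Purity is the fraction of samples whose cohort matches their
cluster's majority cohort. A size-matched random-probe control
(`cluster_and_purity` on random draws) guards against the top-$k$
separation arising by chance.

Candidate-region comparisons (`region_summary()`) average each sample's
betas over the region's probes *first*, then compare the per-sample means
of two groups with a classical unpaired two-sided t test (pooled
variance) or an exact Mann-Whitney test.

## DMR discovery

Significant sites are merged into differentially methylated regions by
treating each CpG as a 1-bp interval $[p, p+1)$ and merging neighbours
whose gap (next start minus previous end) is at most the merge distance
(default 1000 bp) — the gap semantics of `bedtools merge -d`, under which
positions up to 1001 apart merge and positions 1002 apart do not. The
sweep implementation is tested against a brute-force transitive-closure
merge on random instances, and for conservation (total member sites equal
input sites) and idempotence. DMRs are ranked by descending member-site
count with ties in genomic order; per-group DMR means are unweighted
averages of the member probes' group means.

## Longitudinal change

Each follow-up sample is compared to the *same subject's baseline* —
never to the previous follow-up — except in capture mode, which has no
baselines, where consecutive follow-ups are compared. A probe counts as
altered when $|\Delta\beta|$ *strictly* exceeds the cutoff (default 0.2;
a change of exactly 0.2 does not count). Control drift is the mean
altered count over CC subject-by-follow-up pairs in the 6/12/18-month
window, and treated subjects are expressed as fold over that reference.
Altered sets are intersected across a subject's timepoints (the full Venn
cell decomposition; "persistent" means altered at every follow-up) and
across subjects at one timepoint.

Capture mode adds a coverage path: only CpGs covered at least tenfold
(inclusive $\ge$; the strict $>$ reading is available via
`coverage_exclusive`) in *every* sample are analysed. CpGs are classified
as dynamic when their reference mean methylation lies in the inclusive
20-80% band; the reference is the mean over the analysed samples by
default but any external reference vector can be supplied. Enrichment of
alterations between groups is tested with the Yates-corrected chi-squared
on the 2x2 altered/not-altered table,

$$\chi^2 = \frac{N\,\left(\max(0,\,|ad-bc| - N/2)\right)^2}
                {(a+b)(c+d)(a+c)(b+d)},$$

with the continuity correction floored at zero (statistic 0, $p$ = 1 for
tables at or below the correction), matching
`chisq.test(correct = TRUE)`, which serves as the oracle in tests.

## The synthetic cohort generator

`simulate_cohort()` draws a per-probe baseline profile and realises each
sample as baseline + implanted effects + truncated Gaussian noise on the
beta scale, clipped to $[0,1]$. The noise model is deliberately on the
beta scale rather than logit-normal: the analysis reasons entirely in
beta units and clipping keeps every invariant directly testable.

**Baseline profile.** Background probes are dynamic with probability
`dynamic_fraction` (uniform baseline on the 0.2-0.8 band) and otherwise
static (a symmetric Beta(2, 40) mixture hugging 0 and 1). Array mode uses
`dynamic_fraction = 0.14`, matching the observation that 86% of probes on
sperm methylation arrays are hypo- or hypermethylated (<20% or >80%).
ICR probes are drawn around their expected sperm beta (paternal 0.92,
maternal 0.02) with 0.01 jitter; candidate-region probes around the
region's expected level with 0.02 jitter.

**Implanted signatures** (the ground truth for recovery tests): a
20-percentage-point TC hypomethylation across the 21-CpG GDF2-like
promoter, a 15-point HD hypermethylation of the 20-CpG SPON2-like region,
a 15-point hypomethylation of the BASP1P1-like region shared by both
cancer cohorts, and scattered single-CpG effects of ±0.15 beta at
isolated intermediate-methylation probes with a hypomethylation excess
(TC 250 hypo / 150 hyper; HD 210 / 90). Scattered effects sit on probes
with baseline in [0.35, 0.65] so a ±0.15 shift never clips.

**Treatment pulse.** Treated subjects receive an acute ±0.3 beta shift at
2,900 sites at the 6-month collection, decaying geometrically (factor
0.15 per subsequent follow-up) so non-persisters return to control-level
drift by 12 months. One HD subject is a "persister" (decay 0.9) whose
alterations stay above the 0.2 cutoff at every later follow-up. A quarter
of each treated subject's pulse sites come from a pool shared across
subjects (`overlap = 0.25`), so the altered sets of two treated subjects
intersect at roughly 25%.

**Noise calibration.** The per-sample noise SDs are calibration
constants, chosen so the generator reproduces the landscape's published
summary statistics rather than measured from any real variance spectrum:

* Array mode: `dynamic_noise_sd = 0.045`, `static_noise_sd = 0.015`,
  plus `longitudinal_drift_sd = 0.02` on follow-ups. A within-subject
  difference of two draws at a dynamic probe then has SD
  $\sqrt{2\sigma_d^2 + \sigma_{drift}^2} \approx 0.067$, giving
  $P(|\Delta\beta| > 0.2) \approx 2.7\times10^{-3}$ per dynamic probe and
  an expected $385{,}553 \times 0.14 \times 2.7\times10^{-3} \approx 145$
  altered probes per control follow-up — the control-drift level the
  analysis treats as its reference expectation. Static probes contribute
  essentially nothing at these SDs.
* Capture mode: `dynamic_fraction = 0.30` (the capture panel deliberately
  targets dynamic CpGs), `dynamic_noise_sd = 0.0745` and
  `static_noise_sd = 0.057`. The dynamic SD follows the same closed-form
  tail argument (read-sampling at 10-30x makes sequencing betas noisier
  than array betas; binomial sampling alone gives SD
  $\approx\sqrt{0.25/20} \approx 0.11$ for a mid-methylation CpG at 20x,
  which is what a between-timepoint difference of two draws at
  $\sigma_d = 0.0745$ reproduces). The static SD cannot be set by the
  normal-tail formula because clipping at the beta boundaries truncates
  the static tails, so it was calibrated by simulation against two
  targets jointly: about 2.3% of commonly covered CpGs altered per
  control subject between follow-ups, and about 83% of alterations
  falling at dynamic CpGs. Capture mode also draws an over-dispersed
  negative-binomial coverage matrix (mean 30, size 10), which loses about
  7% of CpGs to the tenfold common-coverage filter, and implants a
  treated-subject excess (0.79% of CpGs shifted by 0.3 at the last
  timepoint, 85% of them at dynamic CpGs) so treated men show the
  elevated alteration counts and the strongly significant
  altered-proportion contrast seen in real capture data.

**Determinism.** All randomness flows from the single `rng_seed`;
identical configuration and seed give bit-identical output (the seed is
applied with `withr::with_seed`, so the caller's RNG state is untouched).

## Problem sizes used by the checks

The packaged acceptance script regenerates every quantity at the scale
the landscape statistics refer to: the full 385,553-probe array universe
for control drift, and the full 1,711,875-CpG capture universe for the
dynamic-share calculation. The test suite exercises the same code paths
on reduced universes (typically 15,000-60,000 probes, and 30,000 CpGs in
capture mode) chosen so that each statistical property remains
well-resolved: ICR summaries and implanted-effect recovery do not depend
on the universe size at all, and the scaled capture runs keep several
thousand altered sites per subject, plenty for a share estimated to
within a percentage point. One scaling caveat is embedded in the tests
themselves: the implanted signature has fixed size, so on a reduced
universe its density is many times higher than at full scale, and the
random-probe clustering control must draw from the non-implanted
background to remain a null control.

## What the simulation does and does not establish

The generator reproduces the statistical structure the analysis assumes —
bimodality, imprinted extremes, a dynamic minority with elevated
variance, cohort signatures, acute-then-decaying treatment effects,
somatic contamination as a uniform pull toward somatic levels. Passing
recovery tests on it shows the pipeline is correct *given that
structure*. It does not establish robustness to features real sperm
methylomes can have and the generator omits: within-subject correlation
beyond the shared baseline profile (no subject random effect, so the
within-subject clumping visible in real principal-component plots is not
emulated), batch and position effects, probe-specific biases,
logit-scale heteroscedasticity, missing samples from post-treatment
azoospermia, and genuine biological covariance between neighbouring CpGs
(DMR structure here exists only where implanted). Conclusions about real
data still require the real data's own QC.

## Degenerate inputs and tie-breaks, in one place

* All betas equal at a probe: $F = 0$, $p = 1$; Tukey $p = 1$.
* Zero within-group variance, distinct means: $p = 0$ (ANOVA and Tukey).
* Region t test with both groups at zero variance: $p = 1$ if means are
  equal, else 0.
* Probes with fewer than two cohorts of two or more samples: statistics
  reported missing, counted in a skip log, never fabricated.
* Top-$k$ ties: larger $F$, then lexicographic probe id.
* DMR ranking ties: genomic order.
* Chi-squared at or below the continuity correction: statistic 0, $p$ 1.
* Empty coverage intersection: empty matrix with a warning, not an error.
* An ICR with no probes: reported missing with a warning, not an error.
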