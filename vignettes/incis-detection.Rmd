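---
title: "Detecting in-cis regulated miRNAs from copy number, methylation and expression"
author: "mircis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting in-cis regulated miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircis)
```

## The biological question and the model

miRNA expression in tumors can be altered by events at the miRNA's own
genomic locus: a change in DNA copy number, or a change in promoter CpG
methylation. Because one mature miRNA may be encoded at several loci, and
because miRNAs with identical seed sequence (positions 2–8 of the mature
sequence) form families with overlapping target repertoires, locus-level
reasoning matters: different family members on different chromosomes can be
alternately aberrant across patients while the family as a whole stays
activated ("complementary aberration pattern").

`mircis` formalizes the screen as follows. For each locus and tumor we
derive two categorical aberration axes — copy-number state in
{loss, neutral, gain} and methylation state in {hypo, normal, hyper} — and
then ask, per locus, whether expression differs between aberrant and
non-aberrant patients. Two scenarios are screened: *activating* (gain or
hypomethylation, expected to raise expression) and *silencing* (loss or
hypermethylation, expected to lower it), each in three categories: copy
number alone, methylation alone, and combined (any aberration of the
scenario type on either axis versus patients clean on both axes). The test
is the Wilcoxon rank-sum on normalized expression; p-values are adjusted by
Benjamini–Hochberg within each scenario × category family, i.e. across the
loci testable for that particular question. A locus is declared in-cis if
any of its six tests reaches q < 0.05 *and* passes a direction filter:
Spearman correlation of expression with copy number must be positive, or
with methylation negative, on every axis that contributed altered samples.
The direction filter encodes the causal expectation (more copies or an
opened promoter should not lower expression) and removes significant but
wrongly-signed associations.

The assumptions are modest: expression comparisons are rank-based (no
normality assumed); aberration calling assumes approximately unimodal β in
normal tissue per locus and piecewise-constant copy-number profiles;
independence across patients.

## Stage-by-stage parameters

### Expression

Log2 array intensities are normalized per sample by subtracting the
sample's 90th percentile across miRNAs (`percentile = 0.90`), after
removing miRNAs detected in fewer than 10% of samples
(`detection_fraction = 0.10`). The percentile uses linear interpolation
between order statistics (R's type 7) — the most common convention; the
definition matters only in the third decimal for realistic array sizes.
The detection filter runs first so that undetectable rows cannot drag the
percentile; the two operations nearly commute, but the chosen order is the
conservative one. The mature-level matrix is then expanded so every
genomic locus of a retained mature miRNA carries a copy of its expression
row; arrays cannot attribute a mature transcript to one of several encoding
loci, so all loci inherit the measurement and all subsequent analysis is
locus-keyed.

### Copy number

Log2 ratios are median-centered per sample (median rather than mean for
robustness to large aberrations; configurable) and segmented per sample and
chromosome with exact piecewise-constant fitting: minimize total
within-segment sum of squares plus γ per breakpoint. We solve the exact
O(n²) dynamic program rather than a heuristic — cohort sizes at desk scale
make this affordable (a 2,000-probe chromosome segments in a few
milliseconds in compiled code) and exactness lets tests compare against
brute-force enumeration. Ties in the objective break toward fewer
breakpoints, then earlier breakpoints, so output is deterministic. γ
defaults to 40 for discovery and 50 for lower-resolution replication
arrays. Because the conventional γ = 40 is calibrated for noise-normalized
data while our objective is on the raw log-ratio scale, `segment_cohort()`
scales the penalty by a per-track noise variance estimate — the squared MAD
of lag-1 differences divided by √2 (differencing removes the
piecewise-constant mean except at the rare breakpoints, and the MAD
resists those) — making γ comparable across tracks and platforms.
`pcf_segment()` itself takes the penalty literally, so oracle tests of the
objective remain exact. Missing probes are dropped from a track before
segmentation; segment probe indices refer to the retained order. Each
locus receives the mean of the segment whose probe span covers the locus
start (miRNAs are short; multi-segment spans are resolved by the start
coordinate), or the nearest segment when the locus lies outside all probe
spans. Gains are segment values strictly above +0.1, losses strictly below
−0.1; boundary values stay neutral.

### Methylation

Probes are assigned to loci by a three-tier hierarchy: (1) all
vendor-designated promoter probes of the locus; (2) if none and the miRNA
is intronic in a coding host gene, the host gene's proximal-promoter probes
(TSS1500 / 5′ UTR / first exon — gene-body and 3′ UTR probes are never
used); (3) otherwise the single nearest probe on the chromosome, with
equidistant ties broken toward the lower coordinate (deterministic; the
choice is arbitrary and affects only exact ties). Multi-probe loci take the
per-sample median β. Calling uses a normal-tissue reference per locus:
median *m* and sample standard deviation (n−1 denominator) of β in
normals; a tumor is hyper if β > m + k·SD, hypo if β < m − k·SD, with
k = 2 by default and strict inequalities throughout. When a threshold
leaves the admissible range — m − k·SD < 0 or m + k·SD > 1 — that side
cannot discriminate and the corresponding call is disabled for the locus
(the low-side case arises in practice for barely-methylated promoters with
noisy normals; the high-side rule is the symmetric generalization). k is
configurable so percent-methylation assays (pyrosequencing replication)
reuse the same operation after rescaling by 1/100. Loci with fewer than two
usable normals are excluded from methylation calling.

### Testing, replication and downstream scans

Groups below `min_group_size = 3` make a locus untestable for that
scenario/category and remove it from that family's BH denominator. The
reference group of a single-axis test is every sample lacking the focal
aberration on that axis — so losses sit in the reference of an activating
copy-number test; the procedure is a binary partition of patients per
question, and this choice keeps the partition exhaustive. The combined
reference is stricter: clean on both axes. Driver classes are assigned
deterministically: `copy_number` if only copy-number-category tests are
significant, `methylation` if only methylation-category tests,
`combination` if both single-axis categories are significant or only the
combined test is.

Replication re-runs each candidate's significant scenario/category tests in
the second cohort where the axis was measured, at uncorrected p < 0.05
(discovery already paid the multiplicity cost), requiring the same
aberration type and a passing direction filter. When two CpG assays cover
one promoter, each is tested separately and the larger p is reported — the
conservative choice. Candidates absent from the replication expression
matrix leave the denominator; candidates with no measurable axis are marked
unassessable.

Clinical scans use Wilcoxon for two-level variables and Kruskal–Wallis
(with tie correction) for grade, BH-adjusted across loci per variable and
per cohort; cross-cohort consistency requires significance in both cohorts
and concordant direction (direction concordance is configurable — the
requirement is the stricter reading of "consistently associated").
Survival uses a median split with samples exactly at the median assigned to
the low group (some tie rule is needed; with continuous expression and even
n this gives equal halves), and the standard two-group log-rank statistic
with hypergeometric variance for tied event times. miRNA–mRNA screening
selects pairs with |Spearman ρ| strictly above 0.3 per cohort and keeps
cross-cohort sign-consistent pairs. Functional screen hits use |0.2| on
normalized log2 viability and |z| > 1.96 on lysate endpoints z-scored
against the whole screen; plate-level Loess normalization of the viability
screen is upstream of this package, which consumes normalized values.

## The synthetic cohort generator

`generate_cohort()` builds everything the pipeline consumes, with known
truth. Defaults describe the study conditions the package is validated
under: 100 tumors and 17 methylation-reference normals; five chromosomes of
2,000 copy-number probes at 10 kb spacing; 500 miRNA loci of which 80 are
planted — 20 gain-, 20 hypomethylation-, 15 loss-, 15 hypermethylation-
driven and 10 driven by a combined gain/hypomethylation mechanism — each
altering 30% of tumors and shifting expression by 1.5 log2 units
(noise SD 0.5). Copy-number events are 81-probe segments (≈0.8 Mb) of
amplitude ±0.3 over Gaussian probe noise of SD 0.15; at the scaled default
penalty this length is detected with large margin while pure-noise tracks
stay unsegmented. Methylation events shift β by ±0.2 against clipped
Gaussian noise of SD 0.02 around per-locus baselines drawn uniformly from
[0.15, 0.75]. β noise is a clipped Gaussian rather than a Beta for analytic
transparency of the 2·SD rule (the calibration of a ±2·SD band is exact
under Gaussian noise); a Beta alternative would change tail calibration
only marginally at SD 0.02. Five seed families have two planted members
each with disjoint altered sample sets, mirroring the complementary
aberration pattern; five mature miRNAs are encoded at two loci to exercise
expansion; ten loci are intronic without designated probes and ten more
have only a nearest probe, exercising the assignment tiers. The clinical
table plants a TP53 and a subtype expression effect (+1.2 log2) on two
methylation-driven loci, survival follows an exponential model with
log-hazard −0.8 per standardized expression unit of one prognostic locus
with uniform censoring, and five mRNA genes per candidate miRNA are coupled
at ±0.8.

Twin cohorts for replication testing reuse a template bundle's annotation,
probe layout, baselines and mechanism truth while redrawing patients,
altered sets and all noise — shared biology, independent sampling.

What the generator does *not* emulate: tumor purity and subclonality,
batch and plate effects, probe-specific biases, correlated aberrations
between neighboring loci beyond shared segments, and the marginal
distributions of real array data. Passing the recovery tests therefore
demonstrates the statistical machinery is correct and calibrated under the
stated noise model, not that real-cohort sensitivity will match.

## Numerical and testing choices

All thresholds are strict inequalities; boundary values never trigger
calls. Missing values propagate and are never imputed. BH adjustment
treats untestable loci as absent (they do not inflate the denominator).
Floating-point caveat: the shift-invariance of copy-number calling holds
exactly only away from the cutoffs, since `x + c` need not be exactly
representable.

The test suite validates every statistical routine against an independent
oracle: exact PCF against brute-force enumeration of all breakpoint subsets
(signals up to length 12, 500 random cases), the rank-sum p against
exhaustive enumeration of group assignments (group sizes ≤ 8), BH against
the naive quadratic definition, Spearman against mid-rank-then-Pearson,
the log-rank statistic against a hand-computed observed-minus-expected
table, and Kruskal–Wallis against the definitional H with an exhaustive
relabeling check of the chi-square approximation. End-to-end properties
run at the default study conditions: planted-mechanism recovery and
mechanism labeling over five seeds, replication over five twin pairs, and
FDR calibration on 20 null cohorts (aberrations planted, expression effect
zero, so every test runs under its null). These problem sizes keep the full
suite in the minutes range on one core while giving binomial tolerances
tight enough to detect miscalibration.

## Known limitations

* The exact dynamic program is O(n²) per track; for millions of probes per
  chromosome a heuristic segmenter would be needed.
* Reference groups of single-axis tests include samples aberrant in the
  *opposite* direction; with frequent opposite aberrations this dilutes
  the contrast (and is the documented interpretation of the binary
  partition).
* Driver classification is rule-based on test significance, not a formal
  variance decomposition; "combination" in particular inherits the
  combined test's sensitivity.
* No tumor-purity correction: β and log-ratio shifts are attenuated in
  impure samples, which lowers call rates rather than biasing direction.
* Survival analysis is a single-locus median-split log-rank; no
  multivariate or proportional-hazards modeling.
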