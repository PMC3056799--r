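---
title: "Two-experiment replication analysis of alcohol-exposed embryo microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-experiment replication analysis of alcohol-exposed embryo microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicaseq)
```

## The analysis problem

Whole-embryo culture studies of early alcohol exposure hybridize RNA from
single embryos to expression arrays in very small groups — four controls
against a handful of treated embryos, the treated arm further split by
neural-tube phenotype into closed (ALC-NTC) and open (ALC-NTO) subgroups.
At these sample sizes no single experiment supports aggressive
multiple-testing correction without drowning in false negatives. The
design this package implements instead runs **two independent
experiments** on nested array platforms (the smaller platform's probe sets
are a strict subset of the larger's) and controls error by **replication**:
a gene counts only if it is significant in *both* experiments *with the
same direction of change*.

The package provides every stage as a tested, reusable function:

1. **Detection-call filtering** — only probe sets called Present (MAS5
   "P") on at least half of the arrays of at least one condition enter the
   analysis.
2. **Welch differential expression** — per-probe Welch's *t* on log2
   signals for each of the four contrasts (control vs pooled alcohol, vs
   NTC, vs NTO, and NTC vs NTO), with signed fold changes.
3. **Directional intersection** — replication across experiments with an
   analytic null and an overlap FDR.
4. **On/off presence calls** — genes Present in one arm and Absent on
   *every* array of the other.
5. **A from-scratch GSEA engine** — unweighted running-sum enrichment
   scores, permutation p-values, leading-edge extraction, and a set-level
   cross-experiment replication FDR.
6. **Array clustering** — average-linkage trees meant to recover the
   three phenotype groups.
7. **qRT-PCR confirmation** — ΔΔCt and standard-curve relative
   quantification with ANOVA / pairwise *t* group comparison.

A synthetic-data generator emulates the two-platform design so the whole
pipeline is exercised end-to-end without any external data.

## The replication model

Let each experiment test a common universe of $n$ genes at per-experiment
threshold $\alpha_i$. For a null gene, significance in both experiments
with concordant direction has probability

$$p_{\text{joint}} = \alpha_1 \, \alpha_2 \, \tfrac{1}{2},$$

which is 0.00125 at the default $\alpha_1 = \alpha_2 = 0.05$. The expected
chance overlap is $n \, p_{\text{joint}}$ (for example, 13,810 common genes
give 17.26, displayed as 17), and the replication FDR is

$$\text{FDR} = \frac{\text{expected null overlap}}{\text{observed overlap}}.$$

The same arithmetic applies at the gene-set level: a campaign of
$n_{\text{contrasts}} \times n_{\text{sets}}$ GSEA tests (4 × 606 = 2424
with the default two-database collection) expects
$2424 \times 0.05^2 / 2 \approx 3$ chance-shared sets.

`directional_intersection()` reports the unrounded expectation alongside a
nearest-integer display value, and reports the FDR as undefined (`NA`)
rather than 0 when nothing is observed.

## Statistical choices and their rationale

**Welch's test, not pooled-variance t.** Biological variance differs
between control and alcohol-treated embryos; the unequal-variance form is
the study's own choice. `welch_test()` delegates to `stats::t.test`; the
per-matrix path (`differential_table()`) uses an equivalent vectorized
row-wise implementation, tested against `stats::t.test` to 1e-10. A
degenerate probe with zero variance in both arms and equal means returns
$t = 0, p = 1$.

**Small-sample conservatism.** With four arrays per arm the
Welch–Satterthwaite approximation is conservative: the realized
false-positive rate at $\alpha = 0.05$ falls slightly below 0.05 (the
random estimated df is at most, and usually below, the equal-variance df).
The calibration tests therefore band the empirical per-experiment rate at
0.05 ± 0.01 and the empirical joint directional rate within three binomial
standard deviations of the analytic 0.00125, and the pooled null estimate
is expected to sit *below* 0.00125 rather than on it. This is a property
of the method itself, faithfully reproduced, not an implementation
artifact.

**Fold changes.** Computed as the difference of group means of log2
signals (a geometric-mean ratio), then mapped to the signed convention
used throughout this literature: ratios below 1 are reported as
$-1/\text{ratio}$, so a halving is −2.0 and $|\text{fold}| \ge 1$ always.
The alternative (ratio of arithmetic means) is deliberately not offered as
a default; the log-scale estimator matches the test statistic's scale.

**"At least half" with an odd group.** Interpreted strictly as
$\text{count} \ge \lceil n/2 \rceil$ (4 of 7), the tightest reading;
`half_rule = "floor"` is available for sensitivity analysis. Marginal
("M") calls count as not-present everywhere. The filter is applied once,
on the control condition and the pooled alcohol condition; per-group
conditions (used for the clustering universe) are available via
`per_group_conditions()`.

**On/off calls.** "Off in treated" demands Present under the
$\lceil n/2 \rceil$ rule in the reference arm and Present on *zero*
test-arm arrays — the strictest consistent reading. The attached p-value
is the Welch p of the same contrast by default; a Fisher-exact mode on the
Present/Absent counts is provided because the provenance of printed
on/off p-values in this design is ambiguous.

## The GSEA engine

The ranking metric (default Welch *t*, signal-to-noise optional) is
oriented so positive scores mean higher in the reference (control) arm;
probes collapse to genes by maximum absolute metric with lexicographic
tie-breaking. The enrichment score is the **unweighted Kolmogorov–Smirnov
running sum**: each member hit adds $1/n_{\text{hits}}$, each miss
subtracts $1/(N - n_{\text{hits}})$, and the score is the *maximum* of the
running sum — a one-sided, top-enrichment-only statistic. The running sum
telescopes to zero at the end of the list, which the tests assert to
1e-9. The **leading edge** is the set members at ranks up to the peak.
The weighted 2005-style statistic is intentionally out of scope.

To test enrichment in the other arm the ranking is reversed
(`reverse_ranking()`); both orientations are evaluated and each (set,
contrast, experiment) reports the orientation with the smaller p-value as
its `enriched_in` direction. The set-level expected-overlap formula
$n_{\text{tests}} \alpha^2 / 2$ counts each (set, contrast) once, exactly
as the worked arithmetic above does; because the direction is itself
selected as the better of two one-sided tests, that formula slightly
understates the true chance-sharing rate. We keep the printed arithmetic
(it is the quantity practitioners of this design report) and note the
conservatism here; the end-to-end test verifies that non-planted sharing
stays below 1% of set-contrast pairs on the default synthetic design.

**Permutation null.** Default mode draws random member sets of the same
size from the ranked universe (`mode = "gene"`) with
$p = (1 + \#\{\text{null} \ge \text{observed}\}) / (1 + n_{\text{perm}})$,
$n_{\text{perm}} = 999$, so the smallest attainable p is 0.001. Since this
null depends only on the universe size and the member count, campaigns
cache the null draws per (N, k), which is what makes a 2 × 4 × 606-test
campaign fast. Phenotype permutation (`mode = "phenotype"`) relabels the
contrast's arrays and recomputes the ranking; with four arrays per arm
only $\binom{8}{4} = 70$ distinct relabellings exist, so the
implementation enumerates them exhaustively (exact p, floor 1/70) instead
of sampling. That degeneracy is why gene permutation is the default at
these group sizes. A seed is mandatory wherever permutation runs.

## The synthetic-data generator

`simulation_config()` defaults encode the study conditions: 20,000
platform-B probe sets of which 13,810 form platform A; experiment 1 with
4 controls, 2 NTC, 2 NTO arrays; experiment 2 with 4 controls, 3 NTC,
4 NTO; a 606-set collection split 415/191 across two database labels.
Signals are log-normal — per-probe baselines
$\mathcal{N}(6.6, 2.0^2)$ on the log2 scale, per-array noise sd 0.25 —
stored on the MAS5-style natural scale; all statistics re-log them.
Detection calls are Present iff the log2 signal reaches the threshold
(default 6.0), then flipped symmetrically with probability 0.05 to model
borderline-call noise. With these values roughly 60–70% of probe sets
survive the present filter, the regime such experiments report.

Planted structure, all on the shared platform and mutually disjoint:

* **300 down- and 200 up-regulated probes**, shifted by 1.0 log2 unit
  (2-fold, four noise sd) in every alcohol array of *both* experiments —
  one shared ground-truth effect, which is what the replication logic
  assumes. The counts echo the few-hundred-per-experiment scale of
  detected changes in this design; 4σ effects give the intersection
  enough power that the ≥ 90% recovery property holds with margin.
* **150 NTO-specific probes**, down-shifted only in ALC-NTO arrays. These
  give the two alcohol phenotypes distinguishable profiles, mirroring the
  reported subgroup-specific alterations; without them a three-way
  clustering of the alcohol arm would be impossible by construction.
* **10 "off" probes**: baseline forced comfortably above the detection
  threshold in controls and pushed two log2 units below it in every
  alcohol array. These probes are exempt from call-flip noise so the
  planted on/off truth is exact — the flip noise models borderline calls,
  and a forced-absent probe is not borderline.
* **5 enriched sets** whose members are coherently down-shifted by 0.5
  log2 units in all alcohol arrays. Null sets draw members from the
  *whole* gene universe: real GO collections contain affected genes, and
  restricting null sets to untouched genes would deplete them from the
  top of the ranking and manufacture spurious opposite-direction
  enrichment.

All planted probes have baselines forced above the detection threshold,
since differential expression is only observable for expressed
transcripts. Identical seeds give bit-identical output.

`null_simulation_config()` is the calibration variant: no planted
effects, 4 vs 4 in both experiments, 20,000 shared probes (platform B
carries 5% extra to stay a strict superset), and a high baseline so that
nearly the whole universe passes the filter — calibration measures
test-statistic behaviour, not detection physics, and a large surviving
universe keeps the Monte-Carlo error small.

What the generator does **not** emulate: probe-level PM/MM intensities,
normalization/condensation, batch or litter effects, correlated noise
between probes of one gene, platform-specific intensity scaling, and
between-experiment effect heterogeneity. Passing the recovery tests
therefore demonstrates the pipeline's statistical machinery, not
robustness to those real-data complications.

## Clustering and qPCR stages

Arrays are clustered by average linkage (UPGMA via `stats::hclust`) on
1 − Pearson correlation of log2 signals (Euclidean optional), over the
per-group present universe. Samples are sorted by id before clustering so
input order cannot influence tie-breaking; a constant profile is an error
naming the offending sample. Trees serialize to Newick through `ape`.

ΔΔCt quantification normalizes each sample's target Ct against the
reference gene (Gapdh by convention) measured in the same sample, then
against the control-group mean; relative quantity is $2^{-\Delta\Delta
Ct}$ with the same signed-fold mapping as the array folds. Aggregation is
by per-sample mean Ct by default, with a per-replicate mode, since the
replicate/experiment nesting of such designs is rarely stated. ΔΔCt is
invariant to per-sample machine offsets, which the tests assert. The
standard-curve method fits $Ct = a \log_{10}(\text{amount}) + b$ by least
squares, requires three points spanning two decades, rejects flat curves
($|a| < 0.1$), and reports the amplification efficiency $10^{-1/a} - 1$
for QC. Group comparison is classic one-way ANOVA followed by pairwise
pooled-variance *t* (with two groups, $F = t^2$ exactly); an exactly
zero between-group variance reports $p = 1$.

## Numerical conventions and degenerate inputs

* Signals are floored at 1.0 before log2 (MAS5 signals can be ~0); the
  floor is configurable and every transform round-trips above it.
* p-values are clamped into $(0, 1]$; a zero-variance unequal-means probe
  gets $t = \pm\infty$ and the smallest representable p rather than 0.
* All result tables are written tab-separated, UTF-8, LF, ordered by
  ascending p with ties broken by id, so reruns are byte-identical;
  `manifest.json` records the config hash, seed, thresholds and per-stage
  record counts, and deliberately no timestamps.
* Ranking ties break lexicographically by gene id; ES peak ties take the
  first (left-most) position.

## Problem sizes used by the checks

The package's own test suite runs most properties on compact fixtures
(hundreds of probes) and the end-to-end recovery checks on the full
default design (20,000 probes, 606 sets, 999 permutations), sizes chosen
so the whole suite completes in well under a minute on one core while the
Monte-Carlo bands stay tight. The acceptance script pools five null pairs
of 20,000 shared probes each — about 10^5 tested genes — to estimate the
null directional-replication fraction.

## Known limitations

* The analytic overlap null assumes independent experiments and exact
  per-test level $\alpha$; the Welch small-sample conservatism described
  above makes the realized level slightly lower, so empirical null
  overlap sits a little below the analytic expectation at n = 4.
* Set-level expected sharing uses the printed $\alpha^2/2$ arithmetic and
  so understates chance sharing under two-orientation selection (above).
* Gene-level replication matches probe sets by id across the nested
  platforms; gene-symbol matching is available in the annotation but
  multiple probe sets per gene are reported, not collapsed, at the
  replication stage.
* The qRT-PCR module's correctness surface is analytic and synthetic;
  wet-lab fold-change tables from the motivating design are inputs this
  package cannot regenerate.
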