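---
title: "Community-aggregated rrn copy-number traits: models and methods"
author: "rrntraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-aggregated rrn copy-number traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrntraits)
```

## The trait and why it matters

Bacterial genomes carry between 1 and 15 copies of the ribosomal RNA
operon (rrn). Copy number correlates with maximum growth rate and lag
time: taxa with few copies tend to grow slowly but use resources
efficiently (oligotrophs), taxa with many copies grow fast but
wastefully (copiotrophs). Averaged over a community and weighted by
abundance, the trait becomes a compact summary of the community's growth
strategy, and its trajectory through time tells you which strategy
dominates each stage of succession — for example during biofilm
formation on a stream bed.

`rrntraits` implements this analysis end to end for 16S amplicon OTU
tables:

1. **Assignment** (`assign_rrn()`): each OTU inherits the integer copy
   number of its genus from a lookup table of genus-level mean copy
   numbers. Database means are fractional, so they are rounded to the
   nearest integer (half-up) and clamped into [1, 15]. Half-up rather
   than ceiling is the default because ceiling would systematically
   inflate the trait — genera whose database mean sits just above an
   integer (say 2.1) are conventionally reported at that integer
   (rrn = 2); a `method = "ceiling"` switch exists for comparison.
   OTUs whose genus is unknown or missing from the lookup are *reported*
   as unassigned, never silently dropped.
2. **Binning**: assigned OTUs with 1–3 copies form the low-copy-number
   class (LCN), those with 4–15 the high-copy-number class (HCN). The
   two classes partition the full biological range.
3. **Aggregation** (`trait_profile()`, `trait_profiles()`): per sample,
   the summed relative abundance of each class, their ratio HCN:LCN, the
   abundance-weighted community mean copy number
   $\mathrm{CWM} = \sum_i p_i \, r_i$, the unweighted mean over taxa
   present, and the number of distinct genera with non-zero abundance in
   each class.
4. **Succession** (`trajectory()`): replicate means ± sd per time point,
   with each time point labelled *initial* (≤ 25 days, inclusive and
   configurable) or *late*.
5. **Growth kinetics** (`fit_logistic()`): lag phase and maximum growth
   rate from bulk cell counts, regressed against the trait ratio with
   OLS (`regress_trait_growth()`).
6. **Inference**: a migrant-pool resampling null
   (`migrant_pool_null()`), one-way ANOVA with Tukey HSD
   (`anova_tukey()`), Mann–Whitney U (`mann_whitney()`), Bonferroni
   (`bonferroni()`).

## Numerical and design choices

### Renormalization over assigned core OTUs

Trait profiles are computed, by default, on relative abundances
renormalized over the assigned (and, if given, core-genus) OTUs. This
makes LCN + HCN a partition of unity and makes the HCN:LCN ratio
insensitive to how much of the community could not be assigned — the
discarded fraction cancels from the ratio. Passing
`renormalize = FALSE` keeps whole-sample denominators instead, in which
case LCN + HCN equals the assigned fraction rather than 1. The weighted
mean is always normalized by the total assigned abundance, so it stays
in [1, 15] in both modes.

### Core genera

A genus is "core" when it is detected in every dataset under
comparison; detection defaults to at least one read in at least one
sample (`min_count = 1`, `min_prevalence = 1`), both exposed because
detection thresholds are a perennial judgement call in amplicon data.
The sentinel genus `unassigned` can never be core.

### Presence-based community mean

The unweighted "presence" mean can be taken over OTUs (default) or with
each genus collapsed to a single value first
(`presence_by = "genus"`). Both are offered because community means
over taxa present are reported in the literature without stating the
unit; with one OTU per genus the two coincide.

### Rarefaction

`rarefy()` subsamples each sample without replacement (multivariate
hypergeometric, delegated to `vegan::rrarefy()`), which is the standard
treatment of count tables: sampling with replacement would allow a read
to be counted twice. Samples below the target depth are dropped with a
warning — padding would fabricate reads. The depth is a required
argument with no default; there is no universally right value, it
depends on the survey's sequencing effort.

### The logistic growth model

Growth curves are fitted with the Zwietering re-parameterized logistic

$$ f(t) = \frac{A}{1 + \exp\!\big( \tfrac{4\mu_{\max}}{A}(\lambda - t) + 2 \big)} $$

chosen because its parameters *are* the quantities of interest: $A$ the
asymptote, $\mu_{\max}$ the maximum slope, $\lambda$ the lag phase
(tangent-line construction). Gompertz and Richards alternatives are out
of scope. Fitting is bounded Levenberg–Marquardt least squares on raw
values (a `log_transform` flag exists), initialized from the data
($A_0 = \max y$; $\mu_0$ = the steepest finite-difference slope;
$\lambda_0$ = the time of that slope minus $A_0 / 2\mu_0$, clipped at
0), with up to 5 seeded, jittered restarts. Non-convergence — as for a
constant series, or a fitted lag beyond the observation window — is
flagged (`converged = FALSE` with best-so-far parameters), never an
exception, so that batch fitting over many flumes does not abort.
Parameter-recovery tests sample each synthetic curve through saturation
(times up to $\lambda + 2A/\mu_{\max}$): a slow curve observed only in
its early exponential phase leaves $A$ practically unidentified, which
is a property of the design, not the optimizer.

### The migrant-pool null

To ask whether an observed community mean copy number could arise from
random assembly, `migrant_pool_null()` repeatedly draws 150 OTUs (the
conventional subsample) from the shared genus pool and records each
draw's mean. Draws are without replacement — a "sample of migrants from
the pool" reads as subset selection — with a `replace = TRUE` switch.
The two-sided empirical p uses the add-one convention,
$p = \big(1 + \#\{|m_i - \bar m| \ge |m_{\mathrm{obs}} - \bar m|\}\big) / (n_{\mathrm{rep}} + 1),$
so p is never exactly 0 from a finite resample.

### Degenerate inputs in the test machinery

* ANOVA with zero within-group variance but a real between-group
  difference reports the smallest representable positive p with a
  warning rather than failing on a 0/0.
* `mann_whitney()` uses midranks throughout; with a combined sample
  size of at most 12 the two-sided p comes from exhaustive enumeration
  of all group-label assignments — a permutation test that remains valid
  under ties — otherwise from a normal approximation with tie-corrected
  variance and continuity correction. All-tied data give p = 1
  (variance 0).
* The HCN:LCN ratio of a sample with zero LCN abundance is undefined
  (`NA`), never $+\infty$; `trajectory()` skips undefined values with a
  warning and a reduced replicate count.
* OLS on a numerically constant response reports $R^2 = 0$ and p = 1
  instead of the round-off ratio the naive formula produces.

## What the synthetic generator emulates

`generate_succession()` builds the kind of data the pipeline expects,
with known truth: 60 genera whose copy-number spectrum is
LCN-dominated with a mode at rrn 2 and a small rrn-9 tail (8, 18, 14,
6, 8, 2 and 4 genera at rrn 1, 2, 3, 4, 5, 6 and 9), mirroring the
composition typical of stream biofilm core communities; 3 OTUs per
genus; genus base abundances from a geometric rank-abundance series
(k = 0.05), a simple long-tailed model; counts Dirichlet-multinomial at
depth 10⁴ with concentration 200, because rarefied amplicon tables are
overdispersed multinomials; 8 sampling days across a 45-day window with
3 replicate flumes per regime and day. The "eutrophic" regime starts
with its HCN taxa boosted by a factor $1 + b\,e^{-0.1 t}$ with
$b = 1$: roughly a 1.7-fold HCN excess at day 4 decaying to ~8% by day
25, so the two regimes converge after the initial phase. Setting
$b = 0$ in both regimes is the null scenario. `generate_streams()`
applies a static HCN scaling $e^{\text{shift}}$ per habitat group
instead of a time decay, emulating a two-stream-type comparison.

What the generator does **not** emulate: phylogenetic structure among
genera, sequence-level artefacts (chimeras, OTU-picking noise),
hydraulic effects (regimes are abstract labels), and the real
magnitudes of the succession effect, which the source experiments do
not report — boost and decay were chosen for testability. Passing
tests therefore demonstrate that the pipeline recovers trait dynamics
*of the assumed compositional form* from overdispersed counts; they do
not validate the upstream bioinformatics or the effect sizes of any
particular stream.

## Problem sizes used in the validation suite

Parameter-recovery uses a 12-point noiseless grid plus 50 noisy curves;
null-distribution calibration uses 2000 simulated tests at 200
resamples each; end-to-end succession recovery uses 50 seeded
generator runs at depth 10⁴ (48 samples, 180 OTUs each). These sizes
give Monte-Carlo error comfortably inside the asserted margins while
keeping the whole suite around a minute on one core.

## Worked example

```{r example}
sim <- generate_succession(succession_config(), seed = 42)
prof <- trait_profiles(sim$tables$eutrophic, sim$taxonomy, sim$lookup)
trajectory(prof, "ratio_hcn_lcn", phase_cut = 25)
```

The initial-phase ratios exceed the late-phase ones — the imprinted
early HCN enrichment — and the replicate standard deviations reflect
the Dirichlet-multinomial noise.

## Known limitations

* Genus-level assignment imputes one copy number to every OTU of a
  genus; within-genus variation is invisible by construction.
* No 16S copy-number correction of abundances is performed (the
  analysis studies the trait distribution; correcting counts *by* the
  trait would be a different, and circular, preprocessing step).
* BIOM-HDF5 and other binary formats are not read; inputs are
  plain-text TSV.
* The trait–growth regression treats each experimental unit's
  time-averaged ratio as one point; the unit of replication is the
  caller's choice.
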