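---
title: "Quantifying gut microbiota maturity and dysbiosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut microbiota maturity and dysbiosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gutmaz)
```

This vignette documents the models implemented in `gutmaz`, the
parameter choices that matter, what the synthetic cohort generator does
and does not emulate, and the numerical decisions taken where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The scientific question

A child's gut community matures along a fairly reproducible trajectory:
strict anaerobes and fiber degraders (e.g. *Faecalibacterium*,
*Bacteroides*, *Ruminococcus*) expand through early childhood, while
early colonizers (*Bifidobacterium*, *Veillonella*, *Lactobacillus*)
recede. Chronic disease can stall this program. The package quantifies
that stall as a **microbiota age** — the chronological age a model
trained on healthy children assigns to a sample from its genus
profile — and as the **microbiota-for-age Z score**

$$\mathrm{MAZ} = \frac{\text{microbiota age} - \text{median microbiota
age of healthy same-age reference}}{\text{s.d. of microbiota age of the
healthy same-age reference}}.$$

Negative MAZ means the community looks younger than the child is.

## Table processing

* **Prevalence filter**: OTUs carrying less than 0.001% (1e-5) of the
  grand-total read count are dropped.
* **Averaged rarefaction**: the target depth is
  $d = \lfloor 0.9 \times \min_i \mathrm{depth}_i \rfloor$. Each
  sample is subsampled *without replacement* (multivariate
  hypergeometric) to $d$ reads, 100 times, and the counts averaged.
  Because each resample draws exactly $d$ reads, the pre-rounding mean
  depth is $d$ exactly — a tested invariant. The averaged entries are
  rounded per-entry, half-to-even (base R `round`); the rounding rule
  and the per-entry (rather than renormalize-first) choice were open
  and are our decisions.
* **Genus collapsing** sums member-OTU counts exactly; OTUs without a
  genus assignment are pooled into an explicit `unassigned` column so
  count conservation stays testable. How unassigned taxa were handled
  upstream of genus-level analyses is generally unstated in published
  pipelines; pooling is our choice.

## Ecology statistics

Shannon diversity uses the base-2 logarithm (the QIIME convention; a
`base` argument switches to natural log). Simpson is $1-\sum p_i^2$.
Chao1 uses the classic form $S_{obs} + F_1^2/(2F_2)$ with the standard
$F_2=0$ correction $S_{obs}+F_1(F_1-1)/2$; note that `vegan::estimateR`
reports the *bias-corrected* Chao1, so the two agree only when
singleton/doubleton counts make them coincide — the test suite
therefore oracles ACE (identical formula) against vegan but checks
Chao1 against its closed form.

PERMANOVA computes the pseudo-F from among/within sums of squared
Bray–Curtis distances and a *free* permutation null,
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$; no restricted
permutation strata are offered because the analyses in scope do not use
them. An explicit permutation matrix can be supplied, which switches to
exact enumeration (used by the tests to agree with a brute-force oracle
at $n=6$). Per-factor $R^2$ doubles as the effect-size measure where a
full environmental-fit analysis would otherwise be used; this is a
declared stand-in.

The read-level QC filter (length < 150 bp, mean Phred < 20, any
ambiguous base, mononucleotide run > 8 bp) is provided for FASTQ input
but is optional: the pipeline's universal entry point is the OTU table.

## Microbiota age by random forest

No random-forest package is assumed; `gm_random_forest()` is a compiled
CART forest (bootstrap bagging, `mtry` random features per split,
variance/Gini splitting, impurity importance, out-of-bag predictions)
seeded through R's RNG for exact reproducibility. Defaults follow field
practice: 500 trees and `mtry = p/3` for regression, 1000 trees and
`mtry = sqrt(p)` for classification.

Age-discriminatory genera are ranked by their *mean importance rank*
across 100 forests with different seeds; the panel size defaults to 30
but is configurable (published counts for such panels vary between
sources, e.g. 30 vs 31, so no count is asserted). Stratified models use
the four chronological bands <3, 3–9, 10–18, >18 years (left-closed;
the printed "3–9"/"10–18" bands are interpreted as [3,10) and [10,19)
so the bands tile the axis). The same bands are the default MAZ
reference strata — the appropriate granularity of "same chronological
age" is unstated in the field's descriptions, and four bands keep every
stratum's reference s.d. estimable at desk-scale n. Out-of-bag $R^2$
is the reported explained variance (out-of-bag vs held-out was an open
choice; OOB is labeled as such), and out-of-bag predictions also supply
the healthy reference, since they share the held-out samples' shrinkage
and so avoid the in-sample bias a naive reference would have.

## The image encoder and CNN

The encoder turns one sample into a 3-channel $L \times L$ image
(default $L=256$, i.e. up to 65 536 OTU pixels):

1. **Layout** (computed once per dataset): genera are placed by
   descending mean relative abundance, except that whenever a placed
   genus has retained correlation partners (|Spearman ρ| > 0.75,
   strict) not yet placed, those partners are placed immediately after
   it, depth-first, in descending abundance. The published rule
   ("positioned according to their abundance and correlations, ranging
   from high to low") does not define a total order; this
   partner-insertion rule is our deterministic completion, and the
   layout carries a content hash so determinism is testable. Each genus
   receives a contiguous row-major pixel block sized to its retained
   OTU count, OTUs ordered by descending total abundance.
2. **Intensity**: relative abundance $a$ maps through
   $t = \mathrm{clamp}(2(\log_{10}a - \log_{10}\epsilon)/(-\log_{10}
   \epsilon) - 1, -1, 1)$ with floor $\epsilon = 10^{-6}$ and $a=0$
   pinned to $t=-1$, then to pixel $\mathrm{round}((t+1)/2 \times 255)$.
   So $a=0 \mapsto 0$, $a \ge 1 \mapsto 255$, monotonically — the
   stated [−1, 1] log range is achieved exactly for abundances in
   $[10^{-6}, 1]$.
3. **Channels**: (1) per-OTU intensity, (2) the genus' summed abundance
   broadcast over its block, (3) the genus' maximum retained |ρ|
   scaled to 0–255 broadcast over its block. Whether the three
   published matrices were stacked or tiled, and whether correlations
   were signed, was unstated; stacking and absolute values are our
   choices.

Age-bin classes enumerate the published spans (0–1 y monthly, 1–2 y
every 2 months, 2–4 y every 3 months, 4–10 y yearly, 10–22 y every 2
years, 22–40 y every 3, 40–70 y every 5, 70–102 y every 8);
straightforward enumeration yields 54 left-closed right-open intervals
(the printed total of 52 is not recoverable from the printed spans, so
no count is asserted and custom breaks are accepted). When training
ages are supplied, adjacent underfilled bins merge until each holds at
least `min_count` samples (default 100, matching the published
guarantee; desk-scale tests lower it).

The classifier is a deliberately small CNN — two convolutions (8 and 16
filters, stride 2) with ReLU, a dense softmax head, minibatch SGD with
momentum — implemented in plain R via im2col matrix multiplication.
A 23k-sample ResNet50 at 256×256 is out of desk scale; the encoder,
binning, and **median-of-top-3** aggregation (microbiota age = median
of the three highest-probability bins' midpoints) are the parts with
scientific content and are preserved exactly. Tests run at $L=64$ with
6 bins. Training is deterministic given the seed (single-threaded).

## Dysbiosis statistics

Per-feature association uses a linear model of arcsin-√ relative
abundance on group + covariates with BH-FDR across features — a
transparent stand-in for multivariable association frameworks whose
internal normalizations are not in scope; `logtss` is available as an
alternative transform. Constant features are declared non-associations
(coefficient 0, p 1) rather than NaN.

Co-occurrence networks compute all-pairs Spearman ρ with asymptotic
t-approximation p-values, BH across pairs, and keep edges with
q < 0.05 **and** |ρ| > 0.1, reporting signed edge counts. Networks are
built within a clinical group, mirroring the healthy/disease two-panel
convention.

Classification AUC uses stratified tenfold cross-validation (fold
assignment seeded and reported) of the 1000-tree forest; AUC is the
Mann-Whitney rank statistic with midrank ties.

## Mediation

The mediator is the fitted probability of a logistic regression of the
treatment label on a genus panel's abundances; perfect separation is
caught and the model refit with a small ridge penalty so scores remain
in (0, 1). For the structural model, treatment, mediator, outcome, and
continuous covariates are z-scored; path $a$ is the treatment
coefficient in the mediator regression, $b$ and $c'$ come from the
outcome regression, and the indirect effect is $a \cdot b$ with a
percentile bootstrap (default 5000 resamples; degenerate resamples are
redrawn and counted). The original analysis used a structural-equation
package with unstated estimator details; we default to a **linear
outcome model** so the decomposition $total = c' + a\cdot b$ is an
exact, testable identity, and expose a logistic-outcome option whose
$b$, $c'$ are on the log-odds scale (no exact decomposition — `total`
is `NA` there). SEM fit indices (χ², CFI, …) are artifacts of that
software's model and are deliberately not computed.

## The synthetic cohort generator

`simulate_counts()` draws ages uniformly (default 0–20 y, matching a
pediatric skew), disease with prevalence 0.3, and covariates (sex, BMI
with a mild age slope, district, uncooked-cornstarch use concentrated
in the disease group). Each genus follows a log-weight trajectory by
class:

* `age_discriminatory`: logistic rise with age, level-scaled in
  disease (default panel: ×0.4 depletion);
* `stunted_colonization`: the same rise with the midpoint delayed
  `disease_delay` years in disease (default 6);
* `disrupted_colonization`: a Gaussian bump, suppressed in disease;
* `persistent_overgrowth`: flat in health, ×8 in disease (mirroring
  oral-taxon expansion);
* `background`: constant.

Weights are normalized to compositional means, counts drawn
Dirichlet-multinomial with concentration θ = 50 at depths uniform on
5000–20000, and genus counts split over 10 OTUs by a fixed geometric
series (ratio 0.6). θ = 50 gives visible overdispersion relative to
multinomial while keeping per-genus means recoverable at n = 500 — the
published work states no noise model, and the Dirichlet-multinomial is
the field's standard choice. Row sums equal drawn depths exactly.

The mediation simulator builds $M = aT^{std} + \gamma^\top C + e$ with
noise variance set so $\mathrm{Var}(M)=1$, and the continuous outcome
$Y = bM + c'T^{std} + \delta^\top C + e_Y$ with the noise variance
subtracting the covariance terms ($2abc'$, $2b\gamma^\top\delta$) so
$\mathrm{Var}(Y)=1$ and the standardized estimator recovers $a, b, c'$
consistently. A binary flag is additionally drawn from a logistic link
with the same linear predictor. The consistency acceptance check uses
the continuous outcome: with a binary outcome any linear-probability
coefficient is attenuated by construction, so a ±0.05 recovery of
$a\cdot b$ is only a coherent expectation under the linear outcome
model (see the decisions ledger).

**What the generator does not emulate**: longitudinal sampling, strain
level variation, raw reads, batch effects, non-uniform age pyramids,
and realistic phylogenetic correlation between genera. A green test
therefore establishes that the estimators recover the stated
statistical structure — not that they would behave identically on any
particular real cohort.

### Interpreting trajectory recovery

Because abundances are compositional, a genus whose *absolute* weight
rises can still fall in *relative* abundance when the denominator
rises faster. The slope-recovery invariant is therefore tested on the
additive log-ratio to the background-genus mean, which removes the
common denominator and recovers every planted slope sign at n = 500.

### The delayed-maturation world

The directional MAZ acceptance check simulates stunted maturation by
delaying *every* maturation ramp's midpoint 8 years in disease. With
reference s.d.s of roughly 1–3 years per stratum this is a ≥2 s.d.
lag for children old enough to express it; evaluation is restricted to
ages ≥ 4 because an 8-year midpoint delay is invisible in an infant
whose ramps have not started in health either. Under that world the
mean disease MAZ computed by the tests is below −1 with a one-sided
Wilcoxon p ≪ 0.01 against held-out healthy samples.

## Numerical choices and degenerate inputs

* All permutation p-values have resolution $1/(n_{perm}+1)$ and use a
  $10^{-12}$ tolerance when comparing permuted to observed statistics.
* Constant genera get no correlation edges (warning), zero-variance
  features are declared non-associations, all-zero abundance vectors
  predict the forest's mean response, and zero-depth samples are
  rejected by name everywhere.
* The layout hash is a 32-bit FNV-1a implemented with 16-bit split
  multiplication so double precision is never exceeded.
* Forest and CNN fits consume R's RNG only, so `set.seed()` (or the
  `seed` arguments) make every result bit-reproducible on one machine
  with single-threaded BLAS.

## Known limitations

* The CNN is a desk-scale stand-in; no claim is made about matching a
  deep residual network's accuracy, and its headline validation
  metrics from the original large-cohort setting are explicitly out of
  scope.
* UniFrac (and any phylogeny-aware metric) is out of scope — no tree.
* The per-feature association model is a stand-in, not a reimplementation
  of any specific multivariable framework.
* Cohort-specific published values (group AUCs, network edge counts,
  the cohort's indirect effect of 0.14) require controlled-access data
  and are not reproduction targets; the acceptance suite is
  property-based instead.
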