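---
title: "Measuring regional shifts in crop taxonomic and phylogenetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring regional shifts in crop taxonomic and phylogenetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Large-scale agricultural statistics report, for each region and year, the
area harvested (in hectares) of each *commodity group* — a reporting unit
such as "wheat" or "Vegetables, fresh nes" that maps to one or more crop
species. From such a panel, `cropshift` asks four questions:

1. How has the diversity of crops grown *within* a region changed through
   time, both taxonomically and in terms of the evolutionary breadth of the
   crops grown?
2. When did the major changes start, how long did they last, and how fast
   were they?
3. Do the timings of change agree across diversity metrics and with the
   expansion of agricultural area itself?
4. Have regions become more similar in the crops they grow (homogenization
   of β-diversity)?

The package implements the full path from a long-format area-harvested
panel plus a species-level phylogeny to these answers, with a synthetic
data generator providing known ground truth for every stage.

# Data model and conventions

A **panel** holds records (region, year, group, area ≥ 0). Zero areas and
missing rows both mean absence — agricultural statistics omit crops that
are not grown rather than reporting zeros — but a zero-area row still
marks the region-year as observed, so an *empty* community (nothing grown)
is distinguishable from an *unknown* one (no data; a lookup error). A
region with a truncated reporting history (as Central Asia is in FAO data,
reporting only from 1992) is represented by absent years, never by
zero-filled years, which would fabricate diversity crashes. Labels are
matched case-sensitively after whitespace trimming: mapping errors should
surface, not be guessed away.

**Abundance** is area harvested, the panel's only quantitative signal.
Proportional abundances $p_i$ are areas divided by the region-year total.

# α-diversity metrics

Per region-year community the package computes:

* **SR** — species richness: the number of commodity groups with positive
  area (one species per group).
* **SD** — Gini-Simpson diversity $1 - \sum_i p_i^2$, in $[0, 1)$. The
  Gini-Simpson form is pinned deliberately: it matches the 0–1 range with
  1 meaning "infinite diversity", whereas the inverse-Simpson form is
  unbounded.
* **PD** — Faith's phylogenetic diversity: the summed branch lengths (in
  millions of years, My) of the minimal subtree spanning the community's
  species, *root path included*. Including the root path follows the
  common default of the ecology toolchain (e.g. `picante::pd` with
  `include.root = TRUE`); stated explicitly because either convention is
  defensible.
* **QEphy** — Rao's quadratic entropy
  $\sum_i \sum_{j \ne i} d_{ij} p_i p_j$, the expected patristic distance
  (My) between two random draws from the community.

## The one-species-per-group randomization

Panels report abundance per commodity group; trees live at species level.
Following the convention that assuming one species per group biases less
than assuming all of them, PD and QEphy are computed under repeated random
assignments of one species to each present group — by default 100
replicates, redrawn independently per year, summarized as the replicate
median (an even replicate count takes the midpoint of the two central
order statistics). Two choices the underlying convention leaves open are
resolved as follows:

* *Redraw per year vs. hold per replicate*: the default redraws
  independently each year (`per_year = TRUE`), which keeps years
  exchangeable; a switch holds one assignment per replicate across the
  whole series for users who prefer temporally coherent draws.
* *Duplicate draws*: when two groups draw the same species, presence
  metrics (PD) count it once; abundance metrics (QEphy) pool the areas,
  conserving the region's total.

Randomization is seeded with per-(region, year) substreams, so results are
bit-reproducible and independent of evaluation order.

# The phylogeny: pruning and dating

Trees are read from newick (the package carries its own reader/writer
because pruned trees retain degree-2 pass-through nodes carrying
calibration labels, which mainstream parsers do not round-trip
losslessly). Polytomies are kept. Pruning to a taxon set keeps the minimal
spanning subtree *including* those degree-2 nodes; branch lengths through
them sum identically, so no metric is affected, but calibrations attached
to their labels survive.

Node ages come from a calibration table ("node-label age" lines, ages in
My). Uncalibrated internal nodes receive ages by **even interpolation**,
in the manner of branch-length-adjustment dating of supertrees: walking
root-to-tip, each undated node anchors to the calibrated node or tip
reachable from it through undated nodes only — preferring the *oldest*
such anchor, then the longest undated chain, then the lexicographically
smallest label — and with $m$ undated nodes on the parent-to-anchor path
receives $t_P - (t_P - t_D)/(m + 1)$. Applied recursively this telescopes
to the familiar even spacing $t_A - k\,(t_A - t_D)/(m+1)$ along a chain of
$m$ undated nodes. The oldest-anchor preference is the design choice that
matters: anchoring instead to the chain with the most undated nodes
regardless of age can assign a node an age *younger* than a calibrated
node deeper in one of its other subtrees, violating root-to-tip
monotonicity. With the oldest-anchor rule, every assigned age lies
strictly between the node's parent's age and the ages of all calibrated
descendants, so ages strictly decrease along every edge by construction.
Calibration tables in which a node is younger than a calibrated descendant
are rejected up front as calibration conflicts. Species present in the
panel but absent from the tree are a hard error by default: silently
dropping taxa would bias PD downward invisibly.

# Temporal models

Each diversity series $D(t)$ (and total area, if analysed) is fit with six
candidate mean functions:

| family      | form                                              | parameters |
|-------------|---------------------------------------------------|------------|
| linear      | $a + b\,t$                                        | 2 |
| piecewise2  | $a + b t + c (t-\psi_1) I(t>\psi_1) + d (t-\psi_2) I(t>\psi_2)$ | 6 |
| quadratic   | $a + b t + c t^2$                                 | 3 |
| unimodal    | $a\, b^{(t-c)^2}$                                 | 3 |
| asymptotic  | $a + b \exp(-e^{c} t)$                            | 3 |
| logistic4   | $a + (b-a)/(1+\exp((c-t)/d))$                     | 4 |

The unimodal family is often typeset in a way that is ambiguous between
an exponent and a product; the exponentiated (Gaussian-bump) reading is
the default, with a peak at year $c$ when $0 < b < 1$, and the polynomial
reading $a\,b\,(t-c)^2$ is selectable via `form = "polynomial"`.

Nonlinear families are fit by least squares (`minpack.lm::nlsLM`) on
centered years with data-driven multi-starts (parameters mapped back);
the degenerate flat solution is always evaluated as a candidate so
constant series fit cleanly rather than failing on a singular gradient.

## The two-breakpoint piecewise fit

The piecewise model is the analysis workhorse: its slope is $b$ before
$\psi_1$, $b+c$ between the breakpoints, and $b+c+d$ after $\psi_2$, and
the curve is continuous at both breakpoints by construction. It is fit by
iterative linearization: given current $\psi$, OLS on the basis
$\{1,\ t,\ (t-\psi_m)_+,\ -I(t>\psi_m)\}$ yields a gap coefficient
$\gamma_m$ and slope-difference coefficient for each breakpoint, and the
update $\psi_m \leftarrow \psi_m + \gamma_m/\hat c_m$ is iterated until
$\max|\Delta\psi| < 10^{-6}$ year (at most 50 iterations). Numerical
safeguards: steps are damped to half the data span; updates that leave the
observed range are projected back inside it rather than abandoned; when
the slope difference is numerically zero the breakpoint is left where it
is (so exactly linear data converge immediately). Starts are taken from a
decile grid of initial breakpoint pairs (plus any warm start provided);
converged solutions must have ordered breakpoints strictly inside the data
range with at least two observations per segment — the admissibility rule
that prevents degenerate boundary solutions — and the best-RSS admissible
solution wins.

## Model comparison

Models fit to the same series are ranked by
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$, with $k$ counting mean
parameters plus the error variance; additive constants are dropped, so
only within-series differences are meaningful. An RSS below
$\max(\mathrm{TSS},1)\times 10^{-12}$ is treated as exactly zero and maps
to a $-\infty$ sentinel; such ties are broken by parameter count, so a
noiseless line selects the linear model rather than letting floating-point
dust pick a winner among exact fits. $r^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$
for every family, including nonlinear ones.

## The bootstrap

Because the piecewise fit can have multiple local solutions, all reported
piecewise parameters — $a, b, c, d, \psi_1, \psi_2$, AIC and $r^2$ — are
medians over a case-resampling bootstrap (500 replicates by default):
observation pairs are resampled with replacement at the original size and
the model refit, warm-started at the point-estimate breakpoints with a
full grid fallback. Case resampling (rather than residual resampling) is
the conservative reading of "bootstrapping with replacement" and is robust
to heteroscedasticity. Replicates that fail to converge are excluded and
counted; if fewer than 80% succeed the series is declared unstable and is
dropped from cross-region summaries (listed, never imputed).

# Breakpoint indicators and cross-metric tests

From each bootstrapped piecewise fit: **onset** = median $\psi_1$;
**duration** = median $\psi_2$ − median $\psi_1$, reported as a positive
number of years; **post-break slope** = median $b$ + median $c$, the rate
of change between the breakpoints in metric units per year. Cross-metric
agreement is assessed by OLS of one metric's onsets on another's (paired
by region, converged fits only), and departure from a 1:1 relationship by
the joint F-test of {intercept = 0, slope = 1}:
$F = ((\mathrm{RSS}_r - \mathrm{RSS}_f)/2) / (\mathrm{RSS}_f/(n-2))$
against $F(2, n-2)$, with $\mathrm{RSS}_r$ computed from predictions
$\hat y = x$; an exact identity reports $p = 1$ explicitly. Cross-region
summaries offer mean ± sd and median ± MAD conventions.

# β-diversity

All region-year communities form one global matrix at commodity-group
granularity (pushing the species randomization into β-diversity would add
noise the group-level data cannot justify). Pairwise Bray-Curtis
dissimilarity $\mathrm{BC}_{jk} = \sum_i |x_{ij} - x_{ik}| / \sum_i
(x_{ij} + x_{ik})$ feeds three analyses:

* **NMDS** (via `vegan::metaMDS`): Kruskal stress-1 with monotone
  regression, random restarts plus a metric-scaling start, best stress
  kept, seeded.
* **PERMANOVA** (via `vegan::adonis2`): sequential (Type-I) sums of
  squares in the order region, year, region×year, with free permutation of
  sample labels and $p = (\text{exceedances}+1)/(\text{permutations}+1)$.
  Year enters as a *numeric covariate*: 54 categorical year levels would
  consume most of the degrees of freedom, and a 1-df covariate matches the
  small year effects such data show. A term with a single level
  contributes SS = 0 rather than an error.
* **Similarity trend**: within-year region pairs only (the response is
  each pair's BC dissimilarity — the sign convention is annotated in the
  outputs; similarity is $1-\mathrm{BC}$), regressed on year as one
  observation per pair-year, not yearly averages, by both OLS and the
  piecewise model. With $R$ regions over $Y$ years and one region covering
  $y$ of them, the pair count is $(Y-y)\binom{R-1}{2} + y\binom{R}{2}$ —
  11,823 at the study dimensions $R=22$, $Y=54$, $y=23$.

# The synthetic-data generator

`scenario_spec()` encodes the study conditions the analysis assumes: 22
regions observed 1961–2014 over 157 commodity groups, one region truncated
to 1992 onward; per-region richness trajectories follow the piecewise
model with onsets $\sim N(1982.4,\ 5.6^2)$ years, change rates
$\sim N(2.1,\ 2.4^2)$ groups·yr⁻¹ and durations $\sim N(8.4,\ 5.4^2)$
years (each truncated to keep trajectories feasible within the pool), flat
slopes outside the change window, Gaussian richness noise of sd 1 group,
and heavy-tailed log-normal areas (meanlog 8, sdlog 2 — hectare scales
spanning garden crops to staples). Base richness at the series start is
uniform on 40–80 groups. 20% of groups carry 2–5 species so the
randomization machinery is genuinely exercised.

Composition turns over through per-region *preference orderings*: the
groups present in a year are the first $k$ of a fixed random permutation,
so richness changes imply nested, persistent gains and losses — the way
new commodity groups appear once and persist in real reporting — rather
than uniform resampling. The homogenization variant blends each region's
abundance profile (log-areas declining with preference rank, so major
crops dominate) linearly into a common profile across a convergence
window, giving a near-linear decline in among-region Bray-Curtis
dissimilarity whose window a piecewise fit should recover.

What the generator does **not** emulate: real crop identities, spatial or
trade correlation between regions, temporal autocorrelation of areas
(areas are i.i.d. log-normal per record in the main generator), or
reporting-unit changes. Passing tests therefore demonstrate that the
estimators recover known structure of the assumed form at realistic sizes
and noise; they do not validate the substantive claims on real data,
which require the actual area-harvested extract, species mapping and
calibrated phylogeny as inputs.

# Problem sizes used in validation

The bundled checks run the estimators at the full study dimensions where
the quantity checked is a count or a partition (1,157 samples; 11,823
within-year pairs), and at these sizes elsewhere: 200 simulated series
(n = 54) for breakpoint recovery at noise sd 5% of range with bootstrap
agreement assessed at 100 replicates on 100 series; 100 series for
AIC-selection frequency; 2,000 and 1,000 null replicates for the type-I
calibration of the 1:1 test and PERMANOVA (199 permutations each, making
the 0.05 level exactly attainable); randomization medians at 10–50
replicates inside pipeline tests. These sizes give stable Monte-Carlo
estimates of each property while keeping the whole suite fast enough to
run routinely.

# Known limitations

* Breakpoint inference on series whose true change is weak relative to
  noise (a few groups over a couple of years) is genuinely unstable; such
  regions fail the 80% bootstrap-success rule and are reported as dropped
  rather than forced.
* AIC comparisons use the RSS form and are valid only within a series;
  no AICc/BIC beyond a config toggle, at most two breakpoints, and no
  autocorrelation-aware errors.
* PD and QEphy magnitudes depend on the calibration table; with sparse
  calibrations the even-interpolation ages are a smoothness assumption,
  not an estimate with uncertainty.
* The PERMANOVA year term as a numeric covariate is a modelling choice;
  the term order is configurable but sequential SS always sum to the
  total.
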