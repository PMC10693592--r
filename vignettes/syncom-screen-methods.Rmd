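---
title: "Methods: randomized SynCom screens for host protection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomized SynCom screens for host protection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomscreen)
```

# The problem

A plant microbiota can suppress a foliar pathogen (colonization resistance),
but which property of a community drives the protection — its total
commensal load, its evenness, its phylogenetic diversity, or the identity of
its member strains — cannot be read off observational data. `syncomscreen`
implements a reductionist screen design and its analysis chain: fixed-size
synthetic communities (SynComs) are drawn at random from a defined strain
pool, inoculated onto gnotobiotic plants, challenged with a pathogen, and the
pathogen load per plant (CFU per gram fresh weight) is modelled as a function
of community structure and composition.

The package covers every analysis stage: combinatorial design, preprocessing
of plant-level colonization tables, community-structure metrics,
mixed-effects association models, kernel-density bimodality detection with
bootstrap stability, supervised learning of protection outcomes with
baselines and feature importances, and follow-up group analyses with
Bonferroni-corrected contrasts. A synthetic-screen generator with full
ground-truth bookkeeping stands in for the wet-lab data, so every stage can
be tested for parameter recovery.

# Screen design

With communities of size $k$ drawn without replacement from a pool of $n$
strains, a given strain lands in a community with probability
$\binom{n-1}{k-1}/\binom{n}{k} = k/n$, so over $N$ screened communities its
expected prevalence is

$$E(X) = \frac{k}{n}\,N .$$

The default screen uses $k = 5$, $n = 35$, $N = 136$, giving
$E(X) \approx 19.4$ — about twenty communities per strain, enough for
strain-level analyses. `assemble_communities()` enforces distinct
compositions by rejection sampling: at $N = 136$ out of
$\binom{35}{5} = 324{,}632$ possible communities, collisions are rare but not
negligible, and the independent test screen must not repeat any training
composition.

# Data model and preprocessing

One plant contributes a pathogen CFU/g value and per-strain commensal CFU/g
values for its five inoculated strains. Preprocessing follows fixed rules:

* **Detection floor.** An undetected strain is recorded as a count of 0.09
  at the lowest counted dilution and converted to CFU/g with the same
  dilution-and-weight arithmetic as a real count, so floors are strictly
  positive and `log10` is always defined. The synthetic generator uses a
  configurable final floor (default $10^{3.5}$ CFU/g) because real dilution
  factors are not reproduced.
* **Ambiguous counts.** Strains that cannot be distinguished on plates share
  one pooled count; `partition_ambiguous()` splits it equally among the
  group on the linear scale, conserving total commensal CFU exactly.
* **Log transform.** All CFU values are log10-transformed once; a scale
  marker prevents double transformation.
* **Normalization.** Pathogen values are centered per experiment by the
  axenic infected controls — by their median for screen summaries and by
  their mean for the regression targets; both are exposed because the two
  conventions serve different stages.
* **Outliers.** A value outside the closed interval
  $[Q_1 - 1.5\,\mathrm{IQR},\, Q_3 + 1.5\,\mathrm{IQR}]$ of its treatment
  group is flagged (type-7 quartiles). Flags never exclude a plant by
  themselves; exclusion additionally requires a recorded experimental reason
  (contamination, disturbed box).

# Community-structure metrics

* **Pielou evenness** $J = H'/\ln S$ with $H' = -\sum_i p_i \ln p_i$ over
  the $S$ strains with positive abundance. $S$ defaults to the number of
  strains detected above the floor; a `fixed_richness` option pins it to the
  inoculated size instead.
* **Faith PD** is the branch-length sum of the minimal unrooted subtree
  spanning the members; input trees are unrooted first so an arbitrary root
  never influences the value. Used with inoculum compositions (presence
  only).
* **Weighted mpd** $\sum_{i<j} w_i w_j d_{ij} / \sum_{i<j} w_i w_j$ with
  relative abundances $w$ and patristic distances $d_{ij}$. Self-pairs are
  excluded; the widely used picante implementation includes them, and the
  two conventions differ exactly by the factor $1 - \sum_i w_i^2$, which the
  test suite verifies.

# Association models

Log10 pathogen colonization is regressed on one covariate at a time: total
commensal colonization (log10, centered so the intercept is the expected
pathogen level at mid commensal levels), realized evenness, inoculum Faith
PD, or realized weighted mpd. The random-structure lattice holds seven
models: no random effects; an experiment intercept, optionally with a
covariate slope; and each of those combined with a box intercept or box
intercept + slope (one community per box, nested in experiment; a box term
never appears without the experiment term, and slopes always come with
their intercepts). Random-effect models are fitted by REML with
`lmerTest::lmer` (two-sided t tests on the slope with Satterthwaite degrees
of freedom — the df method was an open choice and Satterthwaite is the
current standard); the no-random model uses `nlme::gls` with REML, keeping
AIC comparable since the fixed part is identical throughout. Models within
$\Delta\mathrm{AIC} < 4$ of the minimum form the selected set; singular fits
(expected with only two experiment levels) are flagged but retained,
non-converged fits are excluded.

Evenness and weighted-mpd analyses exclude communities with ambiguous
counts, because those metrics need each member's abundance; the sensitivity
subsets additionally drop communities with any strain below detection.

# Bimodality and protection classes

The distribution of community-level (box-median) pathogen colonization is
estimated per experiment with a Gaussian KDE (Silverman's rule-of-thumb
bandwidth, 512-point grid spanning the range ± 3 bandwidths). The class
threshold is the lowest interior local minimum between the two
highest-density modes, with two numerical guards: a mode must reach at least
10 % of the highest peak, and the valley must dip at least 10 % below the
smaller flanking mode — otherwise sampling ripples on a unimodal curve
would masquerade as bimodality and the absence of a minimum is reported
instead. Samples strictly below the threshold are *protected* (positive
class); values equal to the threshold are non-protected.

Bootstrap stability resamples the values 1000 times and records, per
replicate, a local minimum inside the reference region (full-data minimum
± 0.5 log10 units; the width is configurable since no canonical value
exists). The detection fraction and the 5th–95th percentiles of the
replicate minima summarise how robust the split is. Thresholds for the
minima-sensitivity refits are drawn from the empirical bootstrap minima
restricted to that percentile range (uniform draws on the range are the
fallback when too few minima exist; drawing from the empirical distribution
is the default because it respects the observed shape).

When one experiment's curve lacks a usable minimum in a given draw,
`fill_missing_thresholds()` borrows the mean threshold of a reference
screen — the documented option of reusing the training threshold for a test
set.

# Machine learning

Twelve model–algorithm combinations: {random forest, elastic net} ×
{box-median, individual-plant rows} × {classification on presence/absence,
regression on presence/absence, regression on colonization features} — with
classification restricted to presence features (4 classification + 8
regression configurations). Tuning uses 10 rounds of 5-fold
cross-validation; folds partition *communities*, never rows, so plants of
one community can never sit on both sides of a fold (the leakage guard is
tested exhaustively). The tuning metric is Cohen's kappa for classification
and RMSE for regression; the tuned model is refitted on all training data.
Hyperparameter grids (not canonical, therefore documented and
configurable): random forest — features per split over
$\{1, \sqrt p, p/3, 8\}$ with 500 trees; elastic net — mixing parameter
$\{0.1, 0.55, 1.0\}$ × 10 penalties on a log scale.

Evaluation uses the independent test screen, classified against its own
density minimum. Baselines: a Monte-Carlo random classifier that assigns
the positive class with the training prevalence (expected precision equals
the test prevalence, expected recall the assignment probability — both
reported alongside the simulation), and a constant prediction of the
training-set mean response ("no model") for regression.

Feature importances are permutation importances (out-of-bag) for random
forests — chosen over impurity importance for comparability with
coefficient magnitudes — and absolute standardized coefficients at the
tuned penalty for the elastic net; each table is scaled to max = 100,
negatives clipped at zero, and medians are taken across the eight seeds and
across configurations. The threshold-sensitivity analysis refits the
presence/individual RF classifier after reclassifying the training rows
with each sampled threshold and reports the stability of the top ranks.

# Follow-up analyses

`split_pr_vs_others()` partitions communities by whether they contain at
least one designated protective strain and compares group medians of the
box medians. Tail communities are "Others" communities below the class
boundary (the default threshold, since no numeric rule is canonical), and
their strain frequencies point to combinations the per-strain importances
miss. Validation experiments are analysed after averaging per box (removing
the grouping structure), with treatment as fixed effect and {none, round
intercept, round intercept + treatment-by-round} random structures selected
by $\Delta\mathrm{AIC} < 4$; pairwise two-sided t contrasts (via emmeans on
the best model) are Bonferroni-corrected over the declared family only —
the family size is the declared pair count, never silently recomputed — and
rendered as compact letters by the insert-and-absorb algorithm, whose
letter-sharing pattern is verified against the significance matrix on every
fixture.

# The synthetic-screen generator

The generator is this package's own construction — the study it emulates
fits models but never states a data-generating process — and every default
is traceable to a reported estimate or range. Per plant, on the log10
scale:

$$y = \mu_e + \underbrace{f\!\big(A(\textstyle\sum_s \delta_s + \sum_{s<s'}
\gamma_{ss'})\big)}_{\text{community effect}} + (\beta_c + b_j)(C - \mu_C)
+ (\eta + h_j)(J - \bar J_k) + u_j + \varepsilon,$$

where $C \sim N(8.0, 0.5)$ is the plant's total commensal colonization,
strain shares are Dirichlet(0.25) and $J$ is their Pielou evenness,
$b_j \sim N(0, 0.6)$, $h_j \sim N(0, 2.2)$, $u_j \sim N(0, 0.15)$ and
$\varepsilon \sim N(0, 0.8)$.

Parameter anchors:

* Strain effects $\delta$: three strong pathogen-reducing (PR) strains at
  −2.0 each (validated single-strain reduction of two orders of magnitude),
  one intermediate strain at −1.0, one weak partner at −0.3, all others 0.
  The intermediate + weak pair carries a synergy $\gamma = -1.0$; PR strains
  combine additively (a pair reaches about four orders).
* Coupling slopes: commensal effect 1.4 with per-community SD 0.6; evenness
  effect −1.3 with per-community SD 2.2 — the reported mixed-model
  estimates.
* $A(\cdot)$ is a context amplification: when effect strains are
  accompanied by neutral commensals the raw effect is multiplied by
  $1 + a$ (default `context_amplification = 0.38`). The motivating
  observation is that screened communities containing a protective strain
  sit ≈ 3 orders of magnitude below the axenic controls although the same
  strains reduce by 2 orders alone — community context amplifies
  protection (the group median alone would suggest $a \approx 0.6$; the
  default balances that anchor against the no-model RMSE calibration
  below). Validation treatments composed solely of effect strains are not
  amplified, which reproduces exactly that contrast.
* $f(\cdot)$ is a soft saturation at −4.2 orders (softness 0.3): observed
  pathogen loads span roughly 4–9 orders of magnitude, i.e. protection
  saturates near the pathogen's establishment floor. This also keeps the
  35-strain control community inside the observed range, where naive
  additivity would predict an absurd 7-order reduction.
* The raw residual SD is 0.8, not the reported 1.0: the reported value is a
  *fitted* model residual, which in this generator also absorbs the
  independent evenness channel; with 0.8 the fitted residual comes out at
  ≈ 0.95–1.0.
* The evenness covariate is centered at its analytic expectation
  $\bar J_k = (\psi(k\alpha + 1) - \psi(\alpha + 1))/\ln k$ under the
  Dirichlet share model, so the coupling (and its large random slope) is
  mean-zero for *every* community size — single-strain validation
  treatments included. Concentration 0.25 puts $\bar J_5 \approx 0.5$
  with SD ≈ 0.2, enough covariate spread to recover the evenness coupling.
* Ambiguity arises from eight designated indistinguishable strain pairs,
  pooled with probability 0.95 when co-inoculated — ambiguity clusters by
  community, as on real plates, yielding ≈ 13–19 % of plants with a pooled
  pair and excluding ≈ 15–25 of 136 communities from the evenness analysis.
  An independent per-plant ambiguity rate would have disqualified half the
  screen, unlike the study conditions.
* Detection floors apply to per-strain values only; pathogen counts (from
  selective plates) are never floored.

Calibration targets were jointly: a constant-mean ("no model") RMSE of
≈ 1.5 ± 0.25 on test-screen normalized reductions, per-experiment bimodality
of box medians, and unbiased recovery of the coupling slopes.

**What the generator does not emulate.** Couplings are independent noise
channels, whereas in real data commensal load, evenness and protection
status are partly confounded (e.g. pathogen growth releasing nutrients for
commensals); fresh weight is uncorrelated noise although infected axenic
plants are lightest in reality; there is no strain–strain ecology beyond
the fixed synergy term; and the per-experiment bimodality of a single draw
is weaker than the real screen's — bootstrap detection fractions typically
land between 0.6 and 1.0 across draws, because the reported noise
anchors, treated as independent channels, place more mass in the
between-mode valley than the real data shows. Passing tests therefore
demonstrate correct recovery of implanted structure, not performance on
real screens.

# Problem sizes and runtime choices

Unit tests run reduced designs (null screens of 30 communities × 2 plants;
2–3 CV repeats; 150–300 bootstrap replicates) chosen to keep the full suite
in the minutes range while leaving Monte-Carlo envelopes meaningful. The
acceptance checks use the full default design: 24 replicate screens for
slope recovery, 10 for baseline calibration, and the complete grouped
10 × 5 cross-validation over 8 seeds for the random-forest train/evaluate
cycle.

# Known limitations

* With only two experiments, random slopes over experiments are usually
  singular; they are flagged, retained, and practically never selected.
* The bimodality guards (10 % mode height, 10 % valley depth) are pragmatic
  defaults; a formal bimodality test (dip test, mixture BIC) is out of
  scope.
* The bootstrap detection criterion inherits the reference-region width
  (± 0.5 log10) as a free parameter.
* Elastic-net importances are coefficient magnitudes on the standardized
  scale and are not directly comparable to permutation importances beyond
  their ranks.
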