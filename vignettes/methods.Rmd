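---
title: "Methods: multimodel inference for microbial structure–function analysis"
author: "microMMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodel inference for microbial structure-function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microMMI)
```

# The question and the statistical machinery

A recurring question in microbial ecology is whether measurements of
microbial community structure add explanatory power for ecosystem process
rates (respiration, nitrification, denitrification, N mineralization) beyond
environmental variables and bulk microbial biomass. `microMMI` operationalizes
that question with per-dataset multimodel inference and cross-dataset
synthesis. This vignette documents the models, assumptions, defaults and
numerical choices; the package's tests and `scripts/acceptance.R` compute
every empirical claim it makes.

## Per-dataset model selection

Within each predictor set (E = environment, M = microbial structure,
B = biomass, and their additive unions) the package fits every predictor
subset by OLS and scores it with

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},
  \qquad \ell = -\tfrac{n}{2}\left(\ln\tfrac{2\pi\,\mathrm{RSS}}{n}+1\right),$$

where $k = p + 2$ counts the intercept, the $p$ slopes and the residual
variance. The likelihood convention matters: software differs in whether the
residual variance is counted, and leaving it implicit makes AICc values
irreproducible. Models with $\Delta\mathrm{AICc} \le 4$ of the best form the
model set; Akaike weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ are
computed **after** truncation and renormalized. (Computing weights over all
candidates first and then renormalizing over the retained set gives exactly
the same weights, because the common reference AICc cancels; the
distinction would only matter if unrenormalized weights were used, which no
averaging convention does, so one code path serves both readings.)

**Model averaging.** The averaged final model uses the *full-average*
(zero-substitution) convention by default: a predictor absent from a model
contributes zero, so weakly supported predictors are shrunk toward zero.
This is the right convention when the averaged model is used for
*prediction*, which is how its adjusted R² is computed. Conditional
averaging is available (`averageModel(..., mode = "conditional")`).

**Adjusted R² of an averaged model** has no standard definition. The package
predicts from the averaged coefficients and penalizes with $p$ equal to the
size of the predictor union across the retained models — the most
conservative defensible choice, since every predictor in the union
influenced the averaged fit. When the union exceeds $n-2$ the value is
reported as `NA` and flagged rather than extrapolated.

**The dual improvement criterion.** A combined set improves on a baseline
only if (i) its best AICc is at least `aicc_gap = 4` units lower
(the best candidate each set can offer is compared, because an averaged
prediction has no AICc of its own), and (ii) the adjusted-R² gain exceeds
`relative_r2_fraction = 0.10` of the baseline's adjusted R². When the
baseline adjusted R² is ≤ 0 the relative threshold collapses to 0, any
positive gain counts, and the case is flagged — the criterion's original
formulation never meets a negative baseline. "Worse than baseline" is
reported as *not improved*, never as negative improvement: the question is
one-directional.

**Guards and tie-breaks.** All predictors are z-scored before fitting.
`max_terms` defaults to $\min(p, \max(1, \lfloor n/10\rfloor))$ — a
one-in-ten rule that keeps candidate models small at the modest sample sizes
(n ≈ 10–100) typical of structure–function datasets. AICc ties break toward
the smaller model, then lexicographic predictor order, so output is
deterministic. A fit with numerically zero RSS (noiseless data) gets
$\ell = +\infty$, $\mathrm{AICc} = -\infty$ and a `degenerate` flag; such a
fit dominates its model set, which is the correct limit, and no error is
thrown so noiseless unit-test fixtures flow through the machinery.

## Condensing community data

Multivariate community tables enter models as a few ordination axis scores
plus the per-sample Shannon index (natural log). Two deliberately
deterministic ordinations are offered:

* **PCA of the Hellinger-transformed table** (default): variance-preserving,
  unique up to axis signs, no tuning. PLFA profiles are treated as
  relative-abundance profiles and ordinated identically.
* **PCoA of Bray–Curtis dissimilarities**: negative eigenvalues are dropped
  and counted in provenance.

NMDS is excluded on purpose — it is iterative and seed-sensitive, and a
framework whose outputs must be byte-reproducible should not depend on a
random start. Axis signs are fixed by forcing the first nonzero loading
(PCA) or score (PCoA) of each axis to be nonnegative.

**Axis retention** keeps the smallest number of leading axes reaching 70%
cumulative variance, capped at $\max(1, \lfloor n/10\rfloor)$ axes. The cap
protects the downstream all-subsets search: with unbounded axes the M set
would grow combinatorially and overfit at small n. Both numbers are
configurable (`pipelineConfig()$ordination`).

Functional-gene datasets bypass ordination: their 1–3 abundance columns
enter models directly, and a Shannon index over gene columns (functional
diversity) is added only when at least 3 columns exist — with fewer, the
index is not meaningfully a diversity.

## Coupling between predictor sets

How much community variation does the environment explain? The package
answers with redundancy analysis:
$R^2 = \operatorname{tr}(\hat Y^\top \hat Y)/\operatorname{tr}(Y_c^\top Y_c)$
from column-wise least squares of the centered response matrix on the
constraints, with the Ezekiel adjustment. With a single response column this
is exactly multiple-regression R², which the tests verify against `lm()` and
`vegan::rda()`.

Constraints are chosen by permutation-based forward selection: at each step
every remaining candidate is tested by permuting its rows (999 permutations,
$p = (1+\#\{\text{perm} \ge \text{obs}\})/(1+999)$, statistic = incremental
explained SS conditional on the current constraints), and the candidate with
the largest adjusted-R² gain among those with $p \le 0.05$ is added.

Two safeguards keep stepwise selection honest. First, a **global
permutation pre-test** of the all-constraints model must reject at
$\alpha$ before any selection starts. Screening five candidates at
$\alpha = 0.05$ without it would select something on pure noise about
$1-0.95^5 \approx 23\%$ of the time; with the pre-test the null selection
rate is close to $\alpha$ (the acceptance suite measures ≥ 90% empty
selections under the null). This is the standard two-stopping-rule remedy
for inflated forward selection in constrained ordination and is on by
default. Second, the classical double-stopping rule (selected model's
adjusted R² may not exceed the all-constraints model's) is available via
`double_stop = TRUE` but off by default, since the global pre-test already
controls the error rate in the regimes the package simulates.

The community response in coupling analyses is the Hellinger-transformed
table itself, not the condensed axes: the constrained ordination describes
the community data, and the axes are already environment-filtered summaries.
`community_response = "axes"` switches this. When selection comes back empty
the coupling adjusted R² is reported as 0 with a flag rather than omitted —
and because both conventions are defensible for averaging across datasets,
the flag lets users drop empty selections from their own aggregations.

## Synthesis across datasets

Subsets (full collection; per process, environment and microbial-data type)
are summarized only with $n \ge 12$ datasets — the replication floor —
otherwise the summary is suppressed with a reason. Reported effect sizes:
mean ± SE adjusted R² per predictor set (SE = sample SD/√n), percent
improved, and the mean adjusted-R² increase averaged over **all** datasets
in the subset, improved or not. "Percent improved" counts the (E vs E+M)
pair by default; a config switch widens it to any microbial-containing
combination.

Between-set comparisons use unpaired one-sided Mann–Whitney U tests
(exact by enumeration when $n_x + n_y \le 12$ with no ties, otherwise the
tie- and continuity-corrected normal approximation). The datasets do
contribute to both sets being compared, so a paired test could be argued;
the framework is specified as unpaired and the package follows that, noting
the discrepancy here. Directions default to "environment > microbial" and
"combined > environment", and every test record carries its direction. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
option exists for users who want it).

# The synthetic-data generator

The generator is first-class, tested code — it defines the study conditions
under which the framework is calibrated.

* Environmental variables: independent standard normals, so effect sizes are
  on a standardized scale.
* Latent community axes:
  $L = \sqrt{c}\,(EW) + \sqrt{1-c}\,Z$ with unit-norm random loadings $W$
  and standard-normal $Z$, standardized per axis; $c$
  (`env_community_coupling`) is the fraction of axis variance carried by the
  environment, and the squared multiple correlation of each axis on the
  environment converges to $c$.
* Taxon table: log-abundances linear in the latent axes (loading SD 0.7,
  taxon noise SD 0.7, baseline SD 1), exponentiated — a log-normal
  composition, strictly positive. A Dirichlet-multinomial count layer is
  deliberately omitted: the analysis consumes only ordination axes and
  Shannon values, which the log-normal model exercises fully.
* Biomass: $\sqrt{r^2}$-weighted environmental projection plus noise, so its
  coupling to the environment is tunable (`biomass_env_r2`).
* Process rate: $y = E\beta_E + L\beta_M + \beta_B b + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$. With independent standardized
  predictors the true-model $R^2$ is
  $\sum\beta^2/(\sum\beta^2+\sigma^2)$, which the truth record stores
  (exact at $c = 0$; at $c > 0$ the environment and axes share variance and
  the recorded shares are the naive per-block values).

Defaults describe a plausible mid-sized study — $n = 40$ samples, 4
environmental drivers, 60 taxa on 3 latent axes, coupling 0.3, environmental
variance share ≈ 0.5, community share ≈ 0.14, biomass share 0.04, residual
SD 0.55 (true $R^2 \approx 0.7$) — chosen once for realism; the source
corpus does not report per-dataset sample sizes or effect sizes, so these
are the package's own conditions, not a reconstruction. The default
collection (`defaultCollectionSpec()`) reproduces the corpus's subset
structure: 26 respiration, 14 nitrification, 17 denitrification and 12
N-mineralization datasets, with sediment and agricultural soil each at the
n = 12 floor and natural soil taking the remainder; one base configuration
is shared by all strata.

Reproducibility rule: a master seed spawns per-dataset (and per-block)
child seeds by seeding the RNG and drawing distinct integers without
replacement (`spawnSeeds()`), so collections are reproducible as a whole and
internally independent, and no generator touches the caller's RNG state
(`withSeed()`).

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: sequence-level noise (reads, OTU picking),
phylogenetic correlation among taxa, zero inflation and compositional count
noise, temporal or spatial autocorrelation, nonlinear environment–process
relationships, and heterogeneous effect sizes across the collection.
Calibration results (false-positive rate, power) are statements about this
generative model at the stated sizes.

# Numerical choices and degenerate inputs

* Eigenvalues below $10^{-9}$ of the largest are treated as zero; a
  community table with no variation raises a no-variation error.
* Shannon requires a nonnegative row with positive sum; all-zero rows raise
  an undefined-diversity error rather than returning 0.
* Bray–Curtis between two all-zero samples is undefined (error), matching
  its formula's 0/0.
* The all-subsets search refuses more than 20 candidates (the subset count
  passes $10^6$); reduce the pool first.
* Constant predictors are dropped with a warning at validation; pairs of
  environmental columns with $|r| > 0.99$ lose the later column. A constant
  response is fatal for the dataset but never for the collection — the
  pipeline isolates per-dataset failures and reports partial success (exit
  status 2).
* Ingestion aligns blocks on the intersection of sample ids, applies
  listwise deletion of samples with any missing value (imputation would
  inject modeling choices into a comparison framework), and requires ≥ 8
  complete samples. Numbers are written with 17 significant digits so a
  write/read round trip is value-identical.

# Problem sizes used for calibration

The acceptance suite runs, as the package's own documented conditions:
null calibration on 200 simulated datasets ($n = 40$, 4 environmental
variables, community effect exactly zero, coupling 0.3); power on 200
datasets where the community axes add a 0.25 incremental variance share at
$n = 60$; forward-selection recovery and null behaviour on 500 replicates
each ($n = 60$ and $n = 50$, five candidates, 999 permutations); 2,000
replicates for Mann–Whitney calibration; and a 40-dataset collection for
byte-level end-to-end determinism. `scripts/acceptance.R` uses 100–200
replicates per condition plus the default 69-dataset collection.

# Known limitations

* The improvement criterion inherits AICc's assumptions: Gaussian errors,
  linear effects, independent samples. Processes with multiplicative error
  should use `transforms$log_response`.
* Ordination axes are estimated, not observed; at high taxon noise the M
  set's power drops with no warning — the truth record lets simulation
  studies quantify this.
* The equal-effect default collection understates the between-dataset
  heterogeneity of a real literature corpus; users synthesizing real data
  should expect wider adjusted-R² spreads than the simulated summaries show.
* RDA coupling is linear; strong nonlinear environment–community relations
  will register as weak coupling.
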