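---
title: "Modelling maternity patient-experience surveys with discrete Bayesian belief networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maternity patient-experience surveys with discrete Bayesian belief networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveybbn)
```

## The problem and the model

National maternity patient-experience surveys score each provider ("trust")
on eight stages of the care journey, S1–S8, on a 0–10 scale. The sections
are strongly and positively intercorrelated, which suggests that experiences
early in the journey shape later ones — but a correlation matrix cannot say
which sections drive which, nor what happens to the rest of the journey if
one section's probability profile shifts. This package models the eight
sections as nodes of a discrete Bayesian belief network: a directed acyclic
graph G plus one conditional probability table (CPT) per node, defining

$$P(x_1,\dots,x_n) = \prod_i P(x_i \mid \mathrm{Pa}_G(x_i)).$$

Everything downstream — prediction, validation, sensitivity — is exact
probabilistic computation on this factorization. The assumptions worth
stating plainly: the sections are treated as discrete ordinal variables
after binning; the trust-level rows are treated as independent and
identically distributed draws; and arcs express probabilistic dependence,
not causal claims (the sensitivity intervention below is an evidence-style
update, not graph surgery, unless explicitly requested).

## The synthetic generator and what it does (and does not) emulate

The survey's trust-level microdata is not redistributable, so the package
ships a generator calibrated to the published summary tables and the
analysis runs end-to-end on synthetic data. `maternity_survey_config()`
encodes:

* 122 trusts, eight sections;
* the published per-section means and SDs (e.g. staff caring: mean 8.35,
  SD 0.31) and the published 8×8 Pearson correlation matrix (strongest
  entries: S2–S3 at 0.80 and S4–S5 at 0.77);
* 50 survey questions grouped into the eight sections, with per-section
  Cronbach alphas (0.53 for care in the hospital up to 0.92 for staff
  caring and care after birth);
* a 7% missing-cell rate, injected completely at random as an exact count
  (`round(rate × cells)`), matching the mean-imputation rationale.

Sections are drawn from a multivariate Gaussian with those moments and
clipped to [0, 10]; at these parameters the bounds sit more than five SDs
from every mean, so clipping is numerically irrelevant. The published
tables note a positive skew that is not quantified anywhere, so the
generator is Gaussian by default — only first and second moments and
correlations are printed, and those are exactly what the generator
reproduces. The per-section item counts are not published either; the
default splits 50 items near-evenly (6,6,6,6,6,7,6,7) and is configurable.

Item blocks are built as $x_{ij} = y_i + (g_{ij} - \bar g_i)$ with
$g_{ij}$ iid Gaussian noise around section score $y_i$. Choosing the noise
variance $\sigma^2 = m\,\sigma_y^2 (1-\rho)/(1+\rho(m-1))$, where $\rho$
is obtained by inverting the Spearman–Brown relation
$\alpha = m\rho/(1+(m-1)\rho)$, gives (a) exact compound symmetry at
$\rho$, (b) population Cronbach alpha exactly equal to the target, and
(c) row means identically equal to the section scores — so section-level
and item-level data are mutually consistent by construction.

What passing tests on this generator do **not** show: robustness to the
skewness, ceiling effects and survey-weighting artefacts of the real data,
nor to missingness that is not completely at random. The generator's printed
correlation matrix happens to be positive semidefinite (smallest eigenvalue
≈ 0.148); for rounded matrices that are not, `repair_correlation()` projects
to the nearest correlation matrix (Higham's alternating projections, via
`Matrix::nearPD`).

## Preprocessing choices

Missing cells are mean-imputed per section column, which preserves observed
column means exactly and never increases variance; the sample-variance
convention is n−1 throughout, fixed once for test stability. An outlier
filter is available (`remove_outliers()`, |z| > 4) but is off by default:
no removal rule is published, and the default path must keep all 122 rows.
Cronbach's alpha uses its defining variance formula with the adequacy band
[0.50, 0.95] flagged in `reliability_report()`.

## Discretization

Three binning methods are implemented — equal-width, equal-frequency and
k-means — under three state-count schemes: all-2-state, all-3-state, or
"mixed", in which each variable's k ∈ {2, 3} maximizes the mean silhouette
width of its one-dimensional k-means clustering (ties go to the smaller k;
the within-cluster-SS elbow curve is attached as a diagnostic only, since no
tie-break between the two heuristics is published). Numerical conventions,
none of which are published and all of which are therefore fixed here
explicitly:

* bins are half-open [lo, hi) with the last bin closed; a value exactly on
  an interior edge belongs to the upper bin;
* out-of-range values at apply time clamp to the boundary bins (relevant
  when a fitted spec is replayed on new data);
* equal-frequency edges are the j/k type-7 quantiles; heavy ties can break
  the ≤1-count balance and then stay together in one bin;
* one-dimensional k-means is solved *exactly* by dynamic programming over
  the sorted values (1-D clusters are contiguous) for n ≤ 2000, which covers
  every survey-scale use; longer vectors fall back to a deterministic,
  quantile-initialized Lloyd iteration. Bin edges are midpoints between
  sorted cluster centers.

States are labelled C0 < C1 < C2 in increasing score order, and the fitted
`binning_spec` is serializable to plain text so a discretization is
auditable and replayable.

## Structure learning

Three learners produce DAGs over the eight sections:

* **Bayesian search (`"bs"`)** — greedy hill climbing over arc additions,
  deletions and reversals maximizing the total BDeu score, restarted from
  seeded random DAGs (default 20 restarts) and keeping the best local
  optimum.
* **Greedy Thick Thinning (`"gtt"`)** — from the empty graph, add the
  best positive-gain arc until none improves, then repeatedly delete the
  arc whose removal most improves the score. Deterministic; the empty-graph
  start is chosen over CI-seeded variants for reproducibility.
* **PC (`"pc"`)** — edge removal by G² conditional-independence tests with
  conditioning sets of increasing size drawn from current adjacencies,
  v-structure orientation from separating sets, Meek rules 1–3 to closure,
  and a deterministic order-based extension of the remaining undirected
  edges (earlier-to-later in node order unless that creates a cycle or a
  new v-structure; with finite-sample inconsistent CPDAGs a new v-structure
  is tolerated rather than failing, but a cycle never is).

The score is BDeu with equivalent sample size 1 and a uniform structure
prior; no scoring function is published for the original analysis, and BDeu
is the standard Bayesian–Dirichlet choice consistent with a "Bayesian
search". α = 0.05 for the PC tests and max_parents = 4 are defaults on the
same grounds; the published 5-arc network needs at most one parent per
node, so the cap is unconstraining. All tie-breaks are lexicographic in
node id, making every learner deterministic given data and seed. Exact
replication of the original GUI tool's internal heuristics is explicitly
not a goal; its hyperparameters are undisclosed.

`learn_grid()` runs the 3 schemes × 3 algorithms grid (nine models) that
the full pipeline validates and selects from.

## Fitting, inference and scale

CPTs are fitted with Laplace pseudocount 1 by default — at n = 122 many
parent configurations are sparse or unseen, and smoothing keeps every row a
proper distribution (unseen configurations become uniform). State spaces
come from the binning spec, not from observed values, so a state absent in
a training fold still exists in the model. Inference is exact variable
elimination with a min-degree elimination order; at 8 nodes and ≤3 states
exactness is cheap, and the test suite verifies it against brute-force
enumeration of the ≤ 3⁸ = 6561-entry joint to 10⁻⁹ on hundreds of random
networks. Virtual (soft) evidence is supported as per-node likelihood
vectors. Networks serialize to a native plain-text format and to the
standard Bayesian-network interchange format (BIF).

## Validation

`cross_validate()` uses seeded, stratified k-fold plans (default k = 10;
stratification is this package's choice to stabilize minority-state counts
at n = 122). The structure is learned once on the full data and held fixed;
only CPTs are refit per training fold — the published workflow validates a
single learned model and is silent on per-fold relearning, and this choice
isolates parameter uncertainty from structure uncertainty. Each test row's
target posterior is computed given all other sections as hard evidence (no
predictor set is published; all-but-target is the natural default), the
argmax state is the prediction, and the report pools a confusion matrix,
accuracy (with its whole-percent rounding alongside the exact value), and
rank-based (Mann–Whitney, midrank ties) AUC — one-vs-rest
prevalence-weighted for 3-state targets, positive state = highest-valued
state for binary ones.

## Sensitivity analysis

Two complementary analyses:

* `influence_scan()` doubles the top-state probability of each node in turn
  (`double_state()`: the boosted state is capped at 1 − ε, default
  ε = 10⁻⁶, and the other states are rescaled by a common factor so their
  mutual ratios are untouched), imposes the new marginal through virtual
  evidence with likelihood q/p — a Jeffrey-style update, which is what
  adjusting a node's probability does in evidence-propagation software —
  and tabulates the **net effect** on every other node: the relative
  percent change of the target's top-state probability. The cap matters
  because doubling a state already above 50% would exceed 1; how the
  original analysis handled this is unexplained, so the cap is explicit and
  configurable. The net-effect metric itself is a documented
  interpretation: the published table never defines its units. Marginally
  d-separated pairs (no shared ancestor) are set to exactly zero
  structurally, which is what d-separation licenses, rather than relying
  on floating-point cancellation; an arc-cutting `do`-style mode is
  available behind a flag. Sources are ranked by summed absolute effect —
  the "most influential factor" criterion.
* `cpt_sensitivity()` perturbs each CPT entry by ±10% (renormalizing its
  row) and records the largest change in a focus node's marginal, ranking
  nodes high/mild/none — the one-way, software-tool-style scan. The ±10%
  size is fixed here; the original tool's derivative method is not
  described.

## The pipeline

`run_pipeline()` chains generate (or load) → impute → describe → the
nine-model grid → validation → selection (accuracy first, AUC tie-break,
matching the published reasoning order) → sensitivity on the winner, with
one master seed split into per-stage seeds and a config hash recorded in
the run log. Reports are plain delimited tables shaped like the published
reliability/descriptive/correlation/performance/sensitivity tables.

## Problem sizes and numerical tolerances

The test suite verifies moment recovery at 50,000–200,000 synthetic rows
(within ±0.01 of the configured correlations at the largest size), alpha
recovery at 50,000 rows, inference–enumeration agreement to 10⁻⁹, scorer
optimality against exhaustive enumeration of all 25 three-node DAGs, PC
skeleton recovery on strong-signal chains at n = 10,000 across 100 seeds,
G² type-I calibration over 1000 null replicates, and chance-AUC calibration
at n = 10,000. These sizes were chosen so each check's Monte-Carlo error is
several times smaller than the tolerance it asserts. CPT rows are required
to normalize to 10⁻⁹; equal-width bin lengths to 10⁻⁹ relative.

## Known limitations

* Gaussian sections cannot exhibit the real data's skew; conclusions about
  discretization boundaries near the scale ceiling may differ on real data.
* With n = 122 and up to 3 states per node, structure learning is
  noise-sensitive: different seeds legitimately select different best
  models, which is why the pipeline reports the full nine-model grid rather
  than a single network.
* The net-effect metric and the doubling cap are documented interpretations
  of an under-specified published procedure; exact published percentages
  are not reproduction targets.
* Inference is exact and therefore exponential in treewidth; this is
  irrelevant at 8 nodes but the package makes no claim beyond
  survey-section scale.
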