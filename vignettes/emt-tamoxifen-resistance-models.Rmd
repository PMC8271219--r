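---
title: "Models of coupled EMT and tamoxifen resistance: ensemble network dynamics and population extinction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of coupled EMT and tamoxifen resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtamr)
```

`emtamr` implements two coupled models of reversible (non-genetic) drug
resistance in ER+ breast cancer:

1. a **regulatory-network ensemble model** of the crosstalk between
   epithelial--mesenchymal plasticity (ZEB1, SLUG, miR-200) and estrogen
   receptor signaling (full-length ERα66 and its truncated variant ERα36),
   which produces six cell phenotypes arranged along an
   epithelial--mesenchymal (EM) axis and a tamoxifen-resistance axis; and
2. an **agent-based population model** of drug-treated sensitive/resistant
   cells that quantifies how heterogeneity, stochastic phenotype switching,
   drug-induced plasticity and MET induction control tumor survival and
   extinction probability.

This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design choices where the underlying
methods are conventionally under-specified.

## The regulatory network and its ODE ensemble

The bundled network (`default_topology()`) has five nodes and ten signed
edges: ERα66 self-activates, represses ERα36 and represses SLUG; SLUG and
ZEB1 repress ERα66; ERα36 activates ZEB1; ZEB1 self-activates and forms a
mutual-inhibition loop with miR-200; SLUG represses miR-200. Topologies are
data, not code: plain-text edge lists (`SOURCE TARGET TYPE`, 1 = activation,
2 = inhibition) read by `read_topology()`, so variant wirings (e.g. ERα36
self-activation, ZEB1 repression of ERα36, GATA3 extensions) are drop-in
files. Two edges of the default file deserve a note: the direction of the
SLUG/miR-200 interaction is not settled in the literature, and miR-200
self-activation is omitted; the bundled file uses SLUG ⊣ miR-200 only.

Node dynamics follow shifted-Hill kinetics,

$$\frac{dX_i}{dt} = g_i \prod_{j \to i} H^s\!\left(X_j; X^0_{ji}, n_{ji},
\lambda_{ji}\right) - k_i X_i, \qquad
H^s(X) = \lambda + \frac{1-\lambda}{1 + (X/X^0)^n},$$

so each incoming edge multiplies the production rate by a factor that is 1
with no regulator and approaches the fold change $\lambda$ at saturation
($\lambda > 1$ activation, $\lambda < 1$ inhibition).

Rather than fitting one parameter set, the model is an *ensemble*: many
kinetic realizations are drawn from biologically plausible ranges and the
robust, parameter-independent behaviors of the wiring are read off the
ensemble statistics. The sampling windows (`sampling_ranges()`) are the
conventional defaults of this ensemble approach: production
$g \sim U[1, 100]$, degradation $k \sim U[0.1, 1]$, integer Hill
coefficient $n \sim U\{1..6\}$, activation fold $\lambda \sim U[1, 100]$
and inhibition fold the reciprocal of such a draw.

### Threshold sampling: the half-functional rule

Each edge's threshold $X^0$ determines whether the regulation is ever
*functional*: if the regulator never reaches its threshold, the edge is
effectively absent. The half-functional rule samples
$X^0 \sim U[0.02\,M, 1.98\,M]$, where $M$ is the median level of the
source gene, so a regulation has roughly even odds of being engaged.

The design question is what "median level" means. Using the unregulated
median $g/k$ is simple but self-defeating for strongly regulated genes:
miR-200 carries two incoming repressions, its realized levels sit far below
$g/k$, and with unregulated-median thresholds its outgoing repression of
ZEB1 is almost never functional — the mutual-inhibition core of the network
silently disconnects and the ensemble collapses into monostability. We
therefore estimate $M$ per node with one level of regulatory context
(`estimate_node_medians()`): Monte-Carlo draws of $g/k$ multiplied by
shifted-Hill factors of each incoming edge with freshly sampled kinetics
and regulator levels at their unregulated scale. This keeps the rule local
(no global self-consistency iteration — we verified that iterating the
estimate to a fixed point changes the medians by little) while honoring the
half-functional intent for repressed and activated genes alike.

### Steady states, initial conditions, and multistability

For each parameter set, `enumerate_steady_states()` relaxes 100 random
initial conditions (log-uniform between each node's minimum and maximum
accessible level, $g/k$ times the product of worst/best-case incoming
folds) with an adaptive embedded Runge--Kutta (Cash--Karp 4/5) integrator,
declaring a steady state when the scaled residual
$\max_i |\dot X_i| / \max(X_i, 1)$ falls below $10^{-6}$ (default horizon
1000 time units; trajectories that never pass the test are reported
non-converged, not dropped). Endpoints are deduplicated at Euclidean
distance 0.1 in log2 concentration space — far above solver jitter, far
below the separation of genuine attractors (≈7% per node). If a new
distinct state first appears in the last quarter of the initial conditions,
one extra batch of equal size is run, since late discovery suggests the
budget had not saturated; 100 initial conditions with this top-up are
near-saturating for five-node networks (quadrupling the budget leaves the
monostable fraction unchanged and moves the bi/tri split by only a couple
of percentage points). Oscillatory solutions are out of
scope: a limit cycle would simply be counted non-converged.

The compiled core exists for throughput — a census over 5000 parameter sets
times 100 initial conditions is half a million relaxations and completes in
about a minute; the test suite cross-checks it against an independent stiff
solver (`deSolve::lsoda`) and, on two-node fixtures, against brute-force
root finding.

### Scores, mixture thresholds, and the six phenotypes

All distinct steady states are pooled (each state one row, however many
states its parameter set has), log2-transformed, and z-normalized per node
(`znormalize()`). Two axes summarize each state:

- EM score $= z(\mathrm{ZEB1}) - z(\mathrm{miR200})$ — positive is
  mesenchymal;
- resistance score $= z(\mathrm{ER\alpha 36}) - z(\mathrm{ER\alpha 66})$ —
  positive is tamoxifen-resistant.

The pooled EM scores are tri-modal (epithelial, hybrid, mesenchymal) and
the resistance scores bi-modal (sensitive, resistant). `fit_thresholds()`
fits 3- and 2-component univariate Gaussian mixtures (EM algorithm via
**mclust**, whose model-based hierarchical initialization makes the fit
deterministic given the data) and places cutpoints at the equal-posterior
boundaries between adjacent components ordered by mean. Whether the
original analysis used equal-posterior boundaries or visually placed
cutpoints is not documented; equal-posterior is the probabilistically
defensible choice and is recovered exactly on synthetic mixtures with known
parameters. A degenerate axis (a failed fit, a component weight under
$10^{-3}$, or no spread at all) falls back to quantile cutpoints with a
warning. Scores exactly at a cutpoint go to the lower (less mesenchymal,
more sensitive) class — a deterministic, measure-zero tie-break.

Crossing the two discretized axes yields six phenotypes: ES, ER, HS, HR,
MS, MR. Ensemble-level checks in the test suite: ES and MR dominate; mean
ZEB1 rises monotonically across ES → ER → HS → HR → MS → MR; SLUG is higher
in HR than HS (SLUG as a hybrid-resistant marker); and EM and resistance
scores are strongly rank-correlated (Spearman ρ ≈ 0.79 at 5000 sets).

Perturbation experiments (`perturbation_report()`) rescale one node's
production rate (default 10×) and re-run the ensemble. Perturbed ensembles
are always scored with the *control* run's normalization statistics and
thresholds; otherwise the thresholds would drift with the perturbation and
frequency shifts would be incomparable. The randomized-topology control
(`randomization_control()`) rewires the network with degree- and
sign-preserving double-edge swaps (self-loops kept as self-loops, sign
labels shuffled over edge positions) and scores each randomized net with
its own normalization; the wild-type correlation sits at the top of the
randomized distribution, which is centered near zero.

### Stochastic dynamics and pseudo-potential landscapes

`euler_maruyama()` discretizes the same ODEs with time step $\Delta t$
(default 0.01) and adds a per-node noise increment
$\eta_i \sqrt{\Delta t}\, N(0,1)$, clipping negative excursions at zero.
The reference formulation writes the increment without a scale; a unit
amplitude is negligible against concentrations of order $10$–$10^3$, so the
package parameterizes $\eta_i$ as a fraction (default 5%) of each node's
$g/k$ scale, with an explicit `eta` override. Because the original noise
magnitude and time step are unknown, landscape reproductions are
qualitative — basin structure and transition routes, not rates.

Trajectories scored with the ensemble's normalization
(`score_trajectory()`) are binned on the (EM, resistance) plane;
`build_landscape()` normalizes occupancy to a probability $P$ and reports
the pseudo-potential $-\log P$. Empty bins stay at $+\infty$ — no
pseudo-count smoothing, so valleys are supported by data. On multistable
parameter sets the landscape shows distinct valleys co-localizing with the
deterministic attractors, and `detect_transitions()` reads committed
phenotype transitions off the labeled score series with a dwell-time
debounce (default 50 recorded steps) so threshold jitter does not register
as switching. Noise-induced MR → HR → ES routes are observed on tristable
exemplars.

## The population model

`pop_config()` + `run_population()` implement an agent-based model of a
drug-treated population. Each cell carries a sensitive score
$\sim N(-2, \sigma^2)$ and a resistant score $\sim N(+2, \sigma^2)$, both
clamped to $[-6, 6]$, fixed for the cell's lifetime, plus a state flag
(S/R) selecting which score faces the drug. The heterogeneity parameter
$\sigma$ (`sd`) is the model's central knob. Per step, in this order:

1. **Death**: an independent basal draw (probability 0.1) and, with drug
   on, a drug draw — a cell with current-state score $x$ *escapes* drug
   death with probability $e^x/(e^x + c)$, $c = 0.6$. The source
   formulation is ambiguous about whether this sigmoid is a death or a
   survival probability; death rising with resistance score would invert
   every downstream result, so it is implemented as the escape
   probability (per-step drug death $\approx 0.82$ for a $-2$ score,
   $\approx 0.075$ for $+2$).
2. **Drug-induced plasticity**: sensitive survivors of drug exposure flip
   to R with probability `drug_induced_psr` ("what does not kill me makes
   me stronger").
3. **Stochastic switching**: S→R with `p_sr`, R→S with `p_rs`, plus an
   independent R→S draw with `met_induced_prs` modeling an MET-inducing
   signal — the mirror image of drug-induced plasticity and the model's
   combination-therapy lever.
4. **Proliferation**: survivors divide with probability
   $0.91\,(1 - N/K)$, $K = 10^5$, where $N$ is the population size at the
   start of the step; this makes the mean-field recursion exactly
   $N' = N(1-d)\,\bigl(1 + r(1 - N/K)\bigr)$, which the test suite checks
   against simulation with drug off. Daughters inherit the mother's state
   and redraw both scores (the mother keeps hers).

The event order within a step is not documented in the source formulation;
the order above makes "cells that survive drug exposure may switch"
literal and is a fixed constant, not a configuration knob. Initial
populations default to 100 cells, all sensitive; initial sensitive cells
resample their sensitive score until it is negative (and initial resistant
cells until positive), so "all-sensitive" is true cell by cell.
`estimate_extinction()` reports the fraction of replicates at zero cells by
the horizon (default 100 steps) with a binomial standard error;
`sweep_plane()` maps mean final sizes over the $(P_{SR}, P_{RS})$ grid.

### What reproduces, and what does not

The qualitative phase structure reproduces robustly: with no
sensitive-to-resistant switching the population is always eliminated;
with $P_{SR} = 1, P_{RS} = 0$ it survives and approaches carrying
capacity; $P_{SR} \gg P_{RS}$ survives, $P_{SR} \ll P_{RS}$ collapses;
MET induction (`met_induced_prs = 1`) collapses an otherwise surviving
population, and never increases final size.

The published *quantitative* extinction probabilities at intermediate
heterogeneity are not reproduced under the documented parameter set, and
the discrepancy is structural rather than a matter of tuning: with
$c = 0.6$ a resistant cell's per-step multiplication factor at low density
is $0.9 \times 0.925 \times 1.91 \approx 1.59$, so any founded resistant
lineage explodes and reported intermediate extinction probabilities
(together with survivor plateaus of order $10^3$ cells against
$K = 10^5$) would require near-critical growth that no ordering of the
stated events yields. The package reports its own computed values; the
corresponding checks in the test suite document the gap rather than hide
it.

## Problem sizes and determinism

Default analysis scales, chosen to make the ensemble statistics stable
(fractions move by under two percentage points between repeat runs) while
keeping a full analysis in the minutes range on one core: 5000 parameter
sets × 100 initial conditions for the census and correlation; 20–100
randomized topologies at 300 sets × 30 initial conditions for the
randomization control; 100 replicates per extinction estimate. Every
random element flows through R's RNG, so `set.seed()` (or the pipeline
functions' `seed` argument, fanned out per stage with `child_seed()`)
makes any run exactly reproducible; the compiled code draws its noise from
R's generator.

## Known limitations

- The synthetic ensemble emulates parameter uncertainty of one fixed
  wiring; it says nothing about expression data, measurement noise, or
  network inference — transcriptomic validation is outside the package's
  scope, so passing tests demonstrate internal consistency of the models,
  not clinical validity.
- Limit cycles are reported as non-converged rather than analyzed.
- Landscapes are occupancy-based pseudo-potentials, not equilibrium free
  energies; transition-rate theory is out of scope.
- The population model is well-mixed and cell-autonomous: no cooperation,
  competition, spatial structure, pharmacokinetics, or acquired mutations.

## A miniature run

```{r mini, eval = FALSE}
res <- run_ensemble_pipeline(n_sets = 500, n_init = 100, seed = 1)
res$multistability
res$correlation$rho
table(res$labels) / length(res$labels)

ext <- estimate_extinction(pop_config(sd = 0.7, p_sr = 0.5, p_rs = 1),
                           horizon = 100, n_replicates = 100)
c(ext$probability, ext$se)
```
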