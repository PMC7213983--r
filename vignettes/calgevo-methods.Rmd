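---
title: "Methods: ancestral calgranulin reconstruction and biophysical fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral calgranulin reconstruction and biophysical fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calgevo)
```

calgevo re-implements, at desk scale, the computational analyses that
surround an ancestral-protein resurrection study of the calgranulins
(S100A8/A9/A12/MRP126): reconstruction-robustness analysis, parsimony
mapping of proteolytic resistance, proteolysis and unfolding fits, and the
antimicrobial / NF-κB reporter assay summaries. This vignette records the
models, the parameter choices, and the reasoning behind design decisions
that the function reference does not cover.

## Ancestral reconstruction

### Model and scope

`marginal_asr()` computes per-site marginal posteriors over the 20 amino
acids at every internal node of a rooted tree by the inside/outside form of
the pruning algorithm: an upward (conditional-likelihood) pass and a
downward pass whose product at a node integrates over the states of all
other nodes. The substitution model is the equal-rates (Poisson-type)
model: all exchanges at the same rate, uniform equilibrium frequencies,
branch lengths in expected substitutions/site, with optional discrete-gamma
rate mixing (`gamma_shape`, mean-of-bin categories, equal weights).

A production reconstruction would use an empirical matrix such as LG with
gamma-distributed rates, fit by ML. We use the equal-rates model
deliberately: the downstream analysis logic — posteriors → altAll →
difference counts → topology comparisons — does not depend on the rate
matrix, and the simple model admits an exact brute-force oracle (exhaustive
summation over all internal-state assignments) against which the pruning
implementation is verified to 1e-10 on random trees. Verifiability was
chosen over fidelity; swapping in another reversible matrix would change
one function.

Trees are used as rooted at their root node, and a basal polytomy is
accepted: the pruning passes handle arbitrary multifurcations, although the
canonical study trees are binary.

### Gaps

Sites at which any tip carries a gap are excluded from posterior
computation and flagged with a warning; ancestors report the gap symbol
there. Indel history (e.g. the C-terminal extension that contributed two
histidines to A9's metal-binding site) is outside the model's scope, and
averaging posteriors over a site with missing data would silently change
the meaning of the confidence summary.

### altAll ancestors

`build_altall()` implements the worst-case-ancestor construction: at every
site whose *runner-up* (best non-ML) state has posterior probability
strictly greater than the threshold θ = 0.20, the runner-up replaces the ML
state. Choices the literature leaves open, fixed here:

* the comparison is strict (`> θ`), so a runner-up at exactly 0.20 is not
  substituted;
* only the single best alternate state is considered. When at most one
  alternate exceeds 0.20 — the typical case, since the ML state and one
  alternate already account for ≥ 0.40 — this coincides with "any state
  above threshold";
* ties between two non-ML states break to the alphabetically first; a tie
  between the ML state and the runner-up keeps the ML state;
* the *average posterior probability* reported for a reconstruction is the
  mean of the ML state's posterior over all non-gap sites, not only over
  unambiguous sites. Averaging over all sites is the conservative choice
  (ambiguous sites pull the average down) and matches how the summary is
  used: as a global confidence score for the reconstruction.

### Topology robustness

`enumerate_clade_topologies()` generates all rooted binary leaf-labeled
topologies over a set of clade names by recursive bipartition, fixing the
first label into one side so each unordered split is visited once. The
count is the double factorial (2n−3)!!: 15 for the four calgranulin clades.
Topologies are canonicalized by ordering, at every node, the child subtree
containing the alphabetically smallest leaf first; deduplication is string
equality on the canonical Newick. `compare_across_topologies()` then
reports, for ancestors reconstructed on each arrangement, the Hamming
distance to the reference ML ancestor, the mean across topologies, the
union of differing sites, and whether that union is contained in the
ML-vs-altAll substituted set — the condition under which the altAll
ancestor already bounds topological uncertainty.

### Parsimony

`fitch_parsimony()` is the textbook bottom-up pass (intersection when
non-empty, otherwise union, counting one change) for a binary trait on a
rooted binary tree. It is verified against brute-force minimization over
every internal labeling for all 1069 topologies with up to six leaves. On
the calgranulin phenotype pattern — A8 and A9 susceptible to proteolysis,
A12 and MRP126 resistant, on (((A8,A9),A12),MRP126) — the unique most
parsimonious scenario is a resistant ancestor with a single loss of
resistance on the A8+A9 stem.

## Densitometry

Gel images are numeric matrices (rows = migration position); lanes are
equal-width vertical strips (explicit boundaries can override) collapsed to
1-D profiles by summing across the strip. `quantify_band()` estimates the
background under a band as the straight line joining the median intensities
of small flanking regions (default 5 positions) on either side of a shared,
user-supplied band window, and integrates profile − background over the
window, floored at zero. This is the simplest scheme that is exactly
testable: it removes any background linear in migration position — hence
any constant offset — exactly, and on the synthetic gels (Gaussian band +
linear gradient) it is linear in the true band area, so fractions intact
are recovered to machine precision without noise. Saturated pixels (at a
user-declared level) produce a warning, not an error. Time courses are
normalized to the same-gel t = 0 lane; normalizing to a separate undigested
control gel would only rescale A₀, not the fitted rate.

## Kinetic and thermodynamic fits

### Exponential decay

`fit_exponential_decay()` fits f(t) = A₀·e^(−kt) by Levenberg–Marquardt
least squares, pooling all replicates into one global (A₀, k). Because
fractions are pre-normalized, A₀ ≈ 1; a per-replicate-amplitude variant
(shared k) sits behind `per_replicate_A0 = TRUE`. The loss is unweighted —
no error model for densitometry points is available. Standard deviations
are square roots of the covariance diagonal at the optimum. Starting values
come from a log-linear regression on the positive fractions. Two distinct
time points suffice arithmetically (the fit is then exact and a warning
notes that uncertainties are not estimable); four or more are needed for
meaningful uncertainties. `compare_rates()` reports pairwise log₁₀ rate
ratios with uncertainties propagated as sd(k)/(k·ln 10) in quadrature — the
scale on which the fast protomer vs slow heterocomplex contrast of roughly
three orders of magnitude is expressed.

### Two-state unfolding

`fit_two_state()` fits the linear extrapolation model

$$y(x) = \frac{b_f + m_f x + (b_u + m_u x)\,e^{-(\Delta G - m x)/RT}}
             {1 + e^{-(\Delta G - m x)/RT}}$$

with R = 0.001987 kcal·K⁻¹·mol⁻¹ and T = 298.15 K. All six parameters
float. Default initial guesses: baselines from linear fits to the three
lowest- and highest-x points; C_m from where the signal crosses the
baseline midpoint; m from the width of the central transition (the 25–75%
unfolded span is 2·ln(3)·RT/m). If the first start fails, up to five
jittered restarts are attempted before erroring. The midpoint C_m = ΔG/m is
reported with sd propagated from the full (ΔG, m) covariance, so
C_m·m = ΔG holds exactly for every fit. Post-fit diagnostics warn when the
fitted C_m lies outside the sampled denaturant range or when the two
baselines coincide at the midpoint (no resolvable transition). Note the
units: the gas constant is in kcal·K⁻¹·mol⁻¹ so that ΔG is in kcal/mol and
m in kcal·mol⁻¹·M⁻¹ — a joule-labeled constant with this numeric value
would be dimensionally inconsistent.

Convergence tolerances are 1e-14 (relative, on both sum-of-squares and
parameters) with at most 1024 iterations; noiseless synthetic curves are
recovered to better than 1e-6 relative error on all six parameters.

### Unfolding kinetics

`fit_unfolding_kinetics()` fits y(t) = y∞ + Δy·e^(−k_u·t) after a spike
into concentrated denaturant. Two situations flag `within_dead_time`: a
fitted relaxation time 1/k_u shorter than the instrument dead time, and a
trace with no resolvable amplitude (|y₁ − y_end| within 3× the point noise
estimated from first differences) — the signature of a protein that
finished unfolding before the first observable point, as fast-unfolding A9
variants do. Non-monotone traces (largest counter-trend excursion beyond 6×
the noise) warn but still fit.

## Assay summaries

`growth_inhibition()` averages technical replicates at the grid time
nearest the evaluation time (within half the 15-min sampling interval; no
interpolation), subtracts the media blank, and reports each treatment as a
percentage of untreated growth, aggregated as mean ± SEM across biological
replicates. Both the 7-h (text) and 12-h (figure) evaluation points are
supported; 7 h is the default and neither is privileged. A non-positive
untreated-minus-blank signal is an error rather than a silently infinite
percentage.

`nfkb_induction()` forms firefly/renilla per well, averages technical
replicates per plate, and linearly maps each treatment between the plate's
own LPS + polymyxin-B background (0) and LPS positive control (1). SEM is
across biological replicates with technical replicates averaged first — n
is the number of plates. Negative inductions are reported as-is. Mock wells
are reported but never enter the normalization, since only the two anchors
define the scale.

## Synthetic data: what it does and does not show

Every generator takes a mandatory seed, returns its ground truth alongside
the data, and is bit-reproducible. Noise models were chosen for
testability, not fidelity: multiplicative Gaussian on gel band areas
(default σ = 3%) and on decay fractions (default σ = 5%); additive Gaussian
on CD and OD600 signals; per-plate renilla scales with multiplicative
firefly noise for reporter plates. Logistic growth with treatment-dependent
lag and carrying capacity emulates the two phenotypes seen in the
antimicrobial assay (delayed growth vs reduced capacity). Named presets
mirror the magnitudes of the study system — "hA9-like" k = 0.3 min⁻¹ vs
"complex-like" k = 3·10⁻⁴ min⁻¹ (a three-orders-of-magnitude proteolysis
contrast) and a 4 kcal/mol stability difference at shared m = 1.6
kcal·mol⁻¹·M⁻¹ (a 2.5 M C_m shift) — but they are illustrative settings,
not measurements.

Passing the synthetic suites therefore demonstrates that the estimators
invert their generating models correctly at realistic noise, not that real
gels, CD traces or plates satisfy those models: real gels have smiling,
lane bleed and nonlinear staining; real unfolding of a calcium-bound dimer
is almost certainly not two-state; real plates have spatial effects. The
suite bounds implementation error, not model error.

Problem sizes used by the test and acceptance suites — 100 random ≤5-leaf
trees for the enumeration oracle, 2-site alignments for brute-force
comparisons, 25 seeded decay simulations per rate at 3 replicates × 10
points, three replicate 10-lane gels per rate — were chosen as the smallest
sizes at which the checked tolerances are comfortably meaningful.

## Known limitations

* The equal-rates substitution model is not an empirical amino-acid matrix;
  absolute posterior values on real alignments would differ (the analysis
  logic would not).
* No indel model: gap sites are excluded, not reconstructed.
* Single-band densitometry only; no multi-band deconvolution or
  molecular-weight calibration.
* Two-state and single-exponential models only; no intermediate-state or
  linkage (calcium-binding) models.
* Assay statistics stop at mean ± SEM, matching how such assays are
  typically reported; no hypothesis testing is implied.
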