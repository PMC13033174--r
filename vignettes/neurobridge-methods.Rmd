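---
title: "Models and methods behind neurobridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurobridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

neurobridge implements a multiscale analysis chain for computational
psychiatry: sparse brain–cognition signatures (SPLS), resting-state EEG
band-power statistics, a reverse-personalized canonical microcircuit
(rpDCM) forward model from synaptic density to EEG spectra, and
cross-modal prediction with nested cross-validated support vector
regression. A synthetic cohort generator with planted ground truth makes
every stage verifiable end to end. This vignette documents the models,
the numerical choices, and their limits.

## 1. The synthetic cohort generator

Real multiscale psychiatric cohorts (clinical scales, voxelwise gray
matter volume, EEG, iPSC-derived neuron assays, expression panels) are
rarely shareable. The generator plants known effects in each block so
that every downstream estimator can be tested against ground truth.

### Latent cross-block signatures

Each `latent_spec` plants one sparse signature linking the phenotype
block X (default 30 columns) and the GMV block Y (default 200 columns).
A latent factor is built from a driver (diagnosis indicator or age):

\[ f = \beta\,d + \sqrt{1 - \beta^2}\,\varepsilon, \qquad
   t_x = \sqrt{c_0} f + \sqrt{1-c_0}\, e_x, \quad
   t_y = \sqrt{c_0} f + \sqrt{1-c_0}\, e_y , \]

and the supported columns receive `t_x` (resp. `t_y`) plus i.i.d. noise
with standard deviation `noise_sd`. Because the *observable* block
scores are signed means over noisy supported columns, their correlation
is attenuated relative to `cor(t_x, t_y)`; the generator compensates by
inflating the latent share,

\[ c_0 = \rho_{\text{target}}
   \sqrt{(1 + \sigma^2/k_u)(1 + \sigma^2/k_v)} , \]

with `k_u`, `k_v` the support sizes, so that the score correlation of
the *observed* data hits the configured target (default 0.57 for the
diagnosis signature, 0.78 for the age signature). This compensation is
exact in expectation and verified at n = 5000 by the acceptance suite.

The two default signatures have disjoint supports (enforced by
validation), which makes "recovered the right signature" well defined in
tests. Realism limits: real signatures overlap, loadings are not
piecewise-constant, and GMV has spatial autocorrelation; none of that is
modeled, because the generator's purpose is estimator verification, not
biological simulation.

### Synapse densities

SYN1 puncta densities are log-normal: subject geometric means come from
`meanlog = log(gmean) - sdlog^2/2`, `sdlog = sqrt(log(1 + cv^2))`, so
the configured reduction (default 12.4%) applies to the *arithmetic*
group mean — the quantity a lab reports. Each subject contributes
`replicates_per_subject` replicate measurements with their own
log-normal scatter. `rho` is the subject mean divided by the HC group
mean, the quantity the rpDCM stage consumes.

### Empirical EEG spectra

Per electrode, the "empirical" PSD is a convex mixture of the subject's
simulated model spectrum (weight = electrode coupling) and a fixed
background `1/f^{1.3} + 0.8\exp(-(f-10)^2/8)`, scaled to a common total
power, then multiplied by mean-one log-normal measurement noise. The
default coupling map is F8-dominant (0.80; central electrodes 0.45;
others 0.15), mirroring the right-DLPFC localization the analysis is
meant to detect. This is the strongest idealization in the package:
real volume conduction mixes sources across all electrodes, and real
EEG noise is neither multiplicative nor independent across frequencies.

## 2. Sparse partial least squares

Components are sparse singular-vector pairs of the cross-covariance
`S = X'Y/(n-1)` of the z-scaled blocks, computed by alternating
soft-thresholded power iterations in the penalized-matrix-decomposition
convention: the L1 budget `c` bounds `||w||_1` of a unit-L2 weight
vector, so `c = 1` forces one nonzero coordinate and `c = sqrt(dim)`
removes the penalty. The per-iteration thresholding problem
`||s(w, lam)||_1 / ||s(w, lam)||_2 = c` is solved exactly: on each
segment between consecutive sorted magnitudes the ratio is a closed-form
scalar function of `lam`, so the active segment is located once and the
root obtained from a quadratic (equivalent to the usual bisection to
~1e-9, at a fraction of the cost; degenerate tied segments fall back to
scalar bisection).

### Budget selection

Budgets are chosen per component by 5-fold cross-validation maximizing
the held-out *covariance* between the two block scores, with a
one-standard-error rule toward sparsity. Covariance, not correlation:
held-out correlation is nearly flat in the budget (noise coordinates
dilute both scores proportionally), whereas covariance is diluted by
signal-free coordinates and therefore has a usable knee.

### Support refinement

Soft-thresholding retains a fringe of lucky-noise coordinates near the
L1 knee: in a fixed dataset some null columns correlate with the score
by chance, and no resampling of that dataset removes them. The fitted
support is therefore refined by universal-threshold screening — keep
coordinates whose correlation with the opposite-block score exceeds the
null scale `sqrt(2 log(dim)/n)` — followed by an exact rank-1 SVD refit
on the screened support, iterated until the support is stable.

### Significance and deflation

Each component is tested by permuting the rows of Y and refitting the
*budgeted soft-threshold* estimator (not the refined one), so observed
and permuted statistics are exchangeable;
`p = (1 + \#\{sv_{perm} \ge sv_{obs}\})/(n_{perm}+1)`. Extraction stops
at the first non-significant component. Between components, projection
deflation `X <- X - (Xu)u'`, `Y <- Y - (Yv)v'` keeps successive training
scores orthogonal.

## 3. EEG spectra and band statistics

Welch PSD: Hann windows of 2 s with 50% overlap, one-sided
normalization `2/(fs \sum w^2)`, native 0.5 Hz resolution, restricted
to 1–70 Hz. Six bands partition [1, 70]: delta 1–4, theta 4–8, alpha
8–12, beta 12–30, gamma1 30–50, gamma2 50–70 Hz. Band powers integrate
the PSD by the trapezoid rule on the shared grid; because adjacent bands
share their edge grid points, band powers are additive and relative
powers sum to exactly 1 (a conservation law the acceptance suite checks
to 1e-9). Group comparisons use the Mann–Whitney U test (exact
enumeration for combined n ≤ 16, tie-corrected normal approximation
otherwise) with Benjamini–Hochberg FDR across all electrode × band
features.

## 4. The canonical microcircuit and rpDCM

Four populations — spiny stellate (ss), superficial pyramidal (sp),
inhibitory interneuron (ii), deep pyramidal (dp) — each with
second-order synaptic kernel dynamics

\[ \ddot v = \kappa H u - 2\kappa\dot v - \kappa^2 v , \]

coupled through eight signed connections (excitatory: ss→sp, ss→ii,
sp→dp, dp→ii; inhibitory: ii→ss, ii→sp, ii→dp, ii→ii) and the centred
sigmoid `sigma(v) = 1/(1+exp(-r v)) - 1/2`. Because `sigma(0) = 0`,
`v = 0` is always an equilibrium; `cmc_fixed_point()` verifies it by
Newton iteration. Linearizing there (`sigma'(0) = r/4`) gives the 8×8
Jacobian, and the output spectrum follows analytically:

\[ \mathrm{PSD}(f) = |L (2\pi i f I - J)^{-1} B|^2 \, S_u(f),
   \qquad S_u(f) = a_{\text{white}} + a_{\text{pink}}/f , \]

with innovations entering the ss velocity (B) and the output a fixed
mixture of population voltages (L, superficial-pyramidal dominated).
The spectrum is exactly linear in the innovation variance — a structural
invariant tested to machine precision.

rpDCM *personalization* runs this model forward per subject: the gains
of a regime-selected connection class (ALL, EXC_ONLY, INH_ONLY, or a
named excitatory subset) are multiplied by the subject's relative
synapse density ρ. No model inversion is performed.

### Calibration of the default parameters

The referenced literature specifies the CMC equations but not a
parameterization for this purpose, so `cmc_default_params()` is the
output of `calibrate_base_params()`: a penalized simulated-annealing
search seeded from two-population loop theory (a slow dp–ii loop sets
the alpha resonance, `omega ≈ 0.707 G^{1/4}`; a fast ss–ii loop sets
gamma). Feasibility constraints, fixed a priori:

1. stability (all Jacobian eigenvalues in the left half-plane);
2. a single dominant spectral peak between 8.5 and 12.5 Hz;
3. a realistic resting band mix (bounded theta and gamma shares, alpha
   at least 20% of total power);
4. monotone theta-up / gamma-down response as excitatory gains scale
   down over ρ in [0.7, 1];
5. regime specificity: at ρ = 0.876 (the 12.4% reduction) the
   schizophrenia pattern theta↑, gamma1↓, gamma2↓ appears under
   EXC_ONLY scaling but *not* under INH_ONLY scaling;
6. Euler fidelity (below).

Subject to feasibility the search maximizes the elasticity
`d log P_gamma1 / d log rho`, which controls how well per-subject
densities can be read back out of gamma-band power.

### Why an Euler-fidelity constraint

The time-domain oracle integrates the nonlinear system with explicit
Euler–Maruyama at dt = 0.5 ms. Explicit Euler reduces the effective
damping of a resonance at angular frequency ω by about `ω² dt/2` — at
40 Hz and this dt, ≈ 8 s⁻¹ — which inflates narrow high-frequency peaks.
Rather than hiding this with a looser test tolerance, calibration
constrains the *exact discrete* transfer function
`|L(zI - (I + J\,dt))^{-1} B\,dt|²` at `z = e^{i\omega dt}` to match the
continuous band powers within ~10%, so parameter sets whose spectra
would be misrepresented by the simulation grid are rejected outright.
The packaged defaults agree with the stochastic simulation within 9%
in every band (acceptance tolerance 15%).

Innovations for the simulation are synthesized in the frequency domain
(Hermitian spectrum with the model's `S_u`, real Nyquist bin), which
gives realizations with exactly the nominal spectrum and avoids
low-frequency truncation bias that recursive pink-noise filters have at
finite length.

## 5. Prediction: nested SVR

`nested_cv_svr()` regresses a continuous target (e.g. a signature's
cognition score) on the expression block with a linear epsilon-SVR
(e1071). The cost parameter is chosen by inner cross-validation on the
training folds only; features are scaled with training-fold statistics
only; predictions are averaged over repeated outer splits. Importance is
CVR-OM: per-feature mean weight over outer folds divided by its standard
error, averaged over repeats (zero-variance weights get a ±1e6
sentinel). Significance comes from label permutation of the full nested
pipeline with a reduced repeat count (a documented cost decision), and a
random-feature baseline situates the observed r against models built on
random feature subsets of equal size. Group discrimination of predicted
scores is summarized by a rank-based AUC, which is invariant under
monotone transforms of the predictions.

## 6. Statistics core

* Mann–Whitney U: exact enumeration over all `choose(n1+n2, n1)` group
  assignments when the combined n ≤ 16 (valid under ties by construction),
  otherwise the tie-corrected normal approximation with a clamped
  continuity correction, `z = max(0, |U - mu| - 1/2) / sigma`, which
  halves the worst-case deviation from the exact test near the n = 16
  boundary while still giving p = 1 exactly for identical groups.
* BH-FDR via `stats::p.adjust`, cross-checked against a brute-force
  step-up implementation in the acceptance suite.
* Spearman: rank-then-Pearson with average ranks and a t p-value.
* Fisher-z confidence intervals for correlations.

## 7. Reproducibility and orchestration

`run_experiment()` executes simulate → spls → eeg → rpdcm → predict,
writing TSV/JSON reports plus the fully-echoed YAML config with an
FNV-1a config hash; a rerun with the same config is byte-identical. All
artifacts are plain text. Every stochastic function takes an explicit
seed, and cohort sub-stages derive their own sub-seeds so that blocks
are reproducible independently.

## 8. Limitations

* The generator's effects are linear-Gaussian with planted supports;
  estimator performance on it is an upper bound, not a forecast for
  clinical data.
* The CMC parameterization is a calibrated construction satisfying the
  qualitative constraints above, not a fit to any subject's EEG.
* One electrode mixture and one background spectrum stand in for volume
  conduction; no connectivity, no topography beyond the coupling map.
* The permutation test for SVR uses fewer internal repeats than the
  observed fit to stay affordable; its p-values are correspondingly
  coarser.
* Problem sizes (30 phenotype features, 200 voxels, 310 genes, 10
  electrodes) are package defaults chosen to keep desk-scale runs in
  minutes; they are not claims about optimal dimensionality.
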