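---
title: "Likelihood targets for experiment-guided structure prediction"
author: "llgrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood targets for experiment-guided structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llgrefine)
```

## The problem

Machine-learned structure predictors produce accurate models of a
protein's most favoured conformation, but experimental data — X-ray
diffraction intensities or cryo-EM half-maps — often capture a different
state. This package implements the computational core of a refinement
strategy that reconciles the two: instead of pushing Cartesian
coordinates against the data, it learns a multiplicative bias `w` and an
additive bias `b` on the predictor's MSA cluster-profile input
(`m = w * m0 + b`) so that the predicted structure maximizes an
experimental log-likelihood gain (LLG). The predictor stays frozen; only
its input representation moves. The package runs at desk scale with a
deterministic toy predictor standing behind the same contract a neural
predictor would satisfy (profile in; coordinates and per-residue
confidence out; differentiable in the profile).

## The experimental likelihoods

**Crystallographic target (LLGI).** Observed intensities and their
uncertainties `(I_o, sigma_I)` are converted into effective normalized
amplitudes `E_e` and an error attenuation `D_obs` in `[0, 1]`. Model
amplitudes are normalized per resolution bin to `E_C`. With
`d = D_obs * sigma_A`, each acentric reflection contributes the log ratio
of a Rice density to the Wilson null, and each centric reflection the
analogous Woolfson/cosh form:

$$\mathrm{LLGI} = \sum_h \ln p(E_e; E_C, d) - \ln p(E_e).$$

`sigma_A`, the resolution-dependent correlation between true and model
structure factors, is refined per bin by Newton–Raphson on the analytic
derivative of the binned LLG, clamped to `[0.015, 0.99]`, using
working-set reflections only. A 5% free set is reserved for `R_free`
reporting.

**Cryo-EM target.** The two half-maps give, per resolution shell, the
signal power `S = max(0, Re<F1 conj(F2)>)` and the noise power (per
averaged-map term) `N = <|F1 - F2|^2>/4`; then `D_obs = sqrt(S/(S+N))`,
and the observed term is the averaged map normalized by `sqrt(S+N)`.
Each Fourier term contributes

$$\frac{2 d E_e E_c \cos\Delta\phi}{1-d^2}
 - \frac{d^2 (E_e^2 + E_c^2)}{1-d^2} - \ln(1-d^2),$$

which is zero when `d = 0` and increasing in the phase agreement.
Because this target carries phases, it determines all six rigid-body
degrees of freedom; the amplitude-only LLGI, by contrast, is *exactly*
invariant under rigid translations of a single molecule in P1, so
translational placement information must come from phase-informed data
(or, upstream, from molecular replacement). Noise shells are spherical;
directional (anisotropic) noise is out of scope.

## Effective amplitudes from intensities

The conversion `(I_o, sigma_I) -> (E_e, D_obs)` uses truncated-Wilson
posterior moments: intensities are scaled by the per-bin Wilson mean, a
Gaussian intensity likelihood is combined with the Wilson prior over
`E >= 0` (acentric `2E exp(-E^2)`, centric `sqrt(2/pi) exp(-E^2/2)`), and
the posterior is integrated numerically on a fixed grid (601 points over
`[0, 6]`). `E_e` is the posterior mean, and
`D_obs = sqrt(1 - Var_post/Var_prior)`, which collapses to 1 as the
noise vanishes and to 0 when the measurement is uninformative. Averaged
over reflections, `D_obs` approximates the correlation between `E_e` and
the true normalized amplitude. Note that the square root makes the
*null* level of `D_obs` decay only like `n^{-1/4}` with the number of
terms used to estimate shell statistics.

## Alignment, pose refinement and confidence weighting

Predictions arrive in an arbitrary frame. Each iteration aligns the
predicted Calphas to the placed reference by a weighted Kabsch
superposition; the weights come from the reference prediction's pLDDT
via the empirical conversion
`pseudoB = (8*pi^2/3) * (1.5 * exp(4*(0.7 - 0.01*pLDDT)))^2` followed by
a piecewise weight (1 below 11.5 Å², a linear ramp to 0.5 at 40 Å², then
`0.5*exp(-sqrt(pseudoB-40))`). Weights are computed once from the first,
unconditioned prediction and frozen. A short gradient ascent over a
6-parameter pose (axis-angle about the weighted centroid, plus
translation) then maximizes the experimental LLG itself; proposals are
accepted only if they improve the target, so the refined pose never
scores worse than the Kabsch pose.

## The two-phase optimization loop

The engine's defaults follow the two-phase schedule: phase 1 runs three
seeded traces of 100 iterations with aggressive learning rates
(`lr_mul = 1.0`, `lr_add = 0.05`, adam), a confidence-weighted L2
restraint to the reference with weight `1e-11`, and only reflections (or
Fourier terms) with `d >= 3` Å; the trace with the best final LLG seeds
phase 2, which runs up to 500 iterations at `lr = 1e-3` for both biases,
drops the restraint, uses all data, and stops early once the LLG has
failed to improve by more than 0.1 for 50 consecutive iterations. The
3-Å phase-1 rule is implemented as *keeping* the low-resolution data
(`d >= 3` Å): low-resolution terms vary smoothly under large moves,
which is what an adventurous phase needs. Adam state is reset between
phases. Traces beyond the first start from a small seeded jitter of the
additive bias (sd 0.02), standing in for the stochasticity a dropout-
enabled neural predictor would supply; per-trace seeds are
`base_seed + trace`.

Within one iteration the loss is `L = -LLG + omega_L2 * L2`, both terms
evaluated at the rigid-body-refined coordinates. Gradients with respect
to `(w, b)` are fully analytic: through the elementwise bias, the
predictor's pooling and linear decoder, the exact rotating-bond Jacobian
of the ideal-geometry chain builder, the entropy-to-pLDDT-to-pseudo-B
confidence head, the structure-factor sum (including the dependence of
the per-bin normalization constants on every member amplitude), and the
likelihood terms. Two quantities are deliberately treated as constants
inside each gradient step: the alignment pose and `sigma_A`. Both sit at
stationary points of the target (the pose by construction of the
rigid-body ascent, `sigma_A` as the per-bin maximizer), so by the
envelope theorem the dropped terms vanish to first order; this is the
"detached alignment" pattern. The finite-difference checks in the test
suite freeze pose and `sigma_A` accordingly.

The biased profile is *not* clipped or renormalized before prediction;
values can leave `[0, 1]`. Only the confidence head, whose entropy is
undefined for negative weights, clamps its input at `1e-6` (with a
matching zero gradient at the clamp).

## The toy predictor and what passing tests mean

The toy predictor pools the profile over clusters (mean), maps each
residue's pooled 23-vector linearly to phi/psi torsion offsets from a
baseline conformation, builds an ideal-geometry N–CA–C backbone, and
emits pLDDT as a fixed logistic function of pooled column entropy
(centred at 3.6 nats with slope 0.25, so typical profiles score in the
high 80s/90s). The decoder coefficients are fixed at construction
(seeded Gaussian, scale 0.25/sqrt(23) per entry); by a minimum-norm
construction an exact additive bias `b*` reproduces any reachable target
conformation. Torsional freedom can be restricted to a window of
residues (`flexible =`): this emulates a predictor whose prior holds the
confidently modelled scaffold rigid while a loop remains ambiguous, and
it is what makes greedy likelihood ascent well-posed at desk scale — a
fully flexible linear decoder has no structural prior and drifts into
distorted local optima that a real predictor's manifold excludes. The
generator emulates: localized two-state conformational change, Wilson-
statistics intensities with Gaussian measurement error, flat Fourier
noise on half-maps, and planted pairwise profile couplings. It does not
emulate side chains, solvent, anisotropy, crystal contacts, or the
highly structured error modes of real predictors, so passing tests
demonstrate the correctness and self-consistency of the machinery, not
performance on real data.

## Map degradation to a target resolution

The parametric curve `FSC(s) = r / (r + exp(delta_B s^2 / 4))` models a
signal/noise power ratio `r` at zero angle with falloff difference
`delta_B`. Empirical coefficient laws give `(r, delta_B)` for a desired
cutoff `s_max` such that the curve crosses 0.143 at `s_max`. Degradation
estimates per-shell signal and noise from the current halves, adds
independent shaped Gaussian noise (generated in real space so maps stay
real) until the *half-map* FSC matches the target curve, clamping at
zero where the data are already worse than the target, and finally
zeroes all terms beyond `s_max`. Shells are uniform in `s` and
concentrate on the retained band (up to `1.3 * s_max`); a shell
straddling the cutoff mixes genuine and zeroed terms, so quantitative
FSC comparisons use shells wholly inside the band.

## Mutual-information analysis of optimized profiles

Cluster profiles are treated as equally weighted soft samples: each
cluster/residue column is renormalized, the joint of a residue pair is
the cluster-averaged outer product, and MI (nats) is taken against the
product of cluster-averaged marginals. Pairs are ranked by `|delta MI|`
between initial and optimized profiles (lexicographic tie-break), and
"muting" restores whole residue columns (every cluster and symbol) of
the selected residues to their initial values — both members of each
top pair. With few clusters the estimator's finite-sample bias makes
even independent sharply-concentrated columns look coupled; the fixture
generator therefore defaults to 24 clusters, enough for planted
couplings to dominate the ranking. Heat-map normalization, when
requested, is min–max to `[0, 1]` and tagged on the returned object.

## Numerical choices

- Bessel/cosh terms are evaluated in log space via exponentially scaled
  `besselI`, stable for arbitrarily large arguments.
- `sigma_A` refinement: vectorized over bins; analytic first derivative,
  first-sweep finite-difference curvature then secant updates; damped
  uphill steps where the objective is locally convex (optimum at a clamp);
  a bounded line search catches unconverged bins; tolerance `1e-4`, at
  most 20 sweeps, warm-started across engine iterations.
- Structure factors: direct summation with 4-Gaussian form factors for
  C/N/O/S (carbon fallback with a warning), compiled kernel, analytic
  reverse mode for coordinates and isotropic B. Space groups are handled
  natively in P1; symmetry metadata (centricity, epsilon) supports the
  common low-symmetry groups, and other groups are expected to arrive
  already expanded to P1.
- Resolution bins: equal-count, default 10–20 bins with a minimum
  occupancy; empty or degenerate bins are an error.
- Equal-arm central differences are used in every finite-difference
  test; gradient tolerances are 1e-4 to 1e-5 relative.
- Degenerate inputs: `d = D_obs*sigma_A >= 1` is rejected (variance
  `1-d^2 <= 0`); all-negative intensity bins warn and proceed; empty
  free sets warn and return `NA` for `R_free`.

## Problem sizes used by the shipped experiments

The end-to-end recovery experiment refines a 16-residue two-state chain
(4-residue loop flip of 1.2/-1.5 rad, Calpha displacement > 2 Å) against
(a) P1 intensities to 3.0 Å with 10% fractional error in a padded box
(margin 10 Å) and (b) 48^3 half-maps (1 Å voxels) with flat Fourier
noise at 25% of mean signal power, scored to 5 Å. Twenty seeded
replicates per modality run the full default schedule. Degradation
fidelity is checked on a 64^3 pair at 6, 8 and 10 Å. These sizes were
chosen so each replicate exercises every stage of the pipeline in a few
tens of seconds on one core.

## Known limitations

- Single chain, isotropic B, no solvent model (a flat-solvent option is
  deliberately omitted by default), no anomalous signal, no twinning.
- Amplitude-only crystallographic data cannot drive translational pose
  corrections (see above); upstream placement is assumed correct up to
  the rotational/loop scale the engine explores.
- The exact construction of `E_e`/`D_obs` in production crystallography
  pipelines involves integration over calibrated error models; the
  moment-matching construction here satisfies the same limits and
  calibration contract but is not numerically interchangeable with any
  specific external implementation.
- pLDDT-as-target optimization is available as a control
  (`plddt_target()`), but with the toy predictor it carries no claim
  about neural-predictor behaviour.

## A short tour

```{r tour, eval = FALSE}
rec <- fixture_recipe(d_min = 3.0, cell_margin = 10, seed = 7)
ts <- make_toy_structure(rec)
prof <- simulate_profiles(rec)
sim <- simulate_reflections(ts$state_b, rec)      # data from state B
target <- xtal_target(sim$refl, sim$cell)

flex <- c(min(rec$loop) - 1, rec$loop, max(rec$loop) + 1)
pred <- toy_predictor(prof$m_init, ts$torsions_a, ts$torsions_b,
                      flexible = flex)
p0 <- pred$predict(prof$m_init)                   # initial prediction: state A
placed <- weighted_kabsch(ca_coords(p0$model), ca_coords(sim$model))

fit <- refine_structure(pred, target, placed$x_aligned, p0$plddt,
                        refinement_config(seed = 7))
summary(fit)
ca_rmsd(fitted(fit), sim$model)                   # closer to state B than p0
plot(fit)
```
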