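# llgrefine

Likelihood-targeted refinement of predicted protein structures, in R.

Structure predictors trained on evolutionary data usually return one
favoured conformation; X-ray diffraction intensities or cryo-EM half-maps
often support another. `llgrefine` implements the computational core of a
refinement strategy that closes this gap *in the predictor's input space*:
it learns a multiplicative bias `w` and an additive bias `b` on an MSA
cluster profile, `m = w ⊙ m₀ + b`, so that the structure predicted from the
biased profile maximizes an experimental log-likelihood gain (LLG). The
package is aimed at methods developers in structural biology who want a
small, fully tested, fully differentiable reference implementation of the
statistical machinery involved.

What is implemented, end to end and with analytic gradients throughout:

- **Crystallographic LLGI target** — intensity-based log-likelihood gain
  with Rice (acentric) and Woolfson (centric) conditional densities,
  `E_e`/`D_obs` effective amplitudes from `(I_o, σ_I)` by truncated-Wilson
  posterior moments, per-bin Wilson E-normalization, and per-bin `σ_A`
  refined by Newton–Raphson, clamped to `[0.015, 0.99]`:
  `LLGI = Σ_h [ln p(E_e; E_C, D_obs σ_A) − ln p(E_e)]`.
- **Cryo-EM LLG target** — per-shell signal/noise from half-map Fourier
  terms (`S = max(0, Re⟨F₁F₂*⟩)`, `N = ⟨|F₁−F₂|²⟩/4`,
  `D_obs = √(S/(S+N))`) and the Fourier-term gain
  `2dE_eE_c cosΔφ/(1−d²) − d²(E_e²+E_c²)/(1−d²) − ln(1−d²)`.
- **Confidence plumbing** — pLDDT → pseudo-B (`(8π²/3)(1.5 e^{4(0.7−0.01·pLDDT)})²`)
  and pseudo-B → piecewise alignment weights.
- **Weighted Kabsch superposition and rigid-body refinement** by gradient
  ascent of the LLG over a 6-parameter pose.
- **The two-phase profile-bias optimizer** — three seeded adventurous
  traces (adam, `lr_mul = 1.0`, `lr_add = 0.05`, weighted L2 restraint
  `ω = 10⁻¹¹`, data to 3 Å) followed by fine-tuning (`lr = 10⁻³`, all data,
  early stop at ≤ 0.1 LLG gain over 50 iterations), behind one fitting
  function returning a classed object.
- **FSC modelling and map degradation** — `FSC(s) = r/(r + e^{ΔB s²/4})`,
  the empirical coefficient laws tying `(r, ΔB)` to a resolution cutoff at
  the 0.143 criterion, least-squares FSC fitting, and seeded noise
  injection that degrades half-maps to a target resolution.
- **Profile mutual information** — MI matrices from cluster profiles,
  ΔMI pair ranking, and progressive muting back to the initial profile,
  with random/entropy/mean-|ΔMI| baselines.
- **Synthetic fixtures** — a two-state ideal-geometry toy chain, simulated
  intensities, half-maps and coupled cluster profiles; plus a deterministic
  differentiable toy predictor with an exact target-reproducing bias.
- **I/O and CLI** — PDB (via bio3d), reflection CIF, MRC maps, plain-text
  profile arrays, YAML configs, and a thin command-line front-end
  (`inst/cli/llgrefine-cli.R`) with `simulate`, `refine-xtal`, `refine-em`,
  `degrade-map`, `mi-analyze` and `validate` subcommands.

## A worked example

Data are simulated from conformation B of a 16-residue two-state chain;
the predictor's baseline output is conformation A (2.3 Å away over the
loop). Refining the profile bias against the intensities moves the model
toward B:

```r
library(llgrefine)

rec  <- fixture_recipe(d_min = 3.0, cell_margin = 10, seed = 7)
ts   <- make_toy_structure(rec)
prof <- simulate_profiles(rec)
sim  <- simulate_reflections(ts$state_b, rec)      # I_o, sigma_I, E_e, D_obs
target <- xtal_target(sim$refl, sim$cell)

flex <- c(min(rec$loop) - 1, rec$loop, max(rec$loop) + 1)
pred <- toy_predictor(prof$m_init, ts$torsions_a, ts$torsions_b,
                      flexible = flex)
p0   <- pred$predict(prof$m_init)                  # initial prediction
placed <- weighted_kabsch(ca_coords(p0$model), ca_coords(sim$model))

fit <- refine_structure(pred, target, placed$x_aligned, p0$plddt,
                        refinement_config(seed = 7))
print(fit)
#> Likelihood-guided profile refinement
#>   best LLG: 161.798  (stop: early_stop, trace 2 selected for phase 2)
#>   iterations: 300 phase 1 (3 traces), 80 phase 2

round(c(start = ca_rmsd(p0$model, sim$model),
        final = ca_rmsd(fitted(fit), sim$model)), 2)
#> start final
#>  2.28  1.24
```

`ca_rmsd` is the Cα root-mean-square deviation to the data-generating
conformation after superposition: the refined model moved from 2.28 Å to
1.24 Å (about half of the loop flip is recovered at this seed; the
best-LLG model is returned), and `logLik(fit)` reports the experimental
LLG of the returned model. `coef(fit)` returns the learned `(w, b)`, `plot(fit)` the LLG
trace across both phases. The same engine drives the cryo-EM target
(`em_target`) against simulated half-maps.

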