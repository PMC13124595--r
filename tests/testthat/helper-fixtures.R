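# shared small fixtures, built once per test run
.fix_env <- new.env()

small_recipe <- function() fixture_recipe(n_residues = 10, d_min = 3.0,
                                          cell_margin = 8, seed = 11L)

# toy structure + simulated reflections for a 10-residue chain (memoized)
get_xtal_fixture <- function() {
  if (is.null(.fix_env$xtal)) {
    rec <- small_recipe()
    ts <- make_toy_structure(rec)
    sim <- simulate_reflections(ts$state_b, rec)
    .fix_env$xtal <- list(rec = rec, ts = ts, sim = sim)
  }
  .fix_env$xtal
}

# small half-map pair on a 48^3 grid (memoized)
get_em_fixture <- function() {
  if (is.null(.fix_env$em)) {
    rec <- fixture_recipe(n_residues = 10, seed = 21L, map_noise = 0.3)
    ts <- make_toy_structure(rec)
    hmv <- simulate_half_maps(ts$state_b, rec)
    ft1 <- map_fourier_terms(hmv$map1)
    ft2 <- map_fourier_terms(hmv$map2)
    sh <- make_shells(ft1$s, n_shells = 10, s_max = 1 / 3)
    hm <- halfmap_statistics(ft1$F, ft2$F, sh)
    .fix_env$em <- list(rec = rec, ts = ts, hmv = hmv, ft1 = ft1, ft2 = ft2,
                        sh = sh, hm = hm)
  }
  .fix_env$em
}

# independent plain-loop structure-factor oracle
sf_brute_force <- function(model, cell, refl) {
  F <- complex(length.out = nrow(refl))
  for (i in seq_len(nrow(refl))) {
    for (j in seq_len(nrow(model))) {
      xf <- cell$frac %*% c(model$x[j], model$y[j], model$z[j])
      ph <- 2 * pi * sum(c(refl$h[i], refl$k[i], refl$l[i]) * xf)
      F[i] <- F[i] + model$occ[j] * form_factor(model$element[j], refl$s[i]) *
        exp(-model$b[j] * refl$s[i]^2 / 4) * exp(1i * ph)
    }
  }
  F
}

# independent unweighted Kabsch via base svd, no shared code path
kabsch_oracle <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
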