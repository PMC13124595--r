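test_that("parametric FSC curve has the stated closed-form properties", {
  m <- fsc_model(100, 400)
  expect_equal(fsc_curve(m, 0), 100 / 101, tolerance = 1e-12)
  # delta_B s^2 / 4 = ln r  ->  FSC = 1/2
  s_half <- sqrt(4 * log(100) / 400)
  expect_equal(fsc_curve(m, s_half), 0.5, tolerance = 1e-12)
  expect_equal(fsc_curve(m, 0.25), 100 / (100 + exp(400 * 0.25^2 / 4)),
               tolerance = 1e-12)
  s <- seq(0, 0.5, 0.01)
  expect_true(all(diff(fsc_curve(m, s)) < 0))
  expect_error(fsc_curve(m, -0.1), "non-negative")
})

test_that("empirical coefficient laws reproduce the resolution criterion", {
  m <- empirical_fsc_target(0.25)
  expect_equal(m$r, 34.4680 * exp(3.00533 * 0.25 + 4.27895 * 0.0625),
               tolerance = 1e-12)
  expect_equal(m$delta_b, 17.1158 + 12.0213 / 0.25 + 21.3225 / 0.0625,
               tolerance = 1e-12)
  expect_lt(abs(m$r - 95.5), 1)
  expect_lt(abs(m$delta_b - 406.4), 1)
  for (smax in c(0.125, 0.25, 0.5)) {
    mm <- empirical_fsc_target(smax)
    expect_lt(abs(fsc_curve(mm, smax) - 0.143), 0.01)
  }
  # r increasing, delta_B decreasing in s_max
  sm <- seq(0.1, 0.5, 0.05)
  rs <- vapply(sm, function(x) empirical_fsc_target(x)$r, numeric(1))
  dbs <- vapply(sm, function(x) empirical_fsc_target(x)$delta_b, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(diff(dbs) < 0))
  expect_error(empirical_fsc_target(0.9), "range")
})

test_that("FSC model fitting recovers parameters and the 0.143 crossing", {
  truth <- fsc_model(150, 245)
  s <- seq(0.02, 0.45, length.out = 40)
  fit <- fit_fsc_model(fsc_curve(truth, s), s)
  expect_lt(abs(fit$r - 150) / 150, 0.02)
  expect_lt(abs(fit$delta_b - 245) / 245, 0.02)
  expect_lt(attr(fit, "residual"), 1e-6)
  expect_lt(abs(fsc_curve(truth, fit$s_max) - 0.143), 1e-4)
  # invariant to duplicating every point
  fit2 <- fit_fsc_model(rep(fsc_curve(truth, s), 2), rep(s, 2))
  expect_equal(fit2$r, fit$r, tolerance = 1e-4)
  # a curve that stays above 0.143 has no crossing
  expect_warning(f3 <- fit_fsc_model(fsc_curve(fsc_model(5000, 5), s), s),
                 "0.143")
  expect_true(is.na(f3$s_max))
})

test_that("shell FSC matches its definition and known signal/noise", {
  set.seed(10)
  n <- 4000
  sh <- list(id = rep(1:4, each = 1000), centers = c(0.1, 0.2, 0.3, 0.4))
  Tsig <- complex(real = rnorm(n), imaginary = rnorm(n))
  F1 <- Tsig; F2 <- Tsig
  expect_equal(compute_fsc(F1, F2, sh), rep(1, 4), tolerance = 1e-12)
  noise <- function(p) complex(real = rnorm(n, 0, sqrt(p / 2)),
                               imaginary = rnorm(n, 0, sqrt(p / 2)))
  expect_true(all(abs(compute_fsc(noise(1), noise(1), sh)) < 0.1))
  S <- 2; N <- c(0.5, 1, 2, 4) * 2
  F1 <- Tsig + noise(1)[1:n] * sqrt(N[sh$id] / 2)
  F2 <- Tsig + noise(1)[1:n] * 0
  # construct with exact per-shell noise powers instead
  mk <- function() complex(real = rnorm(n, 0, sqrt(N[sh$id] / 2)),
                           imaginary = rnorm(n, 0, sqrt(N[sh$id] / 2)))
  f1 <- Tsig + mk(); f2 <- Tsig + mk()
  fsc <- compute_fsc(f1, f2, sh)
  expect_true(all(abs(fsc - S / (S + N)) < 0.05))
})

test_that("degradation matches the target FSC and zeroes beyond s_max", {
  # high-quality input pair: current FSC above any low-resolution target
  rec <- fixture_recipe(n_residues = 10, seed = 31L, map_noise = 0.02)
  ts <- make_toy_structure(rec)
  hmv <- simulate_half_maps(ts$state_b, rec)
  target <- empirical_fsc_target(1 / 8)
  dg <- degrade_half_maps(hmv$map1, hmv$map2, target, seed = 5, n_shells = 6)
  ft1 <- map_fourier_terms(dg$map1)
  ft2 <- map_fourier_terms(dg$map2)
  expect_lt(max(Mod(ft1$F[ft1$s > target$s_max])), 1e-8 * max(Mod(ft1$F)))
  expect_lt(max(Mod(ft2$F[ft2$s > target$s_max])), 1e-8 * max(Mod(ft2$F)))
  fsc <- compute_fsc(ft1$F, ft2$F, dg$shells)
  tgt <- fsc_curve(target, dg$shells$centers)
  nterm <- tabulate(dg$shells$id, nbins = length(dg$shells$centers))
  # compare only shells fully inside the retained band (a shell straddling
  # the cutoff mixes genuine and zeroed terms)
  upper <- dg$shells$edges[-1]
  sel <- which(upper <= target$s_max & nterm >= 50)
  expect_gt(length(sel), 2)
  expect_true(all(abs(fsc[sel] - tgt[sel]) < 0.05))
  # reproducible under the same seed
  dg2 <- degrade_half_maps(hmv$map1, hmv$map2, target, seed = 5, n_shells = 6)
  expect_identical(dg$map1$grid, dg2$map1$grid)
})

test_that("degrading to the pair's own FSC curve adds almost no noise", {
  # construct halves whose true FSC lies exactly in the parametric class:
  # Gaussian-falloff signal power plus flat noise gives
  # FSC = r / (r + exp(delta_B s^2 / 4)) with delta_B twice the signal
  # falloff
  set.seed(17)
  g <- 48
  nvox <- g^3
  e <- array(rnorm(nvox), c(g, g, g))
  ftw <- map_fourier_terms(density_map(e, voxel = 1))
  r0 <- 20; Bs <- 100                        # delta_B = 200 A^2
  shaped <- ftw$F * sqrt(r0 * exp(-Bs * ftw$s^2 / 2))
  sig <- fourier_to_map(shaped, c(g, g, g), voxel = 1)
  half <- function() density_map(sig$grid +
                                   array(rnorm(nvox, 0, 1), c(g, g, g)),
                                 voxel = 1)
  h1 <- half(); h2 <- half()
  fta <- map_fourier_terms(h1$grid |> density_map(voxel = 1))
  ftb <- map_fourier_terms(h2$grid |> density_map(voxel = 1))
  sh_full <- make_shells(fta$s, n_shells = 16, s_max = 0.45)
  fsc0 <- suppressWarnings(compute_fsc(fta$F, ftb$F, sh_full))
  ok0 <- is.finite(fsc0) & fsc0 > 0 & fsc0 < 1
  cur_fit <- fit_fsc_model(fsc0[ok0], sh_full$centers[ok0])
  expect_lt(abs(cur_fit$delta_b - 200) / 200, 0.15)
  dg0 <- suppressWarnings(degrade_half_maps(h1, h2, cur_fit, seed = 6,
                                            n_shells = 10))
  # added power is a small fraction of the per-half noise power (n_vox)
  # over the retained band (shells beyond s_max are zeroed, not matched)
  keep_sh <- dg0$shells$edges[-1] <= cur_fit$s_max
  expect_lt(max(dg0$noise_added[keep_sh]) / nvox, 0.25)
})

test_that("degrade-measure-fit round trip recovers the cutoff", {
  rec <- fixture_recipe(n_residues = 10, seed = 31L, map_noise = 0.02)
  ts <- make_toy_structure(rec)
  hmv <- simulate_half_maps(ts$state_b, rec)
  target <- empirical_fsc_target(1 / 6)
  dg <- suppressWarnings(degrade_half_maps(hmv$map1, hmv$map2, target,
                                           seed = 9, n_shells = 14))
  ft1 <- map_fourier_terms(dg$map1)
  ft2 <- map_fourier_terms(dg$map2)
  fsc <- suppressWarnings(compute_fsc(ft1$F, ft2$F, dg$shells))
  nterm <- tabulate(dg$shells$id, nbins = length(dg$shells$centers))
  ok <- is.finite(fsc) & nterm >= 30 & fsc > 0 & fsc < 1 &
    dg$shells$edges[-1] <= target$s_max
  fit <- fit_fsc_model(fsc[ok], dg$shells$centers[ok])
  shell_w <- diff(dg$shells$edges[1:2])
  expect_lt(abs(fit$s_max - target$s_max), shell_w)
  # two seeds: opposite halves of independently degraded pairs share only
  # the true signal, so their mutual FSC also matches the target
  dgB <- suppressWarnings(degrade_half_maps(hmv$map1, hmv$map2, target,
                                            seed = 10, n_shells = 14))
  fscAB <- suppressWarnings(compute_fsc(ft1$F, map_fourier_terms(dgB$map2)$F,
                                        dg$shells))
  upper <- dg$shells$edges[-1]
  sel <- which(upper <= target$s_max & nterm >= 50)
  tgt <- fsc_curve(target, dg$shells$centers)
  expect_true(all(abs(fscAB[sel] - tgt[sel]) < 0.05))
})
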