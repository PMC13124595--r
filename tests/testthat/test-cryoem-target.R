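test_that("half-map statistics recover signal and noise", {
  set.seed(4)
  n <- 6000
  sh <- list(id = rep(1:6, each = 1000), centers = seq(0.05, 0.3, length.out = 6))
  S_true <- c(40, 25, 12, 6, 3, 1.5)
  N_true <- c(2, 2.5, 3, 3.5, 4, 4.5)
  Tsig <- complex(real = rnorm(n, 0, sqrt(S_true[sh$id] / 2)),
                  imaginary = rnorm(n, 0, sqrt(S_true[sh$id] / 2)))
  mknoise <- function() complex(real = rnorm(n, 0, sqrt(N_true[sh$id] / 2)),
                                imaginary = rnorm(n, 0, sqrt(N_true[sh$id] / 2)))
  F1 <- Tsig + mknoise()
  F2 <- Tsig + mknoise()
  hm <- halfmap_statistics(F1, F2, sh)
  expect_true(all(abs(hm$signal - S_true) / S_true < 0.1))
  # noise is reported per averaged-map term: N_half / 2
  expect_true(all(abs(hm$noise - N_true / 2) / (N_true / 2) < 0.1))
  # symmetric under swapping the halves
  hm2 <- halfmap_statistics(F2, F1, sh)
  expect_equal(hm$signal, hm2$signal)
  expect_equal(hm$noise, hm2$noise)
  expect_equal(hm$D_obs, hm2$D_obs)
  # identical halves: zero noise, D_obs = 1
  hm3 <- halfmap_statistics(F1, F1, sh)
  expect_equal(hm3$noise, rep(0, 6))
  expect_equal(hm3$D_obs, rep(1, 6))
  # independent white noise: D_obs near zero. The square root in
  # D_obs = sqrt(S/(S+N)) turns O(n^-1/2) sampling fluctuations of S into
  # O(n^-1/4) values, so the null level at 1000 terms/shell is ~0.15.
  hm4 <- halfmap_statistics(mknoise(), mknoise(), sh)
  expect_true(all(hm4$D_obs < 0.35))
  expect_lt(mean(hm4$D_obs), 0.2)
  expect_true(all(hm4$D_obs < min(hm$D_obs)))
})

test_that("cryo-EM LLG matches its closed form and monotonicity", {
  sh <- list(id = 1L, centers = 0.2)
  hm <- structure(list(E_e = 1, phi_obs = 0, shell_id = 1L, D_obs = 1,
                       signal = 1, noise = 0), class = "halfmap_fourier")
  # single term, E_e = E_calc = 1, dphi = 0, d = 0.5: 4/3 - 2/3 + ln(4/3)
  v <- llg_cryoem(hm, 1, 0, sigma_a = 0.5)
  expect_equal(as.numeric(v), 4 / 3 - 2 / 3 + log(4 / 3), tolerance = 1e-12)
  expect_equal(round(as.numeric(v), 3), 0.954)
  # d = 0 gives exactly zero
  expect_identical(as.numeric(llg_cryoem(hm, 1, 0, sigma_a = 0)), 0)
  # strictly decreasing in the phase difference on [0, pi]
  vals <- vapply(seq(0, pi, length.out = 20), function(p)
    as.numeric(llg_cryoem(hm, 1, p, sigma_a = 0.5)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(llg_cryoem(hm, 1, 0, sigma_a = 1.2), ">= 1")
})

test_that("per-shell cryo-EM sigma_A hits clamps and matches a grid search", {
  set.seed(6)
  n <- 800
  sh <- list(id = rep(1:2, each = n / 2), centers = c(0.1, 0.2))
  Tsig <- complex(real = rnorm(n, 0, sqrt(1 / 2)),
                  imaginary = rnorm(n, 0, sqrt(1 / 2)))
  F1 <- Tsig; F2 <- Tsig            # noiseless halves
  hm <- halfmap_statistics(F1, F2, sh)
  # perfect model: upper clamp
  E_calc <- hm$E_e
  sa <- sigma_a_em(hm, E_calc, hm$phi_obs)
  expect_true(all(sa > 0.98))
  # uncorrelated model: lower clamp
  sa0 <- sigma_a_em(hm, sample(E_calc), Arg(complex(real = rnorm(n),
                                                    imaginary = rnorm(n))))
  expect_true(all(sa0 < 0.08))
  # grid-search oracle on a synthetic intermediate-quality shell
  Ec_c <- 0.6 * Tsig + complex(real = rnorm(n, 0, sqrt(0.64 / 2)),
                               imaginary = rnorm(n, 0, sqrt(0.64 / 2)))
  sa_m <- sigma_a_em(hm, Mod(Ec_c) / sqrt(mean(Mod(Ec_c)^2)), Arg(Ec_c))
  grid <- seq(0.015, 0.99, 0.001)
  for (b in 1:2) {
    sel <- sh$id == b
    ee <- hm$E_e[sel]; ec <- (Mod(Ec_c) / sqrt(mean(Mod(Ec_c)^2)))[sel]
    cp <- cos(Arg(Ec_c)[sel] - hm$phi_obs[sel])
    f <- function(s) {
      d <- min(hm$D_obs[b] * s, 1 - 1e-9); u <- 1 - d^2
      sum(2 * d * ee * ec * cp / u - d^2 * (ee^2 + ec^2) / u - log(u))
    }
    expect_lt(abs(sa_m[b] - grid[which.max(vapply(grid, f, numeric(1)))]),
              0.002)
  }
})

test_that("cryo-EM target gradient matches finite differences", {
  # 5-atom model on a small Fourier grid
  set.seed(13)
  g <- 16
  map <- density_map(array(0, c(g, g, g)), voxel = 1.5)
  model <- atomic_model(matrix(runif(15, 8, 16), 5, 3),
                        element = c("C", "N", "O", "C", "S"), b = 12)
  truth <- model_density(model, map, d_min = 3.5)
  noisy <- function() density_map(truth$grid +
                                    array(rnorm(g^3, 0, sd(truth$grid) * 0.2),
                                          dim(truth$grid)), voxel = 1.5)
  ft1 <- map_fourier_terms(noisy()); ft2 <- map_fourier_terms(noisy())
  sh <- make_shells(ft1$s, n_shells = 5, s_max = 1 / 3.5)
  hm <- halfmap_statistics(ft1$F, ft2$F, sh)
  tgt <- em_target(hm, map, d_min = 3.5)
  tv <- tgt(model)
  h <- 1e-5
  for (j in c(1, 3)) for (cmp in 1:2) {
    mp <- model; mm <- model
    if (cmp == 1) { mp$x[j] <- mp$x[j] + h; mm$x[j] <- mm$x[j] - h }
    if (cmp == 2) { mp$y[j] <- mp$y[j] + h; mm$y[j] <- mm$y[j] - h }
    fd <- (tgt(mp, sigma_a = tv$sigma_a, gradient = FALSE)$llg -
             tgt(mm, sigma_a = tv$sigma_a, gradient = FALSE)$llg) / (2 * h)
    expect_lt(rel_err(tv$grad_xyz[j, cmp], fd), 1e-4)
  }
})

test_that("cryo-EM LLG is maximized at the true pose", {
  fx <- get_em_fixture()
  tgt <- em_target(fx$hm, fx$hmv$map1, d_min = 4)
  model <- fx$hmv$model
  base <- tgt(model, gradient = FALSE)
  sa <- base$sigma_a
  # grid scan over +-2 voxels along each axis
  for (ax in 1:3) for (dx in c(-2, -1, 1, 2)) {
    m2 <- model
    if (ax == 1) m2$x <- m2$x + dx
    if (ax == 2) m2$y <- m2$y + dx
    if (ax == 3) m2$z <- m2$z + dx
    expect_lt(tgt(m2, sigma_a = sa, gradient = FALSE)$llg, base$llg)
  }
})

test_that("RSCC behaves on self, noise and attenuated maps", {
  fx <- get_em_fixture()
  model <- fx$hmv$model
  self_map <- fx$hmv$truth
  expect_gt(rscc(model, self_map, d_min = 2.5), 1 - 1e-6)
  set.seed(8)
  noise_map <- density_map(array(rnorm(length(self_map$grid)),
                                 dim(self_map$grid)),
                           voxel = self_map$voxel)
  expect_lt(abs(rscc(model, noise_map, d_min = 2.5)), 0.1)
  # known signal/noise: global RSCC close to sqrt(S / (S + N))
  sig_p <- mean(self_map$grid^2)
  lam <- 1.0
  noisy <- density_map(self_map$grid + array(rnorm(length(self_map$grid), 0,
                                                   sqrt(lam * sig_p)),
                                             dim(self_map$grid)),
                       voxel = self_map$voxel)
  expect_lt(abs(rscc(model, noisy, d_min = 2.5) - sqrt(1 / (1 + lam))), 0.05)
  # per-residue values defined for all residues of the centred model
  pr <- rscc(model, self_map, per_residue = TRUE, d_min = 2.5)
  expect_true(all(is.finite(pr)))
  expect_true(all(pr > 0.9))
})

test_that("RSCC-to-B conversion is bounded and monotone", {
  expect_equal(update_b_from_rscc(1), 20)
  expect_equal(update_b_from_rscc(c(0, -0.5)), c(300, 300))
  x <- sort(runif(20))
  expect_true(all(diff(update_b_from_rscc(x)) <= 0))
  expect_true(all(update_b_from_rscc(runif(50, -1, 1)) >= 20))
  expect_true(all(update_b_from_rscc(runif(50, -1, 1)) <= 300))
})
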