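test_that("reflection metadata matches brute-force operator enumeration", {
  cl <- unit_cell(20, 30, 40, 90, 105, 90)
  # P1: nothing centric, epsilon 1
  set.seed(1)
  hkl <- unique(cbind(sample(-4:4, 30, TRUE), sample(-4:4, 30, TRUE),
                      sample(-4:4, 30, TRUE)))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  p1 <- reflection_metadata(cl, spacegroup_ops("P1"), hkl)
  expect_false(any(p1$centric))
  expect_true(all(p1$epsilon == 1))
  # P-1: inversion makes everything centric
  pm1 <- reflection_metadata(cl, spacegroup_ops("P-1"), hkl)
  expect_true(all(pm1$centric))
  # P21: compare against exhaustive operator application
  ops <- spacegroup_ops("P21")
  p21 <- reflection_metadata(cl, ops, hkl)
  for (i in seq_len(nrow(hkl))) {
    h <- hkl[i, ]
    imgs <- sapply(ops$ops, function(o) as.numeric(h %*% o$R))
    expect_equal(p21$centric[i], any(colSums(imgs == -h) == 3))
    expect_equal(p21$epsilon[i], sum(colSums(imgs == h) == 3))
  }
  # resolution from the metric tensor agrees with the direct formula for
  # an orthorhombic cell
  clo <- unit_cell(10, 20, 40)
  s <- reciprocal_s(clo, c(1, 2, 4))
  expect_equal(s, sqrt((1 / 10)^2 + (2 / 20)^2 + (4 / 40)^2), tolerance = 1e-12)
})

test_that("invalid metadata inputs are rejected", {
  cl <- unit_cell(20, 30, 40)
  expect_error(reflection_metadata(cl, spacegroup_ops("P1"),
                                   rbind(c(0, 0, 0))), "not a reflection")
  expect_error(unit_cell(10, 10, 10, alpha = 190), "angles")
  expect_error(unit_cell(-5, 10, 10), "positive")
  expect_true(max(abs(cl$frac %*% cl$orth - diag(3))) < 1e-10)
})

test_that("direct-summation structure factors match a plain-loop oracle", {
  set.seed(7)
  cl <- unit_cell(18, 22, 26, 90, 98, 90)
  hkl <- unique(cbind(sample(-5:5, 20, TRUE), sample(-5:5, 20, TRUE),
                      sample(-5:5, 20, TRUE)))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ][1:15, ]
  refl <- reflection_metadata(cl, spacegroup_ops("P1"), hkl)
  model <- atomic_model(matrix(runif(30, 0, 15), 10, 3),
                        element = sample(c("C", "N", "O", "S"), 10, TRUE),
                        b = runif(10, 5, 30), occ = runif(10, 0.5, 1))
  sf <- sf_calc(model, cl, refl)
  Fb <- sf_brute_force(model, cl, refl)
  expect_lt(max(Mod(sf$F - Fb) / Mod(Fb)), 1e-8)

  # single atom at the origin: phase zero everywhere
  m1 <- atomic_model(matrix(0, 1, 3), element = "C", b = 0)
  f1 <- sf_calc(m1, cl, refl)$F
  expect_lt(max(abs(Arg(f1))), 1e-12)

  # centrosymmetric pair: all structure factors real
  m2 <- atomic_model(rbind(c(3, 4, 5), c(-3, -4, -5)), element = "C", b = 5)
  f2 <- sf_calc(m2, cl, refl)$F
  expect_lt(max(abs(Im(f2))), 1e-9 * max(Mod(f2)))

  # unknown element falls back with a warning; NaN coordinate rejected
  expect_warning(sf_calc(atomic_model(matrix(1, 1, 3), element = "XX"),
                         cl, refl), "XX")
  bad <- model; bad$x[1] <- NaN
  expect_error(sf_calc(bad, cl, refl), "NaN")
})

test_that("structure-factor gradients and lattice invariance hold", {
  set.seed(8)
  cl <- unit_cell(15, 17, 19)
  hkl <- unique(cbind(sample(-4:4, 40, TRUE), sample(-4:4, 40, TRUE),
                      sample(-4:4, 40, TRUE)))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  refl <- reflection_metadata(cl, spacegroup_ops("P1"), hkl)
  model <- atomic_model(matrix(runif(15, 2, 12), 5, 3),
                        element = c("C", "N", "O", "C", "S"), b = runif(5, 5, 20))
  L <- function(m) sum(Mod(sf_calc(m, cl, refl, keep_terms = FALSE)$F))
  sf <- sf_calc(model, cl, refl)
  g <- sf_backward(sf, amp_phase_adjoint(sf$F, g_amp = rep(1, nrow(refl))))
  h <- 1e-6
  for (j in c(1, 4)) for (cmp in 1:3) {
    m2 <- model
    if (cmp == 1) m2$x[j] <- m2$x[j] + h
    if (cmp == 2) m2$y[j] <- m2$y[j] + h
    if (cmp == 3) m2$z[j] <- m2$z[j] + h
    fd <- (L(m2) - L(model)) / h
    expect_lt(rel_err(g$dX[j, cmp], fd), 1e-5)
  }
  # B-factor gradient
  m3 <- model; m3$b[2] <- m3$b[2] + h
  expect_lt(rel_err(g$dB[2], (L(m3) - L(model)) / h), 1e-4)
  # translating by a lattice vector leaves amplitudes unchanged
  m4 <- model
  shift <- cl$orth %*% c(1, -2, 1)
  m4$x <- m4$x + shift[1]; m4$y <- m4$y + shift[2]; m4$z <- m4$z + shift[3]
  expect_lt(max(abs(Mod(sf_calc(m4, cl, refl)$F) - Mod(sf$F))),
            1e-10 * max(Mod(sf$F)))
})

test_that("Wilson E-normalization restores unit means and known toys", {
  fx <- get_xtal_fixture()
  refl <- fx$sim$refl
  nE <- normalize_to_E(refl$F_true, refl)
  means <- tapply(nE$E^2 / refl$epsilon, refl$bin_id, mean)
  expect_true(all(abs(means - 1) < 0.05))
  # constant amplitude in one bin -> E = 1
  toy <- data.frame(h = 1:6, k = 0, l = 0, epsilon = 1, bin_id = 1)
  expect_equal(normalize_to_E(rep(3, 6), toy)$E, rep(1, 6))
  # scale invariance
  e1 <- normalize_to_E(refl$F_true, refl)$E
  e2 <- normalize_to_E(2 * refl$F_true, refl)$E
  expect_equal(e1, e2, tolerance = 1e-12)
  # mixed-epsilon 6-reflection toy, against hand arithmetic
  toy$epsilon <- c(1, 1, 2, 2, 4, 1)
  amps <- c(1, 2, 2, 3, 4, 1)
  S <- mean(amps^2 / toy$epsilon)
  expect_equal(normalize_to_E(amps, toy)$E, amps / sqrt(toy$epsilon * S),
               tolerance = 1e-12)
})

test_that("effective amplitudes have the right limits and calibration", {
  # noiseless limit: E_e reproduces the normalized truth, D_obs -> 1
  fx <- get_xtal_fixture()
  rec0 <- fx$rec
  sim0 <- simulate_reflections(fx$ts$state_b, rec0, noise_frac = 0)
  expect_lt(max(abs(sim0$refl$E_e - sim0$refl$E_true)), 1e-6)
  expect_true(all(sim0$refl$D_obs == 1))
  # uninformative limit
  toy <- data.frame(h = 1:60, k = 0, l = 0, epsilon = 1, bin_id = 1,
                    centric = FALSE)
  ea <- effective_amplitudes(rep(1, 60), rep(1e4, 60), toy)
  expect_true(all(ea$D_obs < 0.05))
  # D_obs decreasing in sigma_I at fixed I_o
  ea_lo <- effective_amplitudes(rep(1, 60), rep(0.2, 60), toy)
  ea_hi <- effective_amplitudes(rep(1, 60), rep(2.0, 60), toy)
  expect_true(all(ea_hi$D_obs < ea_lo$D_obs))
  # negative intensities still give E_e >= 0, with a warning for a
  # fully negative bin
  expect_warning(ean <- effective_amplitudes(rep(-2, 60), rep(1, 60), toy),
                 "negative")
  expect_true(all(ean$E_e >= 0))
})

test_that("mean D_obs approximates corr(E_e, E_true) on simulated data", {
  set.seed(42)
  n <- 5000
  E_true <- sqrt(-log(runif(n)))          # Wilson acentric draws
  sig <- 0.8
  I_o <- E_true^2 + rnorm(n, 0, sig)
  toy <- data.frame(h = seq_len(n), k = 0, l = 0, epsilon = 1, bin_id = 1,
                    centric = FALSE)
  ea <- effective_amplitudes(I_o, rep(sig, n), toy)
  expect_lt(abs(mean(ea$D_obs) - cor(ea$E_e, E_true)), 0.05)
})
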