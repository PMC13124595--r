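engine_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- get_xtal_fixture()
      prof <- simulate_profiles(fx$rec)
      flex <- c(min(fx$rec$loop) - 1, fx$rec$loop, max(fx$rec$loop) + 1)
      pred <- toy_predictor(prof$m_init, fx$ts$torsions_a, fx$ts$torsions_b,
                            flexible = flex)
      tgt <- xtal_target(fx$sim$refl, fx$sim$cell)
      p0 <- pred$predict(prof$m_init)
      kb <- weighted_kabsch(ca_coords(p0$model), ca_coords(fx$sim$model))
      cache <<- list(fx = fx, prof = prof, pred = pred, tgt = tgt, p0 = p0,
                     x_ref = kb$x_aligned,
                     rw = kabsch_weight(plddt_to_pseudob(p0$plddt)))
    }
    cache
  }
})

test_that("bias application is elementwise with no renormalization", {
  set.seed(1)
  m0 <- array(runif(2 * 3 * 23), c(2, 3, 23))
  st <- profile_bias(m0)
  expect_identical(apply_bias(st), m0)
  st$b <- -m0
  expect_equal(apply_bias(st), array(0, dim(m0)))
  st$w <- array(rnorm(length(m0)), dim(m0))
  st$b <- array(rnorm(length(m0)), dim(m0))
  # elementwise oracle by explicit loops
  ref <- array(0, dim(m0))
  for (k in 1:2) for (l in 1:3) for (a in 1:23)
    ref[k, l, a] <- st$w[k, l, a] * m0[k, l, a] + st$b[k, l, a]
  expect_equal(apply_bias(st), ref, tolerance = 1e-15)
  st$b <- array(0, c(2, 3, 22))
  expect_error(apply_bias(st), "shape")
})

test_that("the weighted L2 restraint matches hand arithmetic", {
  x <- matrix(0, 4, 3)
  expect_identical(as.numeric(l2_restraint(x, x, rep(1, 4))), 0)
  x2 <- x; x2[2, 1] <- 2
  expect_equal(as.numeric(l2_restraint(x2, x, rep(1, 4))), 4)
  set.seed(2)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  w <- runif(4)
  ref <- 0
  for (i in 1:4) ref <- ref + w[i] * sum((a[i, ] - b[i, ])^2)
  expect_equal(as.numeric(l2_restraint(a, b, w)), ref, tolerance = 1e-12)
  v <- l2_restraint(a, b, w, gradient = TRUE)
  h <- 1e-7
  a2 <- a; a2[3, 2] <- a2[3, 2] + h
  expect_lt(rel_err(attr(v, "gradient")[3, 2],
                    (l2_restraint(a2, b, w) - as.numeric(v)) / h), 1e-5)
})

test_that("loss gradient with respect to the bias matches finite differences", {
  es <- engine_setup()
  dm <- dim(es$prof$m_init)
  w <- array(1, dm); b <- array(0, dm)
  ev0 <- refinement_loss(w, b, es$pred, es$tgt, es$x_ref, es$rw,
                         omega_l2 = 1e-3, rbr_steps = 3)
  pose <- ev0$pose; sa <- ev0$sigma_a
  f <- function(w, b) refinement_loss(w, b, es$pred, es$tgt, es$x_ref, es$rw,
                                      omega_l2 = 1e-3, pose = pose,
                                      sigma_a = sa, gradient = FALSE)$loss
  ev <- refinement_loss(w, b, es$pred, es$tgt, es$x_ref, es$rw,
                        omega_l2 = 1e-3, pose = pose, sigma_a = sa)
  h <- 1e-6
  f0 <- f(w, b)
  set.seed(4)
  for (r in 1:6) {
    ix <- c(sample(dm[1], 1), sample(dm[2], 1), sample(dm[3], 1))
    b2 <- b; b2[ix[1], ix[2], ix[3]] <- h
    bm <- b; bm[ix[1], ix[2], ix[3]] <- -h
    fd <- (f(w, b2) - f(w, bm)) / (2 * h)
    expect_lt(rel_err(ev$gb[ix[1], ix[2], ix[3]], fd), 1e-4)
    w2 <- w; w2[ix[1], ix[2], ix[3]] <- 1 + h
    wm <- w; wm[ix[1], ix[2], ix[3]] <- 1 - h
    fd <- (f(w2, b) - f(wm, b)) / (2 * h)
    # skip entries whose gradient is so small that finite-difference
    # cancellation noise dominates
    if (abs(fd) > 1e-5 * max(abs(f0), 1))
      expect_lt(rel_err(ev$gw[ix[1], ix[2], ix[3]], fd), 1e-4)
  }
})

test_that("an overwhelming L2 penalty pins the bias", {
  es <- engine_setup()
  dm <- dim(es$prof$m_init)
  w <- array(1, dm); b <- array(0, dm)
  opt <- llgrefine:::adam_init(list(w = w, b = b))
  lrs <- list(w = 1e-6, b = 1e-6)
  for (i in 1:10) {
    ev <- refinement_loss(w, b, es$pred, es$tgt, es$x_ref, es$rw,
                          omega_l2 = 1e6, rbr_steps = 0)
    st <- llgrefine:::adam_step(opt, list(w = w, b = b),
                                list(w = ev$gw, b = ev$gb), lrs)
    opt <- st$opt; w <- st$params$w; b <- st$params$b
  }
  # adam steps are ~lr per entry whatever the gradient, so the bound
  # scales with lr * sqrt(n) * iterations
  expect_lt(sqrt(sum((w - 1)^2)), 1e-3)
  expect_lt(sqrt(sum(b^2)), 1e-3)
  # and the model stays pinned to the reference
  ev_fin <- refinement_loss(w, b, es$pred, es$tgt, es$x_ref, es$rw,
                            omega_l2 = 1e6, rbr_steps = 0, gradient = FALSE)
  ca <- which(ev_fin$model$atom_name == "CA")
  expect_lt(sqrt(mean(rowSums((model_xyz(ev_fin$model)[ca, ] - es$x_ref)^2))),
            0.05)
})

test_that("zero learning rates leave the state unchanged", {
  es <- engine_setup()
  cfg <- refinement_config(lr_mul1 = 0, lr_add1 = 0, lr_mul2 = 0,
                           lr_add2 = 0, n_traces = 1, n_iter1 = 3,
                           n_iter2 = 3, trace_jitter = 0, seed = 2)
  fit <- refine_structure(es$pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  expect_equal(fit$w, array(1, dim(es$prof$m_init)))
  expect_equal(fit$b, array(0, dim(es$prof$m_init)))
  expect_lt(diff(range(fit$trace$llg)), 1e-4 * abs(mean(fit$trace$llg)))
})

test_that("a constant predictor triggers early stop after the window", {
  es <- engine_setup()
  m0 <- es$prof$m_init
  const_model <- es$p0$model
  const_pred <- structure(list(
    m0 = m0,
    predict = function(m) list(model = const_model, plddt = es$p0$plddt,
                               ent = NULL),
    backward = function(pred, g_xyz, g_plddt = NULL) array(0, dim(m0))
  ), class = "toy_predictor")
  cfg <- refinement_config(n_traces = 1, n_iter1 = 2, n_iter2 = 200,
                           trace_jitter = 0, rbr_steps = 0, seed = 3)
  fit <- refine_structure(const_pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  n2 <- sum(fit$trace$phase == 2)
  expect_identical(fit$stop_reason, "early_stop")
  expect_identical(n2, 51L)   # 1 initial + exactly 50 non-improving
})

test_that("phase-2 seeding picks the trace with the best final LLG", {
  es <- engine_setup()
  cfg <- refinement_config(n_traces = 3, n_iter1 = 4, n_iter2 = 2,
                           trace_jitter = 0.05, seed = 7)
  fit <- refine_structure(es$pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  tr <- fit$trace[fit$trace$phase == 1, ]
  finals <- vapply(split(tr, tr$trace), function(d) d$llg[nrow(d)], numeric(1))
  expect_identical(fit$selected_trace, as.integer(which.max(finals)))
})

test_that("refinement traces are reproducible from config and seed", {
  es <- engine_setup()
  cfg <- refinement_config(n_traces = 2, n_iter1 = 4, n_iter2 = 3, seed = 11)
  f1 <- refine_structure(es$pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  f2 <- refine_structure(es$pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$w, f2$w)
})

test_that("fit object methods report the refinement state", {
  es <- engine_setup()
  cfg <- refinement_config(n_traces = 1, n_iter1 = 3, n_iter2 = 3,
                           trace_jitter = 0, seed = 5)
  fit <- refine_structure(es$pred, es$tgt, es$x_ref, es$p0$plddt, cfg)
  expect_s3_class(fit, "llg_refit")
  expect_output(print(fit), "LLG")
  sm <- summary(fit)
  expect_equal(sm$llg_best, fit$best$llg)
  co <- coef(fit)
  expect_identical(dim(co$w), dim(es$prof$m_init))
  expect_equal(as.numeric(logLik(fit)), fit$best$llg)
  expect_s3_class(fitted(fit), "atomic_model")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("the confidence-only target runs through the engine", {
  es <- engine_setup()
  cfg <- refinement_config(n_traces = 1, n_iter1 = 3, n_iter2 = 2,
                           trace_jitter = 0, rbr_steps = 0, seed = 9)
  fit <- refine_structure(es$pred, plddt_target(), es$x_ref, es$p0$plddt, cfg)
  expect_true(all(is.finite(fit$trace$llg)))
  expect_true(all(fit$trace$llg <= 100))
})
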