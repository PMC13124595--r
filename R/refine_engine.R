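#' Multiplicative/additive bias on an MSA cluster profile
#'
#' The refinement engine's parameters: a multiplicative bias w (initialized
#' to 1) and an additive bias b (initialized to 0) with the shape of the
#' base profile, so the biased profile m = w * m0 + b equals m0 exactly at
#' initialization.
#'
#' @param m0 Base cluster profile array (clusters x residues x symbols).
#' @return List of class \code{"profile_bias"}: \code{m0}, \code{w},
#'   \code{b}.
#' @export
profile_bias <- function(m0) {
  structure(list(m0 = m0, w = array(1, dim(m0)), b = array(0, dim(m0))),
            class = "profile_bias")
}

#' Apply a profile bias
#'
#' Elementwise m = w * m0 + b; no renormalization or clipping is applied.
#'
#' @param state A \code{profile_bias} (or a list with m0, w, b).
#' @return The biased profile array.
#' @export
apply_bias <- function(state) {
  if (!identical(dim(state$w), dim(state$m0)) ||
      !identical(dim(state$b), dim(state$m0)))
    stop("bias shapes do not match the base profile")
  state$w * state$m0 + state$b
}

#' Confidence-weighted L2 positional restraint
#'
#' Weighted Calpha squared-distance restraint to the reference model:
#' sum_i w_i ||x_i - x_ref_i||^2.
#'
#' @param x n x 3 Calpha coordinates of the current model.
#' @param x_ref n x 3 reference Calpha coordinates.
#' @param weights Per-residue weights (from \code{\link{kabsch_weight}} on
#'   the reference pseudo-B values).
#' @param gradient Also return dL2/dx?
#' @return Scalar restraint value, with attribute \code{"gradient"} (n x 3)
#'   when requested.
#' @export
l2_restraint <- function(x, x_ref, weights, gradient = FALSE) {
  x <- as.matrix(x); x_ref <- as.matrix(x_ref)
  if (nrow(x) != nrow(x_ref)) stop("coordinate lists differ in length")
  d <- x - x_ref
  val <- sum(weights * rowSums(d^2))
  if (gradient) attr(val, "gradient") <- 2 * weights * d
  val
}

#' Crystallographic likelihood target for the refinement engine
#'
#' Wraps a reflection set and cell into the target-function contract used
#' by \code{\link{refine_structure}}: given a model it returns the LLGI
#' and its analytic gradients with respect to coordinates and per-atom B.
#'
#' @param refl Reflection set with E_e, D_obs, centric, bin_id, free_flag.
#' @param cell The \code{unit_cell}.
#' @return A function(model, sigma_a = NULL, d_min_window = NULL,
#'   gradient = TRUE) returning list(llg, grad_xyz, grad_b, sigma_a).
#' @export
xtal_target <- function(refl, cell) {
  force(refl); force(cell)
  # precomputed bin bookkeeping for the fast normalization path
  bin_code <- as.integer(factor(refl$bin_id))
  nb <- max(bin_code)
  cnt <- as.numeric(rowsum(rep(1, nrow(refl)), bin_code))
  eps <- refl$epsilon
  work <- if (!is.null(refl$free_flag)) !refl$free_flag else rep(TRUE, nrow(refl))
  bins_sorted <- sort(unique(refl$bin_id))
  win_cache <- new.env(parent = emptyenv())
  eng_cache <- new.env(parent = emptyenv())
  function(model, sigma_a = NULL, d_min_window = NULL, gradient = TRUE,
           sigma_a_init = 0.5) {
    if (!is.null(d_min_window)) {
      # resolution-window evaluations run on a cached sub-target
      key <- format(d_min_window)
      if (is.null(win_cache[[key]]))
        win_cache[[key]] <- xtal_target(refl[refl$d >= d_min_window, , drop = FALSE],
                                        cell)
      return(win_cache[[key]](model, sigma_a = sigma_a, gradient = gradient,
                              sigma_a_init = sigma_a_init))
    }
    ekey <- paste(model$element, collapse = "")
    if (is.null(eng_cache[[ekey]]))
      eng_cache[[ekey]] <- sf_engine(cell, refl, model$element)
    sf <- sf_engine_calc(eng_cache[[ekey]], model, keep_terms = gradient)
    amp <- Mod(sf$F)
    S <- as.numeric(rowsum(amp^2 / eps, bin_code)) / cnt
    E_C <- amp / sqrt(eps * S[bin_code])
    if (is.null(sigma_a)) sigma_a <- refine_sigma_a(refl, E_C, init = sigma_a_init)
    sa_code <- if (length(sigma_a) == 1) rep(sigma_a, nb) else as.numeric(sigma_a)
    d <- refl$D_obs * sa_code[bin_code]   # bin_code follows sorted bin ids
    tm <- llgi_terms(refl$E_e[work], E_C[work], pmin(d[work], 1 - 1e-9),
                     refl$centric[work])
    out <- list(llg = sum(tm$llg), sigma_a = sigma_a, E_C = E_C)
    if (gradient) {
      gE <- numeric(nrow(refl))
      gE[work] <- tm$dE_C
      # pull back through the per-bin normalization (including the
      # dependence of the bin scale on every member amplitude)
      gA <- gE / sqrt(eps * S[bin_code])
      cS <- as.numeric(rowsum(gE * (-0.5) * amp / sqrt(eps) * S[bin_code]^(-1.5),
                              bin_code)) / cnt
      gA <- gA + cS[bin_code] * 2 * amp / eps
      gF <- amp_phase_adjoint(sf$F, g_amp = gA)
      bw <- sf_backward(sf, gF)
      out$grad_xyz <- bw$dX
      out$grad_b <- bw$dB
    }
    out
  }
}

#' Cryo-EM likelihood target for the refinement engine
#'
#' Wraps half-map Fourier statistics into the target-function contract:
#' model structure factors are evaluated on the map's Fourier indices
#' (band-limited), normalized per shell, and scored with the Fourier-term
#' LLG; gradients flow through amplitudes, phases and B factors.
#'
#' @param hm A \code{halfmap_fourier} from \code{\link{halfmap_statistics}}.
#' @param map A \code{density_map} (geometry only).
#' @param d_min Band limit (A) for the model terms (default: the shell
#'   range of \code{hm}).
#' @return A function(model, sigma_a = NULL, d_min_window = NULL,
#'   gradient = TRUE) returning list(llg, grad_xyz, grad_b, sigma_a).
#' @export
em_target <- function(hm, map, d_min = NULL) {
  ft <- map_fourier_terms(map)
  sel <- hm$shell_id > 0
  if (!is.null(d_min)) sel <- sel & ft$s <= 1 / d_min
  idx <- which(sel)
  cell <- unit_cell(dim(map$grid)[1] * map$voxel[1],
                    dim(map$grid)[2] * map$voxel[2],
                    dim(map$grid)[3] * map$voxel[3])
  refl_sub <- data.frame(h = ft$hkl[idx, 1], k = ft$hkl[idx, 2],
                         l = ft$hkl[idx, 3], s = ft$s[idx],
                         epsilon = 1, bin_id = hm$shell_id[idx])
  hm_sub <- structure(list(E_e = hm$E_e[idx], phi_obs = hm$phi_obs[idx],
                           shell_id = hm$shell_id[idx], D_obs = hm$D_obs,
                           signal = hm$signal, noise = hm$noise),
                      class = "halfmap_fourier")
  origin <- map$origin
  bin_code <- as.integer(factor(refl_sub$bin_id))
  cnt <- as.numeric(rowsum(rep(1, nrow(refl_sub)), bin_code))
  win_cache <- new.env(parent = emptyenv())
  eng_cache <- new.env(parent = emptyenv())
  function(model, sigma_a = NULL, d_min_window = NULL, gradient = TRUE,
           sigma_a_init = 0.5) {
    if (!is.null(d_min_window) && (is.null(d_min) || d_min_window > d_min)) {
      key <- format(d_min_window)
      if (is.null(win_cache[[key]]))
        win_cache[[key]] <- em_target(hm, map, d_min = d_min_window)
      return(win_cache[[key]](model, sigma_a = sigma_a, gradient = gradient,
                              sigma_a_init = sigma_a_init))
    }
    shifted <- model
    shifted$x <- model$x - origin[1]
    shifted$y <- model$y - origin[2]
    shifted$z <- model$z - origin[3]
    ekey <- paste(model$element, collapse = "")
    if (is.null(eng_cache[[ekey]]))
      eng_cache[[ekey]] <- sf_engine(cell, refl_sub, model$element)
    sf <- sf_engine_calc(eng_cache[[ekey]], shifted, keep_terms = gradient)
    amp <- Mod(sf$F)
    S <- as.numeric(rowsum(amp^2, bin_code)) / cnt
    E_C <- amp / sqrt(S[bin_code])
    phi <- Arg(sf$F)
    if (is.null(sigma_a)) sigma_a <- sigma_a_em(hm_sub, E_C, phi)
    val <- llg_cryoem(hm_sub, E_C, phi, sigma_a, gradient = gradient)
    out <- list(llg = as.numeric(val), sigma_a = sigma_a, E_C = E_C)
    if (gradient) {
      gE <- attr(val, "dE_calc")
      gA <- gE / sqrt(S[bin_code])
      cS <- as.numeric(rowsum(gE * (-0.5) * amp * S[bin_code]^(-1.5),
                              bin_code)) / cnt
      gA <- gA + cS[bin_code] * 2 * amp
      gF <- amp_phase_adjoint(sf$F, g_amp = gA, g_phi = attr(val, "dphi_calc"))
      bw <- sf_backward(sf, gF)
      out$grad_xyz <- bw$dX
      out$grad_b <- bw$dB
    }
    out
  }
}

#' Confidence-metric target (no experimental data)
#'
#' A control target that scores a prediction by its own mean pLDDT instead
#' of experimental agreement.
#'
#' @return A target function with the engine contract whose "LLG" is the
#'   mean pLDDT; gradients flow only through the confidence head.
#' @export
plddt_target <- function() {
  f <- function(model, sigma_a = NULL, d_min_window = NULL, gradient = TRUE,
                sigma_a_init = 0.5) {
    out <- list(llg = NA_real_, sigma_a = NULL,
                grad_xyz = matrix(0, nrow(model), 3),
                grad_b = numeric(nrow(model)))
    out
  }
  attr(f, "plddt_direct") <- TRUE
  f
}

#' Engine configuration
#'
#' Defaults follow the two-phase schedule: an adventurous phase 1 (three
#' seeded traces of 100 iterations, lr_mul = 1, lr_add = 0.05, L2 weight
#' 1e-11, data restricted to d >= 3 A) and a fine-tuning phase 2 (500
#' iterations, both learning rates 1e-3, no L2 restraint, early stop when
#' the LLG fails to improve by more than 0.1 for 50 consecutive
#' iterations).
#'
#' @param lr_mul1,lr_add1 Phase-1 learning rates (1.0, 0.05).
#' @param lr_mul2,lr_add2 Phase-2 learning rates (1e-3, 1e-3).
#' @param omega_l2 Phase-1 L2 restraint weight (1e-11).
#' @param n_traces Phase-1 traces (3).
#' @param n_iter1,n_iter2 Iterations per phase (100, 500).
#' @param early_stop_window,early_stop_tol Early stop: window (50) and
#'   minimum LLG improvement (0.1).
#' @param phase1_cutoff Phase-1 low-resolution cutoff in A: phase 1 uses
#'   only reflections/terms with d >= this value (3).
#' @param rbr_steps Rigid-body gradient steps per iteration (2).
#' @param sigma_a_interval Refine sigma_A every this many iterations (1;
#'   larger skips for speed).
#' @param trace_jitter Standard deviation of the seeded additive-bias
#'   jitter that differentiates phase-1 traces beyond the first (0.02).
#' @param seed Base seed; trace t uses seed + t.
#' @return List of class \code{"refinement_config"}.
#' @export
refinement_config <- function(lr_mul1 = 1.0, lr_add1 = 0.05,
                              lr_mul2 = 1e-3, lr_add2 = 1e-3,
                              omega_l2 = 1e-11, n_traces = 3,
                              n_iter1 = 100, n_iter2 = 500,
                              early_stop_window = 50, early_stop_tol = 0.1,
                              phase1_cutoff = 3, rbr_steps = 2,
                              sigma_a_interval = 1, trace_jitter = 0.02,
                              seed = 1L) {
  structure(as.list(environment()), class = "refinement_config")
}

# Adam optimizer state over a named list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0)
}

adam_step <- function(opt, params, grads, lrs, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lrs[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, params = params)
}

#' One evaluation of the refinement objective with its bias gradient
#'
#' Runs a full forward pass -- apply bias, predict, confidence-to-B,
#' weighted Kabsch alignment to the reference, rigid-body refinement,
#' likelihood evaluation and L2 restraint -- and pulls the gradient of the
#' combined loss L = -LLG + omega_L2 * L2 back to the bias parameters
#' (w, b). The alignment pose and sigma_A are treated as fixed within the
#' evaluation (they sit at stationary points of the target); pass
#' \code{pose}/\code{sigma_a} to freeze them explicitly, e.g. for
#' finite-difference checks.
#'
#' @param w,b Bias arrays.
#' @param predictor A \code{toy_predictor} (or any object with the same
#'   predict/backward contract).
#' @param target A target function (\code{\link{xtal_target}},
#'   \code{\link{em_target}} or \code{\link{plddt_target}}).
#' @param x_ref Reference Calpha coordinates (n x 3).
#' @param ref_weights Per-residue alignment/restraint weights.
#' @param omega_l2 L2 weight.
#' @param d_min_window Optional resolution window (keep d >= this).
#' @param pose Optional fixed \code{rototranslation} applied instead of
#'   Kabsch + rigid-body refinement.
#' @param sigma_a Optional fixed sigma_A.
#' @param rbr_steps Rigid-body steps (0 disables).
#' @param gradient Compute gradients?
#' @return List: \code{loss}, \code{llg}, \code{l2}, \code{gw}, \code{gb},
#'   \code{pose}, \code{sigma_a}, \code{model} (posed model),
#'   \code{plddt}.
#' @export
refinement_loss <- function(w, b, predictor, target, x_ref, ref_weights,
                            omega_l2 = 0, d_min_window = NULL, pose = NULL,
                            sigma_a = NULL, sigma_a_init = 0.5, rbr_steps = 6,
                            gradient = TRUE) {
  m <- apply_bias(list(m0 = predictor$m0, w = w, b = b))
  pred <- predictor$predict(m)
  model <- pred$model
  ca_idx <- which(model$atom_name == "CA")
  plddt_direct <- isTRUE(attr(target, "plddt_direct"))
  last_tv <- NULL
  if (is.null(pose)) {
    kb <- weighted_kabsch(model_xyz(model)[ca_idx, , drop = FALSE], x_ref,
                          ref_weights)
    pose_k <- structure(list(R = kb$R, t = kb$t), class = "rototranslation")
    if (!plddt_direct && rbr_steps > 0) {
      xk <- apply_pose(pose_k, model_xyz(model))
      llg_fn <- function(x, gradient = TRUE) {
        mm <- model
        mm$x <- x[, 1]; mm$y <- x[, 2]; mm$z <- x[, 3]
        tv <- target(mm, sigma_a = sigma_a, d_min_window = d_min_window,
                     gradient = gradient, sigma_a_init = sigma_a_init)
        if (is.null(sigma_a)) sigma_a <<- tv$sigma_a
        if (gradient) last_tv <<- tv
        structure(tv$llg, grad_xyz = tv$grad_xyz)
      }
      rb <- rigid_body_refine(xk, llg_fn, n_steps = rbr_steps)
      pose <- compose_pose(rb$pose, pose_k)
    } else {
      pose <- pose_k
    }
  }
  x_pred <- model_xyz(model)
  x_fin <- apply_pose(pose, x_pred)
  mfin <- model; mfin$x <- x_fin[, 1]; mfin$y <- x_fin[, 2]; mfin$z <- x_fin[, 3]
  # the last gradient evaluation inside the rigid-body loop is at the final
  # pose; reuse it rather than re-evaluating the target
  tv <- if (!is.null(last_tv) && gradient) last_tv else
    target(mfin, sigma_a = sigma_a, d_min_window = d_min_window,
           gradient = gradient, sigma_a_init = sigma_a_init)
  llg <- if (plddt_direct) mean(pred$plddt) else tv$llg
  l2 <- l2_restraint(x_fin[ca_idx, , drop = FALSE], x_ref, ref_weights,
                     gradient = gradient)
  loss <- -llg + omega_l2 * as.numeric(l2)
  out <- list(loss = loss, llg = llg, l2 = as.numeric(l2), pose = pose,
              sigma_a = tv$sigma_a, model = mfin, plddt = pred$plddt,
              E_C = tv$E_C)
  if (!is.finite(loss)) stop("non-finite refinement loss")
  if (gradient) {
    g_fin <- -tv$grad_xyz
    g_fin[ca_idx, ] <- g_fin[ca_idx, ] + omega_l2 * attr(l2, "gradient")
    g_pred <- g_fin %*% pose$R
    res_f <- factor(model$resno, levels = unique(model$resno))
    g_b_res <- as.numeric(tapply(-tv$grad_b, res_f, sum))
    g_plddt <- plddt_to_pseudob_grad(pred$plddt) * g_b_res
    if (plddt_direct) g_plddt <- g_plddt - rep(1 / length(pred$plddt),
                                               length(pred$plddt))
    g_m <- predictor$backward(pred, g_pred, g_plddt)
    out$gw <- g_m * predictor$m0
    out$gb <- g_m
  }
  out
}

#' Likelihood-guided refinement of a structure prediction
#'
#' The package's main fitting function: learns multiplicative and additive
#' biases on an MSA cluster profile so that the predictor's output agrees
#' with experimental data under a likelihood target. Runs an adventurous
#' phase 1 (several seeded traces, aggressive learning rates, data
#' restricted to low resolution, confidence-weighted L2 restraint to the
#' reference) followed by a fine-tuning phase 2 (small learning rates, all
#' data, early stopping), and returns the best-LLG model.
#'
#' @param predictor A \code{\link{toy_predictor}}-style object.
#' @param target A target function from \code{\link{xtal_target}},
#'   \code{\link{em_target}} or \code{\link{plddt_target}}.
#' @param x_ref Reference Calpha coordinates (n x 3), e.g. the placed
#'   initial prediction.
#' @param ref_plddt Per-residue pLDDT of the reference prediction; the
#'   alignment/restraint weights are computed from it once and frozen.
#' @param config A \code{\link{refinement_config}}.
#' @return Object of class \code{"llg_refit"}; see
#'   \code{\link{print.llg_refit}} and friends.
#' @export
refine_structure <- function(predictor, target, x_ref, ref_plddt,
                             config = refinement_config()) {
  ref_weights <- kabsch_weight(plddt_to_pseudob(ref_plddt))
  m0 <- predictor$m0
  trace_rows <- list()
  run_phase <- function(w, b, n_iter, lrs, omega, window, phase, trace_id,
                        early_stop = FALSE) {
    opt <- adam_init(list(w = w, b = b))
    best_llg <- -Inf
    best_state <- list(w = w, b = b, llg = -Inf, model = NULL)
    stall <- 0L
    stop_reason <- "max_iter"
    rows <- vector("list", n_iter)
    sa_cache <- NULL
    for (it in seq_len(n_iter)) {
      recompute <- (it - 1L) %% config$sigma_a_interval == 0L || is.null(sa_cache)
      ev <- refinement_loss(w, b, predictor, target, x_ref, ref_weights,
                            omega_l2 = omega, d_min_window = window,
                            sigma_a = if (recompute) NULL else sa_cache,
                            sigma_a_init = if (is.null(sa_cache)) 0.5 else sa_cache,
                            rbr_steps = config$rbr_steps)
      sa_cache <- ev$sigma_a
      rows[[it]] <- data.frame(phase = phase, trace = trace_id, iter = it,
                               llg = ev$llg, l2 = ev$l2, loss = ev$loss)
      if (ev$llg > best_llg + config$early_stop_tol) {
        best_llg <- max(best_llg, ev$llg)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (ev$llg > best_state$llg)
        best_state <- list(w = w, b = b, llg = ev$llg, model = ev$model,
                           sigma_a = ev$sigma_a, plddt = ev$plddt)
      if (early_stop && stall >= config$early_stop_window) {
        stop_reason <- "early_stop"
        rows <- rows[seq_len(it)]
        break
      }
      st <- adam_step(opt, list(w = w, b = b), list(w = ev$gw, b = ev$gb), lrs)
      opt <- st$opt
      w <- st$params$w; b <- st$params$b
    }
    list(w = w, b = b, rows = do.call(rbind, rows), best = best_state,
         final_llg = rows[[length(rows)]]$llg, stop_reason = stop_reason)
  }
  lrs1 <- list(w = config$lr_mul1, b = config$lr_add1)
  lrs2 <- list(w = config$lr_mul2, b = config$lr_add2)
  traces <- vector("list", config$n_traces)
  for (tr in seq_len(config$n_traces)) {
    w <- array(1, dim(m0)); b <- array(0, dim(m0))
    if (tr > 1 && config$trace_jitter > 0) {
      old <- local_seed(config$seed + tr)
      b <- b + array(stats::rnorm(length(b), 0, config$trace_jitter), dim(m0))
      restore_seed(old)
    }
    traces[[tr]] <- run_phase(w, b, config$n_iter1, lrs1, config$omega_l2,
                              config$phase1_cutoff, phase = 1L, trace_id = tr)
  }
  finals <- vapply(traces, `[[`, numeric(1), "final_llg")
  sel <- which.max(finals)
  ph2 <- run_phase(traces[[sel]]$w, traces[[sel]]$b, config$n_iter2, lrs2,
                   omega = 0, window = NULL, phase = 2L, trace_id = sel,
                   early_stop = TRUE)
  all_rows <- do.call(rbind, c(lapply(traces, `[[`, "rows"), list(ph2$rows)))
  cands <- c(lapply(traces, `[[`, "best"), list(ph2$best))
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "llg"))]]
  structure(list(best = best, trace = all_rows, selected_trace = sel,
                 stop_reason = ph2$stop_reason, config = config,
                 w = ph2$w, b = ph2$b, ref_weights = ref_weights,
                 x_ref = x_ref),
            class = "llg_refit")
}
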