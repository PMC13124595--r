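#' Parametric FSC model
#'
#' Two-parameter Fourier-shell-correlation curve
#' FSC(s) = r / (r + exp(delta_B s^2 / 4)), where r is the signal-to-noise
#' power ratio at s = 0 and delta_B is the difference in falloff B factors
#' between signal and noise.
#'
#' @param r Signal/noise power ratio at s = 0 (> 0).
#' @param delta_b Falloff difference (A^2).
#' @param s_max Optional resolution cutoff 1/d_min (1/A) where the curve
#'   crosses the 0.143 criterion.
#' @return Object of class \code{"fsc_model"}.
#' @export
fsc_model <- function(r, delta_b, s_max = NULL) {
  stopifnot(r > 0)
  structure(list(r = r, delta_b = delta_b, s_max = s_max), class = "fsc_model")
}

#' @export
print.fsc_model <- function(x, ...) {
  cat(sprintf("FSC model: r = %.4g, delta_B = %.4g A^2", x$r, x$delta_b))
  if (!is.null(x$s_max)) cat(sprintf(", s_max = %.4g 1/A (d_min = %.3g A)",
                                     x$s_max, 1 / x$s_max))
  cat("\n")
  invisible(x)
}

#' Evaluate an FSC model
#'
#' @param model An \code{fsc_model}.
#' @param s Reciprocal resolutions (1/A), >= 0.
#' @return FSC values in (0, 1).
#' @examples
#' fsc_curve(fsc_model(100, 400), 0)  # r/(r+1)
#' @export
fsc_curve <- function(model, s) {
  if (any(s < 0)) stop("s must be non-negative")
  model$r / (model$r + exp(model$delta_b * s^2 / 4))
}

#' Empirical FSC target for a resolution cutoff
#'
#' The coefficient laws fitted over deposited half-map FSC curves:
#' r = 34.4680 exp(3.00533 s_max + 4.27895 s_max^2) and
#' delta_B = 17.1158 + 12.0213/s_max + 21.3225/s_max^2, so that the
#' resulting curve crosses 0.143 at s = s_max.
#'
#' @param s_max Target cutoff 1/d_min in (0.05, 0.7) 1/A.
#' @return An \code{fsc_model} with \code{s_max} set.
#' @examples
#' m <- empirical_fsc_target(0.25)
#' fsc_curve(m, 0.25)  # about 0.143
#' @export
empirical_fsc_target <- function(s_max) {
  if (s_max <= 0.05 || s_max >= 0.7) stop("s_max out of supported range (0.05, 0.7)")
  r <- 34.4680 * exp(3.00533 * s_max + 4.27895 * s_max^2)
  db <- 17.1158 + 12.0213 / s_max + 21.3225 / s_max^2
  fsc_model(r, db, s_max = s_max)
}

#' Fit the parametric FSC model to an observed curve
#'
#' Least-squares fit of (r, delta_B) to (s, FSC) points, then locates the
#' 0.143 crossing of the fitted curve (s_max); if the curve never crosses
#' 0.143 in range, s_max is NA with a warning.
#'
#' @param fsc Observed FSC values in (0, 1).
#' @param s Corresponding reciprocal resolutions.
#' @return An \code{fsc_model} with a \code{"residual"} attribute (RMS).
#' @export
fit_fsc_model <- function(fsc, s) {
  keep <- is.finite(fsc) & fsc > 0 & fsc < 1 & s > 0
  if (sum(keep) < 5) stop("need at least 5 usable (s, FSC) points")
  fs <- fsc[keep]; ss <- s[keep]
  obj <- function(p) {
    m <- fsc_model(exp(p[1]), p[2])
    sum((fsc_curve(m, ss) - fs)^2)
  }
  # initialize from the logit-linearization: log(1/FSC - 1) = dB s^2/4 - log r
  y <- log(1 / fs - 1)
  co <- stats::coef(stats::lm(y ~ I(ss^2 / 4)))
  p0 <- c(max(-co[1], log(1.1)), max(co[2], 1))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  m <- fsc_model(exp(fit$par[1]), fit$par[2])
  g <- function(x) fsc_curve(m, x) - 0.143
  s_hi <- max(ss) * 1.5
  if (g(1e-6) > 0 && g(s_hi) < 0) {
    m$s_max <- stats::uniroot(g, c(1e-6, s_hi), tol = 1e-8)$root
  } else {
    warning("fitted FSC curve does not cross 0.143 in range; s_max undefined")
    m$s_max <- NA_real_
  }
  attr(m, "residual") <- sqrt(fit$value / sum(keep))
  m
}

#' Fourier shell correlation between two sets of terms
#'
#' FSC_b = Re sum(F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2) per shell.
#'
#' @param F1,F2 Complex Fourier terms on identical grids.
#' @param shells Shell assignment (\code{\link{make_shells}} result or
#'   integer vector).
#' @return Numeric vector of FSC per shell (NA for empty shells, with a
#'   warning).
#' @export
compute_fsc <- function(F1, F2, shells) {
  if (length(F1) != length(F2)) stop("grids do not match")
  id <- if (is.list(shells)) shells$id else shells
  ns <- max(id)
  out <- rep(NA_real_, ns)
  for (b in seq_len(ns)) {
    sel <- id == b
    if (!any(sel)) { warning("empty shell ", b); next }
    out[b] <- Re(sum(F1[sel] * Conj(F2[sel]))) /
      sqrt(sum(Mod(F1[sel])^2) * sum(Mod(F2[sel])^2))
  }
  out
}

#' Degrade half-maps to a target FSC curve
#'
#' Adds independent, seeded Gaussian noise to each half-map so that their
#' shell-wise FSC matches a target model, then removes all Fourier terms
#' beyond the target's resolution cutoff s_max. Per shell, with signal S
#' and per-half-map noise 2N estimated from the current halves, the added
#' per-half-map noise power is chosen so the half-map FSC
#' S/(S + 2(N + N_add/2)) equals the target (clamped at zero when the
#' current FSC is already below target, with a warning). Noise is generated
#' in real space and shaped per shell, so degraded maps remain real.
#'
#' @param map1,map2 Two \code{density_map} half-maps on identical grids.
#' @param target An \code{fsc_model} with \code{s_max} set (for example
#'   from \code{\link{empirical_fsc_target}}).
#' @param seed Integer RNG seed (recorded in the output).
#' @param n_shells Number of resolution shells (default 20).
#' @return List: \code{map1}, \code{map2} (degraded), \code{shells},
#'   \code{fsc_before}, \code{fsc_target}, \code{noise_added} (per-shell
#'   per-half-map power), \code{seed}.
#' @export
degrade_half_maps <- function(map1, map2, target, seed = 1L, n_shells = 20) {
  if (!identical(dim(map1$grid), dim(map2$grid))) stop("half-map grids differ")
  if (is.null(target$s_max) || !is.finite(target$s_max))
    stop("target model needs a finite s_max")
  ft1 <- map_fourier_terms(map1)
  ft2 <- map_fourier_terms(map2)
  # shells concentrate on the band that survives the cutoff; everything
  # beyond s_max is zeroed regardless
  sh <- make_shells(ft1$s, n_shells = n_shells,
                    s_max = min(max(ft1$s), 1.3 * target$s_max))
  ns <- length(sh$centers)
  fsc_now <- compute_fsc(ft1$F, ft2$F, sh)
  fsc_tgt <- fsc_curve(target, sh$centers)
  # per-term target noise: shell-wise signal/noise estimates, but the
  # target curve evaluated at each term's own resolution, so steep target
  # curves are matched without within-shell discretization bias
  t_term <- fsc_curve(target, ft1$s)
  n_add_term <- numeric(length(ft1$F))
  n_add <- numeric(ns)
  for (b in seq_len(ns)) {
    sel <- sh$id == b
    if (!any(sel)) next
    S <- max(0, mean(Re(ft1$F[sel] * Conj(ft2$F[sel]))))
    Nhalf <- mean(Mod(ft1$F[sel] - ft2$F[sel])^2) / 2   # per-half-map noise power
    tgt <- fsc_tgt[b]
    if (tgt <= 0) next
    # noise profile follows the curve within the shell, with the shell
    # mean pinned to the centre target so the aggregated shell FSC is
    # unbiased
    w_i <- (1 - t_term[sel]) / pmax(t_term[sel], 1e-12)
    scale <- S * (1 - tgt) / tgt / mean(w_i)
    n_add_term[sel] <- pmax(0, scale * w_i - Nhalf)
    n_add[b] <- mean(n_add_term[sel])
    if (is.finite(fsc_now[b]) && fsc_now[b] < tgt - 1e-6 && n_add[b] == 0)
      warning("shell ", b, ": current FSC already below target; no noise removed")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  d <- dim(map1$grid)
  shaped_noise <- function() {
    e <- array(stats::rnorm(prod(d)), d)
    Ef <- fft(e, inverse = TRUE)
    v <- as.vector(Ef)
    for (b in seq_len(ns)) {
      sel <- sh$id == b
      if (!any(sel)) next
      p <- mean(Mod(v[sel])^2)
      v[sel] <- v[sel] * sqrt(n_add_term[sel] / p)
    }
    v[sh$id == 0 & !ft1$dc] <- 0
    v[ft1$dc] <- 0
    v
  }
  keep <- ft1$s <= target$s_max
  f1 <- (ft1$F + shaped_noise()) * keep
  f2 <- (ft2$F + shaped_noise()) * keep
  out1 <- fourier_to_map(f1, d, voxel = map1$voxel, origin = map1$origin)
  out2 <- fourier_to_map(f2, d, voxel = map2$voxel, origin = map2$origin)
  list(map1 = out1, map2 = out2, shells = sh, fsc_before = fsc_now,
       fsc_target = fsc_tgt, noise_added = n_add, seed = seed)
}
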