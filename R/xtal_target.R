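# numerically stable special functions for the Rice / Woolfson likelihoods
log_bessel_i0 <- function(x) log(besselI(x, 0, expon.scaled = TRUE)) + abs(x)
bessel_ratio_i10 <- function(x) besselI(x, 1, expon.scaled = TRUE) /
  besselI(x, 0, expon.scaled = TRUE)
log_cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

#' Conditional amplitude probability density
#'
#' Density of the observed effective normalized amplitude E_e given the
#' calculated normalized amplitude E_C at correlation d = D_obs * sigma_A:
#' the Rice form for acentric reflections and the Woolfson (folded-normal)
#' form for centric reflections. At d = 0 both reduce to the Wilson null
#' densities 2E exp(-E^2) and sqrt(2/pi) exp(-E^2/2).
#'
#' @param E_e Observed effective normalized amplitudes (>= 0).
#' @param E_C Calculated normalized amplitudes (>= 0).
#' @param d Product D_obs * sigma_A, in [0, 1).
#' @param centric Logical vector.
#' @param log Return log density?
#' @return Density (or log density) values.
#' @export
conditional_density <- function(E_e, E_C, d, centric, log = FALSE) {
  if (any(d < 0) || any(d >= 1)) stop("d = D_obs * sigma_A must lie in [0, 1)")
  if (any(E_e < 0) || any(E_C < 0)) stop("amplitudes must be non-negative")
  n <- max(length(E_e), length(E_C), length(d), length(centric))
  E_e <- rep_len(E_e, n); E_C <- rep_len(E_C, n)
  d <- rep_len(d, n); centric <- rep_len(centric, n)
  u <- 1 - d^2
  lp <- numeric(n)
  a_idx <- !centric
  if (any(a_idx)) {
    ee <- E_e[a_idx]; ec <- E_C[a_idx]; uu <- u[a_idx]; dd <- d[a_idx]
    arg <- 2 * dd * ee * ec / uu
    lp[a_idx] <- log(2 * ee) - log(uu) - (ee^2 + (dd * ec)^2) / uu + log_bessel_i0(arg)
  }
  if (any(centric)) {
    ee <- E_e[centric]; ec <- E_C[centric]; uu <- u[centric]; dd <- d[centric]
    arg <- dd * ee * ec / uu
    lp[centric] <- 0.5 * log(2 / (pi * uu)) - (ee^2 + (dd * ec)^2) / (2 * uu) +
      log_cosh(arg)
  }
  if (log) lp else exp(lp)
}

#' Per-reflection intensity-based log-likelihood-gain terms
#'
#' Computes LLGI = ln p(E_e; E_C) - ln p(E_e) per reflection together with
#' the analytic derivatives with respect to E_C and with respect to
#' d = D_obs * sigma_A (used by the sigma_A refinement).
#'
#' @param E_e,E_C,d,centric As in \code{\link{conditional_density}}.
#' @return List: \code{llg} (per reflection), \code{dE_C}, \code{dd}.
#' @export
llgi_terms <- function(E_e, E_C, d, centric) {
  n <- max(length(E_e), length(E_C), length(d), length(centric))
  E_e <- rep_len(E_e, n); E_C <- rep_len(E_C, n)
  d <- rep_len(d, n); centric <- rep_len(centric, n)
  if (any(d < 0 | d >= 1)) stop("d must lie in [0, 1)")
  u <- 1 - d^2
  llg <- numeric(n); gE <- numeric(n); gd <- numeric(n)
  a <- !centric
  if (any(a)) {
    ee <- E_e[a]; ec <- E_C[a]; uu <- u[a]; dd <- d[a]
    arg <- 2 * dd * ee * ec / uu
    r <- bessel_ratio_i10(arg)
    llg[a] <- -log(uu) - (ee^2 + (dd * ec)^2) / uu + ee^2 + log_bessel_i0(arg)
    gE[a] <- -2 * dd^2 * ec / uu + r * 2 * dd * ee / uu
    gd[a] <- 2 * dd / uu - 2 * dd * (ee^2 + ec^2) / uu^2 +
      r * 2 * ee * ec * (1 + dd^2) / uu^2
  }
  if (any(centric)) {
    ee <- E_e[centric]; ec <- E_C[centric]; uu <- u[centric]; dd <- d[centric]
    arg <- dd * ee * ec / uu
    t <- tanh(arg)
    llg[centric] <- -0.5 * log(uu) - (ee^2 + (dd * ec)^2) / (2 * uu) + ee^2 / 2 +
      log_cosh(arg)
    gE[centric] <- -dd^2 * ec / uu + t * dd * ee / uu
    gd[centric] <- dd / uu - dd * (ee^2 + ec^2) / uu^2 +
      t * ee * ec * (1 + dd^2) / uu^2
  }
  if (any(!is.finite(llg))) stop("non-finite LLGI term at reflection ",
                                 which(!is.finite(llg))[1])
  list(llg = llg, dE_C = gE, dd = gd)
}

#' Crystallographic LLGI target
#'
#' Sums the intensity-based log-likelihood gain over the working set of a
#' reflection set, given calculated normalized amplitudes and per-bin
#' sigma_A values. Reflections outside the resolution window are ignored.
#'
#' @param refl Reflection set with \code{E_e}, \code{D_obs}, \code{centric},
#'   \code{bin_id} and optionally \code{free_flag}.
#' @param E_C Calculated normalized amplitudes, one per reflection.
#' @param sigma_a Per-bin sigma_A values (named or indexed by bin id), or a
#'   single number.
#' @param d_min,d_max Optional resolution window in Angstrom (keeps
#'   reflections with d_min <= d <= d_max).
#' @param gradient Also return d(LLGI)/dE_C (zero outside the working set)?
#' @return The scalar LLGI, with attribute \code{"gradient"} when requested.
#' @examples
#' tf <- llgi_terms(1, 1, 0.5, centric = FALSE)
#' round(tf$llg, 4)  # 0.024
#' @export
llgi <- function(refl, E_C, sigma_a, d_min = NULL, d_max = NULL, gradient = FALSE) {
  n <- nrow(refl)
  stopifnot(length(E_C) == n)
  sa <- sigma_a_per_reflection(refl, sigma_a)
  use <- rep(TRUE, n)
  if (!is.null(refl$free_flag)) use <- use & !refl$free_flag
  if (!is.null(d_min)) use <- use & (refl$d >= d_min)
  if (!is.null(d_max)) use <- use & (refl$d <= d_max)
  g <- numeric(n)
  val <- 0
  if (any(use)) {
    tm <- llgi_terms(refl$E_e[use], E_C[use], refl$D_obs[use] * sa[use],
                     refl$centric[use])
    val <- sum(tm$llg)
    g[use] <- tm$dE_C
  }
  if (gradient) attr(val, "gradient") <- g
  val
}

sigma_a_per_reflection <- function(refl, sigma_a) {
  if (length(sigma_a) == 1) return(rep(sigma_a, nrow(refl)))
  if (!is.null(names(sigma_a))) return(as.numeric(sigma_a[as.character(refl$bin_id)]))
  as.numeric(sigma_a[refl$bin_id])
}

#' Refine per-bin sigma_A by Newton-Raphson
#'
#' Maximizes the binned LLGI with respect to sigma_A, one scalar problem per
#' resolution bin, using the analytic first derivative and a
#' central-difference curvature. Updates are clamped to [0.015, 0.99]; a
#' golden-section fallback handles non-concave points. Only working-set
#' reflections contribute.
#'
#' @param refl Reflection set with \code{E_e}, \code{D_obs}, \code{centric},
#'   \code{bin_id}, optional \code{free_flag}.
#' @param E_C Calculated normalized amplitudes.
#' @param init Initial sigma_A (default 0.5).
#' @param tol Convergence tolerance on sigma_A (default 1e-4).
#' @param max_iter Maximum Newton steps per bin (default 20).
#' @return Named numeric vector of sigma_A per bin (names = bin ids), with
#'   attribute \code{"iterations"}.
#' @export
refine_sigma_a <- function(refl, E_C, init = 0.5, tol = 1e-4, max_iter = 20) {
  lo <- 0.015; hi <- 0.99
  work <- if (!is.null(refl$free_flag)) !refl$free_flag else rep(TRUE, nrow(refl))
  bins <- sort(unique(refl$bin_id))
  nb <- length(bins)
  bin_f <- factor(refl$bin_id[work], levels = bins)
  ee <- refl$E_e[work]; ec <- E_C[work]
  Do <- refl$D_obs[work]; cen <- refl$centric[work]
  # per-bin gradient of the binned LLG, evaluated for all bins in one
  # vectorized sweep
  bin_i <- as.integer(bin_f)
  grad_all <- function(sa_bins) {
    sa <- sa_bins[bin_i]
    tm <- llgi_terms(ee, ec, pmin(Do * sa, 1 - 1e-9), cen)
    as.numeric(rowsum(tm$dd * Do, bin_i))
  }
  val_bin <- function(sa, bi) {
    sel <- bin_i == bi
    sum(llgi_terms(ee[sel], ec[sel], pmin(Do[sel] * sa, 1 - 1e-9), cen[sel])$llg)
  }
  sa <- rep_len(init, nb)
  iters <- rep(0L, nb)
  done <- rep(FALSE, nb)
  h <- 1e-4
  g <- grad_all(sa)
  # curvature by finite differences on the first sweep, then secant updates
  g_h <- grad_all(pmin(sa + h, hi))
  g2 <- (g_h - g) / (pmin(sa + h, hi) - sa)
  for (it in seq_len(max_iter)) {
    concave <- is.finite(g) & is.finite(g2) & g2 < 0
    # Newton step where the problem is locally concave; a damped uphill
    # step elsewhere (the optimum then usually sits at a clamp boundary)
    step <- ifelse(concave, pmin(pmax(-g / g2, -0.3), 0.3),
                   0.1 * sign(g))
    sa_new <- pmin(pmax(sa + step, lo), hi)
    newly <- !done & abs(sa_new - sa) < tol
    iters[newly] <- it
    sa_prev <- sa; g_prev <- g
    sa <- ifelse(done, sa, sa_new)
    done <- done | newly
    if (all(done)) break
    g <- grad_all(sa)
    ds <- sa - sa_prev
    g2 <- ifelse(abs(ds) > 1e-12, (g - g_prev) / ds, g2)
  }
  # Newton failures (non-concave points) fall back to a bounded line search
  for (bi in which(iters == 0L)) {
    opt <- stats::optimize(val_bin, c(lo, hi), bi = bi, maximum = TRUE,
                           tol = tol / 10)
    cand <- c(opt$maximum, lo, hi, sa[bi])
    sa[bi] <- cand[which.max(vapply(cand, val_bin, numeric(1), bi = bi))]
    iters[bi] <- max_iter
  }
  out <- pmin(pmax(sa, lo), hi)
  names(out) <- as.character(bins)
  attr(out, "iterations") <- iters
  out
}

#' Crystallographic R factors
#'
#' R = sum | |F_o| - k |F_c| | / sum |F_o| with the scale k fit by least
#' squares on the working set.
#'
#' @param F_obs,F_calc Observed and calculated amplitudes.
#' @param free_flags Logical: TRUE marks the free (test) set.
#' @return List with \code{r_work}, \code{r_free} (NA with a warning when
#'   the free set is empty) and \code{scale}.
#' @export
r_factors <- function(F_obs, F_calc, free_flags) {
  stopifnot(length(F_obs) == length(F_calc), length(free_flags) == length(F_obs))
  w <- !free_flags
  if (!any(w)) stop("empty working set")
  k <- sum(F_obs[w] * F_calc[w]) / sum(F_calc[w]^2)
  rfac <- function(sel) sum(abs(F_obs[sel] - k * F_calc[sel])) / sum(F_obs[sel])
  r_work <- rfac(w)
  if (any(free_flags)) {
    r_free <- rfac(free_flags)
  } else {
    warning("empty free set; R_free undefined")
    r_free <- NA_real_
  }
  list(r_work = r_work, r_free = r_free, scale = k)
}
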