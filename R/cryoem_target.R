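#' Half-map Fourier statistics
#'
#' Estimates signal and noise per resolution shell from two independent
#' half-map reconstructions: the signal from the correlation of their
#' Fourier terms, S = max(0, Re<F1 conj(F2)>), and the noise (per
#' averaged-map term) from their difference, N = <|F1 - F2|^2>/4. The
#' observed term for the likelihood is the averaged map, normalized by
#' sqrt(S + N), and the attenuation is D_obs = sqrt(S / (S + N)).
#'
#' @param F1,F2 Complex Fourier terms of the two half-maps (identical
#'   ordering/grids).
#' @param shells Shell assignment from \code{\link{make_shells}} (list with
#'   \code{id}, \code{centers}), or an integer vector of shell ids.
#' @return List of class \code{"halfmap_fourier"}: per-term \code{E_e},
#'   \code{phi_obs}, \code{shell_id}; per-shell \code{signal}, \code{noise},
#'   \code{D_obs}, \code{s_center}, \code{n_terms}; plus \code{F_avg}.
#' @export
halfmap_statistics <- function(F1, F2, shells) {
  if (length(F1) != length(F2)) stop("half-map grids do not match")
  id <- if (is.list(shells)) shells$id else shells
  centers <- if (is.list(shells)) shells$centers else NULL
  stopifnot(length(id) == length(F1))
  ns <- max(id)
  S <- N <- Do <- nt <- numeric(ns)
  for (b in seq_len(ns)) {
    sel <- id == b
    nt[b] <- sum(sel)
    if (nt[b] == 0) next
    S[b] <- max(0, mean(Re(F1[sel] * Conj(F2[sel]))))
    N[b] <- mean(Mod(F1[sel] - F2[sel])^2) / 4
    tot <- S[b] + N[b]
    if (tot <= 0) {
      warning("all-zero shell ", b, "; D_obs set to 0")
      Do[b] <- 0
    } else {
      Do[b] <- sqrt(S[b] / tot)
    }
  }
  Favg <- (F1 + F2) / 2
  denom <- sqrt(pmax(S + N, .Machine$double.xmin))[pmax(id, 1)]
  E_e <- ifelse(id > 0, Mod(Favg) / denom, 0)
  phi <- Arg(Favg)
  structure(list(E_e = E_e, phi_obs = phi, shell_id = id,
                 signal = S, noise = N, D_obs = Do,
                 s_center = centers, n_terms = nt, F_avg = Favg),
            class = "halfmap_fourier")
}

#' Cryo-EM Fourier-term log-likelihood gain
#'
#' For each Fourier term, with d = D_obs * sigma_A, u = 1 - d^2 and
#' dphi = phi_calc - phi_obs:
#' LLG = 2 d E_e E_calc cos(dphi)/u - d^2 (E_e^2 + E_calc^2)/u - ln(u),
#' summed over terms. Exactly 0 when d = 0 everywhere.
#'
#' @param hm A \code{halfmap_fourier}.
#' @param E_calc Calculated normalized amplitudes, one per term (terms with
#'   shell id 0 are ignored).
#' @param phi_calc Calculated phases (rad).
#' @param sigma_a Per-shell sigma_A (vector indexed by shell), or a scalar.
#' @param gradient Also return derivatives with respect to E_calc and
#'   phi_calc?
#' @return Scalar LLG; with \code{gradient = TRUE}, attributes
#'   \code{"dE_calc"} and \code{"dphi_calc"}.
#' @export
llg_cryoem <- function(hm, E_calc, phi_calc, sigma_a, gradient = FALSE) {
  id <- hm$shell_id
  sel <- id > 0
  sa <- if (length(sigma_a) == 1) rep(sigma_a, max(id)) else sigma_a
  d <- numeric(length(id))
  d[sel] <- hm$D_obs[id[sel]] * sa[id[sel]]
  if (any(d >= 1)) stop("D_obs * sigma_A >= 1")
  u <- 1 - d^2
  dphi <- phi_calc - hm$phi_obs
  ee <- hm$E_e
  term <- ifelse(sel,
                 2 * d * ee * E_calc * cos(dphi) / u -
                   d^2 * (ee^2 + E_calc^2) / u - log(u),
                 0)
  val <- sum(term)
  if (gradient) {
    gE <- ifelse(sel, 2 * d * ee * cos(dphi) / u - 2 * d^2 * E_calc / u, 0)
    gP <- ifelse(sel, -2 * d * ee * E_calc * sin(dphi) / u, 0)
    attr(val, "dE_calc") <- gE
    attr(val, "dphi_calc") <- gP
  }
  val
}

#' Per-shell sigma_A for the cryo-EM target
#'
#' Maximizes the Fourier-term LLG shell by shell over sigma_A in
#' [0.015, 0.99] by bounded scalar search; degenerate shells fall to the
#' lower clamp with a warning.
#'
#' @param hm A \code{halfmap_fourier}.
#' @param E_calc,phi_calc Calculated normalized amplitudes and phases.
#' @return Numeric vector of sigma_A per shell.
#' @export
sigma_a_em <- function(hm, E_calc, phi_calc) {
  id <- hm$shell_id
  ns <- max(id)
  out <- numeric(ns)
  dphi <- phi_calc - hm$phi_obs
  for (b in seq_len(ns)) {
    sel <- id == b
    if (!any(sel) || hm$D_obs[b] <= 0) {
      if (any(sel)) warning("degenerate shell ", b, "; sigma_A at lower clamp")
      out[b] <- 0.015
      next
    }
    ee <- hm$E_e[sel]; ec <- E_calc[sel]; cp <- cos(dphi[sel]); Do <- hm$D_obs[b]
    f <- function(sa) {
      d <- min(Do * sa, 1 - 1e-9); u <- 1 - d^2
      sum(2 * d * ee * ec * cp / u - d^2 * (ee^2 + ec^2) / u - log(u))
    }
    opt <- stats::optimize(f, c(0.015, 0.99), maximum = TRUE, tol = 1e-5)
    cand <- c(opt$maximum, 0.015, 0.99)
    out[b] <- cand[which.max(vapply(cand, f, numeric(1)))]
  }
  out
}

#' Real-space correlation coefficient
#'
#' Pearson correlation between a model-derived density (band-limited
#' inverse Fourier synthesis of the model structure factors) and an
#' experimental map, globally or per residue over a spherical atom mask.
#'
#' @param model An \code{atomic_model} in the map frame.
#' @param map A \code{density_map}.
#' @param per_residue Return one value per residue (default FALSE)?
#' @param d_min Band limit for the model density (A, default 2).
#' @param mask_radius Mask radius around atoms for per-residue values (A,
#'   default 2.5).
#' @return A single correlation, or a named vector per residue (NA with a
#'   warning for residues outside the map).
#' @export
rscc <- function(model, map, per_residue = FALSE, d_min = 2, mask_radius = 2.5) {
  dm <- model_density(model, map, d_min = d_min)
  if (!per_residue) return(stats::cor(as.vector(dm$grid), as.vector(map$grid)))
  d <- dim(map$grid)
  ax <- map$origin[1] + (seq_len(d[1]) - 1) * map$voxel[1]
  ay <- map$origin[2] + (seq_len(d[2]) - 1) * map$voxel[2]
  az <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel[3]
  resnos <- unique(model$resno)
  out <- setNames(rep(NA_real_, length(resnos)), resnos)
  for (ri in seq_along(resnos)) {
    at <- model[model$resno == resnos[ri], , drop = FALSE]
    ix <- which(ax >= min(at$x) - mask_radius & ax <= max(at$x) + mask_radius)
    iy <- which(ay >= min(at$y) - mask_radius & ay <= max(at$y) + mask_radius)
    iz <- which(az >= min(at$z) - mask_radius & az <= max(at$z) + mask_radius)
    if (!length(ix) || !length(iy) || !length(iz)) {
      warning("residue ", resnos[ri], " lies outside the map")
      next
    }
    sub_m <- dm$grid[ix, iy, iz]
    sub_e <- map$grid[ix, iy, iz]
    # refine box to spherical mask around the residue atoms
    gx <- ax[ix][slice.index(sub_m, 1)]
    gy <- ay[iy][slice.index(sub_m, 2)]
    gz <- az[iz][slice.index(sub_m, 3)]
    keep <- rep(FALSE, length(gx))
    for (j in seq_len(nrow(at))) {
      keep <- keep | ((gx - at$x[j])^2 + (gy - at$y[j])^2 + (gz - at$z[j])^2
                      <= mask_radius^2)
    }
    if (sum(keep) >= 4) out[ri] <- stats::cor(as.vector(sub_m)[keep],
                                              as.vector(sub_e)[keep])
  }
  out
}

#' Residue B factors from local map correlation
#'
#' Monotone non-increasing conversion of per-residue RSCC to an isotropic
#' B factor: B = B_min + (B_max - B_min) * (1 - clamp(RSCC, 0, 1)), so a
#' perfect local fit gets B_min and uncorrelated or anti-correlated density
#' gets B_max.
#'
#' @param rscc_values Per-residue correlations.
#' @param b_min,b_max Bounds in A^2 (defaults 20 and 300).
#' @return Per-residue B factors.
#' @export
update_b_from_rscc <- function(rscc_values, b_min = 20, b_max = 300) {
  cc <- pmin(pmax(rscc_values, 0), 1)
  cc[is.na(cc)] <- 0
  b_min + (b_max - b_min) * (1 - cc)
}
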