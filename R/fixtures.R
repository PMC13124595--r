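#' Recipe for synthetic test data
#'
#' Bundles every knob of the synthetic data generators: a toy structure in
#' two conformations, crystallographic intensities, cryo-EM half-maps and
#' MSA cluster profiles. All generators are bit-reproducible given the
#' recipe (the seed is mandatory).
#'
#' @param n_residues Chain length (default 16).
#' @param loop Residue indices whose torsions differ between states A and B
#'   (default 7:10).
#' @param loop_shift Torsion change (rad) applied to the loop in state B
#'   (default c(phi = 1.2, psi = -1.5)).
#' @param d_min Crystallographic resolution limit in A (default 2.5).
#' @param noise_frac Fractional intensity error (default 0.1).
#' @param cell_margin Padding around the model when building the P1 box
#'   cell (A, default 12).
#' @param grid Map grid dimension (default 48, giving a grid^3 map).
#' @param voxel Map voxel size (A, default 1).
#' @param map_noise Per-Fourier-term noise power added to each half map,
#'   as a fraction of the mean signal power (default 0.25).
#' @param n_clusters Profile clusters (default 24; enough soft samples for
#'   the pairwise mutual-information estimator to separate planted
#'   couplings from its finite-sample bias).
#' @param n_symbols Profile symbol channels (default 23).
#' @param coupled_pairs Residue pairs (2-column matrix) planted as coupled
#'   columns in the "final" profile (default 3 pairs spread over the chain).
#' @param free_fraction Free-set fraction for reflections (default 0.05).
#' @param seed Integer seed (mandatory).
#' @return List of class \code{"fixture_recipe"}.
#' @export
fixture_recipe <- function(n_residues = 16, loop = NULL,
                           loop_shift = c(phi = 1.2, psi = -1.5),
                           d_min = 2.5, noise_frac = 0.1, cell_margin = 12,
                           grid = 48, voxel = 1, map_noise = 0.25,
                           n_clusters = 24, n_symbols = 23,
                           coupled_pairs = NULL, free_fraction = 0.05,
                           seed = 1L) {
  stopifnot(n_residues >= 5, d_min >= 1.5, !missing(seed) || is.numeric(seed))
  if (is.null(loop))
    loop <- seq(max(2, floor(n_residues / 2) - 1), length.out = 4)
  loop <- loop[loop >= 2 & loop <= n_residues - 1]
  if (is.null(coupled_pairs))
    coupled_pairs <- cbind(c(2, 4, 6),
                           c(n_residues - 3, n_residues - 1, n_residues - 5))
  structure(list(n_residues = n_residues, loop = loop, loop_shift = loop_shift,
                 d_min = d_min, noise_frac = noise_frac,
                 cell_margin = cell_margin, grid = grid, voxel = voxel,
                 map_noise = map_noise, n_clusters = n_clusters,
                 n_symbols = n_symbols, coupled_pairs = coupled_pairs,
                 free_fraction = free_fraction, seed = as.integer(seed)),
            class = "fixture_recipe")
}

#' Baseline backbone torsions of the toy structure
#'
#' Helix-like torsions with a small deterministic per-residue ripple so the
#' chain is not exactly symmetric.
#'
#' @param n Number of residues.
#' @return List with \code{phi}, \code{psi} in radians.
#' @export
toy_torsions <- function(n) {
  i <- seq_len(n)
  list(phi = -1.05 + 0.08 * sin(1.7 * i),
       psi = -0.79 + 0.08 * cos(2.3 * i))
}

#' Build the two-state toy structure
#'
#' State A is the baseline helix-like chain; state B applies the recipe's
#' torsion shift to the loop residues, producing a localized conformational
#' change of more than 2 A over the loop.
#'
#' @param recipe A \code{fixture_recipe}.
#' @return List: \code{state_a}, \code{state_b} (atomic models),
#'   \code{torsions_a}, \code{torsions_b}.
#' @export
make_toy_structure <- function(recipe) {
  tt <- toy_torsions(recipe$n_residues)
  ta <- tt
  tb <- tt
  tb$phi[recipe$loop] <- tb$phi[recipe$loop] + recipe$loop_shift[["phi"]]
  tb$psi[recipe$loop] <- tb$psi[recipe$loop] + recipe$loop_shift[["psi"]]
  list(state_a = build_backbone(ta$phi, ta$psi),
       state_b = build_backbone(tb$phi, tb$psi),
       torsions_a = ta, torsions_b = tb)
}

#' P1 box cell that contains a model
#'
#' @param model An \code{atomic_model}.
#' @param margin Padding (A).
#' @return List: \code{cell} (a \code{unit_cell}) and \code{model} shifted
#'   so all coordinates are at least margin/2 from the box faces.
#' @export
box_cell <- function(model, margin = 12) {
  X <- model_xyz(model)
  span <- apply(X, 2, function(v) diff(range(v)))
  a <- span + margin
  shift <- -apply(X, 2, min) + margin / 2
  model$x <- model$x + shift[1]
  model$y <- model$y + shift[2]
  model$z <- model$z + shift[3]
  list(cell = unit_cell(a[1], a[2], a[3]), model = model)
}

# Friedel-unique Miller indices to resolution d_min in a P1 cell
unique_hkl <- function(cell, d_min) {
  smax <- 1 / d_min
  hm <- ceiling(smax * c(cell$a, cell$b, cell$c))
  g <- expand.grid(h = -hm[1]:hm[1], k = -hm[2]:hm[2], l = 0:hm[3])
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  # hemisphere l >= 0; on l = 0 keep k > 0 or (k = 0, h > 0)
  keep <- g$l > 0 | (g$l == 0 & (g$k > 0 | (g$k == 0 & g$h > 0)))
  g <- g[keep, ]
  hkl <- as.matrix(g)
  s <- reciprocal_s(cell, hkl)
  hkl[s <= smax, , drop = FALSE]
}

#' Simulate a crystallographic reflection set from a model
#'
#' Places the model in a padded P1 box, computes true structure factors by
#' direct summation, and simulates observed intensities
#' I_o = |F|^2 + N(0, sigma_I) with sigma_I a constant fractional error
#' plus a floor. Bins, free flags and effective amplitudes (E_e, D_obs)
#' are filled in.
#'
#' @param model An \code{atomic_model} (e.g. from
#'   \code{\link{make_toy_structure}}).
#' @param recipe A \code{fixture_recipe}.
#' @param noise_frac Override the recipe's fractional error (optional).
#' @return List: \code{refl} (reflection set with I_o, sigma_I, E_e, D_obs,
#'   free_flag and truth columns F_true, E_true), \code{cell},
#'   \code{model} (shifted into the box).
#' @export
simulate_reflections <- function(model, recipe, noise_frac = NULL) {
  if (is.null(noise_frac)) noise_frac <- recipe$noise_frac
  bx <- box_cell(model, recipe$cell_margin)
  cell <- bx$cell
  model <- bx$model
  hkl <- unique_hkl(cell, recipe$d_min)
  refl <- reflection_metadata(cell, spacegroup_ops("P1"), hkl)
  refl <- assign_bins(refl, n_bins = 10, min_per_bin = 50)
  sf <- sf_calc(model, cell, refl, keep_terms = FALSE)
  I_true <- Mod(sf$F)^2
  old <- local_seed(recipe$seed)
  on.exit(restore_seed(old))
  floor_I <- noise_frac * stats::median(I_true)
  sigma_I <- noise_frac * I_true + floor_I
  if (noise_frac == 0) sigma_I <- rep(0, length(I_true))
  I_o <- I_true + stats::rnorm(length(I_true), 0, sigma_I)
  refl$I_o <- I_o
  refl$sigma_I <- sigma_I
  refl <- assign_free_set(refl, recipe$free_fraction, seed = recipe$seed + 1L)
  ea <- effective_amplitudes(I_o, sigma_I, refl)
  refl$E_e <- ea$E_e
  refl$D_obs <- ea$D_obs
  refl$F_true <- Mod(sf$F)
  refl$E_true <- normalize_to_E(Mod(sf$F), refl)$E
  list(refl = refl, cell = cell, model = model, wilson_scale = ea$wilson_scale)
}

#' Simulate a pair of cryo-EM half-maps from a model
#'
#' Computes the band-limited model density on a cubic grid and creates two
#' half-maps by adding independent Gaussian white noise whose per-term
#' Fourier power is \code{map_noise} times the mean signal power.
#'
#' @param model An \code{atomic_model}; it is centred in the box.
#' @param recipe A \code{fixture_recipe}.
#' @param d_min Band limit of the model density (A, default 2.5).
#' @return List: \code{map1}, \code{map2}, \code{truth} (noise-free map),
#'   \code{model} (centred), \code{noise_power} (per-term).
#' @export
simulate_half_maps <- function(model, recipe, d_min = 2.5) {
  g <- recipe$grid
  vox <- recipe$voxel
  box <- g * vox
  X <- model_xyz(model)
  ctr <- colMeans(X)
  model$x <- model$x - ctr[1] + box / 2
  model$y <- model$y - ctr[2] + box / 2
  model$z <- model$z - ctr[3] + box / 2
  empty <- density_map(array(0, c(g, g, g)), voxel = vox)
  truth <- model_density(model, empty, d_min = d_min)
  ft <- map_fourier_terms(truth)
  sig_power <- mean(Mod(ft$F[!ft$dc])^2)
  noise_power <- recipe$map_noise * sig_power
  sd_rs <- sqrt(noise_power / prod(dim(truth$grid)))
  old <- local_seed(recipe$seed + 2L)
  on.exit(restore_seed(old))
  mk <- function() density_map(truth$grid + array(stats::rnorm(prod(dim(truth$grid)), 0, sd_rs),
                                                  dim(truth$grid)),
                               voxel = vox)
  list(map1 = mk(), map2 = mk(), truth = truth, model = model,
       noise_power = noise_power)
}

#' Simulate initial and optimized MSA cluster profiles
#'
#' The initial profile has independent random columns (each cluster/residue
#' column a normalized positive vector). The "final" profile is identical
#' except at the recipe's planted coupled residue pairs, where both columns
#' of each pair are replaced, cluster by cluster, with sharply concentrated
#' distributions over a shared per-cluster symbol, creating strong pairwise
#' correlation across clusters.
#'
#' @param recipe A \code{fixture_recipe}.
#' @param planted Plant the couplings (default TRUE; FALSE returns a null
#'   pair with independent perturbation-free profiles).
#' @return List: \code{m_init}, \code{m_final} (arrays clusters x residues
#'   x symbols), \code{pairs}.
#' @export
simulate_profiles <- function(recipe, planted = TRUE) {
  K <- recipe$n_clusters; L <- recipe$n_residues; A <- recipe$n_symbols
  old <- local_seed(recipe$seed + 3L)
  on.exit(restore_seed(old))
  m0 <- array(stats::runif(K * L * A, 0.2, 1), c(K, L, A))
  for (k in seq_len(K)) for (l in seq_len(L)) m0[k, l, ] <- m0[k, l, ] / sum(m0[k, l, ])
  m1 <- m0
  pairs <- recipe$coupled_pairs
  if (planted && !is.null(pairs) && nrow(pairs) > 0) {
    for (p in seq_len(nrow(pairs))) {
      sym <- sample.int(A, K, replace = TRUE)   # shared symbol per cluster
      for (k in seq_len(K)) {
        col <- rep(0.1 / A, A)
        col[sym[k]] <- col[sym[k]] + 0.9
        m1[k, pairs[p, 1], ] <- col
        m1[k, pairs[p, 2], ] <- col
      }
    }
  }
  list(m_init = m0, m_final = m1, pairs = if (planted) pairs else NULL)
}
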