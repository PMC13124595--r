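#' Construct a density map
#'
#' A real-space density grid with voxel size and origin metadata.
#'
#' @param grid 3-D numeric array.
#' @param voxel Voxel edge lengths (A), length 1 or 3.
#' @param origin Cartesian origin of grid point (1,1,1) (A).
#' @return Object of class \code{"density_map"}.
#' @export
density_map <- function(grid, voxel = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  voxel <- rep_len(voxel, 3)
  structure(list(grid = grid, voxel = voxel, origin = origin),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("Density map %d x %d x %d, voxel %.3f x %.3f x %.3f A, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# integer FFT frequencies for an axis of length n: 0, 1, ..., floor(n/2), -...
fft_freqs <- function(n) {
  f <- seq_len(n) - 1
  f[f > n / 2] <- f[f > n / 2] - n
  f
}

#' Fourier terms of a density map
#'
#' Computes the complex Fourier terms F(h) = sum rho(x) exp(+2 pi i h.x_frac)
#' of a map (the crystallographic structure-factor convention), together
#' with the integer indices and reciprocal resolution of every term. The
#' zero-frequency term is flagged.
#'
#' @param map A \code{density_map}.
#' @return List: \code{F} (complex vector, length = n voxels), \code{hkl}
#'   (n x 3 integer), \code{s} (1/A), \code{dc} (logical, the F000 term),
#'   \code{dim}, \code{voxel}.
#' @export
map_fourier_terms <- function(map) {
  d <- dim(map$grid)
  F <- fft(map$grid, inverse = TRUE)     # sum rho exp(+2 pi i h.x/n)
  h <- fft_freqs(d[1]); k <- fft_freqs(d[2]); l <- fft_freqs(d[3])
  hg <- array(h[slice.index(F, 1)], d)
  kg <- array(k[slice.index(F, 2)], d)
  lg <- array(l[slice.index(F, 3)], d)
  a <- d * map$voxel                      # box edge lengths
  s <- sqrt((hg / a[1])^2 + (kg / a[2])^2 + (lg / a[3])^2)
  list(F = as.vector(F), hkl = cbind(as.vector(hg), as.vector(kg), as.vector(lg)),
       s = as.vector(s), dc = as.vector(s) == 0, dim = d, voxel = map$voxel)
}

#' Invert Fourier terms back to a density map
#'
#' @param F Complex vector as produced by \code{map_fourier_terms} (same
#'   ordering).
#' @param dim Grid dimensions.
#' @param voxel Voxel size.
#' @param origin Origin.
#' @return A \code{density_map} (real part of the inverse transform).
#' @export
fourier_to_map <- function(F, dim, voxel = 1, origin = c(0, 0, 0)) {
  arr <- array(F, dim)
  g <- Re(fft(arr)) / prod(dim)
  density_map(g, voxel = voxel, origin = origin)
}

#' Uniform resolution shells
#'
#' Assigns each Fourier term to a shell uniform in s; the DC term gets
#' shell 0 (excluded from statistics).
#'
#' @param s Reciprocal resolutions (1/A).
#' @param n_shells Number of shells (default 20).
#' @param s_max Upper edge (default max(s)).
#' @return List: \code{id} (integer shell per term, 0 = DC), \code{edges},
#'   \code{centers}.
#' @export
make_shells <- function(s, n_shells = 20, s_max = NULL) {
  if (is.null(s_max)) s_max <- max(s)
  edges <- seq(0, s_max, length.out = n_shells + 1)
  id <- findInterval(s, edges, rightmost.closed = TRUE)
  id[id > n_shells] <- 0L          # beyond s_max: ignore
  id[s == 0] <- 0L
  list(id = id, edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

#' Model density on a map grid
#'
#' Computes the model-derived density by placing structure factors of the
#' atomic model on the Fourier grid of the target map (band-limited at
#' \code{d_min}) and inverting.
#'
#' @param model An \code{atomic_model} (coordinates in the map frame).
#' @param map A \code{density_map} providing grid geometry.
#' @param d_min Low-pass band limit in A (default 2).
#' @return A \code{density_map} with the model density.
#' @export
model_density <- function(model, map, d_min = 2) {
  ft <- map_fourier_terms(map)
  sel <- !ft$dc & ft$s <= 1 / d_min
  cell <- unit_cell(ft$dim[1] * map$voxel[1], ft$dim[2] * map$voxel[2],
                    ft$dim[3] * map$voxel[3])
  shifted <- model
  shifted$x <- model$x - map$origin[1]
  shifted$y <- model$y - map$origin[2]
  shifted$z <- model$z - map$origin[3]
  refl <- data.frame(h = ft$hkl[sel, 1], k = ft$hkl[sel, 2], l = ft$hkl[sel, 3],
                     s = ft$s[sel])
  sf <- sf_calc(shifted, cell, refl, keep_terms = FALSE)
  F <- complex(length.out = length(ft$F))
  F[sel] <- sf$F
  fourier_to_map(F, ft$dim, voxel = map$voxel, origin = map$origin)
}
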