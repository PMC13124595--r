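#' Construct a crystallographic unit cell
#'
#' Builds a unit cell object holding cell constants together with the
#' orthogonalization and fractionalization matrices (PDB convention:
#' a along x, b in the xy plane).
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class \code{"unit_cell"} with fields \code{a, b, c,
#'   alpha, beta, gamma}, \code{orth} (fractional -> Cartesian, 3x3),
#'   \code{frac} (Cartesian -> fractional, 3x3) and \code{volume} (A^3).
#' @examples
#' cl <- unit_cell(30, 40, 50)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("cell angles are geometrically impossible (non-positive volume)")
  v <- a * b * c * sqrt(vfac)
  # orthogonalization matrix, columns are the cell axes in Cartesian space
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, v / (a * b * sg)
  ), 3, 3, byrow = TRUE)
  frac <- solve(orth)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 orth = orth, frac = frac, volume = v),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Reciprocal resolution of Miller indices
#'
#' Computes s = 1/d for each reflection from the reciprocal metric tensor.
#'
#' @param cell A \code{unit_cell}.
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @return Numeric vector of s values (1/Angstrom).
#' @export
reciprocal_s <- function(cell, hkl) {
  hkl <- as_hkl_matrix(hkl)
  # row of frac matrix transposed maps hkl to reciprocal-space vector
  q <- hkl %*% cell$frac            # n x 3, units 1/A
  sqrt(rowSums(q^2))
}

as_hkl_matrix <- function(hkl) {
  if (is.vector(hkl)) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3) stop("hkl must have three columns")
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  storage.mode(hkl) <- "double"
  hkl
}

#' Space-group symmetry operators
#'
#' Returns the rotation/translation operators of a small set of common
#' space groups, or validates a user-supplied list. Operators act on
#' fractional coordinates as \code{x' = R x + t}.
#'
#' @param name One of \code{"P1"}, \code{"P-1"}, \code{"P2"}, \code{"P21"},
#'   \code{"P212121"}, or a list of operators (each a list with 3x3 integer
#'   matrix \code{R} and length-3 translation \code{t}).
#' @return Object of class \code{"spacegroup_ops"}: list of operators plus a
#'   \code{centrosymmetric} flag.
#' @export
spacegroup_ops <- function(name = "P1") {
  op <- function(R, t = c(0, 0, 0)) list(R = matrix(R, 3, 3, byrow = TRUE), t = t)
  I3 <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  ops <- if (is.list(name)) {
    lapply(name, function(o) {
      stopifnot(is.matrix(o$R), all(dim(o$R) == c(3, 3)), length(o$t) == 3)
      o
    })
  } else switch(toupper(name),
    "P1" = list(op(I3)),
    "P-1" = list(op(I3), op(-I3)),
    "P2" = list(op(I3), op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1))),
    "P21" = list(op(I3), op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0.5, 0))),
    "P212121" = list(
      op(I3),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0.5, 0, 0.5)),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0.5, 0.5)),
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(0.5, 0.5, 0))
    ),
    stop("unknown space group: ", name)
  )
  centro <- any(vapply(ops, function(o) all(o$R == -diag(3)), logical(1)))
  structure(list(ops = ops, centrosymmetric = centro,
                 name = if (is.character(name)) toupper(name) else "custom"),
            class = "spacegroup_ops")
}

#' Reflection metadata: resolution, centricity and epsilon factors
#'
#' Builds the symmetry-derived skeleton of a reflection set: reciprocal
#' resolution s = 1/d from the cell metric, the centric flag (some operator
#' maps hkl to -hkl) and the multiplicity factor epsilon (number of
#' operators whose rotation part leaves hkl fixed).
#'
#' @param cell A \code{unit_cell}.
#' @param ops A \code{spacegroup_ops}.
#' @param hkl Integer matrix (n x 3) of Miller indices; (0,0,0) is rejected.
#' @return A data frame of class \code{"reflection_set"} with columns
#'   \code{h, k, l, s, d, epsilon, centric}.
#' @examples
#' cl <- unit_cell(20, 30, 40)
#' rs <- reflection_metadata(cl, spacegroup_ops("P21"), rbind(c(1, 2, 3), c(0, 2, 0)))
#' rs$epsilon
#' @export
reflection_metadata <- function(cell, ops, hkl) {
  hkl <- as_hkl_matrix(hkl)
  if (nrow(hkl) == 0) stop("hkl is empty")
  if (any(rowSums(abs(hkl)) == 0)) stop("the (0,0,0) index is not a reflection")
  s <- reciprocal_s(cell, hkl)
  n <- nrow(hkl)
  centric <- logical(n)
  eps <- integer(n)
  # reciprocal-space action of an operator with rotation R is h' = h R
  rots <- lapply(ops$ops, `[[`, "R")
  for (i in seq_len(n)) {
    h <- hkl[i, ]
    imgs <- vapply(rots, function(R) as.numeric(h %*% R), numeric(3))
    centric[i] <- any(apply(imgs, 2, function(hh) all(hh == -h)))
    eps[i] <- sum(apply(imgs, 2, function(hh) all(hh == h)))
  }
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    s = s, d = 1 / s, epsilon = eps, centric = centric)
  class(out) <- c("reflection_set", "data.frame")
  out
}

#' Assign equal-count resolution bins
#'
#' Adds a \code{bin_id} column (1 = lowest resolution) by splitting
#' reflections into bins of approximately equal population, ordered by s.
#' Tail bins with fewer than \code{min_per_bin} reflections are merged into
#' their neighbour.
#'
#' @param refl A \code{reflection_set}.
#' @param n_bins Target number of bins (default 20).
#' @param min_per_bin Minimum reflections per bin (default 50).
#' @return The reflection set with a \code{bin_id} column.
#' @export
assign_bins <- function(refl, n_bins = 20, min_per_bin = 50) {
  n <- nrow(refl)
  n_bins <- max(1L, min(n_bins, n %/% min_per_bin))
  if (n_bins < 1L) n_bins <- 1L
  ord <- order(refl$s)
  bin <- integer(n)
  bin[ord] <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  refl$bin_id <- bin
  refl
}

#' Assign cross-validation (free-set) flags
#'
#' Marks a random fraction of reflections as the free (test) set, seeded.
#'
#' @param refl A \code{reflection_set}.
#' @param fraction Free-set fraction (default 0.05).
#' @param seed Integer RNG seed.
#' @return The reflection set with a logical \code{free_flag} column.
#' @export
assign_free_set <- function(refl, fraction = 0.05, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nrow(refl)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  k <- round(fraction * n)
  flag <- logical(n)
  if (k > 0) flag[sample.int(n, k)] <- TRUE
  refl$free_flag <- flag
  refl
}

# seed handling used by every stochastic entry point: set a local RNG state
# and restore the caller's afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
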