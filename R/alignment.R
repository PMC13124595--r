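#' Weighted Kabsch superposition
#'
#' Finds the proper rototranslation C minimizing
#' sum_i w_i || x_ref_i - C x_pred_i ||^2 over corresponding points
#' (typically Calpha atoms): translation from weighted centroids, rotation
#' from the SVD of the weighted covariance with reflection correction.
#'
#' @param x_pred n x 3 matrix of moving coordinates.
#' @param x_ref n x 3 matrix of reference coordinates.
#' @param weights Non-negative weights, not all zero (default: unit).
#' @return List of class \code{"rototranslation"}: \code{R} (3 x 3 proper
#'   orthogonal), \code{t} (length 3), and \code{x_aligned} = the
#'   transformed moving coordinates.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- weighted_kabsch(x, x)
#' max(abs(fit$R - diag(3)))
#' @export
weighted_kabsch <- function(x_pred, x_ref, weights = NULL) {
  x_pred <- as.matrix(x_pred); x_ref <- as.matrix(x_ref)
  stopifnot(ncol(x_pred) == 3, ncol(x_ref) == 3, nrow(x_pred) == nrow(x_ref))
  n <- nrow(x_pred)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative and not all zero")
  nz <- weights > 0
  if (sum(nz) < 3) stop("need at least 3 weighted points")
  w <- weights / sum(weights)
  cp <- colSums(x_pred * w)      # weighted centroids
  cr <- colSums(x_ref * w)
  P <- sweep(x_pred, 2, cp)
  Q <- sweep(x_ref, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  if (qr(P)$rank < 2) stop("weighted points are collinear")
  t <- cr - as.numeric(R %*% cp)
  x_aligned <- t(R %*% t(x_pred)) + matrix(t, n, 3, byrow = TRUE)
  structure(list(R = R, t = t, x_aligned = x_aligned), class = "rototranslation")
}

#' Apply a rototranslation
#'
#' @param pose A \code{"rototranslation"} (fields R, t).
#' @param x n x 3 coordinate matrix.
#' @return Transformed coordinates.
#' @export
apply_pose <- function(pose, x) {
  x <- as.matrix(x)
  t(pose$R %*% t(x)) + matrix(pose$t, nrow(x), 3, byrow = TRUE)
}

compose_pose <- function(outer, inner) {
  # outer(inner(x)) = R_o (R_i x + t_i) + t_o
  structure(list(R = outer$R %*% inner$R,
                 t = as.numeric(outer$R %*% inner$t) + outer$t),
            class = "rototranslation")
}

identity_pose <- function() {
  structure(list(R = diag(3), t = c(0, 0, 0)), class = "rototranslation")
}

axis_angle_matrix <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) return(diag(3))
  k <- omega / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid-body refinement against a likelihood target
#'
#' Gradient ascent of a log-likelihood-gain target over a 6-parameter pose
#' (axis-angle rotation about the weighted centroid plus translation),
#' starting from the given coordinates (typically the Kabsch-aligned
#' model). The target function must return the scalar LLG with a
#' \code{"grad_xyz"} attribute (n x 3 gradient with respect to the
#' coordinates).
#'
#' @param x n x 3 starting coordinates (Angstrom).
#' @param llg_fn Function(x, gradient = TRUE) -> scalar LLG, with attribute
#'   "grad_xyz" when \code{gradient} is TRUE (proposal evaluations ask for
#'   the value only).
#' @param n_steps Gradient steps (default 50).
#' @param step_t Initial translation step (A, default 0.1).
#' @param step_r Initial rotation step (degrees, default 0.5).
#' @param decay Per-accepted-step multiplicative decay (default 0.9).
#' @return List of class \code{"rbr_fit"}: \code{pose} (the incremental
#'   rototranslation applied), \code{x} (refined coordinates), \code{llg0},
#'   \code{llg} (start/final target values), \code{n_accepted}.
#' @export
rigid_body_refine <- function(x, llg_fn, n_steps = 50, step_t = 0.1,
                              step_r = 0.5, decay = 0.9) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  f0 <- llg_fn(x, gradient = TRUE)
  if (!is.finite(f0)) stop("non-finite LLG at the starting pose")
  llg0 <- as.numeric(f0)
  omega <- c(0, 0, 0); trans <- c(0, 0, 0)
  st <- step_t; sr <- step_r * pi / 180
  cur <- f0
  acc <- 0L
  for (i in seq_len(n_steps)) {
    g <- attr(cur, "grad_xyz")
    gt <- colSums(g)                                   # d LLG / d translation
    xc <- sweep(pose_coords(x, omega, trans, ctr), 2, ctr + trans)
    gr <- colSums(cross3(xc, g))                       # d LLG / d rotation (about centre)
    nt <- sqrt(sum(gt^2)); nr <- sqrt(sum(gr^2))
    prop_t <- trans + if (nt > 0) st * gt / nt else 0
    prop_o <- omega + if (nr > 0) sr * gr / nr else 0
    xp <- pose_coords(x, prop_o, prop_t, ctr)
    fp <- llg_fn(xp, gradient = FALSE)
    if (is.finite(fp) && as.numeric(fp) > as.numeric(cur)) {
      trans <- prop_t; omega <- prop_o
      cur <- llg_fn(xp, gradient = TRUE)
      acc <- acc + 1L
      st <- st * decay; sr <- sr * decay
    } else {
      st <- st * 0.5; sr <- sr * 0.5
      if (st < 1e-6 && sr < 1e-8) break
    }
  }
  R <- axis_angle_matrix(omega)
  pose <- structure(list(R = R, t = ctr + trans - as.numeric(R %*% ctr)),
                    class = "rototranslation")
  list(pose = pose, x = pose_coords(x, omega, trans, ctr),
       llg0 = llg0, llg = as.numeric(cur), n_accepted = acc)
}

pose_coords <- function(x, omega, trans, ctr) {
  R <- axis_angle_matrix(omega)
  t(R %*% t(sweep(x, 2, ctr))) + matrix(ctr + trans, nrow(x), 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
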