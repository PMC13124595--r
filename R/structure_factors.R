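# 4-Gaussian scattering-factor coefficients (International Tables vol. C),
# f(s) = sum_i a_i exp(-b_i (s/2)^2) + c with s = 1/d. Hydrogens are ignored
# by the model builders; unknown elements fall back to carbon with a warning.
.ff_coefs <- list(
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.86500),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' Atomic scattering factor
#'
#' Evaluates the 4-Gaussian-plus-constant X-ray scattering factor for an
#' element at reciprocal resolution s = 1/d.
#'
#' @param element Element symbol ("C", "N", "O", "S"; others fall back to
#'   carbon with a warning).
#' @param s Numeric vector of 1/d values (1/Angstrom).
#' @return Numeric vector of f(s) in electrons.
#' @export
form_factor <- function(element, s) {
  el <- toupper(element)
  cf <- .ff_coefs[[el]]
  if (is.null(cf)) {
    warning("no scattering coefficients for element '", element, "'; using carbon")
    cf <- .ff_coefs$C
  }
  s2 <- (s / 2)^2
  out <- rep(cf$c, length(s))
  for (i in 1:4) out <- out + cf$a[i] * exp(-cf$b[i] * s2)
  out
}

#' Construct an atomic model
#'
#' A light container for an (optionally multi-conformation) atomic model:
#' a data frame with one row per atom.
#'
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param element Character vector of element symbols.
#' @param occ Occupancies in (0, 1] (default 1).
#' @param b Isotropic B factors in A^2, >= 0 (default 10).
#' @param resno Integer residue numbers (default: one residue per atom).
#' @param atom_name Atom names (default element symbols).
#' @param chain Chain identifier (default "A").
#' @return Data frame of class \code{"atomic_model"} with columns
#'   \code{x, y, z, element, occ, b, resno, atom_name, chain}.
#' @export
atomic_model <- function(xyz, element, occ = 1, b = 10,
                         resno = NULL, atom_name = NULL, chain = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  n <- nrow(xyz)
  if (any(!is.finite(xyz))) stop("non-finite coordinate in model")
  occ <- rep_len(occ, n); b <- rep_len(b, n)
  if (any(occ <= 0 | occ > 1)) stop("occupancies must lie in (0, 1]")
  if (any(b < 0)) stop("B factors must be non-negative")
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(atom_name)) atom_name <- rep_len(element, n)
  out <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    element = rep_len(element, n), occ = occ, b = b,
                    resno = rep_len(resno, n),
                    atom_name = rep_len(atom_name, n),
                    chain = rep_len(chain, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("atomic_model", "data.frame")
  out
}

model_xyz <- function(model) cbind(model$x, model$y, model$z)

# Precomputed reflection-side constants for repeated structure-factor
# evaluations against a fixed reflection set (used by the engine targets):
# q vectors, s^2/4 and the B-independent form-factor matrix.
sf_engine <- function(cell, refl, elements) {
  hkl <- cbind(refl$h, refl$k, refl$l)
  q <- hkl %*% cell$frac
  s2q <- refl$s^2 / 4
  els <- toupper(elements)
  f_by_el <- lapply(unique(els), function(e) form_factor(e, refl$s))
  names(f_by_el) <- unique(els)
  fel <- matrix(0, nrow(refl), length(els))
  for (e in unique(els)) fel[, els == e] <- f_by_el[[e]]
  list(q = q, s2q = s2q, fel = fel, n_atoms = length(els), s = refl$s)
}

sf_engine_calc <- function(eng, model, keep_terms = TRUE) {
  X <- model_xyz(model)
  kern <- .sf_kernel_forward(eng$q, X, eng$fel, model$occ, model$b, eng$s2q,
                             keep_terms)
  out <- list(F = kern$F, s = eng$s)
  if (keep_terms) {
    out$terms <- kern$terms
    out$q <- eng$q
    out$s2q <- eng$s2q
    out$n_atoms <- eng$n_atoms
  }
  class(out) <- "sf_calc"
  out
}

#' Direct-summation structure factors
#'
#' Computes complex structure factors F_c(h) = sum_atoms occ f(s)
#' exp(-B s^2/4) exp(2 pi i h . x_frac) by direct summation, retaining the
#' per-atom terms so that gradients with respect to Cartesian coordinates
#' and B factors can be pulled back with \code{sf_backward}.
#'
#' @param model An \code{atomic_model}.
#' @param cell A \code{unit_cell}.
#' @param refl A \code{reflection_set} (needs h, k, l, s).
#' @param keep_terms Keep the reflection x atom term matrix for gradient
#'   pull-back (default TRUE).
#' @return List of class \code{"sf_calc"}: \code{F} (complex), \code{s},
#'   and, when kept, the internals needed by \code{sf_backward}.
#' @export
sf_calc <- function(model, cell, refl, keep_terms = TRUE) {
  X <- model_xyz(model)
  if (any(!is.finite(X))) stop("NaN/Inf coordinate in model")
  unknown <- setdiff(toupper(unique(model$element)), names(.ff_coefs))
  if (length(unknown))
    warning("elements without coefficients, using carbon: ", paste(unknown, collapse = ", "))
  hkl <- cbind(refl$h, refl$k, refl$l)
  q <- hkl %*% cell$frac                       # n_refl x 3, h . x_frac = q . x_cart
  s <- refl$s
  n <- nrow(hkl); m <- nrow(X)
  s2q <- s^2 / 4
  els <- toupper(model$element)
  # the unknown-element warning was already raised above
  f_by_el <- lapply(unique(els), function(e) suppressWarnings(form_factor(e, s)))
  names(f_by_el) <- unique(els)
  fel <- matrix(0, n, m)
  for (e in unique(els)) fel[, els == e] <- f_by_el[[e]]
  kern <- .sf_kernel_forward(q, X, fel, model$occ, model$b, s2q, keep_terms)
  out <- list(F = kern$F, s = s)
  if (keep_terms) {
    out$terms <- kern$terms
    out$q <- q
    out$s2q <- s2q
    out$n_atoms <- m
  }
  class(out) <- "sf_calc"
  out
}

#' Pull back a gradient through the structure-factor calculation
#'
#' Given the adjoint of a real scalar loss with respect to the complex
#' structure factors (encoded as \code{gF = dL/dRe(F) + i dL/dIm(F)}),
#' returns the gradient with respect to Cartesian coordinates and isotropic
#' B factors.
#'
#' @param ctx The \code{sf_calc} result (with \code{keep_terms = TRUE}).
#' @param gF Complex adjoint vector, one per reflection.
#' @return List with \code{dX} (atoms x 3) and \code{dB} (atoms).
#' @export
sf_backward <- function(ctx, gF) {
  if (is.null(ctx$terms)) stop("sf_calc was run with keep_terms = FALSE")
  .sf_kernel_backward(ctx$terms, ctx$q, ctx$s2q, as.complex(gF))
}

#' Amplitude and phase adjoints to a complex adjoint
#'
#' Converts gradients with respect to |F| and phi into the complex adjoint
#' convention used by \code{sf_backward}. d|F|/dF pulls back as
#' e^{i phi} g_amp and dphi/dF as i e^{i phi} g_phi / |F|.
#'
#' @param F Complex structure factors.
#' @param g_amp Gradient with respect to |F| (0 if NULL).
#' @param g_phi Gradient with respect to the phase in radians (0 if NULL).
#' @return Complex adjoint vector.
#' @export
amp_phase_adjoint <- function(F, g_amp = NULL, g_phi = NULL) {
  amp <- Mod(F)
  u <- ifelse(amp > 0, F / amp, 1 + 0i)
  g <- 0 + 0i
  if (!is.null(g_amp)) g <- g + g_amp * u
  if (!is.null(g_phi)) g <- g + ifelse(amp > 0, g_phi / amp, 0) * 1i * u
  g
}

#' Normalize amplitudes to E values
#'
#' Binned Wilson normalization: E = |F| / sqrt(epsilon * <|F|^2/epsilon>_bin),
#' restoring a per-bin mean of one for E^2/epsilon-weighted amplitudes.
#'
#' @param amplitudes Non-negative amplitudes |F|.
#' @param refl Reflection set with \code{epsilon} and \code{bin_id}.
#' @return List: \code{E} (normalized amplitudes), \code{scale_bin}
#'   (per-bin mean of |F|^2/epsilon, indexed by bin id).
#' @export
normalize_to_E <- function(amplitudes, refl) {
  if (is.null(refl$bin_id)) stop("reflection set has no bins; call assign_bins() first")
  eps <- refl$epsilon
  bins <- sort(unique(refl$bin_id))
  i2 <- amplitudes^2 / eps
  sc <- tapply(i2, refl$bin_id, mean)
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    bad <- bins[!is.finite(sc) | sc <= 0][1]
    stop("degenerate resolution bin ", bad, " in normalization")
  }
  E <- amplitudes / sqrt(eps * sc[as.character(refl$bin_id)])
  list(E = as.numeric(E), scale_bin = sc)
}

# Pull a gradient wrt E back to a gradient wrt |F|, including the dependence
# of the per-bin normalization constant on every member amplitude:
#   E_i = A_i / sqrt(eps_i S_b),  S_b = mean_j(A_j^2/eps_j)
norm_E_backward <- function(gE, amplitudes, refl, scale_bin) {
  eps <- refl$epsilon
  S <- as.numeric(scale_bin[as.character(refl$bin_id)])
  gA <- gE / sqrt(eps * S)
  # chain through S_b: dE_i/dS = -A_i eps_i^{-1/2} S^{-3/2} / 2
  cS <- tapply(gE * (-0.5) * amplitudes / sqrt(eps) * S^(-1.5), refl$bin_id, sum)
  nb <- tapply(rep(1, nrow(refl)), refl$bin_id, sum)
  cS_i <- as.numeric(cS[as.character(refl$bin_id)] / nb[as.character(refl$bin_id)])
  gA + cS_i * 2 * amplitudes / eps
}
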