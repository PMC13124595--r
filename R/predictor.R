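#' Deterministic toy structure predictor
#'
#' A desk-scale stand-in for a neural structure predictor exposing the same
#' contract: it maps an MSA cluster profile to coordinates and per-residue
#' pLDDT, differentiably. The decoder pools the profile over clusters
#' (mean), maps the pooled per-residue feature delta linearly to phi/psi
#' torsion offsets from a baseline conformation, and builds an
#' ideal-geometry backbone. pLDDT is a fixed smooth (logistic) function of
#' the pooled column entropy. By construction, the additive bias returned
#' in \code{target_bias} reproduces the supplied target conformation
#' exactly.
#'
#' @param m0 Baseline cluster profile, array clusters x residues x symbols.
#' @param torsions_base List with \code{phi}, \code{psi} (radians) for the
#'   baseline conformation.
#' @param torsions_target Optional target conformation torsions; when
#'   given, \code{target_bias} holds (w*, b*) with w* = 1 reproducing it.
#' @param gain Scale of the linear decoder coefficients (default 0.25).
#' @param flexible Residue indices whose torsions respond to the profile
#'   (default: all). Restricting flexibility to a window emulates a
#'   predictor whose prior holds the confidently-modelled scaffold rigid
#'   while a loop region remains ambiguous.
#' @param seed Seed for the fixed random decoder coefficients (default 99).
#' @return Object of class \code{"toy_predictor"} with elements
#'   \code{predict(m)} -> list(model, plddt, internals) and
#'   \code{backward(pred, g_xyz, g_plddt)} -> gradient with respect to the
#'   profile, plus \code{m0}, \code{target_bias}.
#' @export
toy_predictor <- function(m0, torsions_base, torsions_target = NULL,
                          gain = 0.25, flexible = NULL, seed = 99L) {
  dm <- dim(m0)
  K <- dm[1]; L <- dm[2]; A <- dm[3]
  stopifnot(length(torsions_base$phi) == L)
  old <- local_seed(seed)
  J <- array(stats::rnorm(2 * A * L, 0, gain / sqrt(A)), c(2, A, L))
  restore_seed(old)
  if (!is.null(flexible)) {
    rigid <- setdiff(seq_len(L), flexible)
    J[, , rigid] <- 0
  }
  f0 <- apply(m0, c(2, 3), mean)          # L x A pooled baseline features
  # pLDDT = 100 * logistic((h0 - H)/hs) of the pooled column entropy H
  h0 <- 3.6; hs <- 0.25
  ent_eps <- 1e-6

  pool <- function(m) apply(m, c(2, 3), mean)

  entropy_plddt <- function(f) {
    fe <- pmax(f, ent_eps)
    S <- rowSums(fe)
    p <- fe / S
    H <- -rowSums(p * log(p))
    plddt <- 100 * stats::plogis((h0 - H) / hs)
    list(plddt = plddt, H = H, p = p, S = S, clamped = f < ent_eps)
  }

  predict_fn <- function(m) {
    stopifnot(identical(dim(m), dm))
    f <- pool(m)
    delta <- f - f0
    dphi <- vapply(seq_len(L), function(l) sum(J[1, , l] * delta[l, ]), numeric(1))
    dpsi <- vapply(seq_len(L), function(l) sum(J[2, , l] * delta[l, ]), numeric(1))
    phi <- torsions_base$phi + dphi
    psi <- torsions_base$psi + dpsi
    model <- build_backbone(phi, psi)
    ep <- entropy_plddt(f)
    model$b <- rep(plddt_to_pseudob(ep$plddt), each = 3)
    list(model = model, plddt = ep$plddt, phi = phi, psi = psi,
         f = f, ent = ep)
  }

  backward_fn <- function(pred, g_xyz, g_plddt = NULL) {
    # torsion path
    tg <- backbone_torsion_grad(model_xyz(pred$model), g_xyz)
    gf <- matrix(0, L, A)
    for (l in seq_len(L)) {
      gf[l, ] <- J[1, , l] * tg$dphi[l] + J[2, , l] * tg$dpsi[l]
    }
    # entropy -> pLDDT path
    if (!is.null(g_plddt)) {
      ep <- pred$ent
      pl <- ep$plddt
      dplddt_dH <- -100 * (pl / 100) * (1 - pl / 100) / hs
      # dH/df_a = -(log p_a + H) / S, zero where the clamp is active
      dH_df <- -(log(ep$p) + ep$H) / ep$S
      dH_df[ep$clamped] <- 0
      gf <- gf + (g_plddt * dplddt_dH) * dH_df
    }
    # pooling: every cluster contributes 1/K
    g_m <- array(0, dm)
    for (k in seq_len(K)) g_m[k, , ] <- gf / K
    g_m
  }

  target_bias <- NULL
  if (!is.null(torsions_target)) {
    b_star <- array(0, dm)
    for (l in seq_len(L)) {
      Jl <- rbind(J[1, , l], J[2, , l])          # 2 x A
      dtheta <- c(torsions_target$phi[l] - torsions_base$phi[l],
                  torsions_target$psi[l] - torsions_base$psi[l])
      if (all(Jl == 0)) {
        if (any(abs(dtheta) > 1e-12))
          stop("target torsion change at rigid residue ", l,
               " is unreachable by the decoder")
        next
      }
      delta <- t(Jl) %*% solve(Jl %*% t(Jl), dtheta)   # minimum-norm solution
      for (k in seq_len(K)) b_star[k, l, ] <- delta
    }
    target_bias <- list(w = array(1, dm), b = b_star)
  }

  structure(list(predict = predict_fn, backward = backward_fn,
                 m0 = m0, J = J, f0 = f0, dim = dm,
                 torsions_base = torsions_base,
                 target_bias = target_bias),
            class = "toy_predictor")
}

#' @export
print.toy_predictor <- function(x, ...) {
  d <- x$dim
  cat(sprintf("Toy structure predictor: profile %d clusters x %d residues x %d symbols\n",
              d[1], d[2], d[3]))
  if (!is.null(x$target_bias)) cat("  carries an exact target-reproducing bias (w*, b*)\n")
  invisible(x)
}
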