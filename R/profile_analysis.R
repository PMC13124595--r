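#' Mutual-information matrix of an MSA cluster profile
#'
#' Treats the clusters as equally weighted soft samples: each cluster's
#' column is renormalized to a distribution over symbols, the joint
#' distribution of a residue pair is the cluster average of the outer
#' product of their columns, and MI (nats) is computed per pair against
#' the product of marginals. The diagonal is zero by convention.
#'
#' @param m Profile array (clusters x residues x symbols), values >= 0.
#' @param normalize Min-max normalize the matrix to [0, 1] (default FALSE).
#' @return Symmetric residue x residue matrix of class \code{"mi_matrix"}
#'   with attribute \code{"normalized"}.
#' @export
profile_mi <- function(m, normalize = FALSE) {
  dm <- dim(m)
  K <- dm[1]; L <- dm[2]; A <- dm[3]
  if (K < 2) stop("need at least 2 clusters")
  if (any(m < 0)) stop("profile values must be non-negative")
  # renormalize columns per cluster
  p <- m
  for (k in seq_len(K)) {
    cs <- rowSums(p[k, , , drop = TRUE])
    if (any(cs <= 0)) stop("all-zero profile column at residue ",
                           which(cs <= 0)[1])
    p[k, , ] <- p[k, , ] / cs
  }
  mi <- matrix(0, L, L)
  marg <- apply(p, c(2, 3), mean)   # L x A cluster-averaged marginals
  for (i in seq_len(L - 1)) {
    Pi <- p[, i, ]                  # K x A
    for (j in (i + 1):L) {
      Pj <- p[, j, ]
      joint <- crossprod(Pi, Pj) / K          # A x A: mean_k outer(Pi_k, Pj_k)
      pij <- marg[i, ] %o% marg[j, ]
      nz <- joint > 0 & pij > 0
      mi[i, j] <- mi[j, i] <- sum(joint[nz] * log(joint[nz] / pij[nz]))
    }
  }
  if (normalize) {
    rng <- range(mi[upper.tri(mi)])
    if (diff(rng) > 0) {
      mi[upper.tri(mi) | lower.tri(mi)] <-
        (mi[upper.tri(mi) | lower.tri(mi)] - rng[1]) / diff(rng)
    }
  }
  structure(mi, class = c("mi_matrix", "matrix"), normalized = normalize)
}

#' Rank residue pairs by change in mutual information
#'
#' Sorts pairs by |MI_final - MI_init| (descending; ties broken by (i, j)
#' lexicographic order) and tabulates, for the top pairs, how often each
#' residue appears (its "degree").
#'
#' @param mi_init,mi_final MI matrices of identical shape.
#' @param top_n Number of top pairs to analyse (default: all pairs).
#' @return List: \code{pairs} (data frame i, j, delta_mi, rank),
#'   \code{top_residues} (unique residues in the top_n pairs, by first
#'   appearance), \code{degree} (named count per residue over top_n pairs).
#' @export
delta_mi_ranking <- function(mi_init, mi_final, top_n = NULL) {
  if (!identical(dim(mi_init), dim(mi_final))) stop("matrix shapes differ")
  L <- nrow(mi_init)
  ut <- which(upper.tri(mi_init), arr.ind = TRUE)
  d <- abs(mi_final - mi_init)[upper.tri(mi_init)]
  ord <- order(-d, ut[, 1], ut[, 2])
  pairs <- data.frame(i = ut[ord, 1], j = ut[ord, 2], delta_mi = d[ord])
  pairs$rank <- seq_len(nrow(pairs))
  if (is.null(top_n)) top_n <- nrow(pairs)
  top_n <- min(top_n, nrow(pairs))
  top <- pairs[seq_len(top_n), ]
  res_seq <- c(rbind(top$i, top$j))
  deg <- table(factor(res_seq, levels = seq_len(L)))
  list(pairs = pairs, top_residues = unique(res_seq),
       degree = deg[deg > 0])
}

#' Mute optimized profile signal at selected residues
#'
#' Restores, for the selected residues, every profile entry (all clusters
#' and symbols) to its value in the initial profile, leaving other
#' residues untouched. Idempotent; duplicate indices are collapsed with a
#' warning.
#'
#' @param m_final Optimized profile.
#' @param m_init Initial profile (same shape).
#' @param residues Residue indices to mute.
#' @return The muted profile array.
#' @export
mute_profile <- function(m_final, m_init, residues) {
  if (!identical(dim(m_final), dim(m_init))) stop("profile shapes differ")
  if (anyDuplicated(residues)) {
    warning("duplicate residue indices collapsed")
    residues <- unique(residues)
  }
  if (length(residues) && (min(residues) < 1 || max(residues) > dim(m_final)[2]))
    stop("residue index out of range")
  out <- m_final
  out[, residues, ] <- m_init[, residues, ]
  out
}

#' Baseline muting strategies
#'
#' Selects k residues by a simple statistic and mutes them: uniform random
#' (seeded), change in per-residue column entropy, or mean absolute MI
#' change.
#'
#' @param m_final,m_init Profiles (same shape).
#' @param k Number of residues to mute.
#' @param mode One of "random", "entropy", "mean_abs_mi".
#' @param seed Seed for random mode.
#' @return List: \code{profile} (muted), \code{residues} (selected).
#' @export
muting_baselines <- function(m_final, m_init, k,
                             mode = c("random", "entropy", "mean_abs_mi"),
                             seed = 1L) {
  mode <- match.arg(mode)
  L <- dim(m_final)[2]
  if (k > L) stop("k exceeds the number of residues")
  sel <- switch(mode,
    random = {
      old <- local_seed(seed)
      on.exit(restore_seed(old))
      sample.int(L, k)
    },
    entropy = {
      ent <- function(m) {
        f <- apply(m, c(2, 3), mean)
        f <- pmax(f, 1e-12)
        f <- f / rowSums(f)
        -rowSums(f * log(f))
      }
      order(-abs(ent(m_final) - ent(m_init)))[seq_len(k)]
    },
    mean_abs_mi = {
      dmi <- abs(profile_mi(m_final) - profile_mi(m_init))
      order(-rowMeans(dmi))[seq_len(k)]
    })
  list(profile = mute_profile(m_final, m_init, sel), residues = sel)
}
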