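#' @export
print.llg_refit <- function(x, ...) {
  cat("Likelihood-guided profile refinement\n")
  cat(sprintf("  best LLG: %.3f  (stop: %s, trace %d selected for phase 2)\n",
              x$best$llg, x$stop_reason, x$selected_trace))
  n1 <- sum(x$trace$phase == 1); n2 <- sum(x$trace$phase == 2)
  cat(sprintf("  iterations: %d phase 1 (%d traces), %d phase 2\n",
              n1, x$config$n_traces, n2))
  invisible(x)
}

#' @export
summary.llg_refit <- function(object, ...) {
  tr <- object$trace
  first <- tr$llg[1]
  out <- list(llg_start = first, llg_best = object$best$llg,
              llg_gain = object$best$llg - first,
              stop_reason = object$stop_reason,
              n_iterations = nrow(tr),
              selected_trace = object$selected_trace,
              bias_norms = c(w = sqrt(mean((object$w - 1)^2)),
                             b = sqrt(mean(object$b^2))),
              mean_plddt = mean(object$best$plddt))
  class(out) <- "summary.llg_refit"
  out
}

#' @export
print.summary.llg_refit <- function(x, ...) {
  cat("Likelihood-guided profile refinement\n")
  cat(sprintf("  LLG: %.3f -> %.3f (gain %.3f) over %d iterations [%s]\n",
              x$llg_start, x$llg_best, x$llg_gain, x$n_iterations,
              x$stop_reason))
  cat(sprintf("  bias RMS: |w - 1| = %.4g, |b| = %.4g;  mean pLDDT %.1f\n",
              x$bias_norms["w"], x$bias_norms["b"], x$mean_plddt))
  invisible(x)
}

#' Learned profile bias of a refinement fit
#'
#' @param object An \code{llg_refit}.
#' @param ... Ignored.
#' @return List with the multiplicative (\code{w}) and additive (\code{b})
#'   bias arrays at the best-LLG state.
#' @export
coef.llg_refit <- function(object, ...) {
  list(w = object$best$w, b = object$best$b)
}

#' @export
logLik.llg_refit <- function(object, ...) {
  structure(object$best$llg, df = 2 * length(object$best$w),
            class = "logLik")
}

#' Best refined model of a fit
#'
#' @param object An \code{llg_refit}.
#' @param ... Ignored.
#' @return The \code{atomic_model} with the best LLG.
#' @export
fitted.llg_refit <- function(object, ...) object$best$model

#' Plot the LLG trace of a refinement
#'
#' @param x An \code{llg_refit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.llg_refit <- function(x, ...) {
  tr <- x$trace
  idx <- seq_len(nrow(tr))
  graphics::plot(idx, tr$llg, type = "n", xlab = "iteration",
                 ylab = "LLG", ...)
  for (t in unique(tr$trace[tr$phase == 1])) {
    sel <- tr$phase == 1 & tr$trace == t
    graphics::lines(idx[sel], tr$llg[sel], col = "grey50")
  }
  sel <- tr$phase == 2
  graphics::lines(idx[sel], tr$llg[sel], col = "purple", lwd = 2)
  graphics::abline(v = max(idx[tr$phase == 1]) + 0.5, lty = 3)
  invisible(x)
}
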