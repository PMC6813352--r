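#' @export
print.dipfit <- function(x, ...) {
  k <- length(x$model$r)
  cat(sprintf("Gaussian distance-distribution fit (%d component%s, %s)\n",
              k, if (k > 1L) "s" else "", x$opts$optimizer))
  print(x$model)
  cat(sprintf("chi2 = %.4g (%d parameters, %d points)%s\n", x$chi2,
              x$n_params, length(x$residuals),
              if (isTRUE(x$converged)) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
coef.dipfit <- function(object, ...) object$coefficients

#' @export
fitted.dipfit <- function(object, ...) object$fitted.values

#' @export
residuals.dipfit <- function(object, ...) object$residuals

#' @export
deviance.dipfit <- function(object, ...) object$chi2

#' Covariance matrix of the fitted parameters
#'
#' Local Jacobian-based covariance of the scaled-residual least squares at
#' the optimum.
#' @param object a `dipfit`.
#' @param ... unused.
#' @export
vcov.dipfit <- function(object, ...) {
  opts <- object$opts
  k <- opts$n_gaussians
  pred <- .pair_predictor(object$single, opts$r_step)
  pick <- function(par, what) par[seq.int(what, 3L * k, by = 3L)]
  par <- unname(object$coefficients[seq_len(3L * k)])
  rf <- function(p) (object$data$intensity -
                       pred(pick(p, 1L), pick(p, 2L), pick(p, 3L))) /
    object$sigma
  r0 <- rf(par)
  J <- matrix(0, length(r0), length(par))
  hstep <- pmax(1e-5, 1e-5 * abs(par))
  for (j in seq_along(par)) {
    pp <- par; pp[j] <- pp[j] + hstep[j]
    J[, j] <- (rf(pp) - r0) / hstep[j]
  }
  v <- tryCatch(solve(crossprod(J)), error = function(e) {
    warning("singular Jacobian; covariance unavailable")
    matrix(NA_real_, length(par), length(par))
  })
  dimnames(v) <- list(.par_names(k), .par_names(k))
  v
}

#' Predict a dipolar-broadened spectrum from a fitted model
#'
#' @param object a `dipfit`.
#' @param single optional single-label `field_spectrum` to which the
#'   fitted distance model is applied; defaults to the reference used in
#'   the fit (returning the fitted spectrum).
#' @param ... unused.
#' @return A `field_spectrum`.
#' @export
predict.dipfit <- function(object, single = NULL, ...) {
  if (is.null(single)) {
    out <- object$data
    out$intensity <- object$fitted.values
    out$label <- "fitted"
    return(out)
  }
  forward_model(single, object$model, r_step = object$opts$r_step)
}

#' Simulate replicate data sets from a fitted model
#'
#' Residual-bootstrap replicates: the fitted spectrum plus residuals
#' resampled with replacement, as used for uncertainty estimation.
#'
#' @param object a `dipfit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `field_spectrum` objects.
#' @export
simulate.dipfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nsim), function(b) {
      out <- object$data
      out$intensity <- object$fitted.values +
        sample(object$residuals, length(object$residuals), replace = TRUE)
      out$label <- sprintf("simulated replicate %d", b)
      out
    })
  })
}

#' Summarize a distance-distribution fit
#'
#' @param object a `dipfit`.
#' @param uncertainty include residual-bootstrap parameter uncertainties
#'   (slower; calls [estimate_uncertainty()]).
#' @param n_boot,seed passed to [estimate_uncertainty()].
#' @param ... unused.
#' @export
summary.dipfit <- function(object, uncertainty = FALSE, n_boot = 100L,
                           seed = 1L, ...) {
  un <- object$uncertainty
  if (uncertainty && is.null(un))
    un <- estimate_uncertainty(object, n_boot = n_boot, seed = seed)
  structure(list(fit = object, uncertainty = un,
                 rms_residual = sqrt(mean(object$residuals^2)),
                 pp_data = peak_to_peak(object$data)),
            class = "summary.dipfit")
}

#' @export
print.summary.dipfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("RMS residual %.3g (data peak-to-peak %.3g); noise sigma %.3g\n",
              x$rms_residual, x$pp_data, x$fit$sigma))
  if (!is.null(x$uncertainty)) {
    cat("parameter uncertainties (residual bootstrap / covariance):\n")
    print(x$uncertainty, row.names = FALSE, digits = 3)
    if (isTRUE(attr(x$uncertainty, "unreliable")))
      cat("  [flagged unreliable: >20% of bootstrap refits failed]\n")
  }
  invisible(x)
}

#' Diagnostic plot of a distance fit
#'
#' Three panels: data with the fitted spectrum overlaid, residuals, and
#' the fitted distance distribution P(r).
#'
#' @param x a `dipfit`.
#' @param ... passed to the spectrum panel.
#' @export
plot.dipfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$data$field, x$data$intensity, type = "l",
                 xlab = "Field (G)", ylab = "dA/dB", main = "data + fit", ...)
  graphics::lines(x$data$field, x$fitted.values, col = 2, lty = 2)
  graphics::plot(x$data$field, x$residuals, type = "l", xlab = "Field (G)",
                 ylab = "residual", main = "residuals")
  graphics::abline(h = 0, col = "grey")
  r <- seq(0.4, 3, by = 0.005)
  graphics::plot(r, distance_distribution(x$model, r), type = "l",
                 xlab = "r (nm)", ylab = "P(r)",
                 main = sprintf("distance distribution (f_non = %.0f%%)",
                                100 * x$model$f_non))
  invisible(x)
}
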