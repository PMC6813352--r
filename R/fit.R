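## Fast forward-model predictor for a fixed single-label spectrum.
## The dipolar-broadened spectrum is linear in the distance-distribution
## weights, so the convolutions y (*) K(r_j) are precomputed once for every
## grid distance r_j and each objective evaluation reduces to a
## matrix-vector product.  Numerically identical to forward_model().
.pair_predictor <- function(single, r_step = 0.02) {
  h <- field_step(single)
  y <- single$intensity
  r_grid <- default_r_grid(r_step)
  half <- dipolar_constant() / min(r_grid)^3 + 6 * h
  offs <- kernel_offsets(h, half)
  K <- .pake_matrix(offs, r_grid)
  n <- length(y); m <- nrow(K)
  ic <- (m + 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2L)
  fy <- stats::fft(c(y, numeric(nfft - n)))
  C <- matrix(0, n, ncol(K))
  for (j in seq_len(ncol(K))) {
    fk <- stats::fft(c(K[, j], numeric(nfft - m)))
    full <- Re(stats::fft(fy * fk, inverse = TRUE)) / nfft
    C[, j] <- full[ic:(ic + n - 1L)] * h
  }
  function(r, dr, f) {
    f_non <- 1 - sum(f)
    out <- f_non * y
    for (i in seq_along(r)) {
      if (f[i] == 0) next
      sigma <- fwhm_to_sigma(dr[i])
      sel <- r_grid >= max(min(r_grid), r[i] - 3 * sigma) - 1e-12 &
             r_grid <= min(max(r_grid), r[i] + 3 * sigma) + 1e-12
      if (sum(sel) < 2L) sel <- which.min(abs(r_grid - r[i]))
      w <- stats::dnorm(r_grid[sel], r[i], sigma)
      w <- w / sum(w)
      out <- out + f[i] * drop(C[, sel, drop = FALSE] %*% w)
    }
    out
  }
}

## noise scale from the outer edge windows of the data
.edge_sigma <- function(y, fraction = 0.05) {
  n <- length(y)
  k <- max(4L, floor(fraction * n))
  s <- stats::sd(c(y[seq_len(k)], y[seq.int(n - k + 1L, n)]))
  max(s, 1e-10 * max(abs(y), .Machine$double.eps))
}

.par_names <- function(k) {
  if (k == 1L) c("r", "dr", "f")
  else as.vector(t(outer(1:2, c("r", "dr", "f"),
                         function(i, nm) paste0(nm, i))))
}

#' Fitting options for the distance fitter
#'
#' @param n_gaussians 1 or 2 Gaussian distance components.
#' @param optimizer `"levenberg-marquardt"` (bounded multistart LM) or
#'   `"monte-carlo-simplex"` (random search alternated with Nelder-Mead
#'   refinement in a bounded transform).
#' @param n_starts number of Latin-hypercube LM starts (>= 1).
#' @param n_proposals random-proposal budget for the MC/simplex optimizer.
#' @param seed integer seed controlling starts/proposals.
#' @param r_bounds,dr_bounds,f_bounds per-parameter box bounds; defaults
#'   are the conventional fit ranges r 0.8-2.8 nm, FWHM 0.04-2 nm, f 0-1.
#' @param noise_sigma noise standard deviation for the chi-squared scale;
#'   `NULL` (default) estimates it from the outer 5% edge windows.
#' @param r_step distance-grid resolution, nm.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_gaussians = 2L,
                        optimizer = c("levenberg-marquardt",
                                      "monte-carlo-simplex"),
                        n_starts = 8L, n_proposals = 2000L, seed = 1L,
                        r_bounds = c(0.8, 2.8), dr_bounds = c(0.04, 2),
                        f_bounds = c(0, 1), noise_sigma = NULL,
                        r_step = 0.02) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_gaussians %in% 1:2, n_starts >= 1L)
  structure(list(n_gaussians = as.integer(n_gaussians), optimizer = optimizer,
                 n_starts = as.integer(n_starts),
                 n_proposals = as.integer(n_proposals),
                 seed = as.integer(seed), r_bounds = r_bounds,
                 dr_bounds = dr_bounds, f_bounds = f_bounds,
                 noise_sigma = noise_sigma, r_step = r_step),
            class = "fit_options")
}

#' Fit Gaussian interspin distance distributions to a dipolar-broadened spectrum
#'
#' The inverse problem of dipolar CW-EPR distance analysis: given a
#' double-label spectrum and its single-label (no spin-spin interaction)
#' reference, find the 1- or 2-Gaussian distance model whose forward
#' convolution best reproduces the data.  Minimizes
#' `chi^2 = sum((data - forward)^2) / sigma^2`
#' over the bounded parameters `(r_i, dr_i, f_i)` with the non-interacting
#' fraction `f_non = 1 - sum(f_i)` constrained to [0, 1].  The default
#' optimizer runs bounded Levenberg-Marquardt from seeded Latin-hypercube
#' multistarts and returns the global best; a Monte-Carlo/simplex
#' alternative is available.  Components are reported sorted by ascending
#' r (ties by larger f).
#'
#' @param double_spectrum dipolar-broadened `field_spectrum`.
#' @param single_spectrum single-label reference on the same field axis.
#' @param opts a [fit_options()] list; individual `...` arguments override
#'   its fields (e.g. `fit_distance(d, s, n_gaussians = 1)`).
#' @param normalize spin-normalize `double_spectrum` to the reference
#'   before fitting.  Default FALSE: the fitter expects pre-normalized
#'   inputs (see [normalize_to_spins()]).  Set TRUE for raw instrument
#'   data, but note that a broadened spectrum loses some wing intensity
#'   beyond the sweep window, so renormalizing over the window introduces
#'   a small amplitude bias relative to the convolution model.
#' @param ... overrides for [fit_options()] fields.
#' @return An object of class `dipfit`; see [coef.dipfit()],
#'   [summary.dipfit()], [predict.dipfit()], [plot.dipfit()].
#' @examples
#' ax <- seq(3330, 3530, length.out = 512)
#' single <- simulate_powder(nitroxide_system(), ax, orientations = 800)
#' truth <- distance_model(r = 1.2, dr = 0.5, f = 0.6)
#' pair <- forward_model(single, truth)
#' fit <- fit_distance(pair, single, n_gaussians = 1, n_starts = 4)
#' coef(fit)
#' @export
fit_distance <- function(double_spectrum, single_spectrum,
                         opts = fit_options(...), normalize = FALSE, ...) {
  stopifnot(inherits(double_spectrum, "field_spectrum"),
            inherits(single_spectrum, "field_spectrum"))
  if (!isTRUE(all.equal(double_spectrum$field, single_spectrum$field,
                        tolerance = 1e-9)))
    stop("double and single spectra are on different field axes; ",
         "resample() to a common axis first")
  if (normalize)
    double_spectrum <- normalize_to_spins(double_spectrum, single_spectrum)
  data <- double_spectrum$intensity
  sigma <- if (is.null(opts$noise_sigma)) .edge_sigma(data) else opts$noise_sigma
  pred <- .pair_predictor(single_spectrum, opts$r_step)
  k <- opts$n_gaussians
  lower <- rep(c(opts$r_bounds[1L], opts$dr_bounds[1L], opts$f_bounds[1L]), k)
  upper <- rep(c(opts$r_bounds[2L], opts$dr_bounds[2L], opts$f_bounds[2L]), k)
  pick <- function(par, what) par[seq.int(what, 3L * k, by = 3L)]
  pen_scale <- 1e3 * sqrt(sum((data / sigma)^2))
  resid_fn <- function(par) {
    f <- pick(par, 3L)
    r <- (data - pred(pick(par, 1L), pick(par, 2L), f)) / sigma
    c(r, pen_scale * max(0, sum(f) - 1))
  }
  obj_fn <- function(par) sum(resid_fn(par)^2)
  best <- withr::with_seed(opts$seed, {
    if (opts$optimizer == "levenberg-marquardt")
      .fit_lm_multistart(resid_fn, lower, upper, opts$n_starts)
    else
      .fit_mc_simplex(obj_fn, lower, upper, opts$n_proposals)
  })
  par <- pmin(pmax(best$par, lower), upper)
  f <- pick(par, 3L)
  if (sum(f) > 1) f <- f / sum(f)          # penalty leaves at most tiny excess
  model <- distance_model(r = pick(par, 1L), dr = pick(par, 2L), f = f,
                          f_non = max(0, 1 - sum(f)))
  par_sorted <- as.vector(rbind(model$r, model$dr, model$f))
  names(par_sorted) <- .par_names(k)
  fitted <- pred(model$r, model$dr, model$f)
  res <- data - fitted
  chi2 <- sum((res / sigma)^2)
  structure(list(
    model = model,
    coefficients = c(par_sorted, f_non = model$f_non),
    chi2 = chi2, sigma = sigma,
    fitted.values = fitted, residuals = res,
    data = double_spectrum, single = single_spectrum,
    n_params = 3L * k, converged = best$converged,
    n_starts_used = best$n_starts_used,
    opts = opts,
    uncertainty = NULL,
    call = match.call()
  ), class = "dipfit")
}

## Seeded Latin-hypercube multistart: oversample candidate parameter
## vectors, rank them by the objective (one cheap evaluation each), and run
## bounded LM from the best `n_starts`.  Ranking costs little and makes the
## start set concentrate on the promising basins of the multimodal
## 6-parameter landscape.
.fit_lm_multistart <- function(resid_fn, lower, upper, n_starts,
                               oversample = 25L) {
  npar <- length(lower)
  cand <- lhs::randomLHS(oversample * n_starts, npar)
  cand <- sweep(sweep(cand, 2L, upper - lower, "*"), 2L, lower, "+")
  vals <- apply(cand, 1L, function(p) sum(resid_fn(p)^2))
  starts <- cand[order(vals)[seq_len(n_starts)], , drop = FALSE]
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    if (conv) n_ok <- n_ok + 1L
    val <- sum(fit$fvec^2)
    if (is.null(best) || val < best$value)
      best <- list(par = fit$par, value = val, converged = conv,
                   n_starts_used = n_starts)
  }
  if (is.null(best))
    stop("all Levenberg-Marquardt starts failed")
  best$converged <- n_ok > 0L && best$converged
  best$n_starts_used <- n_starts
  best
}

## random proposals alternated with Nelder-Mead refinement in a logistic
## bound transform (keeps the simplex strictly inside the box)
.fit_mc_simplex <- function(obj_fn, lower, upper, n_proposals) {
  npar <- length(lower)
  to_u <- function(p) stats::qlogis(pmin(pmax((p - lower) / (upper - lower),
                                              1e-6), 1 - 1e-6))
  to_p <- function(u) lower + (upper - lower) * stats::plogis(u)
  n_rand <- max(50L, as.integer(0.6 * n_proposals))
  props <- matrix(stats::runif(n_rand * npar), n_rand, npar)
  props <- sweep(sweep(props, 2L, upper - lower, "*"), 2L, lower, "+")
  vals <- apply(props, 1L, obj_fn)
  ord <- order(vals)
  best_par <- props[ord[1L], ]
  best_val <- vals[ord[1L]]
  budget <- n_proposals - n_rand
  for (s in seq_len(3L)) {
    start <- if (s == 1L) best_par else props[ord[min(s, nrow(props))], ]
    o <- stats::optim(to_u(start), function(u) obj_fn(to_p(u)),
                      method = "Nelder-Mead",
                      control = list(maxit = max(100L, budget %/% 3L),
                                     reltol = 1e-12))
    if (o$value < best_val) {
      best_val <- o$value
      best_par <- to_p(o$par)
    }
  }
  list(par = best_par, value = best_val, converged = TRUE,
       n_starts_used = 3L)
}

#' Chi-squared ratio comparison of nested distance fits
#'
#' Compares the 1- and 2-Gaussian fits of one data set by their
#' chi-squared ratio; the 2-Gaussian model is flagged preferred when
#' `chi2(1G)/chi2(2G)` exceeds `threshold`.
#'
#' @param fit1,fit2 `dipfit` objects on identical data (any order; they
#'   are identified by parameter count).
#' @param threshold preference threshold for the ratio (default 1.2).
#' @return An object of class `dipfit_comparison` with elements `ratio`,
#'   `chi2_simple`, `chi2_complex`, `preferred`, `threshold`.
#' @export
compare_models <- function(fit1, fit2, threshold = 1.2) {
  stopifnot(inherits(fit1, "dipfit"), inherits(fit2, "dipfit"))
  if (!isTRUE(all.equal(fit1$data$field, fit2$data$field)) ||
      !isTRUE(all.equal(fit1$data$intensity, fit2$data$intensity)))
    stop("fits are not on identical data")
  if (fit1$n_params > fit2$n_params) { tmp <- fit1; fit1 <- fit2; fit2 <- tmp }
  ratio <- fit1$chi2 / fit2$chi2
  preferred <- if (fit1$n_params == fit2$n_params) "neither"
               else if (ratio > threshold) "complex" else "simple"
  structure(list(ratio = ratio, chi2_simple = fit1$chi2,
                 chi2_complex = fit2$chi2, n_params = c(fit1$n_params,
                                                        fit2$n_params),
                 preferred = preferred, threshold = threshold),
            class = "dipfit_comparison")
}

#' @export
print.dipfit_comparison <- function(x, ...) {
  cat(sprintf("chi2 ratio (simple/complex): %.3g  [chi2 = %.4g vs %.4g]\n",
              x$ratio, x$chi2_simple, x$chi2_complex))
  cat("preferred model:",
      switch(x$preferred, complex = "more complex (ratio above threshold",
             simple = "simpler (ratio below threshold",
             "neither (same complexity; threshold"),
      sprintf("%.3g)\n", x$threshold))
  invisible(x)
}

#' Parameter uncertainties by residual bootstrap
#'
#' Resamples the fit residuals with replacement onto the fitted curve and
#' refits from the best-fit point (`n_boot` seeded replicates); the
#' reported uncertainty of each parameter is the larger of the bootstrap
#' standard deviation and the local covariance (Jacobian-based) estimate.
#'
#' @param fit a converged `dipfit`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return A data.frame with columns `parameter`, `estimate`, `sd_boot`,
#'   `sd_cov`, `pm` (reported +/-), plus attribute `unreliable` set when
#'   more than 20% of refits fail to converge.  The result is also stored
#'   on the returned fit via `attr(fit, ...)`-free functional style: call
#'   as `fit$uncertainty <- estimate_uncertainty(fit)` or use
#'   [summary.dipfit()] which does so on the fly when asked.
#' @export
estimate_uncertainty <- function(fit, n_boot = 100L, seed = 1L) {
  stopifnot(inherits(fit, "dipfit"))
  if (!isTRUE(fit$converged))
    stop("uncertainty estimation requires a converged fit")
  opts <- fit$opts
  k <- opts$n_gaussians
  pred <- .pair_predictor(fit$single, opts$r_step)
  lower <- rep(c(opts$r_bounds[1L], opts$dr_bounds[1L], opts$f_bounds[1L]), k)
  upper <- rep(c(opts$r_bounds[2L], opts$dr_bounds[2L], opts$f_bounds[2L]), k)
  pick <- function(par, what) par[seq.int(what, 3L * k, by = 3L)]
  sigma <- fit$sigma
  base_par <- unname(fit$coefficients[seq_len(3L * k)])
  make_resid <- function(y) {
    force(y)
    function(par) (y - pred(pick(par, 1L), pick(par, 2L),
                            pick(par, 3L))) / sigma
  }
  ## local covariance from a finite-difference Jacobian of scaled residuals
  r0 <- make_resid(fit$data$intensity)(base_par)
  J <- matrix(0, length(r0), length(base_par))
  hstep <- pmax(1e-5, 1e-5 * abs(base_par))
  for (j in seq_along(base_par)) {
    pp <- base_par; pp[j] <- pp[j] + hstep[j]
    J[, j] <- (make_resid(fit$data$intensity)(pp) - r0) / hstep[j]
  }
  sd_cov <- tryCatch(sqrt(diag(solve(crossprod(J)))),
                     error = function(e) rep(NA_real_, length(base_par)))
  boot <- withr::with_seed(as.integer(seed), {
    n <- length(fit$residuals)
    out <- matrix(NA_real_, n_boot, length(base_par))
    fails <- 0L
    for (b in seq_len(n_boot)) {
      y_star <- fit$fitted.values + sample(fit$residuals, n, replace = TRUE)
      bf <- tryCatch(
        minpack.lm::nls.lm(par = base_par, fn = make_resid(y_star),
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(bf) || !bf$info %in% 1:4) { fails <- fails + 1L; next }
      p <- bf$par
      o <- order(pick(p, 1L), -pick(p, 3L))  # keep component labels aligned
      out[b, ] <- as.vector(rbind(pick(p, 1L)[o], pick(p, 2L)[o],
                                  pick(p, 3L)[o]))
    }
    list(mat = out, fails = fails)
  })
  sd_boot <- apply(boot$mat, 2L, stats::sd, na.rm = TRUE)
  pm <- pmax(sd_boot, sd_cov, na.rm = TRUE)
  res <- data.frame(parameter = .par_names(k), estimate = base_par,
                    sd_boot = sd_boot, sd_cov = sd_cov, pm = pm)
  attr(res, "unreliable") <- boot$fails > 0.2 * n_boot
  attr(res, "n_failed") <- boot$fails
  res
}

#' Table-style report of distance fits
#'
#' One row per fit in the layout of the standard distance-distribution
#' tables: label, number of Gaussians, chi2, then `r +/- u`, `dr +/- u` and
#' `f%` per component, with components fitted beyond 2.5 nm pooled into the
#' `>2.5` column together with the non-interacting fraction (distances
#' above 2.5 nm are below CW dipolar detectability).
#'
#' @param fits list of `dipfit` objects.
#' @param labels character labels, one per fit.
#' @param uncertainties optional list of [estimate_uncertainty()] results
#'   (or `NULL` entries), parallel to `fits`.
#' @param file optional path; when given the table is also written as CSV.
#' @param pool_threshold distance (nm) above which components are pooled
#'   with the non-interacting fraction.
#' @return A data.frame of class `dipfit_table`.
#' @export
report_table <- function(fits, labels = NULL, uncertainties = NULL,
                         file = NULL, pool_threshold = 2.5) {
  if (is.null(labels))
    labels <- if (length(fits)) paste0("fit", seq_along(fits)) else character(0)
  stopifnot(length(labels) == length(fits))
  fmt_pm <- function(v, u) {
    if (is.null(u) || !is.finite(u)) sprintf("%.2f", v)
    else sprintf("%.2f ± %.2f", v, u)
  }
  rows <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    ft <- fits[[i]]
    if (!inherits(ft, "dipfit")) stop("element ", i, " is not a dipfit")
    un <- if (!is.null(uncertainties)) uncertainties[[i]] else NULL
    m <- ft$model
    pooled <- m$f_non
    r_txt <- dr_txt <- f_txt <- character(0)
    for (j in seq_along(m$r)) {
      if (m$r[j] > pool_threshold) {
        pooled <- pooled + m$f[j]
        next
      }
      u_r <- u_dr <- NULL
      if (!is.null(un)) {
        nm <- if (length(m$r) == 1L) c("r", "dr") else paste0(c("r", "dr"), j)
        u_r <- un$pm[match(nm[1L], un$parameter)]
        u_dr <- un$pm[match(nm[2L], un$parameter)]
      }
      r_txt <- c(r_txt, fmt_pm(m$r[j], u_r))
      dr_txt <- c(dr_txt, fmt_pm(m$dr[j], u_dr))
      f_txt <- c(f_txt, sprintf("%.0f", 100 * m$f[j]))
    }
    pad <- function(x) c(x, rep("", 2L - length(x)))[1:2]
    r_txt <- pad(r_txt); dr_txt <- pad(dr_txt); f_txt <- pad(f_txt)
    rows[[i]] <- data.frame(
      label = labels[i], n_gaussians = length(ft$model$r),
      chi2 = signif(ft$chi2, 3),
      r1_nm = r_txt[1L], dr1_nm = dr_txt[1L], f1_pct = f_txt[1L],
      r2_nm = r_txt[2L], dr2_nm = dr_txt[2L], f2_pct = f_txt[2L],
      gt2.5_pct = sprintf("%.0f", 100 * pooled),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), n_gaussians = integer(0),
               chi2 = numeric(0), r1_nm = character(0), dr1_nm = character(0),
               f1_pct = character(0), r2_nm = character(0),
               dr2_nm = character(0), f2_pct = character(0),
               gt2.5_pct = character(0), stringsAsFactors = FALSE)
  class(out) <- c("dipfit_table", "data.frame")
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @export
print.dipfit_table <- function(x, ...) {
  cat("Distance-distribution fits (r, dr in nm; f in %; >2.5 pools",
      "non-interacting spins)\n")
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}
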