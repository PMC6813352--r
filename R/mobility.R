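#' Effective outer hyperfine splitting 2T_eff
#'
#' Locates the outermost low-field maximum and the outermost high-field
#' minimum of a first-derivative nitroxide spectrum; half their field
#' separation is the effective splitting T_eff (approaching the rigid-limit
#' value A_zz' as motion freezes).  Extrema are refined to sub-grid
#' precision by a local 5-point parabola.
#'
#' @param s a `field_spectrum`.
#' @param prominence minimum extremum height as a fraction of the
#'   peak-to-peak amplitude; features below it are ignored.
#' @return T_eff in Gauss, with attributes `B_low` and `B_high` (the two
#'   extremum fields).
#' @examples
#' ax <- seq(3330, 3530, length.out = 2048)
#' s <- simulate_powder(nitroxide_system(), ax)
#' measure_teff(s)  # ~35 G
#' @export
measure_teff <- function(s, prominence = 0.02) {
  y <- s$intensity
  n <- length(y)
  pp <- max(y) - min(y)
  if (pp <= 0) stop("flat spectrum; no extrema")
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  locmin <- which(diff(sign(diff(y))) > 0) + 1L
  locmax <- locmax[y[locmax] > prominence * pp]
  locmin <- locmin[y[locmin] < -prominence * pp]
  if (length(locmax) == 0L || length(locmin) == 0L)
    stop("outer extrema not resolvable (motionally averaged spectrum?); ",
         "T_eff is undefined in the fast-motion regime")
  i_lo <- min(locmax)           # outermost low-field maximum
  i_hi <- max(locmin)           # outermost high-field minimum
  if (s$field[i_hi] <= s$field[i_lo])
    stop("outer extrema not resolvable: high-field minimum not above ",
         "low-field maximum")
  b_lo <- .refine_extremum(s$field, y, i_lo)
  b_hi <- .refine_extremum(s$field, y, i_hi)
  teff <- (b_hi - b_lo) / 2
  attr(teff, "B_low") <- b_lo
  attr(teff, "B_high") <- b_hi
  teff
}

## parabolic sub-grid refinement of an extremum over +/-2 points
.refine_extremum <- function(x, y, i) {
  n <- length(x)
  j <- max(3L, min(n - 2L, i))
  idx <- (j - 2L):(j + 2L)
  fit <- stats::lm.fit(cbind(1, x[idx] - x[j], (x[idx] - x[j])^2), y[idx])
  b <- fit$coefficients
  if (abs(b[3L]) < .Machine$double.eps) return(x[i])
  vertex <- x[j] - b[2L] / (2 * b[3L])
  if (vertex < x[j - 2L] || vertex > x[j + 2L]) x[i] else vertex
}

#' Goldman effective rotational correlation time
#'
#' Empirical calibration mapping the effective outer splitting of a
#' nitroxide spectrum to a rotational correlation time,
#' `tau_eff = a * (1 - T_eff/T_max)^b`
#' with a = 5.4e-10 s, b = -1.36 and T_max = 35 G (the rigid-limit
#' splitting).  Valid for 0 <= T_eff < T_max; at T_eff = T_max the motion is
#' at the rigid limit (infinite tau), beyond it the formula is undefined.
#'
#' @param T_eff effective splitting in Gauss (vectorized).
#' @param a,b,T_max calibration constants.
#' @return Correlation time(s) in seconds; `Inf` at the rigid limit,
#'   `NaN` (with a warning) above it.
#' @examples
#' tau_eff(0)    # 5.4e-10 s
#' tau_eff(28)   # ~4.8e-9 s
#' @export
tau_eff <- function(T_eff, a = 5.4e-10, b = -1.36, T_max = 35) {
  T_eff <- as.numeric(T_eff)
  if (any(T_eff < 0)) stop("T_eff must be non-negative")
  out <- ifelse(T_eff < T_max, a * (1 - T_eff / T_max)^b,
                ifelse(T_eff == T_max, Inf, NaN))
  if (any(is.nan(out)))
    warning("T_eff above the rigid limit T_max = ", T_max,
            " G; tau_eff undefined")
  out
}

#' Slow/fast peak-height ratio
#'
#' For a two-component (immobilized + mobile) spectrum, the ratio of the
#' maximum absolute intensity in the low-field slow-component window to
#' that in the fast-component window — an indicator of steric hindrance
#' around the labeled side chain.
#'
#' @param s a `field_spectrum`.
#' @param slow_window,fast_window numeric length-2 field ranges (G); must
#'   be disjoint, inside the axis, with the slow window at lower field.
#' @return Unitless ratio.
#' @export
slow_fast_ratio <- function(s, slow_window, fast_window) {
  chk <- function(w, nm) {
    if (length(w) != 2L || w[1L] >= w[2L]) stop(nm, " must be an increasing length-2 range")
    if (w[1L] < s$field[1L] || w[2L] > s$field[length(s$field)])
      stop(nm, " outside the field axis")
    sel <- s$field >= w[1L] & s$field <= w[2L]
    if (!any(sel)) stop(nm, " contains no grid points")
    sel
  }
  ss <- chk(slow_window, "slow_window")
  fs <- chk(fast_window, "fast_window")
  if (slow_window[2L] > fast_window[1L])
    stop("slow window must lie entirely at lower field than the fast window")
  max(abs(s$intensity[ss])) / max(abs(s$intensity[fs]))
}

## the three sharpest extrema of the reference (by |second derivative|),
## widened to +/- half_width G: the fast-component feature windows
.fast_feature_windows <- function(reference, half_width = 3) {
  y <- reference$intensity
  x <- reference$field
  ext <- sort(c(which(diff(sign(diff(y))) < 0), which(diff(sign(diff(y))) > 0)) + 1L)
  if (length(ext) == 0L) stop("reference has no extrema")
  h <- x[2L] - x[1L]
  d2 <- abs(c(0, diff(y, differences = 2), 0)) / h^2
  ext <- ext[order(-d2[ext])]
  ext <- utils::head(ext, 3L)
  lapply(ext, function(i) c(x[i] - half_width, x[i] + half_width))
}

#' Two-component spectral subtraction
#'
#' Decomposes a composite spectrum into a fast (mobile) component with the
#' lineshape of `reference` plus an immobile remainder: finds the fraction
#' `x` of the reference whose removal best nulls the sharp fast-component
#' features in the difference `composite - x * reference`.  The criterion is
#' the locally detrended residual power inside the fast-feature windows
#' (the three sharpest extrema of the reference, +/- `window_half_width` G);
#' a local quadratic detrend makes the score blind to the broad, smoothly
#' curved immobile background under the sharp lines while the narrow
#' derivative features of the mobile component survive it.  `x` is scanned
#' on a grid with
#' parabolic refinement, subject to the difference's double integral staying
#' above -1% of the composite's.
#'
#' Both spectra should be spin-normalized ([normalize_to_spins()]) so that
#' `x` reads directly as the mobile population fraction and `1 - x` as the
#' immobile fraction.
#'
#' @param composite two-component `field_spectrum`.
#' @param reference mobile (fast-component) `field_spectrum`, same axis.
#' @param step grid step for the fraction scan.
#' @param window_half_width half width (G) of each fast-feature window.
#' @param windows optional list of length-2 field ranges overriding the
#'   auto-detected windows.
#' @return An object of class `subtraction`: list with `fraction` (x, the
#'   removed reference fraction), `difference` (`composite - x*reference`),
#'   `criterion_value`, `multiplier` (display scale making the difference's
#'   peak-to-peak match the composite's), and `windows`.
#' @examples
#' ax <- seq(3380, 3480, length.out = 1024)
#' mob <- simulate_mobile(nitroxide_system(), S = 0.3, axis = ax)
#' rig <- simulate_powder(nitroxide_system(), ax)
#' mix <- mix_spectra(list(mob, rig), c(0.55, 0.45))
#' subtract_component(mix, mob)$fraction  # ~0.55
#' @export
subtract_component <- function(composite, reference, step = 0.005,
                               window_half_width = 3, windows = NULL) {
  if (!isTRUE(all.equal(composite$field, reference$field, tolerance = 1e-9)))
    stop("composite and reference are on different field axes")
  if (is.null(windows))
    windows <- .fast_feature_windows(reference, window_half_width)
  x_ax <- composite$field
  sel <- lapply(windows, function(w) which(x_ax >= w[1L] & x_ax <= w[2L]))
  if (!length(sel) || any(!lengths(sel))) stop("empty fast-feature windows")
  di_comp <- double_integral(composite)$value
  score <- function(x) {
    d <- composite$intensity - x * reference$intensity
    s <- 0
    for (ii in sel) {
      xi <- x_ax[ii] - mean(x_ax[ii])
      fit <- stats::lm.fit(cbind(1, xi, xi^2), d[ii])
      s <- s + sum(fit$residuals^2)
    }
    s
  }
  feasible <- function(x) {
    d <- composite
    d$intensity <- composite$intensity - x * reference$intensity
    double_integral(d)$value >= -0.01 * abs(di_comp)
  }
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, score, numeric(1))
  ok <- vapply(grid, feasible, logical(1))
  vals[!ok] <- Inf
  i <- which.min(vals)
  x_best <- grid[i]
  if (i > 1L && i < length(grid) && is.finite(vals[i - 1L]) &&
      is.finite(vals[i + 1L])) {
    denom <- vals[i - 1L] - 2 * vals[i] + vals[i + 1L]
    if (denom > 0)
      x_best <- grid[i] + step * (vals[i - 1L] - vals[i + 1L]) / (2 * denom)
  } else {
    warning("subtraction criterion optimal at the boundary x = ", grid[i],
            "; no interior optimum")
  }
  diff_s <- composite
  diff_s$intensity <- composite$intensity - x_best * reference$intensity
  diff_s$label <- "difference"
  mult <- peak_to_peak(composite) / max(peak_to_peak(diff_s),
                                        .Machine$double.eps)
  structure(list(fraction = x_best, difference = diff_s,
                 criterion_value = score(x_best), multiplier = mult,
                 windows = windows),
            class = "subtraction")
}

#' @export
print.subtraction <- function(x, ...) {
  cat(sprintf("two-component subtraction: removed %.1f%% of reference\n",
              100 * x$fraction))
  cat(sprintf("  immobile remainder: %.1f%%; display multiplier %.2g\n",
              100 * (1 - x$fraction), x$multiplier))
  invisible(x)
}
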