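#' Construct a field-swept EPR spectrum
#'
#' A `field_spectrum` holds a uniformly sampled first-derivative absorption
#' spectrum with its field axis (Gauss) and acquisition metadata.  All
#' package operations accept and return this class.
#'
#' @param field numeric vector of magnetic-field values in Gauss; strictly
#'   increasing and uniformly spaced, length >= 64.
#' @param intensity numeric vector of first-derivative absorption values
#'   (arbitrary units), same length as `field`; must be finite.
#' @param mw_frequency microwave frequency in GHz.
#' @param temperature sample temperature in Kelvin.
#' @param label free-text label.
#' @return An object of class `field_spectrum` with elements `field`,
#'   `intensity`, `center_field`, `sweep_width`, `mw_frequency`,
#'   `temperature`, `label`.
#' @examples
#' ax <- seq(3330, 3530, length.out = 1024)
#' s <- field_spectrum(ax, -deriv_gaussian(ax, 3430, 10))
#' s
#' @export
field_spectrum <- function(field, intensity, mw_frequency = 9.6,
                           temperature = 170, label = "") {
  field <- as.numeric(field)
  intensity <- as.numeric(intensity)
  if (length(field) < 64L)
    stop("field axis must have at least 64 points, got ", length(field))
  if (length(intensity) != length(field))
    stop("field and intensity lengths differ (", length(field), " vs ",
         length(intensity), ")")
  d <- diff(field)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop("field axis not strictly increasing at row ", bad + 1L,
         " (field = ", field[bad + 1L], " G)")
  }
  h <- d[1L]
  if (any(abs(d - h) > 1e-9 * abs(h))) {
    bad <- which(abs(d - h) > 1e-9 * abs(h))[1L]
    stop("field axis not uniformly spaced at row ", bad + 1L,
         " (step ", signif(d[bad], 8), " G, expected ", signif(h, 8), " G)")
  }
  if (!all(is.finite(intensity)))
    stop("intensity contains non-finite values")
  structure(list(
    field = field,
    intensity = intensity,
    center_field = (field[1L] + field[length(field)]) / 2,
    sweep_width = field[length(field)] - field[1L],
    mw_frequency = mw_frequency,
    temperature = temperature,
    label = label
  ), class = "field_spectrum")
}

#' @export
print.field_spectrum <- function(x, ...) {
  cat("CW-EPR spectrum", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  %d points, %.6g-%.6g G (sweep %.6g G, step %.4g G)\n",
              length(x$field), x$field[1L], x$field[length(x$field)],
              x$sweep_width, field_step(x)))
  cat(sprintf("  mw %.4g GHz, %.4g K, peak-to-peak %.4g a.u.\n",
              x$mw_frequency, x$temperature, peak_to_peak(x)))
  invisible(x)
}

#' @export
as.data.frame.field_spectrum <- function(x, ...) {
  data.frame(field_G = x$field, intensity = x$intensity)
}

#' @export
plot.field_spectrum <- function(x, ..., xlab = "Field (G)",
                                ylab = "dA/dB (a.u.)", type = "l") {
  graphics::plot(x$field, x$intensity, type = type, xlab = xlab, ylab = ylab,
                 main = x$label, ...)
  invisible(x)
}

## grid step of the field axis
field_step <- function(s) (s$field[length(s$field)] - s$field[1L]) /
  (length(s$field) - 1L)

#' Peak-to-peak amplitude of a spectrum
#' @param s a `field_spectrum`.
#' @return `max(intensity) - min(intensity)`.
#' @export
peak_to_peak <- function(s) max(s$intensity) - min(s$intensity)

## derivative of a unit-area Gaussian absorption line; handy for fixtures
#' First derivative of a unit-area Gaussian line
#'
#' Utility lineshape: d/dB of a Gaussian absorption of unit area centred at
#' `center` with standard deviation `sigma` (all in Gauss).
#' @param field field values (G).
#' @param center line centre (G).
#' @param sigma standard deviation (G).
#' @export
deriv_gaussian <- function(field, center, sigma) {
  z <- (field - center) / sigma
  -z / sigma * stats::dnorm(z) / sigma
}

#' Read a spectrum from a two-column ASCII file
#'
#' The native dialect is whitespace-separated `field_G intensity` rows with
#' optional `#`-prefixed `key: value` header lines (keys `mw_frequency_GHz`,
#' `temperature_K`, `label`; `center_field_G` and `sweep_width_G` are
#' recomputed from the axis).  A JCAMP-DX-like dialect (`##KEY=value`
#' headers, same numeric body) is also accepted.
#'
#' @param path path to the file.
#' @param dialect `"two-column-ascii"` (default) or `"jcamp-dx-like"`.
#' @return A [field_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, dialect = c("two-column-ascii", "jcamp-dx-like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_hdr <- if (dialect == "two-column-ascii") startsWith(lines, "#")
            else startsWith(lines, "##")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  if (length(body) < 64L)
    stop("fewer than 64 numeric rows in ", path)
  mat <- utils::read.table(text = body, col.names = c("field", "intensity"),
                           colClasses = "numeric")
  meta <- list(mw_frequency = 9.6, temperature = 170, label = "")
  kv <- if (dialect == "two-column-ascii")
    regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  else
    regmatches(hdr, regexec("^##([^=]+)=(.*)$", hdr))
  for (m in kv) {
    if (length(m) != 3L) next
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (key == "mw_frequency_GHz") meta$mw_frequency <- as.numeric(val)
    if (key == "temperature_K") meta$temperature <- as.numeric(val)
    if (key == "label") meta$label <- val
  }
  field_spectrum(mat$field, mat$intensity, mw_frequency = meta$mw_frequency,
                 temperature = meta$temperature, label = meta$label)
}

#' Write a spectrum to the native two-column ASCII dialect
#'
#' Values are printed at full precision (17 significant digits) so that a
#' write/read round trip is bit-identical.
#'
#' @param s a `field_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  hdr <- c(
    sprintf("# center_field_G: %.17g", s$center_field),
    sprintf("# sweep_width_G: %.17g", s$sweep_width),
    sprintf("# mw_frequency_GHz: %.17g", s$mw_frequency),
    sprintf("# temperature_K: %.17g", s$temperature),
    sprintf("# label: %s", s$label)
  )
  body <- sprintf("%.17g %.17g", s$field, s$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Spin quantification by double integration
#'
#' Twice integrates the first-derivative spectrum: a linear baseline fitted
#' to the outer edge windows is removed, one trapezoidal integration gives
#' the absorption spectrum, a linear ramp re-zeroing the absorption at both
#' edges guards against drift, and a second trapezoidal integration gives
#' the double integral, proportional to the number of spins.
#'
#' @param s a `field_spectrum`.
#' @param baseline_window_fraction fraction of points at each edge used for
#'   the baseline fit (and the re-zeroing means); in (0, 0.25].
#' @return An object of class `spin_count`: list with `value` (a.u. G^2),
#'   `baseline_window_fraction`, and `negative_absorption` (TRUE when the
#'   corrected absorption is predominantly negative, flagged rather than
#'   raised).
#' @examples
#' ax <- seq(3330, 3530, length.out = 1024)
#' s <- field_spectrum(ax, deriv_gaussian(ax, 3430, 5))
#' double_integral(s)$value  # ~1
#' @export
double_integral <- function(s, baseline_window_fraction = 0.05) {
  stopifnot(baseline_window_fraction > 0, baseline_window_fraction <= 0.25)
  n <- length(s$field)
  k <- max(2L, floor(baseline_window_fraction * n))
  edge <- c(seq_len(k), seq.int(n - k + 1L, n))
  bl <- stats::lm.fit(cbind(1, s$field[edge]), s$intensity[edge])$coefficients
  y <- s$intensity - (bl[1L] + bl[2L] * s$field)
  absn <- pracma::cumtrapz(s$field, y)[, 1L]
  ## re-zero absorption edges with a linear ramp through the edge means
  a0 <- mean(absn[seq_len(k)])
  a1 <- mean(absn[seq.int(n - k + 1L, n)])
  t <- (s$field - s$field[1L]) / (s$field[n] - s$field[1L])
  absn <- absn - (a0 + (a1 - a0) * t)
  value <- pracma::trapz(s$field, absn)
  structure(list(value = value,
                 baseline_window_fraction = baseline_window_fraction,
                 negative_absorption = value < 0),
            class = "spin_count")
}

#' @export
print.spin_count <- function(x, ...) {
  cat(sprintf("spin count (double integral): %.6g a.u. G^2%s\n", x$value,
              if (x$negative_absorption) "  [negative absorption]" else ""))
  invisible(x)
}

#' Scale a spectrum to the spin count of a reference
#'
#' Multiplies `s` by the scalar making its double integral equal the
#' reference's, so two spectra can be compared at equal numbers of spins.
#'
#' @param s spectrum to rescale.
#' @param reference spectrum defining the target spin count; must share the
#'   field axis of `s` (use [resample()] first otherwise).
#' @param baseline_window_fraction passed to [double_integral()].
#' @return The rescaled `field_spectrum`.
#' @export
normalize_to_spins <- function(s, reference, baseline_window_fraction = 0.05) {
  if (!isTRUE(all.equal(s$field, reference$field, tolerance = 1e-9)))
    stop("spectra are on different field axes; resample() first")
  di_ref <- double_integral(reference, baseline_window_fraction)$value
  di_s <- double_integral(s, baseline_window_fraction)$value
  if (abs(di_ref) < .Machine$double.eps * 64 * max(abs(reference$intensity), 1))
    stop("reference spectrum has zero spin count; cannot normalize")
  if (abs(di_s) == 0) stop("spectrum has zero spin count; cannot normalize")
  out <- s
  out$intensity <- s$intensity * (di_ref / di_s)
  out
}

#' Resample a spectrum onto a new field axis
#'
#' Cubic (spline) interpolation onto `target_axis`, which must lie inside
#' the source field range (no extrapolation).
#'
#' @param s a `field_spectrum`.
#' @param target_axis new field axis (Gauss, uniform, increasing).
#' @return A `field_spectrum` on `target_axis`.
#' @export
resample <- function(s, target_axis) {
  target_axis <- as.numeric(target_axis)
  n <- length(s$field)
  if (min(target_axis) < s$field[1L] - 1e-9 ||
      max(target_axis) > s$field[n] + 1e-9)
    stop("target axis [", min(target_axis), ", ", max(target_axis),
         "] G extends beyond source range [", s$field[1L], ", ", s$field[n],
         "] G; extrapolation not supported")
  y <- stats::spline(s$field, s$intensity, xout = target_axis,
                     method = "fmm")$y
  ## preserve endpoints exactly where the target hits a source grid point
  hit <- match(round(target_axis, 12), round(s$field, 12))
  y[!is.na(hit)] <- s$intensity[hit[!is.na(hit)]]
  field_spectrum(target_axis, y, mw_frequency = s$mw_frequency,
                 temperature = s$temperature, label = s$label)
}
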