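#' Nitroxide spin-system parameters
#'
#' Principal g- and 14N hyperfine values plus intrinsic linewidths for a
#' nitroxide radical.  Defaults fix A_zz at 35 G so that the simulated
#' rigid-limit outer splitting matches the 2 x 35 G rigid-limit constant of
#' the Goldman calibration; the g-values are conventional nitroxide
#' magnitudes and the linewidths (Gaussian 3 G, Lorentzian 1 G FWHM) are
#' fixture conventions, not measured label properties.
#'
#' @param g_principal three principal g-values.
#' @param A_principal three principal 14N hyperfine values, Gauss; the
#'   largest must be A_zz.
#' @param linewidth_gaussian Gaussian FWHM, Gauss.
#' @param linewidth_lorentzian Lorentzian FWHM, Gauss.
#' @param mw_frequency microwave frequency, GHz.
#' @return An object of class `nitroxide_system`.
#' @export
nitroxide_system <- function(g_principal = c(2.0086, 2.0066, 2.0032),
                             A_principal = c(6, 6, 35),
                             linewidth_gaussian = 3,
                             linewidth_lorentzian = 1,
                             mw_frequency = 9.6) {
  stopifnot(length(g_principal) == 3L, length(A_principal) == 3L,
            linewidth_gaussian > 0, linewidth_lorentzian > 0)
  if (max(A_principal) != A_principal[3L])
    stop("A_zz (third element) must be the largest hyperfine principal value")
  structure(list(g_principal = g_principal, A_principal = A_principal,
                 linewidth_gaussian = linewidth_gaussian,
                 linewidth_lorentzian = linewidth_lorentzian,
                 mw_frequency = mw_frequency),
            class = "nitroxide_system")
}

#' @export
print.nitroxide_system <- function(x, ...) {
  cat("nitroxide system:\n")
  cat("  g =", paste(format(x$g_principal), collapse = ", "), "\n")
  cat("  A =", paste(format(x$A_principal), collapse = ", "), "G\n")
  cat(sprintf("  linewidths %g G (Gaussian) / %g G (Lorentzian) FWHM, mw %g GHz\n",
              x$linewidth_gaussian, x$linewidth_lorentzian, x$mw_frequency))
  invisible(x)
}

#' Default field axis for simulated spectra
#' @param center centre field, G.
#' @param sweep sweep width, G.
#' @param n number of points.
#' @export
default_field_axis <- function(center = 3430, sweep = 200, n = 1024L)
  seq(center - sweep / 2, center + sweep / 2, length.out = n)

## angle-dependent effective g and A (standard first-order ellipsoids)
.orient_gA <- function(sys, ct2, st2, cp2, sp2) {
  g2 <- sys$g_principal^2
  a2 <- sys$A_principal^2
  g <- sqrt(g2[1L] * st2 * cp2 + g2[2L] * st2 * sp2 + g2[3L] * ct2)
  a <- sqrt(a2[1L] * st2 * cp2 + a2[2L] * st2 * sp2 + a2[3L] * ct2)
  list(g = g, A = a)
}

## unit-area Voigt broadening + derivative of a stick histogram
.broaden_derivative <- function(axis, stick, fwhm_g, fwhm_l, amplitude) {
  h <- axis[2L] - axis[1L]
  half <- max(6 * fwhm_g, 30 * fwhm_l, 10 * h)
  offs <- kernel_offsets(h, half)
  gk <- stats::dnorm(offs, 0, fwhm_g / (2 * sqrt(2 * log(2))))
  gk <- gk / (sum(gk) * h)
  hw <- fwhm_l / 2
  lk <- hw / (pi * (offs^2 + hw^2))
  lk <- lk / (sum(lk) * h)
  absn <- convolve_kernel(stick, gk, h)
  absn <- convolve_kernel(absn, lk, h)
  area <- pracma::trapz(axis, absn)
  if (area <= 0) stop("degenerate spectrum: non-positive absorption area")
  absn <- absn * (amplitude / area)
  pracma::gradient(absn, h)
}

#' Simulate a rigid-limit nitroxide powder spectrum
#'
#' First-order powder simulation: resonance fields
#' `B(theta, phi, m_I) = h nu / (g(theta, phi) mu_B) - A(theta, phi) m_I`
#' summed over a sin-theta-weighted orientation grid and the three 14N
#' nuclear projections, convolved with a Voigt line, returned as the field
#' derivative with the total absorption area normalized to `amplitude`
#' (so the spin count of the result is `amplitude`).
#'
#' @param sys a [nitroxide_system()].
#' @param axis field axis (G); defaults to a 200 G sweep about 3430 G.
#' @param orientations total orientation count (>= 200); split into a
#'   theta x phi grid with 20 phi points.
#' @param amplitude target double integral (spin amplitude).
#' @return A `field_spectrum` (temperature tagged 170 K).
#' @examples
#' s <- simulate_powder(nitroxide_system(), orientations = 800)
#' @export
simulate_powder <- function(sys, axis = default_field_axis(),
                            orientations = 4000L, amplitude = 1) {
  stopifnot(inherits(sys, "nitroxide_system"), orientations >= 200)
  extent <- 2 * max(sys$A_principal) +
    6 * (sys$linewidth_gaussian + sys$linewidth_lorentzian)
  if ((max(axis) - min(axis)) < extent)
    warning("field axis narrower than the spectral extent (",
            signif(extent, 4), " G); spectrum will be truncated")
  n_phi <- 20L
  n_theta <- max(10L, as.integer(ceiling(orientations / n_phi)))
  theta <- (seq_len(n_theta) - 0.5) / n_theta * (pi / 2)
  phi <- (seq_len(n_phi) - 0.5) / n_phi * (pi / 2)
  ct2 <- cos(theta)^2; st2 <- sin(theta)^2
  cp2 <- cos(phi)^2; sp2 <- sin(phi)^2
  w_th <- sin(theta)
  h <- axis[2L] - axis[1L]
  n <- length(axis)
  stick <- numeric(n)
  ## field at g for this microwave frequency, in Gauss
  b_of_g <- function(g) .planck_h * sys$mw_frequency * 1e9 /
    (g * .bohr_magneton) * 1e4
  for (j in seq_len(n_phi)) {
    ga <- .orient_gA(sys, ct2, st2, cp2[j], sp2[j])
    b0 <- b_of_g(ga$g)
    for (mi in c(-1, 0, 1)) {
      b <- b0 - ga$A * mi
      i <- floor((b - axis[1L]) / h) + 1L
      frac <- (b - axis[1L]) / h - (i - 1L)
      idx <- c(i, i + 1L)
      val <- c(w_th * (1 - frac), w_th * frac)
      keep <- idx >= 1L & idx <= n
      if (any(keep)) {
        acc <- rowsum(val[keep], idx[keep])
        stick[as.integer(rownames(acc))] <-
          stick[as.integer(rownames(acc))] + acc[, 1L]
      }
    }
  }
  dy <- .broaden_derivative(axis, stick, sys$linewidth_gaussian,
                            sys$linewidth_lorentzian, amplitude)
  field_spectrum(axis, dy, mw_frequency = sys$mw_frequency,
                 temperature = 170, label = "rigid-limit powder")
}

#' Simulate a motionally averaged nitroxide spectrum
#'
#' Partial motional averaging modelled by an order parameter S scaling the
#' tensor anisotropies about their isotropic means:
#' `A'_i = a_iso + S (A_i - a_iso)` (g analogous).  By construction the
#' effective outer splitting is `T_eff ~ a_iso + S (A_zz - a_iso)`, so S is
#' a direct control knob for T_eff when generating mobility fixtures.
#' S = 1 reproduces [simulate_powder()]; S = 0 gives the isotropic
#' three-line spectrum.
#'
#' @param sys a [nitroxide_system()].
#' @param S order parameter in [0, 1].
#' @param axis field axis (G).
#' @param orientations,amplitude as in [simulate_powder()].
#' @return A `field_spectrum` (temperature tagged 298 K).
#' @export
simulate_mobile <- function(sys, S, axis = default_field_axis(sweep = 100),
                            orientations = 4000L, amplitude = 1) {
  stopifnot(S >= 0, S <= 1)
  g_iso <- mean(sys$g_principal)
  a_iso <- mean(sys$A_principal)
  scaled <- nitroxide_system(
    g_principal = g_iso + S * (sys$g_principal - g_iso),
    A_principal = pmax(a_iso + S * (sys$A_principal - a_iso), 1e-3),
    linewidth_gaussian = sys$linewidth_gaussian,
    linewidth_lorentzian = sys$linewidth_lorentzian,
    mw_frequency = sys$mw_frequency)
  out <- simulate_powder(scaled, axis, orientations, amplitude)
  out$temperature <- 298
  out$label <- sprintf("mobile (S = %.2f)", S)
  out
}

#' Synthetic double-label pair spectrum
#'
#' Convenience wrapper applying the dipolar forward model to a single-label
#' spectrum: one call builds a fixture for the inverse problem.
#'
#' @param single single-label `field_spectrum`.
#' @param model a [distance_model()].
#' @param ... passed to [forward_model()].
#' @return A `field_spectrum`.
#' @export
make_pair_spectrum <- function(single, model, ...)
  forward_model(single, model, ...)

#' Convex combination of spectra
#'
#' Pointwise mixture `sum_i w_i s_i` of spectra sharing one field axis,
#' with non-negative fractions summing to 1.
#'
#' @param components list of `field_spectrum` objects.
#' @param fractions numeric weights.
#' @return A `field_spectrum`.
#' @export
mix_spectra <- function(components, fractions) {
  stopifnot(length(components) == length(fractions), length(components) >= 1L)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", signif(sum(fractions), 10), ")")
  ax <- components[[1L]]$field
  for (s in components[-1L])
    if (!isTRUE(all.equal(ax, s$field, tolerance = 1e-9)))
      stop("all components must share one field axis")
  y <- numeric(length(ax))
  for (i in seq_along(components))
    y <- y + fractions[i] * components[[i]]$intensity
  out <- components[[1L]]
  out$intensity <- y
  out$label <- "mixture"
  out
}

#' Add reproducible white noise to a spectrum
#'
#' Gaussian noise with standard deviation `peak_to_peak(s) / snr`, drawn
#' from a local RNG stream so the realization depends only on `(seed, snr)`
#' and the global RNG state is untouched.
#'
#' @param s a `field_spectrum`.
#' @param snr peak-to-peak signal to noise-sd ratio (> 0).
#' @param seed integer seed.
#' @return A `field_spectrum`.
#' @export
add_noise <- function(s, snr, seed = 1L) {
  stopifnot(snr > 0)
  sigma <- peak_to_peak(s) / snr
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(s$intensity), 0, sigma))
  out <- s
  out$intensity <- s$intensity + noise
  out
}
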