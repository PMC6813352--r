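test_that("rigid-limit outer splitting equals twice the A_zz rigid constant", {
  s <- fix_single(1024L)
  teff <- measure_teff(s)
  expect_equal(as.numeric(teff), 35, tolerance = 1.5 / 35)
})

test_that("an isotropic system gives three equal lines spaced by a_iso", {
  a_iso <- 15
  sys <- nitroxide_system(g_principal = rep(2.0061, 3),
                          A_principal = c(a_iso, a_iso, a_iso + 1e-9))
  ax <- default_field_axis(n = 2048)
  s <- simulate_powder(sys, ax)
  absn <- pracma::cumtrapz(ax, s$intensity)[, 1]
  pk <- order(absn, decreasing = TRUE)
  centre <- ax[which.max(absn)]
  ## line centres: absorption maxima separated by ~a_iso
  loc <- which(diff(sign(diff(absn))) < 0) + 1L
  loc <- loc[absn[loc] > 0.5 * max(absn)]
  expect_length(loc, 3L)
  expect_equal(diff(ax[loc]), c(a_iso, a_iso), tolerance = 0.05)
  ## equal integrated intensity per line: split at midpoints
  cuts <- c(min(ax), ax[loc][1:2] + a_iso / 2, max(ax))
  areas <- vapply(1:3, function(i) {
    sel <- ax >= cuts[i] & ax < cuts[i + 1]
    pracma::trapz(ax[sel], absn[sel])
  }, numeric(1))
  expect_equal(areas / mean(areas), rep(1, 3), tolerance = 0.02)
})

test_that("the orientation grid is converged at the default density", {
  ax <- fix_axis()
  s800 <- simulate_powder(nitroxide_system(), ax, orientations = 800)
  s1600 <- simulate_powder(nitroxide_system(), ax, orientations = 1600)
  rms <- sqrt(mean((s800$intensity - s1600$intensity)^2))
  expect_lt(rms / peak_to_peak(s1600), 0.005)
})

test_that("a narrow axis triggers a truncation warning", {
  expect_warning(
    simulate_powder(nitroxide_system(), seq(3400, 3460, length.out = 256)),
    "truncat")
})

test_that("order-parameter scaling reproduces the constructed T_eff", {
  sys <- nitroxide_system()
  ax <- fix_axis(1024L)
  ## S = 1 is exactly the rigid powder
  s1 <- simulate_mobile(sys, S = 1, axis = ax)
  rigid <- simulate_powder(sys, ax)
  expect_equal(s1$intensity, rigid$intensity, tolerance = 1e-12)
  a_iso <- mean(sys$A_principal)
  ## S = 0: fully averaged three-line spectrum with splitting a_iso
  s0 <- simulate_mobile(sys, S = 0, axis = ax)
  expect_equal(as.numeric(measure_teff(s0)), a_iso, tolerance = 1.5 / a_iso)
  ## S = 0.8: splitting at the constructed interpolation
  s08 <- simulate_mobile(sys, S = 0.8, axis = ax)
  expected <- a_iso + 0.8 * (max(sys$A_principal) - a_iso)
  expect_equal(as.numeric(measure_teff(s08)), expected,
               tolerance = 1.5 / expected)
  ## monotone non-decreasing T_eff over S
  te <- vapply(c(0.3, 0.5, 0.8, 1), function(S)
    as.numeric(measure_teff(simulate_mobile(sys, S, ax))), numeric(1))
  expect_true(all(diff(te) >= -1e-9))
})

test_that("pair-spectrum generation is the dipolar forward model", {
  single <- fix_single()
  none <- distance_model(r = 1, dr = 0.1, f = 0, f_non = 1)
  expect_equal(make_pair_spectrum(single, none)$intensity, single$intensity,
               tolerance = 1e-12)
  tab <- make_pair_spectrum(single, pair_model("cTnI(43/47MSL)", 2))
  ratio <- peak_to_peak(normalize_to_spins(tab, single)) / peak_to_peak(single)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.85)
})

test_that("mixing is a convex, symmetric, area-linear combination", {
  p <- fix_mobility_pair()
  expect_equal(mix_spectra(list(p$mobile), 1)$intensity, p$mobile$intensity)
  mix <- mix_spectra(list(p$mobile, p$rigid), c(0.55, 0.45))
  expect_equal(double_integral(mix)$value,
               0.55 * double_integral(p$mobile)$value +
                 0.45 * double_integral(p$rigid)$value,
               tolerance = 1e-9)
  swapped <- mix_spectra(list(p$rigid, p$mobile), c(0.5, 0.5))
  expect_equal(mix_spectra(list(p$mobile, p$rigid), c(0.5, 0.5))$intensity,
               swapped$intensity)
  expect_error(mix_spectra(list(p$mobile, p$rigid), c(0.7, 0.7)), "sum to 1")
  off <- fix_single()
  expect_error(mix_spectra(list(p$mobile, off), c(0.5, 0.5)), "one field axis")
})

test_that("noise is seed-reproducible with the nominal amplitude", {
  s <- fix_single(1024L)
  n1 <- add_noise(s, snr = 50, seed = 7)
  n2 <- add_noise(s, snr = 50, seed = 7)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(add_noise(s, 50, seed = 8)$intensity, n1$intensity))
  ## near-infinite snr behaves as the identity
  expect_equal(add_noise(s, snr = 1e12, seed = 1)$intensity, s$intensity,
               tolerance = 1e-9)
  ## edge-window sd close to the nominal sigma
  k <- 51
  edges <- c(seq_len(k), seq.int(1024 - k + 1, 1024))
  resid <- n1$intensity[edges] - s$intensity[edges]
  expect_equal(sd(resid), peak_to_peak(s) / 50, tolerance = 0.1)
})
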