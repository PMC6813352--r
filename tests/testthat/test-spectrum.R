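test_that("constructor enforces the axis and intensity invariants", {
  ax <- seq(3330, 3530, length.out = 128)
  s <- field_spectrum(ax, sin(ax / 10))
  expect_s3_class(s, "field_spectrum")
  expect_equal(s$sweep_width, 200)
  expect_equal(s$center_field, 3430)

  expect_error(field_spectrum(ax[1:32], sin(ax[1:32])), "at least 64")
  expect_error(field_spectrum(ax, sin(ax)[-1]), "lengths differ")
  ax_dup <- ax; ax_dup[10] <- ax_dup[9]
  expect_error(field_spectrum(ax_dup, sin(ax)), "not strictly increasing at row 10")
  ax_bad <- ax; ax_bad[50] <- ax_bad[50] + 0.05
  expect_error(field_spectrum(ax_bad, sin(ax)), "not uniformly spaced")
  y <- sin(ax); y[5] <- NA
  expect_error(field_spectrum(ax, y), "non-finite")
})

test_that("spectrum files round-trip bit-identically through the ASCII dialect", {
  ax <- seq(3330, 3530, length.out = 1024)
  s <- field_spectrum(ax, deriv_gaussian(ax, 3401.237, 4.56789),
                      mw_frequency = 9.648, temperature = 170.5,
                      label = "round trip")
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_identical(r$field, s$field)
  expect_identical(r$intensity, s$intensity)
  expect_equal(r$sweep_width, 200)
  expect_equal(r$mw_frequency, 9.648)
  expect_equal(r$temperature, 170.5)
  expect_equal(r$label, "round trip")
})

test_that("reader rejects malformed axes and missing files", {
  path <- withr::local_tempfile(fileext = ".txt")
  ax <- seq_len(100) + 3000
  rows <- sprintf("%g %g", ax, sin(ax))
  rows[40] <- rows[39]  # duplicated field value
  writeLines(rows, path)
  expect_error(read_spectrum(path), "row 40")
  expect_error(read_spectrum(file.path(tempdir(), "nope.txt")), "not found")
  writeLines(rows[1:20], path)
  expect_error(read_spectrum(path), "fewer than 64")
})

test_that("double integration recovers the analytic area of a Gaussian line", {
  ax <- seq(3330, 3530, length.out = 2048)
  s <- field_spectrum(ax, deriv_gaussian(ax, 3430, 5))
  di <- double_integral(s)
  expect_s3_class(di, "spin_count")
  expect_equal(di$value, 1, tolerance = 1e-3)
  expect_false(di$negative_absorption)

  s3 <- s; s3$intensity <- 3 * s$intensity
  expect_equal(double_integral(s3)$value, 3 * di$value, tolerance = 1e-9)

  flipped <- s; flipped$intensity <- -s$intensity
  expect_true(double_integral(flipped)$negative_absorption)
})

test_that("double integration is linear and shift-invariant", {
  ax <- seq(3330, 3530, length.out = 1024)
  s1 <- field_spectrum(ax, deriv_gaussian(ax, 3410, 4))
  s2 <- field_spectrum(ax, deriv_gaussian(ax, 3455, 7))
  mixed <- s1; mixed$intensity <- 2.5 * s1$intensity + 0.7 * s2$intensity
  expect_equal(double_integral(mixed)$value,
               2.5 * double_integral(s1)$value + 0.7 * double_integral(s2)$value,
               tolerance = 1e-9)
  shifted <- field_spectrum(ax + 7, s1$intensity)
  expect_equal(double_integral(shifted)$value, double_integral(s1)$value,
               tolerance = 1e-6)
})

test_that("the powder generator's double integral matches its spin amplitude", {
  s <- fix_single(1024L)
  expect_equal(double_integral(s)$value, 1, tolerance = 1e-2)
})

test_that("spin-count normalization scales to the reference", {
  s <- fix_single()
  expect_equal(normalize_to_spins(s, s)$intensity, s$intensity,
               tolerance = 1e-12)
  s2 <- s; s2$intensity <- 2 * s$intensity
  expect_equal(normalize_to_spins(s2, s)$intensity, s$intensity,
               tolerance = 1e-9)
  zero <- s; zero$intensity <- rep(0, length(s$field))
  expect_error(normalize_to_spins(s, zero), "zero spin count")
})

test_that("dipolar broadening conserves spins but lowers the central amplitude", {
  single <- fix_single()
  pair <- make_pair_spectrum(single, distance_model(r = 0.9, dr = 0.1, f = 1))
  pair_n <- normalize_to_spins(pair, single)
  expect_lt(peak_to_peak(pair_n), peak_to_peak(single))
})

test_that("resampling is the identity on its own axis and conserves area", {
  s <- fix_single(1024L)
  expect_equal(resample(s, s$field)$intensity, s$intensity, tolerance = 1e-12)
  down <- resample(s, seq(s$field[1], s$field[1024], length.out = 512))
  expect_equal(double_integral(down)$value, double_integral(s)$value,
               tolerance = 1e-3)
  smooth <- fix_line(1024L, sigma = 5)
  inner <- seq(3340, 3520, length.out = 911)
  sub <- smooth$field[smooth$field >= 3340 & smooth$field <= 3520]
  rt <- resample(resample(smooth, inner), sub)
  expect_lt(max(abs(rt$intensity - smooth$intensity[match(sub, smooth$field)])),
            1e-6 * peak_to_peak(smooth))
  expect_error(resample(s, seq(3320, 3530, length.out = 256)),
               "extrapolation")
})
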