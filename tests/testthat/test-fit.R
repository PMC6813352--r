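test_that("a single-Gaussian model is recovered from noiseless data", {
  single <- fix_single()
  truth <- distance_model(r = 1.3, dr = 0.6, f = 0.55)
  pair <- forward_model(single, truth)
  fit <- fit_distance(pair, single, n_gaussians = 1, n_starts = 4, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$model$r, truth$r, tolerance = 0.01)
  expect_equal(fit$model$dr, truth$dr, tolerance = 0.02)
  expect_equal(fit$model$f, truth$f, tolerance = 0.01)
  ## residuals + prediction reconstruct the data exactly
  expect_equal(fit$fitted.values + fit$residuals, fit$data$intensity,
               tolerance = 1e-12)
})

test_that("identical double and single spectra fit as all non-interacting", {
  single <- fix_single()
  fit <- fit_distance(single, single, n_gaussians = 1, n_starts = 4, seed = 1)
  expect_gt(fit$model$f_non, 0.97)
})

test_that("the reported chi2 equals an independent evaluation at the optimum", {
  single <- fix_single()
  pair <- forward_model(single, distance_model(r = 1.1, dr = 0.4, f = 0.7))
  fit <- fit_distance(pair, single, n_gaussians = 1, n_starts = 4, seed = 1)
  chi2_direct <- sum(((fit$data$intensity - fit$fitted.values) / fit$sigma)^2)
  expect_equal(fit$chi2, chi2_direct, tolerance = 1e-10)
  ## and against the forward model evaluated at the returned parameters
  pred <- forward_model(single, fit$model)
  chi2_fwd <- sum(((fit$data$intensity - pred$intensity) / fit$sigma)^2)
  expect_equal(fit$chi2, chi2_fwd, tolerance = 1e-8)
})

test_that("fits are bit-for-bit deterministic given options and data", {
  single <- fix_single()
  pair <- forward_model(single, distance_model(r = 1.2, dr = 0.5, f = 0.6))
  f1 <- fit_distance(pair, single, n_gaussians = 2, n_starts = 4, seed = 3)
  f2 <- fit_distance(pair, single, n_gaussians = 2, n_starts = 4, seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chi2, f2$chi2)
})

test_that("the Monte-Carlo/simplex optimizer recovers an easy model", {
  single <- fix_single()
  truth <- distance_model(r = 1.1, dr = 0.4, f = 0.7)
  pair <- forward_model(single, truth)
  fit <- fit_distance(pair, single,
                      opts = fit_options(n_gaussians = 1,
                                         optimizer = "monte-carlo-simplex",
                                         n_proposals = 600, seed = 1))
  expect_equal(fit$model$r, truth$r, tolerance = 0.03)
  expect_equal(fit$model$dr, truth$dr, tolerance = 0.05)
  expect_equal(fit$model$f, truth$f, tolerance = 0.03)
})

test_that("nested-model comparison prefers two Gaussians only for bimodal data", {
  single <- fix_single()
  bimodal <- distance_model(r = c(0.9, 1.8), dr = c(0.1, 0.6),
                            f = c(0.4, 0.4))
  noisy_b <- add_noise(forward_model(single, bimodal), snr = 50, seed = 11)
  fb1 <- fit_distance(noisy_b, single, n_gaussians = 1, n_starts = 6, seed = 1)
  fb2 <- fit_distance(noisy_b, single, n_gaussians = 2, n_starts = 6, seed = 1)
  cmp_b <- compare_models(fb1, fb2)
  expect_gt(cmp_b$ratio, 1.2)
  expect_equal(cmp_b$preferred, "complex")
  ## chi2 dominance of the richer nested model
  expect_lte(fb2$chi2, fb1$chi2 * (1 + 1e-9))

  unimodal <- distance_model(r = 1.3, dr = 0.5, f = 0.6)
  noisy_u <- add_noise(forward_model(single, unimodal), snr = 50, seed = 12)
  fu1 <- fit_distance(noisy_u, single, n_gaussians = 1, n_starts = 6, seed = 1)
  fu2 <- fit_distance(noisy_u, single, n_gaussians = 2, n_starts = 6, seed = 1)
  cmp_u <- compare_models(fu1, fu2)
  expect_lt(cmp_u$ratio, 1.2)
  expect_gte(cmp_u$ratio, 1 - 1e-9)
  ## self-comparison is neutral
  self <- compare_models(fu1, fu1)
  expect_equal(self$ratio, 1)
  expect_equal(self$preferred, "neither")
  ## different data is rejected
  expect_error(compare_models(fb1, fu2), "identical data")
})

test_that("bootstrap uncertainties are near zero without noise and grow as snr falls", {
  single <- fix_single()
  truth <- distance_model(r = 0.9, dr = 0.1, f = 0.5)
  clean <- forward_model(single, truth)
  fit0 <- fit_distance(clean, single, n_gaussians = 1, n_starts = 4, seed = 1)
  un0 <- estimate_uncertainty(fit0, n_boot = 20, seed = 1)
  expect_lt(un0$pm[un0$parameter == "r"], 0.02)

  u_r <- vapply(c(200, 50, 12), function(snr) {
    noisy <- add_noise(clean, snr = snr, seed = 21)
    ft <- fit_distance(noisy, single, n_gaussians = 1, n_starts = 4, seed = 1)
    un <- estimate_uncertainty(ft, n_boot = 40, seed = 2)
    un$pm[un$parameter == "r"]
  }, numeric(1))
  ## at snr 50 the centre uncertainty is of order 0.01 nm
  expect_gt(u_r[2], 0.0005)
  expect_lt(u_r[2], 0.05)
  expect_true(all(diff(u_r) > 0))
})

test_that("report tables follow the published column layout", {
  empty <- report_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("label", "n_gaussians", "chi2", "r1_nm", "dr1_nm",
                    "f1_pct", "r2_nm", "dr2_nm", "f2_pct", "gt2.5_pct")
                  %in% names(empty)))
  single <- fix_single()
  pair <- forward_model(single, pair_model("cTnI(43/47MTSL)+cTnC", 2))
  fit2 <- fit_distance(pair, single, n_gaussians = 2, n_starts = 8, seed = 1)
  tab <- report_table(list(fit2), labels = "43/47+cTnC")
  expect_equal(nrow(tab), 1L)
  expect_match(tab$r1_nm, "^0\\.9")
  expect_match(tab$f1_pct, "^48$")
  ## a suite of five pairs reported with both models gives ten rows
  fits10 <- rep(list(fit2), 10)
  tab10 <- report_table(fits10, labels = rep(sprintf("pair%d", 1:5), each = 2))
  expect_equal(nrow(tab10), 10L)
  ## components beyond 2.5 nm pool with the non-interacting fraction
  far <- fit2
  far$model <- distance_model(r = c(0.9, 2.7), dr = c(0.1, 0.3),
                              f = c(0.3, 0.4))
  tab_far <- report_table(list(far))
  expect_equal(tab_far$gt2.5_pct, "70")
  expect_equal(tab_far$r2_nm, "")
})
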