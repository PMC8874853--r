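test_that("generation is deterministic under a fixed seed", {
  truth <- ground_truth("static", kb = 3e4, noise_cv = 0.02, seed = 99)
  s1 <- generate_titration(truth)
  s2 <- generate_titration(truth)
  expect_identical(s1$intensity_obs, s2$intensity_obs)
  s3 <- generate_titration(ground_truth("static", kb = 3e4, noise_cv = 0.02,
                                        seed = 100))
  expect_false(identical(s1$intensity_obs, s3$intensity_obs))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(generate_titration(
    ground_truth("static", noise_cv = 0.05, seed = 2)))
  after <- runif(5)
  expect_identical(before, after)
})

test_that("generated intensity decreases strictly with quencher at zero noise", {
  set.seed(31)
  for (mech in c("static", "dynamic")) {
    for (i in 1:4) {
      truth <- ground_truth(mech, kb = 10^runif(1, 2, 6),
                            n = runif(1, 0.5, 1.5),
                            ksv = 10^runif(1, 3, 5))
      s <- generate_titration(truth)
      expect_true(all(diff(s$intensity) < 0))
    }
  }
})

test_that("reverse-applied inner filter attenuation is undone by correction", {
  truth <- ground_truth("static", kb = 2.07e4,
                        ife = list(a_ex = 0.05, a_em = 0.05))
  s <- generate_titration(truth)
  clean <- generate_titration(ground_truth("static", kb = 2.07e4))
  expect_lt(max(s$intensity_obs / clean$intensity), 1)  # attenuated as observed
  expect_equal(s$intensity, clean$intensity, tolerance = 1e-12)  # corrected
})

test_that("competitive attenuation follows the closed form", {
  s <- generate_titration(ground_truth("static", kb = 2.07e4,
                                       competitor_k = 6.33e6,
                                       competitor_conc = 5.5))
  res <- double_log_fit(s)
  expect_equal(res$kb, 2.07e4 / (1 + 6.33e6 * 5.5e-6), tolerance = 1e-6)
  expect_equal(res$kb, apparent_kb(2.07e4, 6.33e6, 5.5), tolerance = 1e-6)
})

test_that("dynamic-mechanism Ksv rises with temperature by the stated coefficient", {
  truth <- ground_truth("dynamic", ksv = 1e4)
  k298 <- stern_volmer_fit(generate_titration(truth, temperature = 298))$ksv
  k310 <- stern_volmer_fit(generate_titration(truth, temperature = 310))$ksv
  expect_equal(k310 / k298, 1 + 0.01 * 12, tolerance = 1e-6)
})

test_that("van't Hoff set follows the closed-form K(T) and tracks the published constants", {
  sets <- generate_vant_hoff_set(-260.80, -793.31, c(298, 303, 310))
  k <- vapply(sets, `[[`, numeric(1L), "kb")
  expect_equal(k, exp(-(-260.80) * 1000 / (8.314 * c(298, 303, 310)) +
                        (-793.31) / 8.314), tolerance = 1e-12)
  # the published constants scatter around their own van't Hoff line by up
  # to ~20% in each pairwise ratio, so agreement is order-of-magnitude, not
  # tight: the generated set must land within 30% of each published value
  # on the log scale
  published <- c(2.07e4, 2.83e3, 3.44e2)
  expect_true(all(abs(log(k) - log(published)) < log(1.3)))

  # zero enthalpy: identical K at all temperatures
  k0 <- vapply(generate_vant_hoff_set(0, -50, c(298, 303, 310)), `[[`,
               numeric(1L), "kb")
  expect_equal(diff(range(k0)), 0, tolerance = 1e-12)
})

test_that("van't Hoff fit on a noise-free generated set recovers the inputs", {
  sets <- generate_vant_hoff_set(-120.5, -310.2, c(290, 298, 305, 312))
  kb_fit <- vapply(sets, function(x) double_log_fit(x$series)$kb, numeric(1L))
  temps <- vapply(sets, function(x) x$series$temperature, numeric(1L))
  res <- vant_hoff_fit(temps, kb_fit)
  expect_equal(res$delta_h, -120.5, tolerance = 1e-6)
  expect_equal(res$delta_s, -310.2, tolerance = 1e-6)
})

test_that("generated spectra reproduce the requested shift and damping", {
  pair <- generate_spectra("emission", shift_nm = 8, damping = 0.81)
  ps <- peak_shift(pair$free, pair$bound)
  expect_equal(ps$shift, 8, tolerance = 0.01)
  expect_equal(ps$direction, "redshift")
  expect_equal(ps$intensity_change_pct, -19, tolerance = 0.01)

  same <- generate_spectra("emission", shift_nm = 0, damping = 1)
  ps0 <- peak_shift(same$free, same$bound)
  expect_identical(ps0$shift, 0)
  expect_equal(ps0$intensity_change_pct, 0, tolerance = 1e-9)
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_titration(ground_truth("static"),
                                  conc_grid = c(0, -1, 5)), "non-negative")
  expect_error(generate_titration(ground_truth("static"),
                                  conc_grid = c(1, 2, 3)), "start at 0")
  expect_error(generate_vant_hoff_set(-100, -200, c(298, 298)), "distinct")
  expect_error(ground_truth("static", kb = -1))
})
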