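make_system <- function(kb, temperature = 298, competitor = NULL) {
  conc <- seq(0, 27.5, length.out = 11)
  f <- 1000 / (1 + kb * conc * 1e-6)
  s <- titration_series(conc, f, temperature, competitor = competitor)
  list(quenching = stern_volmer_fit(s), binding = double_log_fit(s),
       series = s)
}

test_that("binary vs ternary comparison reports fold change and quench delta", {
  binary <- make_system(2.07e4)
  ternary <- make_system(0.20e2,
                         competitor = list(name = "quercetin", conc_uM = 5.5))
  rep <- compare_systems(binary, ternary)
  expect_equal(rep$fold_change, 2.07e4 / 0.20e2, tolerance = 1e-6)
  expect_equal(rep$fold_change, 1035, tolerance = 1e-4)
  expect_equal(rep$quench_pct_delta,
               rep$quench_pct_ternary - rep$quench_pct_binary,
               tolerance = 1e-12)
  expect_match(rep$interpretation, "reduces")
})

test_that("identical systems give fold change 1 and a no-effect call", {
  sys <- make_system(1e4)
  rep <- compare_systems(sys, sys)
  expect_equal(rep$fold_change, 1, tolerance = 1e-12)
  expect_equal(rep$quench_pct_delta, 0, tolerance = 1e-12)
  expect_match(rep$interpretation, "no effect")
})

test_that("quenching percentages mirror observed binary/ternary drops", {
  mk <- function(f_last) {
    s <- titration_series(c(0, 10, 27.5), c(100, (100 + f_last) / 2, f_last),
                          298)
    # attach fits from a well-behaved series; only quench pct uses `series`
    ref <- make_system(1e4)
    list(quenching = ref$quenching, binding = ref$binding, series = s)
  }
  rep <- compare_systems(mk(81), mk(55))
  expect_equal(rep$quench_pct_binary, 19)
  expect_equal(rep$quench_pct_ternary, 45)
  expect_equal(rep$quench_pct_delta, 26)
})

test_that("fold changes of swapped arguments are reciprocal", {
  a <- make_system(3e4)
  b <- make_system(4e2)
  expect_equal(compare_systems(a, b)$fold_change *
                 compare_systems(b, a)$fold_change, 1, tolerance = 1e-12)
})

test_that("temperature mismatch between systems is rejected", {
  expect_error(compare_systems(make_system(1e4),
                               make_system(1e3, temperature = 310)),
               "temperatures differ")
})

test_that("the Ksv-up/Kb-down displacement signature is flagged", {
  conc <- seq(0, 27.5, length.out = 11)
  binary <- make_system(2.07e4)
  # ternary with steeper quenching (higher Ksv) but much weaker binding:
  # sub-linear isotherm, n < 1, scaled so initial slope exceeds the binary's
  f_t <- 1000 / (1 + 100 * (conc * 1e-6)^0.4)
  st <- titration_series(conc, f_t, 298)
  ternary <- list(quenching = suppressWarnings(stern_volmer_fit(st)),
                  binding = double_log_fit(st), series = st)
  expect_gt(ternary$quenching$ksv, binary$quenching$ksv)
  expect_lt(ternary$binding$kb, binary$binding$kb)
  rep <- compare_systems(binary, ternary)
  expect_match(rep$interpretation, "Ksv rises while Kb falls")
})

test_that("site inference assigns the single influential marker's site", {
  sites <- c(phenylbutazone = "Site I", ibuprofen = "Site II")
  res <- site_marker_inference(2.07e4,
                               c(ibuprofen = 2.05e4, phenylbutazone = 0.4e4),
                               sites)
  expect_equal(res$site, "Site I")
  expect_equal(res$markers_above_threshold, "phenylbutazone")

  # all markers within threshold -> undetermined
  res2 <- site_marker_inference(2.07e4,
                                c(ibuprofen = 2.0e4, phenylbutazone = 1.9e4),
                                sites)
  expect_equal(res2$site, "undetermined")

  # two markers above threshold -> undetermined, both listed
  res3 <- site_marker_inference(2.07e4,
                                c(ibuprofen = 0.5e4, phenylbutazone = 0.4e4),
                                sites)
  expect_equal(res3$site, "undetermined")
  expect_setequal(res3$markers_above_threshold,
                  c("ibuprofen", "phenylbutazone"))

  expect_error(site_marker_inference(2.07e4, c(warfarin = 1e4), sites),
               "no site mapping")
})

test_that("site inference is invariant to uniform rescaling of all Kb values", {
  sites <- c(phenylbutazone = "Site I", ibuprofen = "Site II")
  kbm <- c(ibuprofen = 2.05e4, phenylbutazone = 0.4e4)
  r1 <- site_marker_inference(2.07e4, kbm, sites)
  r2 <- site_marker_inference(2.07e4 * 1e3, kbm * 1e3, sites)
  expect_equal(r1$site, r2$site)
  expect_equal(r1$marker_effects, r2$marker_effects, tolerance = 1e-12)
})

test_that("generated competitive data always lowers the apparent binding constant", {
  set.seed(21)
  for (i in 1:6) {
    kb <- 10^runif(1, 3, 6)
    kc <- 10^runif(1, 4, 7)
    cc <- runif(1, 0.5, 20)
    free <- double_log_fit(static_series(kb = kb))
    tern <- double_log_fit(static_series(kb = kb, competitor_k = kc,
                                         competitor_conc = cc))
    expect_lt(tern$kb, free$kb)
    expect_equal(tern$kb, kb / (1 + kc * cc * 1e-6), tolerance = 1e-6)
  }
})
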