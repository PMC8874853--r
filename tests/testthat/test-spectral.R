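gaussian_spectrum <- function(center, grid = 300:500, width = 25,
                              amplitude = 1000) {
  emission_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * width^2)))
}

test_that("peak finding refines a Gaussian center to sub-grid accuracy", {
  p <- find_peak(gaussian_spectrum(340))
  expect_equal(p$flag, "peak")
  expect_lt(abs(p$wavelength - 340), 0.1)
  # off-grid center is still resolved
  p2 <- find_peak(gaussian_spectrum(341.4))
  expect_lt(abs(p2$wavelength - 341.4), 0.1)
})

test_that("peak ties, monotone spectra, and flat spectra follow the stated rules", {
  # two equal maxima: lowest wavelength wins (unrefined grid argmax)
  s <- emission_spectrum(1:7, c(0, 1, 5, 1, 5, 1, 0))
  expect_equal(find_peak(s, refine = FALSE)$wavelength, 3)

  mono <- emission_spectrum(300:320, seq(1, 10, length.out = 21))
  expect_equal(find_peak(mono)$flag, "boundary")

  flat <- emission_spectrum(300:320, rep(5, 21))
  expect_equal(find_peak(flat)$flag, "flat")
})

test_that("peak shift reports magnitude, direction, and intensity change", {
  ps <- peak_shift(gaussian_spectrum(340), gaussian_spectrum(348))
  expect_equal(ps$shift, 8, tolerance = 0.01)
  expect_equal(ps$direction, "redshift")

  same <- peak_shift(gaussian_spectrum(340), gaussian_spectrum(340))
  expect_identical(same$shift, 0)
  expect_equal(same$direction, "none")
  expect_equal(same$intensity_change_pct, 0, tolerance = 1e-9)

  blue <- peak_shift(gaussian_spectrum(340), gaussian_spectrum(339))
  expect_equal(blue$shift, -1, tolerance = 0.01)
  expect_equal(blue$direction, "blueshift")

  expect_error(peak_shift(gaussian_spectrum(340, grid = 300:400),
                          gaussian_spectrum(500, grid = 450:550)),
               "overlap")
})

test_that("peak shift is zero on identical input and antisymmetric under swap", {
  set.seed(14)
  for (i in 1:5) {
    a <- gaussian_spectrum(runif(1, 320, 360))
    b <- gaussian_spectrum(runif(1, 320, 360))
    expect_identical(peak_shift(a, a)$shift, 0)
    expect_equal(peak_shift(a, b)$shift, -peak_shift(b, a)$shift,
                 tolerance = 1e-9)
  }
})

test_that("synchronous spectrum samples the constant-offset diagonal", {
  # separable EEM whose intensity depends only on the emission wavelength
  exg <- seq(250, 320, by = 5)
  emg <- seq(250, 420, by = 5)
  f_em <- function(l) 100 + (l - 250)^1.5 / 10
  m <- matrix(rep(f_em(emg), each = length(exg)), nrow = length(exg))
  sync <- synchronous_spectrum(eem(exg, emg, m), 15)
  expect_equal(sync$intensities, f_em(sync$wavelengths + 15),
               tolerance = 1e-9)

  # delta = 0 traces the Rayleigh ridge
  sync0 <- synchronous_spectrum(eem(exg, emg, m), 0)
  expect_equal(sync0$intensities, f_em(sync0$wavelengths), tolerance = 1e-9)

  expect_error(synchronous_spectrum(eem(exg, emg, m), 500), "diagonal")
})

test_that("synchronous spectrum of a Trp-like EEM peaks at its excitation center", {
  pair <- generate_spectra("eem",
                           eem_peaks_at = list(list(ex = 280, em = 340,
                                                    amplitude = 1000)),
                           ridge_amplitude = 0)
  sync <- synchronous_spectrum(pair$free, 60)
  expect_equal(find_peak(sync)$wavelength, 280, tolerance = 0.5)
})

test_that("synchronous extraction commutes with uniform intensity scaling", {
  pair <- generate_spectra("eem")
  e1 <- pair$free
  e2 <- eem(e1$excitation_grid, e1$emission_grid, 3.7 * e1$intensity_matrix)
  s1 <- synchronous_spectrum(e1, 60)
  s2 <- synchronous_spectrum(e2, 60)
  expect_equal(s2$intensities, 3.7 * s1$intensities, tolerance = 1e-12)
})

test_that("EEM analysis finds scattering ridges and both protein peaks", {
  pair <- generate_spectra("eem", damping = 0.7)
  res <- eem_peaks(pair$free)
  expect_equal(res$flag, "ok")
  expect_equal(c(res$peak1$ex, res$peak1$em), c(280, 340))
  expect_equal(c(res$peak2$ex, res$peak2$em), c(230, 330))

  # ridge cells are exactly those within tolerance of em = k * ex
  exg <- pair$free$excitation_grid
  emg <- pair$free$emission_grid
  expected_ray <- which(abs(outer(exg, emg, "-")) <= res$tolerance,
                        arr.ind = TRUE)
  expect_equal(nrow(res$rayleigh_ridge), nrow(expected_ray))
  expect_true(all(abs(res$rayleigh_ridge$ex - res$rayleigh_ridge$em) <=
                    res$tolerance))
  expect_true(all(abs(2 * res$second_order_ridge$ex -
                        res$second_order_ridge$em) <= res$tolerance))

  # damped bound EEM: both peak intensities decline vs the free reference
  res_b <- eem_peaks(pair$bound, reference = pair$free)
  expect_lt(res_b$intensity_delta[["peak1"]], 0)
  expect_lt(res_b$intensity_delta[["peak2"]], 0)
})

test_that("an EEM with only a diagonal ridge yields no off-ridge peaks", {
  exg <- seq(200, 350, by = 5)
  emg <- seq(250, 550, by = 5)
  m <- outer(exg, emg, function(a, b) 200 * exp(-(b - a)^2 / 18))
  res <- eem_peaks(eem(exg, emg, m))
  expect_equal(res$flag, "no-peaks")
  expect_null(res$peak1)
  expect_null(res$peak2)
  expect_gt(nrow(res$rayleigh_ridge), 0)
})

test_that("spectrum and EEM CSV readers round-trip generated data", {
  s <- gaussian_spectrum(340)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,intensity",
               paste(s$wavelengths, s$intensities, sep = ",")), path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$intensities, s$intensities, tolerance = 1e-12)

  pair <- generate_spectra("eem")
  e <- pair$free
  path2 <- withr::local_tempfile(fileext = ".csv")
  body <- rbind(c(NA, e$emission_grid),
                cbind(e$excitation_grid, e$intensity_matrix))
  write.table(body, path2, sep = ",", row.names = FALSE, col.names = FALSE,
              na = "0")
  e2 <- read_eem_csv(path2)
  expect_equal(e2$excitation_grid, e$excitation_grid)
  expect_equal(e2$emission_grid, e$emission_grid)
  expect_equal(e2$intensity_matrix, e$intensity_matrix, tolerance = 1e-9,
               ignore_attr = TRUE)
})
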