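test_that("wavenumber grids and spectra enforce their invariants", {
  g <- wavenumber_grid(400, 2000, 660)
  expect_equal(g$n_points, 660L)
  expect_true(all(diff(g$wavenumbers) > 0))
  expect_equal(diff(range(diff(g$wavenumbers))), 0, tolerance = 1e-9)
  expect_error(wavenumber_grid(2000, 400), "start < end")
  expect_error(wavenumber_grid(0, 1, 1), "n_points")
  expect_error(spectrum_1d(1:10, g), "660")
  expect_error(spectrum_1d(c(rep(1, 659), NA), g), "finite")
})

test_that("spectrum CSV round-trips preserve values", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("1000,0.0\n1001,1.0\n1002,0.0", p)
  s <- read_spectrum_csv(p)
  expect_equal(s$grid$n_points, 3L)
  expect_equal(s$grid$wavenumbers[which.max(s$intensities)], 1001)

  s2 <- random_spectrum(seed = 7)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s2, p2)
  expect_equal(length(readLines(p2)) - 1L, s2$grid$n_points)
  back <- read_spectrum_csv(p2)
  expect_equal(back$intensities, s2$intensities, tolerance = 1e-9)
  expect_equal(back$grid$wavenumbers, s2$grid$wavenumbers, tolerance = 1e-9)
})

test_that("resampling onto the file's own grid is the identity", {
  s <- random_spectrum(seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, p)
  r <- read_spectrum_csv(p, grid_policy = "resample", grid = s$grid)
  expect_equal(r$intensities, s$intensities, tolerance = 1e-9)
})

test_that("spectrum sets round-trip through a CSV directory with manifest", {
  refs <- default_reference_library()
  d <- withr::local_tempdir()
  write_spectrum_set(refs, d)
  back <- read_spectrum_set(d)
  expect_equal(back$role, "reference")
  expect_equal(names(back$spectra), names(refs$spectra))
  for (nm in names(refs$spectra))
    expect_equal(back$spectra[[nm]]$intensities,
                 refs$spectra[[nm]]$intensities, tolerance = 1e-9)
})

test_that("CSV reader reports malformed input with line context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "1000,1.0", "1001,oops"), p)
  expect_error(read_spectrum_csv(p), "line 3")
  writeLines(c("1000,1.0", "1000,2.0"), p)
  expect_error(read_spectrum_csv(p), "duplicated")
})

test_that("Savitzky-Golay smoothing fixes polynomials up to its degree", {
  g <- wavenumber_grid(0, 10, 101)
  const <- spectrum_1d(rep(2.5, 101), g)
  expect_equal(sg_smooth(const)$intensities, const$intensities,
               tolerance = 1e-9)
  x <- g$wavenumbers
  cubic <- spectrum_1d(1 + 0.5 * x - 0.2 * x^2 + 0.03 * x^3, g)
  expect_equal(sg_smooth(cubic, 5, 3)$intensities, cubic$intensities,
               tolerance = 1e-9)
  expect_error(sg_smooth(const, window = 4), "odd")
  expect_error(sg_smooth(const, window = 3, degree = 3), "exceed")
})

test_that("smoothing reduces white-noise variance", {
  set.seed(11)
  g <- wavenumber_grid(0, 100, 500)
  noisy <- spectrum_1d(rnorm(500, sd = 1), g)
  sm <- sg_smooth(noisy)
  expect_lt(var(sm$intensities), var(noisy$intensities))
})

test_that("baseline subtraction removes ramps and keeps narrow peaks", {
  g <- wavenumber_grid(400, 2000, 660)
  ramp <- spectrum_1d(seq(0, 5, length.out = 660), g)
  res <- subtract_baseline(ramp, window = 659)
  expect_lt(max(abs(res$intensities)), 1e-6 * 5)

  zero <- spectrum_1d(rep(0, 660), g)
  expect_equal(subtract_baseline(zero)$intensities, rep(0, 660))

  peak_only <- make_reference(
    reference_definition("X", list(peak_spec(1200, 12, 1))), g)
  on_ramp <- spectrum_1d(peak_only$intensities + seq(0, 2, length.out = 660), g)
  corrected <- subtract_baseline(on_ramp)
  apex <- which.max(peak_only$intensities)
  expect_equal(corrected$intensities[apex], peak_only$intensities[apex],
               tolerance = 0.1)
  # the ramp is removed to within 5% of its range away from the peak
  away <- abs(g$wavenumbers - 1200) > 200
  ramp_resid <- corrected$intensities[away] - peak_only$intensities[away]
  expect_lt(max(abs(ramp_resid)), 0.05 * 2)
})

test_that("smoothing and baseline subtraction are linear operators", {
  s1 <- random_spectrum(seed = 1)
  s2 <- random_spectrum(seed = 2)
  a <- 2.5; b <- -0.7
  comb <- spectrum_1d(a * s1$intensities + b * s2$intensities, s1$grid)
  for (f in list(function(s) sg_smooth(s),
                 function(s) subtract_baseline(s, window = 221))) {
    lhs <- f(comb)$intensities
    rhs <- a * f(s1)$intensities + b * f(s2)$intensities
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("max_normalize scales to unit maximum and inverts exactly", {
  g <- tiny_grid()
  s <- spectrum_1d(c(rep(1, g$n_points - 1), 4), g)
  r <- max_normalize(s)
  expect_equal(r$max_height, 4)
  expect_equal(max(r$spectrum$intensities), 1)
  unit <- max_normalize(r$spectrum)
  expect_equal(unit$max_height, 1)
  expect_equal(unit$spectrum$intensities, r$spectrum$intensities)
  expect_error(max_normalize(spectrum_1d(rep(-1, g$n_points), g)),
               "positive")
  set.seed(42)
  for (i in 1:1000) {
    y <- abs(rnorm(20)) + 1e-6
    r <- max_normalize(spectrum_1d(y, wavenumber_grid(0, 1, 20)))
    expect_equal(max(r$spectrum$intensities), 1)
    expect_equal(r$spectrum$intensities * r$max_height, y, tolerance = 1e-12)
  }
})
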