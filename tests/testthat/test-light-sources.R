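# Source spectra, irradiance normalization, action spectra, photon flux.

test_that("source shapes match their definitions", {
  w <- light_source("white")
  expect_true(all(w$irradiance == w$irradiance[1]))

  led <- light_source("led", center = 520)
  on <- led$wavelength[led$irradiance > 0]
  expect_equal(range(on), c(510, 530))

  led2 <- light_source("led", center = 513)
  expect_equal(range(led2$wavelength[led2$irradiance > 0]), c(503, 523))

  rgb <- light_source("rgb")
  for (pk in c(458, 521, 628)) {
    win <- abs(rgb$wavelength - pk) <= 15
    expect_lte(abs(rgb$wavelength[win][which.max(rgb$irradiance[win])] - pk),
               1)
  }

  sun <- light_source("sunlight")
  expect_equal(sun$wavelength[which.max(sun$irradiance)], 550)
  lamp <- light_source("lamp")
  expect_equal(lamp$wavelength[which.max(lamp$irradiance)], 600)
})

test_that("invalid sources are rejected", {
  expect_error(light_source("laser"), "arg")
  expect_error(light_source("led", center = 385), "beyond the grid")
  expect_error(light_source("led", grid = light_grid(450, 700)),
               "390-700")
})

test_that("integrated-irradiance scaling has the stated properties", {
  w <- light_source("white", grid = light_grid(390, 700))
  s <- scale_to_irradiance(w, 1.2e-9)
  expect_equal(trapz(s$wavelength, s$irradiance), 1.2e-9, tolerance = 1e-9)
  # flat spectrum: density is total / width everywhere
  expect_equal(s$irradiance, rep(1.2e-9 / 310, length(s$wavelength)),
               tolerance = 1e-12)
  # linearity
  s2 <- scale_to_irradiance(w, 2.4e-9)
  expect_equal(s2$irradiance, 2 * s$irradiance, tolerance = 1e-12)
  # zero target
  z <- scale_to_irradiance(w, 0)
  expect_true(all(z$irradiance == 0))
  expect_error(scale_to_irradiance(z, 1e-9), "all-zero")
})

test_that("band-referenced scaling matches the integral convention for LEDs", {
  led <- light_source("led", center = 513)
  a <- set_irradiance(led, 1e-7, mode = "band")
  b <- scale_to_irradiance(led, 1e-7)
  expect_equal(a$irradiance, b$irradiance, tolerance = 1e-12)
  # peak density of any band-scaled source is E / ref_band
  w <- set_irradiance(light_source("white"), 1e-7, mode = "band")
  expect_equal(max(w$irradiance), 1e-7 / 20)
})

test_that("action spectrum evaluates the summed-Gaussian fit", {
  ch <- opsin("ChRmine")
  # direct closed-form evaluation at the main Gaussian centre
  expect_equal(action_spectrum(ch, 515),
               0.973 + 0.0973 * exp(-(515 - 450)^2 / 3200),
               tolerance = 1e-12)
  # single-term fit: value A1 at centre, symmetric about it
  f <- action_spectrum_fit(A = c(0.7, 0, 0), B = c(500, 0, 0),
                           sigma = c(25, 0, 0))
  expect_equal(action_spectrum(f, 500), 0.7)
  expect_equal(action_spectrum(f, 520), action_spectrum(f, 480))
  # negative lobes are floored at zero
  g <- action_spectrum_fit(A = c(1, -2, 0), B = c(500, 600, 0),
                           sigma = c(20, 20, 0))
  expect_equal(action_spectrum(g, 600), 0)
  expect_error(action_spectrum_fit(A = 1, B = 500, sigma = 0), "sigma")
})

test_that("peak activation wavelength is the argmax of the fit", {
  expect_equal(opsin("ChRmine")$lambda_peak, 513)
  f <- action_spectrum_fit(A = c(1, 0, 0), B = c(560, 0, 0),
                           sigma = c(30, 0, 0))
  expect_equal(peak_wavelength(f), 560)
})

test_that("effective photon flux: reference value, zero, linearity", {
  flat_eps <- action_spectrum_fit(A = c(1, 0, 0), B = c(505, 0, 0),
                                  sigma = c(1e9, 1, 1))
  # ~monochromatic line at 505 nm carrying 0.04 uW/mm^2 with eps = 1
  line <- scale_to_irradiance(light_source("led", center = 505,
                                           bandwidth = 2), 4e-8)
  phi <- effective_photon_flux(line, flat_eps)
  expect_equal(phi, 1.03e11, tolerance = 0.02)

  ch <- opsin("ChRmine")
  z <- scale_to_irradiance(light_source("white"), 0)
  expect_equal(effective_photon_flux(z, ch), 0)

  w1 <- set_irradiance(light_source("white"), 1e-8)
  w2 <- set_irradiance(light_source("white"), 2e-8)
  expect_equal(effective_photon_flux(w2, ch),
               2 * effective_photon_flux(w1, ch), tolerance = 1e-9)
})

test_that("narrow LED at the peak wavelength matches the point formula", {
  ch <- opsin("ChRmine")
  E <- 1e-7
  led <- set_irradiance(light_source("led", center = 513), E)
  phi <- effective_photon_flux(led, ch)
  point <- action_spectrum(ch, 513) * E * 513e-9 /
    (6.62607015e-34 * 2.99792458e8)
  expect_equal(phi, point, tolerance = 0.01)
})

test_that("broadband beats off-peak narrowband flux for ChRmine", {
  ch <- opsin("ChRmine")
  E <- 1e-7
  phi_w <- effective_photon_flux(set_irradiance(light_source("white"), E),
                                 ch)
  for (cw in c(420, 450, 560, 600, 640)) {
    led <- set_irradiance(light_source("led", center = cw), E)
    expect_gt(phi_w, effective_photon_flux(led, ch))
  }
})

test_that("source ordering of effective flux for ChRmine at equal irradiance", {
  ch <- opsin("ChRmine")
  E <- 1e-7
  phi <- vapply(c("white", "sunlight", "lamp", "rgb"), function(k)
    effective_photon_flux(set_irradiance(light_source(k), E), ch),
    numeric(1))
  led <- effective_photon_flux(
    set_irradiance(light_source("led", center = 513), E), ch)
  expect_gt(phi[["white"]], phi[["sunlight"]])
  expect_gt(phi[["sunlight"]], phi[["lamp"]])
  expect_gt(phi[["sunlight"]], phi[["rgb"]])
  expect_gt(min(phi[["lamp"]], phi[["rgb"]]), led)
})

test_that("spectra export and source configs round-trip", {
  led <- set_irradiance(light_source("led", center = 500), 1e-8)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(led, path)
  back <- utils::read.csv(path)
  expect_equal(back$spectral_irradiance_W_per_mm2_per_nm, led$irradiance)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("- kind: led", "  name: green", "  center: 520",
               "- kind: white"), yml)
  srcs <- read_source_config(yml)
  expect_named(srcs, c("green", "white"))
  expect_s3_class(srcs$green, "light_spectrum")
  expect_equal(attr(srcs$green, "params")$center, 520)
})
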