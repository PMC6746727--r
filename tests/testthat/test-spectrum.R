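test_that("inverse-Compton peak energy follows 4 gamma^2 E_L", {
  expect_equal(compton_peak_energy(1, 1), 0.004)
  expect_equal(compton_peak_energy(83.75, 1.2),
               4 * 83.75^2 * 1.2 / 1000)  # 33.66 keV by hand
  # quadratic scaling in gamma
  expect_equal(compton_peak_energy(40, 1.5),
               4 * compton_peak_energy(20, 1.5))
  expect_error(compton_peak_energy(-1, 1), "positive")
})

test_that("energy grid invariants are enforced", {
  expect_error(energy_grid(bin_width = 0.1), "0.05")
  expect_error(energy_grid(e_min = 20), "\\[15, 60\\]")
  g <- energy_grid()
  expect_true(all(diff(g$centers) > 0))
})

test_that("a symmetric line (tail_shape 0) has mean at the peak", {
  s <- model_spectrum(source_config(tail_shape = 0))
  expect_equal(mean_energy(s), 33.69, tolerance = 0.025 / 2)
})

test_that("spectrum integrates to the total flux and is non-negative", {
  s <- model_spectrum(source_config(total_flux = 2.5e9))
  expect_equal(sum(s$fluence_rate), 2.5e9, tolerance = 1e-9)
  expect_true(all(s$fluence_rate >= 0))
  # mode sits at the peak energy
  expect_equal(s$grid$centers[which.max(s$fluence_rate)], 33.69,
               tolerance = 0.05)
})

test_that("calibrated default source reproduces the tuned mean energies", {
  sp <- default_spectra()
  expect_equal(mean_energy(sp$unfiltered), 33.18, tolerance = 0.02)
  expect_equal(mean_energy(sp$filtered), 32.59, tolerance = 0.05)
  # 0.59 keV separation between the two scans
  expect_equal(mean_energy(sp$unfiltered) - mean_energy(sp$filtered),
               0.59, tolerance = 0.05)
})

test_that("source configuration validates its physical bounds", {
  expect_error(source_config(peak_energy = 40), "\\[15, 35\\]")
  expect_error(source_config(fwhm_fraction = 0.1), "0.045")
  expect_error(source_config(tail_shape = -1), ">= 0")
  narrow <- structure(list(centers = seq(31, 35, 0.025), bin_width = 0.025),
                      class = "energy_grid")
  expect_error(model_spectrum(source_config(), narrow), "3 FWHM")
})

test_that("filtering is multiplicative, commutative and never amplifies", {
  s <- model_spectrum(source_config())
  half <- filter_spec("iodine", 145)
  full <- filter_spec("iodine", 290)
  water <- filter_spec("water", 2000)
  twice <- apply_filter(apply_filter(s, half), half)
  once <- apply_filter(s, full)
  expect_equal(twice$fluence_rate, once$fluence_rate, tolerance = 1e-12)
  ab <- apply_filter(apply_filter(s, full), water)
  ba <- apply_filter(apply_filter(s, water), full)
  expect_equal(ab$fluence_rate, ba$fluence_rate, tolerance = 1e-12)
  expect_true(all(once$fluence_rate <= s$fluence_rate))
  # zero thickness is the identity
  s0 <- apply_filter(s, filter_spec("iodine", 0, allow_zero = TRUE))
  expect_equal(s0$fluence_rate, s$fluence_rate)
})

test_that("the iodine filter removes the above-edge beam preferentially", {
  sp <- default_spectra()
  expect_lt(mean_energy(sp$filtered), mean_energy(sp$unfiltered))
  surv <- above_edge_fraction(sp$unfiltered, sp$filtered)
  below_surv <- sum(sp$filtered$fluence_rate[
    sp$filtered$grid$centers <= iodine_k_edge()]) /
    sum(sp$unfiltered$fluence_rate[
      sp$unfiltered$grid$centers <= iodine_k_edge()])
  expect_lt(surv, 0.02)        # high-energy part almost fully absorbed
  expect_lt(surv, below_surv)  # and much harder hit than the below-edge part
  # the remnant above-edge share of the filtered beam is the few-percent
  # figure quoted for the filtered spectrum
  expect_lt(abs(above_edge_share(sp$filtered) - 0.03), 0.01)
})

test_that("above_edge_fraction handles identity, zero and degenerate input", {
  s <- model_spectrum(source_config())
  expect_equal(above_edge_fraction(s, s), 1)
  z <- s; z$fluence_rate[] <- 0
  expect_equal(above_edge_fraction(s, z), 0)
  expect_error(above_edge_fraction(z, s), "no above-edge")
  expect_error(mean_energy(z), "all-zero")
  # energy weighting flag
  expect_equal(above_edge_fraction(s, s, weighting = "energy"), 1)
})

test_that("a single-bin spectrum has its bin energy as mean", {
  g <- energy_grid()
  phi <- numeric(length(g$centers))
  i <- which.min(abs(g$centers - 33))
  phi[i] <- 5e9
  s <- structure(list(grid = g, fluence_rate = phi, label = "delta"),
                 class = "kesct_spectrum")
  expect_equal(mean_energy(s), g$centers[i])
})

test_that("spectra round-trip through CSV", {
  s <- model_spectrum(source_config())
  f <- tempfile(fileext = ".csv")
  write_spectrum(s, f)
  r <- read_spectrum(f)
  expect_equal(r$fluence_rate, s$fluence_rate, tolerance = 1e-12)
  expect_equal(r$grid$centers, s$grid$centers)
  unlink(f)
})
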