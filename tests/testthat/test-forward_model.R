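test_that("effective pixel size follows the magnification ratio", {
  expect_equal(effective_pixel_size(74.8, 15.3, 16.4), 69.78,
               tolerance = 0.0005)
  expect_equal(round(effective_pixel_size(74.8, 15.3, 16.4) / 10) * 10, 70)
  expect_equal(effective_pixel_size(100, 5, 5), 100)   # unit magnification
  expect_equal(effective_pixel_size(100, 5, 20),
               effective_pixel_size(100, 5, 10) / 2)   # proportionality
  expect_error(effective_pixel_size(-1, 1, 2), "positive")
})

test_that("geometry invariants are enforced", {
  expect_error(ct_geometry(source_sample_m = 17, source_detector_m = 16.4),
               "source_detector_m > source_sample_m")
  g <- ct_geometry(n_angles = 1000)
  expect_equal(length(g$angles_deg), 1000)
  expect_equal(diff(g$angles_deg)[1], 0.36)
  expect_lt(max(g$angles_deg), 360)
})

test_that("line integrals of a zero map vanish and need a matched geometry", {
  z <- mu_map(matrix(0, 64, 64), 0.56)
  expect_true(all(line_integrals(z, test_geometry(8, 0.56)) == 0))
  expect_error(line_integrals(z, test_geometry(8, 0.2)), "does not match")
})

test_that("rotating the map 90 degrees permutes the angle axis", {
  n <- 64
  m <- matrix(0, n, n); m[12:20, 40:52] <- 0.3
  geo <- test_geometry(4, 0.56)
  s1 <- line_integrals(mu_map(m, 0.56), geo)
  s2 <- line_integrals(mu_map(t(m)[n:1, ], 0.56), geo)   # rotate +90
  perms <- list(c(2, 3, 4, 1), c(4, 1, 2, 3))
  errs <- vapply(perms, function(p) max(abs(s2[p, ] - s1)), numeric(1))
  expect_lt(min(errs), 1e-8)
})

test_that("a monochromatic spectrum reduces to exp(-line integrals)", {
  ph <- kidney_phantom(n = 96, voxel_size_mm = 0.38, seed = 2)
  g <- energy_grid()
  phi <- numeric(length(g$centers))
  phi[which.min(abs(g$centers - 33.18))] <- 1e10
  mono <- structure(list(grid = g, fluence_rate = phi, label = "mono"),
                    class = "kesct_spectrum")
  geo <- test_geometry(12, 0.38)
  scan <- polychromatic_projection(ph, mono, geo, noise = FALSE)
  e_bin <- g$centers[which.min(abs(g$centers - 33.18))]
  oracle <- exp(-line_integrals(render_mu_map(ph, e_bin), geo))
  expect_equal(scan$transmission, oracle, tolerance = 1e-12)
})

test_that("empty phantom transmits (near) unity", {
  ph <- phantom_spec(c(48, 48), 0.75, list())
  sp <- model_spectrum(source_config())
  geo <- test_geometry(6, 0.75)
  scan <- polychromatic_projection(ph, sp, geo, noise = FALSE)
  expect_true(all(scan$transmission <= 1))
  expect_true(all(scan$transmission > 0.998))  # air only attenuates ~1e-3
})

test_that("slab transmission matches a two-bin hand computation", {
  g <- energy_grid()
  phi <- numeric(length(g$centers))
  i1 <- which.min(abs(g$centers - 30)); i2 <- which.min(abs(g$centers - 35))
  phi[i1] <- 2e9; phi[i2] <- 1e9
  s <- structure(list(grid = g, fluence_rate = phi, label = "2bin"),
                 class = "kesct_spectrum")
  d <- 20  # mm of water
  e1 <- g$centers[i1]; e2 <- g$centers[i2]
  mu1 <- linear_attenuation("water", e1); mu2 <- linear_attenuation("water", e2)
  hand <- (e1 * 2e9 * exp(-mu1 * d) + e2 * 1e9 * exp(-mu2 * d)) /
    (e1 * 2e9 + e2 * 1e9)
  expect_equal(slab_transmission("water", d, s), hand, tolerance = 1e-12)
  # photon-counting weighting drops the energy factors
  hand_pc <- (2e9 * exp(-mu1 * d) + 1e9 * exp(-mu2 * d)) / 3e9
  expect_equal(slab_transmission("water", d, s, detector = "photon_counting"),
               hand_pc, tolerance = 1e-12)
})

test_that("the edge-straddling beam hardens in iodinated water, mono does not", {
  sp <- default_spectra()$unfiltered
  depths <- seq(2, 30, by = 4)
  t_poly <- slab_transmission(iodinated_water(51.5), depths, sp)
  mu_eff <- -log(t_poly) / depths
  expect_true(all(diff(mu_eff) < 0))  # effective mu falls with depth
  g <- energy_grid()
  phi <- numeric(length(g$centers)); phi[which.min(abs(g$centers - 33.18))] <- 1e10
  mono <- structure(list(grid = g, fluence_rate = phi, label = "m"),
                    class = "kesct_spectrum")
  t_mono <- slab_transmission(iodinated_water(51.5), depths, mono)
  mu_mono <- -log(t_mono) / depths
  expect_lt(max(abs(diff(mu_mono))), 1e-12)
})

test_that("Poisson noise variance matches prediction at high counts", {
  ph <- phantom_spec(c(32, 32), 1.12,
                     list(phantom_primitive("disc", c(0, 0), 14,
                                            material = "water",
                                            label = "w")))
  sp <- model_spectrum(source_config())
  geo <- test_geometry(250, 1.12)
  base <- polychromatic_projection(ph, sp, geo, noise = FALSE)
  # raise exposure so every ray collects >= 1e4 photons
  expo <- 1e4 / (base$photons_per_pixel / 0.044 * min(base$transmission))
  noisy <- polychromatic_projection(ph, sp, geo, exposure_s = expo,
                                    noise = TRUE, seed = 123)
  n0 <- noisy$photons_per_pixel
  expect_gte(n0 * min(base$transmission), 1e4)
  z <- (noisy$transmission - base$transmission) /
    sqrt(base$transmission / n0)
  expect_equal(mean(z^2), 1, tolerance = 0.05)
  # determinism under a fixed seed
  again <- polychromatic_projection(ph, sp, geo, exposure_s = expo,
                                    noise = TRUE, seed = 123)
  expect_identical(noisy$transmission, again$transmission)
})

test_that("filtered transmission exceeds unfiltered on vessel rays", {
  ph <- test_phantom()
  sp <- default_spectra()
  geo <- test_geometry(8, 0.14)
  su <- polychromatic_projection(ph, sp$unfiltered, geo, noise = FALSE)
  sf <- polychromatic_projection(ph, sp$filtered, geo, noise = FALSE)
  # rays crossing vessels: project the vessel mask
  vm <- region_masks(ph)$vessel
  lv <- line_integrals(mu_map(vm * 1.0, 0.14), geo)
  vessel_rays <- lv > 1    # > 1 mm of vessel in the path
  expect_gt(sum(vessel_rays), 50)
  expect_true(all(sf$transmission[vessel_rays] >
                    su$transmission[vessel_rays]))
})

test_that("absorption is one minus transmission, clipped but raw kept", {
  t <- matrix(c(1, 0.044, 0.5, 1.2), 2, 2)
  a <- absorption_image(t)
  expect_equal(a[1, 1], 0)
  expect_equal(a[2, 1], 0.956)
  expect_equal(attr(a, "raw")[2, 2], -0.2)
  expect_equal(a[2, 2], 0)
  expect_error(absorption_image(matrix(-0.1)), ">= 0")
  # monotone decreasing in transmission
  tt <- seq(0, 1, 0.1)
  expect_true(all(diff(as.vector(absorption_image(matrix(tt, 1)))) < 0))
})
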