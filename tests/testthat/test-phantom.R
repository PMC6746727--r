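test_that("vessel and stone materials hit their calibration targets", {
  conc <- calibrate_vessel_concentration()
  rho <- calibrate_stone_density()
  expect_equal(linear_attenuation(iodinated_water(conc), 33.18), 0.2184,
               tolerance = 1e-9)
  stone <- make_mixture(c("whewellite", "weddellite"), c(0.9, 0.1),
                        "stone", density = rho)
  expect_equal(linear_attenuation(stone, 33.18), 0.2105, tolerance = 1e-9)
  # plausible physical ranges: tens of mg/ml iodine, roughly mineral density
  expect_gt(conc, 10); expect_lt(conc, 200)
  expect_gt(rho, 1); expect_lt(rho, 3)
})

test_that("the same seed reproduces the phantom bit-identically", {
  a <- kidney_phantom(n = 96, voxel_size_mm = 0.38, seed = 11)
  b <- kidney_phantom(n = 96, voxel_size_mm = 0.38, seed = 11)
  c <- kidney_phantom(n = 96, voxel_size_mm = 0.38, seed = 12)
  expect_identical(render_labels(a), render_labels(b))
  expect_false(identical(render_labels(a), render_labels(c)))
  # phantom generation must not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(kidney_phantom(n = 64, voxel_size_mm = 0.56,
                                         seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("region labels partition the grid and regions are present", {
  ph <- test_phantom()
  masks <- region_masks(ph)
  total <- Reduce(`+`, lapply(masks, sum))
  expect_equal(total, prod(ph$grid_shape))
  for (rn in c("air", "beaker", "water", "tissue", "vessel", "stone"))
    expect_gt(sum(masks[[rn]]), 0)
  # every voxel belongs to exactly one region
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_true(all(overlap == 1))
})

test_that("rendered maps carry the ground-truth attenuation", {
  ph <- test_phantom()
  masks <- region_masks(ph)
  mu <- render_mu_map(ph, 33.18)
  expect_equal(unique(unclass(mu)[masks$stone]), 0.2105, tolerance = 1e-9)
  expect_equal(unique(unclass(mu)[masks$vessel]), 0.2184, tolerance = 1e-9)
  gt <- phantom_ground_truth(ph, c(33.18, 32.59))
  expect_equal(gt$mu_at_33.18[gt$region == "vessel"], 0.2184,
               tolerance = 1e-9)
  expect_equal(gt$mu_at_33.18[gt$region == "stone"], 0.2105,
               tolerance = 1e-9)
  # the stone/vessel contrast at the calibration energy is below 0.008/mm
  expect_lt(abs(0.2184 - 0.2105), 0.008)
})

test_that("iodine vessels straddle the edge; the stone does not", {
  ph <- test_phantom()
  masks <- region_masks(ph)
  lo <- render_mu_map(ph, 32.59)
  hi <- render_mu_map(ph, 33.69)
  expect_lt(mean(unclass(lo)[masks$vessel]), mean(unclass(hi)[masks$vessel]))
  # calcium oxalate attenuates smoothly: lower energy, higher mu
  expect_gt(mean(unclass(lo)[masks$stone]), mean(unclass(hi)[masks$stone]))
})

test_that("rendered mu scales linearly with a density override", {
  m1 <- material("x1", density = 1.1, table = "water")
  m2 <- material("x2", density = 2.2, table = "water")
  p1 <- phantom_spec(c(32, 32), 1,
                     list(phantom_primitive("disc", c(0, 0), 8,
                                            material = m1, label = "d")))
  p2 <- phantom_spec(c(32, 32), 1,
                     list(phantom_primitive("disc", c(0, 0), 8,
                                            material = m2, label = "d")))
  r1 <- render_mu_map(p1, 33); r2 <- render_mu_map(p2, 33)
  inside <- unclass(r1) > 0.01
  expect_equal(unclass(r2)[inside], 2 * unclass(r1)[inside],
               tolerance = 1e-12)
})

test_that("an empty phantom renders to (near-vacuum) air", {
  p <- phantom_spec(c(16, 16), 1, list())
  r <- render_mu_map(p, 33.18)
  expect_true(all(unclass(r) < 1e-4))     # air is ~2.6e-5 1/mm
  expect_true(all(unclass(r) >= 0))
})

test_that("disc phantom line integrals have the analytic closed form", {
  n <- 128; vox <- 0.28; r <- 10; mu <- 0.2
  d <- disc_phantom(r, mu, n, vox)
  geo <- test_geometry(4, vox)
  sino <- line_integrals(d, geo)
  s <- (seq_len(n) - (n + 1) / 2) * vox
  oracle <- ifelse(abs(s) < r, 2 * mu * sqrt(pmax(r^2 - s^2, 0)), 0)
  # central ray = 2 mu r; outside rays zero; interior rays < 1% error
  expect_equal(sino[1, which.min(abs(s))], 2 * mu * r, tolerance = 0.005)
  expect_true(all(sino[1, abs(s) > r + 2 * vox] < 1e-6))
  inside <- abs(s) < 0.8 * r
  expect_lt(max(abs(sino[1, inside] - oracle[inside]) / oracle[inside]),
            0.01)
  # area consistency: integral over s equals mu * pi * r^2
  expect_equal(sum(sino[1, ]) * vox, mu * pi * r^2, tolerance = 0.002)
})

test_that("vessel placement failure raises a placement error", {
  expect_error(kidney_phantom(n = 96, voxel_size_mm = 0.1, n_vessels = 10,
                              vessel_radius_mm = c(2.4, 2.5), seed = 3,
                              max_tries = 5),
               "placement")
})
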