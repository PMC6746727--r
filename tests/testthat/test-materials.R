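test_that("interpolation returns stored values exactly at grid nodes", {
  tab <- raw_table("water")
  idx <- c(1, 25, 90, nrow(tab))
  got <- mass_attenuation("water", tab$energy_keV[idx])
  expect_equal(got, tab$mu_over_rho_cm2_g[idx], tolerance = 1e-12)
})

test_that("interpolated values stay between bracketing samples", {
  tab <- raw_table("iodine")
  set.seed(42)
  for (q in runif(50, 15.1, 59.9)) {
    lo <- max(which(tab$energy_keV <= q))
    hi <- min(which(tab$energy_keV > q))
    v <- mass_attenuation("iodine", q)
    expect_gte(v, min(tab$mu_over_rho_cm2_g[c(lo, hi)]) * (1 - 1e-12))
    expect_lte(v, max(tab$mu_over_rho_cm2_g[c(lo, hi)]) * (1 + 1e-12))
  }
})

test_that("iodine has exactly one K edge in range and the jump exceeds 1", {
  tab <- attenuation_table("iodine")
  expect_equal(length(tab$edges), 1L)
  expect_equal(tab$edges, iodine_k_edge(), tolerance = 1e-6)
  eps <- 1e-6
  below <- mass_attenuation("iodine", iodine_k_edge() - eps)
  above <- mass_attenuation("iodine", iodine_k_edge() + eps)
  expect_gt(above, below)
  expect_gt(above / below, 4)   # K-shell jump ratio for iodine is ~5.5
  # an exact-edge query returns the below-edge branch
  expect_lt(mass_attenuation("iodine", iodine_k_edge()), below * 1.001)
})

test_that("energy outside the table range is a range error", {
  expect_error(mass_attenuation("water", 14.5), "outside")
  expect_error(mass_attenuation("water", 61), "outside")
  expect_error(kes_material("unobtainium"), "unknown material")
})

test_that("whewellite equals the hand-summed elemental mixture", {
  # CaC2O4.H2O mass fractions from atomic masses
  m <- c(Ca = 40.078, C = 2 * 12.011, O = 5 * 15.999, H = 2 * 1.008)
  w <- m / sum(m)
  hand <- function(e)
    w[["Ca"]] * mass_attenuation("calcium", e) +
    w[["C"]] * mass_attenuation("carbon", e) +
    w[["O"]] * mass_attenuation("oxygen", e) +
    w[["H"]] * mass_attenuation("hydrogen", e)
  # the packaged compound table carries the exact sum at its grid nodes
  for (e in c(20, 33.25, 33.5, 45, 59))
    expect_equal(mass_attenuation("whewellite", e), hand(e),
                 tolerance = 1e-9)
  # off-node (33.18 keV) the independently interpolated tables agree to
  # interpolation accuracy only ...
  expect_equal(mass_attenuation("whewellite", 33.18), hand(33.18),
               tolerance = 1e-5)
  # ... while the mixture operation reproduces the hand sum exactly there
  mix <- make_mixture(c("calcium", "carbon", "oxygen", "hydrogen"),
                      unname(w), "whewellite_by_elements", density = 2.23)
  expect_equal(mass_attenuation(mix, 33.18), hand(33.18),
               tolerance = 1e-12)
})

test_that("mixtures are linear in their mass fractions", {
  mix <- make_mixture(c("whewellite", "weddellite"), c(0.9, 0.1),
                      "stone", density = 2.0)
  for (e in c(16, 25, 33.18, 40, 58)) {
    hand <- 0.9 * mass_attenuation("whewellite", e) +
      0.1 * mass_attenuation("weddellite", e)
    expect_equal(mass_attenuation(mix, e), hand, tolerance = 1e-14)
  }
  # identity and idempotence
  one <- make_mixture("water", 1, "w1", density = 1)
  self <- make_mixture(c("water", "water"), c(0.5, 0.5), "w2", density = 1)
  e <- seq(16, 59, by = 2.5)
  expect_equal(mass_attenuation(one, e), mass_attenuation("water", e))
  expect_equal(mass_attenuation(self, e), mass_attenuation("water", e),
               tolerance = 1e-15)
})

test_that("mixture fractions must sum to one", {
  expect_error(make_mixture(c("water", "iodine"), c(0.6, 0.5), "x", 1),
               "sum to 1")
  expect_error(make_mixture(c("water", "iodine"), c(-0.1, 1.1), "x", 1),
               "\\[0, 1\\]")
})

test_that("linear attenuation is mass attenuation times density, in 1/mm", {
  tab <- raw_table("water")
  i <- which.min(abs(tab$energy_keV - 33.25))
  e <- tab$energy_keV[i]
  hand <- tab$mu_over_rho_cm2_g[i] * 0.998 / 10
  expect_equal(linear_attenuation("water", e), hand, tolerance = 1e-12)
  # density 0 gives 0; doubling density doubles the output
  void <- material("void", density = 0, table = "water")
  expect_identical(linear_attenuation(void, 33), 0)
  heavy <- material("heavy_water", density = 2 * 0.998, table = "water")
  expect_equal(linear_attenuation(heavy, e),
               2 * linear_attenuation("water", e))
})

test_that("iodinated water adds solute attenuation on top of water", {
  sol <- iodinated_water(50)
  e <- 34
  hand <- 0.050 * mass_attenuation("iodine", e) / 10 +
    0.998 * mass_attenuation("water", e) / 10
  expect_equal(linear_attenuation(sol, e), hand, tolerance = 1e-12)
})
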