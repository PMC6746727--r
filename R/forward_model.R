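#' Parallel-beam CT geometry
#'
#' The source-to-sample distance (15.3 m) is three orders of magnitude
#' larger than the sample, so the cone angle is negligible and rays are
#' treated as parallel; the finite distances enter only through the
#' magnification that maps detector pixels to the effective pixel size at
#' the sample.
#'
#' @param n_angles Number of equally spaced projections.
#' @param span_deg Angular span in degrees (360 for the full protocol).
#' @param source_sample_m,source_detector_m Distances in metres
#'   (`source_detector_m > source_sample_m > 0`).
#' @param detector_pixel_um Detector pixel pitch in micrometres.
#' @param n_detector_bins Number of detector bins per projection; defaults
#'   to the phantom grid size when used.
#' @return Object of class `ct_geometry` with an `angles_deg` vector.
#' @export
ct_geometry <- function(n_angles = 1000, span_deg = 360,
                        source_sample_m = 15.3, source_detector_m = 16.4,
                        detector_pixel_um = 74.8, n_detector_bins = NULL) {
  if (!(source_detector_m > source_sample_m && source_sample_m > 0))
    stop("need source_detector_m > source_sample_m > 0", call. = FALSE)
  stopifnot(n_angles >= 1, span_deg > 0)
  angles <- seq(0, span_deg, length.out = n_angles + 1)[-(n_angles + 1)]
  structure(list(n_angles = n_angles, span_deg = span_deg,
                 angles_deg = angles, source_sample_m = source_sample_m,
                 source_detector_m = source_detector_m,
                 detector_pixel_um = detector_pixel_um,
                 n_detector_bins = n_detector_bins),
            class = "ct_geometry")
}

#' Effective pixel size at the sample position
#'
#' Detector pixels are demagnified onto the sample plane by the distance
#' ratio: `detector_pixel_um * source_sample_m / source_detector_m`.
#' With the 74.8 um detector at 15.3 m / 16.4 m this gives 69.78 um,
#' i.e. the protocol's 70 um effective pixels.
#'
#' @inheritParams ct_geometry
#' @return Effective pixel size in micrometres.
#' @export
effective_pixel_size <- function(detector_pixel_um = 74.8,
                                 source_sample_m = 15.3,
                                 source_detector_m = 16.4) {
  if (detector_pixel_um <= 0 || source_sample_m <= 0 ||
      source_detector_m <= 0)
    stop("all geometry inputs must be positive", call. = FALSE)
  detector_pixel_um * source_sample_m / source_detector_m
}

# Bilinear rotation about the grid centre; zero fill outside.  Rotating the
# *image* by +angle and summing columns realises the projection at that
# angle (rotate-and-sum Radon transform).
rotate_bilinear <- function(m, angle_deg) {
  n <- nrow(m)
  th <- angle_deg * pi / 180
  c0 <- (n + 1) / 2
  idx <- seq_len(n) - c0
  # inverse rotation of output coords (row=y, col=x)
  x <- matrix(idx, n, n, byrow = TRUE); y <- matrix(idx, n, n)
  xs <- cos(th) * x + sin(th) * y + c0
  ys <- -sin(th) * x + cos(th) * y + c0
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 <= n - 1 & y0 >= 1 & y0 <= n - 1
  out <- matrix(0, n, n)
  i00 <- (x0 - 1) * n + y0
  v <- numeric(sum(ok))
  o <- which(ok)
  v <- (1 - fx[o]) * ((1 - fy[o]) * m[i00[o]] + fy[o] * m[i00[o] + 1]) +
    fx[o] * ((1 - fy[o]) * m[i00[o] + n] + fy[o] * m[i00[o] + n + 1])
  out[o] <- v
  out
}

#' Parallel-beam line integrals (Radon transform)
#'
#' Computes `integral of mu dl` along parallel rays for every projection
#' angle by rotating the map (bilinear interpolation) and summing along
#' the beam direction.  The result is dimensionless (1/mm times mm).
#'
#' @param mu_map A [mu_map()] (values in 1/mm).
#' @param geometry A [ct_geometry()]; its effective pixel size must match
#'   the map's voxel size within 1%, and the number of detector bins must
#'   equal the grid size.
#' @return Matrix of path integrals, `n_angles` rows x `n` detector bins.
#' @export
line_integrals <- function(mu_map, geometry) {
  stopifnot(inherits(mu_map, "mu_map"), inherits(geometry, "ct_geometry"))
  check_geometry_match(mu_map, geometry)
  n <- nrow(mu_map)
  vox <- attr(mu_map, "voxel_size_mm")
  m <- unclass(mu_map)
  sino <- matrix(0, geometry$n_angles, n)
  for (i in seq_len(geometry$n_angles))
    sino[i, ] <- colSums(rotate_bilinear(m, geometry$angles_deg[i])) * vox
  sino
}

check_geometry_match <- function(mu_map, geometry) {
  eff <- effective_pixel_size(geometry$detector_pixel_um,
                              geometry$source_sample_m,
                              geometry$source_detector_m) / 1000
  vox <- attr(mu_map, "voxel_size_mm")
  if (abs(eff / vox - 1) > 0.01)
    stop(sprintf(paste("effective pixel size (%.4f mm) does not match the",
                       "map voxel size (%.4f mm) within 1%%;",
                       "adjust detector_pixel_um"), eff, vox),
         call. = FALSE)
  if (!is.null(geometry$n_detector_bins) &&
      geometry$n_detector_bins != nrow(mu_map))
    stop("n_detector_bins must equal the phantom grid size", call. = FALSE)
  invisible(TRUE)
}

#' Photons incident per detector pixel
#'
#' The total source flux is spread over the elliptic beam footprint at the
#' detector (62 x 74 mm^2 for the 4 mrad opening at 16.4 m), giving the
#' fluence normalisation for shot noise.
#'
#' @param flux Total photon flux, photons/s.
#' @param exposure_s Exposure time per projection, s.
#' @param detector_pixel_um Detector pixel pitch, um.
#' @param beam_area_mm2 Beam footprint area at the detector, mm^2.
#' @return Expected photon count per pixel per projection.
#' @export
photons_per_pixel <- function(flux = 1.3e10, exposure_s = 0.044,
                              detector_pixel_um = 74.8,
                              beam_area_mm2 = beam_area_at()) {
  stopifnot(flux > 0, exposure_s > 0, beam_area_mm2 > 0)
  flux * exposure_s * (detector_pixel_um / 1000)^2 / beam_area_mm2
}

#' Elliptic beam footprint area
#'
#' @param distance_m Distance from the source, m.
#' @param axes_mm Full beam extent `c(width, height)` in mm at
#'   `ref_distance_m`.
#' @param ref_distance_m Distance at which `axes_mm` is specified.
#' @return Beam area in mm^2 at `distance_m`.
#' @export
beam_area_at <- function(distance_m = 16.4, axes_mm = c(62, 74),
                         ref_distance_m = 16.4) {
  stopifnot(distance_m > 0)
  pi * prod(axes_mm / 2) * (distance_m / ref_distance_m)^2
}

# Coarsen a spectrum to quadrature bins for the projection energy sum:
# per coarse bin, total fluence and fluence-weighted mean energy.
spectrum_quadrature <- function(spectrum, quad_bin_keV) {
  e <- spectrum$grid$centers; phi <- spectrum$fluence_rate
  keep <- phi > max(phi) * 1e-12
  e <- e[keep]; phi <- phi[keep]
  if (quad_bin_keV <= spectrum$grid$bin_width)
    return(list(energy = e, fluence = phi))
  grp <- floor((e - min(e)) / quad_bin_keV)
  # never merge across the iodine K edge
  grp <- grp + 0.5 * (e > iodine_k_edge())
  f <- tapply(phi, grp, sum)
  em <- tapply(phi * e, grp, sum) / f
  list(energy = as.numeric(em), fluence = as.numeric(f))
}

#' Polychromatic forward projection of a phantom
#'
#' Simulates one CT scan: per ray, the detected transmission is
#' `T = sum_E w(E) Phi(E) exp(-integral mu(E) dl) / sum_E w(E) Phi(E)`
#' with detector weight `w(E) = E` for the energy-integrating scintillator
#' (set `detector = "photon_counting"` for `w = 1`).  Path integrals are
#' computed once per material region and reused across energies.  With
#' `noise = TRUE`, detected counts are drawn Poisson with mean equal to
#' the incident photons per pixel times the transmission, then flat-field
#' normalised by the expected incident counts; the draw is deterministic
#' under a fixed `seed`.
#'
#' @param phantom A `phantom_spec`.
#' @param spectrum The illuminating `kesct_spectrum`.
#' @param geometry A [ct_geometry()].
#' @param exposure_s Exposure per projection, s.
#' @param noise Add Poisson counting noise?
#' @param seed RNG seed for the noise draw.
#' @param detector Energy weighting model.
#' @param quad_bin_keV Width of the spectral quadrature bins used in the
#'   energy sum (the spectrum itself stays on its fine grid); bins never
#'   merge across the iodine K-edge.
#' @param beam_area_mm2 Beam footprint at the detector for the photon
#'   budget.
#' @return Object of class `ct_scan`: list with the `transmission` matrix
#'   (`n_angles` x n, noiseless values in (0, 1]), acquisition metadata
#'   and the spectrum's mean energy.
#' @export
polychromatic_projection <- function(phantom, spectrum, geometry,
                                     exposure_s = 0.044, noise = FALSE,
                                     seed = NULL,
                                     detector = c("energy_integrating",
                                                  "photon_counting"),
                                     quad_bin_keV = 0.1,
                                     beam_area_mm2 = beam_area_at()) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(spectrum, "kesct_spectrum"))
  detector <- match.arg(detector)
  if (sum(spectrum$fluence_rate) <= 0)
    stop("zero-flux spectrum", call. = FALSE)
  vox <- phantom$voxel_size_mm
  masks <- region_masks(phantom)
  mats <- list(air = kes_material("air"))
  for (p in phantom$primitives) mats[[p$label]] <- p$material
  # per-region path-length sinograms (mm)
  L <- lapply(names(masks), function(lb) {
    mm <- mu_map(masks[[lb]] * 1.0, vox)
    line_integrals(mm, geometry)
  })
  names(L) <- names(masks)

  q <- spectrum_quadrature(spectrum, quad_bin_keV)
  w <- if (detector == "energy_integrating") q$energy else rep(1, length(q$energy))
  mu_reg <- vapply(names(L), function(lb)
    linear_attenuation(mats[[lb]], q$energy),
    numeric(length(q$energy)))
  if (is.null(dim(mu_reg))) mu_reg <- matrix(mu_reg, nrow = 1)

  num <- 0; den <- sum(w * q$fluence)
  for (k in seq_along(q$energy)) {
    A <- 0
    for (j in seq_along(L)) A <- A + mu_reg[k, j] * L[[j]]
    num <- num + (w[k] * q$fluence[k]) * exp(-A)
  }
  trans <- num / den

  n0 <- photons_per_pixel(sum(spectrum$fluence_rate), exposure_s,
                          geometry$detector_pixel_um, beam_area_mm2)
  if (noise) {
    draw <- function() {
      cnt <- rpois(length(trans), n0 * trans)
      matrix(cnt / n0, nrow(trans), ncol(trans))
    }
    trans <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  structure(list(transmission = trans, geometry = geometry,
                 exposure_s = exposure_s,
                 flux = sum(spectrum$fluence_rate),
                 mean_energy = mean_energy(spectrum),
                 label = spectrum$label, noise = noise, seed = seed,
                 photons_per_pixel = n0,
                 voxel_size_mm = vox),
            class = "ct_scan")
}

#' @export
print.ct_scan <- function(x, ...) {
  cat(sprintf(paste0("<ct_scan> '%s': %d angles x %d bins, mean energy ",
                     "%.3f keV, %s\n"),
              x$label, nrow(x$transmission), ncol(x$transmission),
              x$mean_energy,
              if (x$noise) sprintf("Poisson noise (%.0f ph/px)",
                                   x$photons_per_pixel) else "noiseless"))
  invisible(x)
}

#' Transmission through a uniform slab
#'
#' Direct Beer--Lambert evaluation (no imaging), used for beam-hardening
#' and noise diagnostics:
#' `T(d) = sum w(E) Phi(E) exp(-mu(E) d) / sum w(E) Phi(E)`.
#'
#' @param material Slab material (name or `kesct_material`).
#' @param thickness_mm Slab thicknesses, mm (vectorised).
#' @param spectrum Illuminating spectrum.
#' @param detector Energy weighting as in [polychromatic_projection()].
#' @return Transmission values in (0, 1].
#' @export
slab_transmission <- function(material, thickness_mm, spectrum,
                              detector = c("energy_integrating",
                                           "photon_counting")) {
  detector <- match.arg(detector)
  e <- spectrum$grid$centers; phi <- spectrum$fluence_rate
  w <- if (detector == "energy_integrating") e else 1
  mu <- linear_attenuation(material, e)
  vapply(thickness_mm, function(d)
    sum(w * phi * exp(-mu * d)) / sum(w * phi), numeric(1))
}

#' Absorption image
#'
#' `A = 1 - T`, the convention used for projection grey values.  Reported
#' values are clipped at zero; the unclipped values are kept in the
#' `"raw"` attribute.
#'
#' @param transmission Transmission values (matrix or `ct_scan`).
#' @return Absorption values with attribute `raw`.
#' @export
absorption_image <- function(transmission) {
  if (inherits(transmission, "ct_scan"))
    transmission <- transmission$transmission
  if (any(transmission < 0)) stop("transmission must be >= 0", call. = FALSE)
  raw <- 1 - transmission
  structure(pmax(raw, 0), raw = raw)
}
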