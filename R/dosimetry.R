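#' Air kerma rate of a beam
#'
#' Kinetic energy released per unit mass of air:
#' `K = sum_E (Phi(E)/area) * E * (mu_en/rho)_air(E)`, converted to mGy/s.
#' The air mass energy-absorption coefficients are packaged as a table
#' (NIST values, log-log interpolated).
#'
#' @param spectrum A `kesct_spectrum` (fluence rate in photons/s per bin).
#' @param beam_area_mm2 Beam cross-section over which the flux is spread,
#'   mm^2 (> 0); see [beam_area_at()].
#' @return Air kerma rate in mGy/s.
#' @examples
#' s <- model_spectrum(source_config())
#' air_kerma_rate(s, beam_area_at(15.3))   # at the sample position
#' @export
air_kerma_rate <- function(spectrum, beam_area_mm2) {
  stopifnot(inherits(spectrum, "kesct_spectrum"))
  if (beam_area_mm2 <= 0) stop("beam area must be positive", call. = FALSE)
  e <- spectrum$grid$centers
  phi <- spectrum$fluence_rate
  if (all(phi == 0)) return(0)
  mu_en <- air_mass_energy_absorption(e)            # cm^2/g
  fluence_cm2 <- phi / (beam_area_mm2 / 100)        # ph / (s cm^2) per bin
  e_joule <- e * 1.602176634e-16
  gy_per_s <- sum(fluence_cm2 * e_joule * mu_en * 1000)  # J/kg/s
  gy_per_s * 1000                                   # mGy/s
}

#' @rdname air_kerma_rate
#' @param energy Energies in keV (vectorised).
#' @export
air_mass_energy_absorption <- function(energy) {
  tab <- .kesct$air_mu_en
  if (is.null(tab)) {
    path <- system.file("extdata", "attenuation", "air_mu_en.tsv",
                        package = "kesct")
    tab <- read.delim(path)
    .kesct$air_mu_en <- tab
  }
  if (any(energy < min(tab$energy_keV) | energy > max(tab$energy_keV)))
    stop("energy outside the air mu_en table range", call. = FALSE)
  exp(approx(log(tab$energy_keV), log(tab$mu_en_over_rho_cm2_g),
             xout = log(energy))$y)
}

#' Dose report for an acquisition protocol
#'
#' Accumulates air kerma over the scans of a protocol and converts to
#' effective dose with a kerma-to-effective-dose conversion coefficient
#' for kidney tissue.  The default coefficient, 0.2587 Sv/Gy, is the value
#' implied by the reported 10.32 mGy total kerma and 2.67 mSv effective
#' dose of the two-scan protocol.
#'
#' @param kerma_rates_mGy_s Named vector of per-scan kerma rates, mGy/s.
#' @param scan_times_s Scan durations in seconds (recycled if scalar);
#'   each scan of the reference protocol lasts 1000 x 44 ms = 44 s.
#' @param conversion_sv_per_gy Effective-dose conversion coefficient.
#' @return Object of class `dose_report`: list with per-scan kerma,
#'   `total_kerma_mGy` and `effective_dose_mSv`.
#' @examples
#' total_dose(c(unfiltered = 0.16, filtered = 0.07), 44)
#' @export
total_dose <- function(kerma_rates_mGy_s, scan_times_s,
                       conversion_sv_per_gy = 0.2587) {
  if (any(scan_times_s <= 0)) stop("scan times must be > 0", call. = FALSE)
  if (conversion_sv_per_gy < 0)
    stop("conversion coefficient must be >= 0", call. = FALSE)
  scan_times_s <- rep(scan_times_s, length.out = length(kerma_rates_mGy_s))
  per_scan <- kerma_rates_mGy_s * scan_times_s
  structure(list(kerma_rates_mGy_s = kerma_rates_mGy_s,
                 scan_times_s = scan_times_s,
                 kerma_per_scan_mGy = per_scan,
                 total_kerma_mGy = sum(per_scan),
                 conversion_sv_per_gy = conversion_sv_per_gy,
                 effective_dose_mSv = sum(per_scan) * conversion_sv_per_gy),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n")
  for (i in seq_along(x$kerma_rates_mGy_s))
    cat(sprintf("  %-12s %.4f mGy/s x %.1f s = %.3f mGy\n",
                names(x$kerma_rates_mGy_s)[i] %||% paste0("scan", i),
                x$kerma_rates_mGy_s[i], x$scan_times_s[i],
                x$kerma_per_scan_mGy[i]))
  cat(sprintf("  total air kerma  %.3f mGy\n", x$total_kerma_mGy))
  cat(sprintf("  effective dose   %.3f mSv (%.4f Sv/Gy)\n",
              x$effective_dose_mSv, x$conversion_sv_per_gy))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a dose report
#'
#' Round-trips losslessly through a DCF text file (full double
#' precision).
#'
#' @param report A `dose_report`.
#' @param path File path.
#' @return `read_dose_report()` returns the `dose_report`.
#' @export
write_dose_report <- function(report, path) {
  stopifnot(inherits(report, "dose_report"))
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  dcf <- rbind(c(scan_labels = paste(names(report$kerma_rates_mGy_s),
                                     collapse = " "),
                 kerma_rates_mGy_s = num(report$kerma_rates_mGy_s),
                 scan_times_s = num(report$scan_times_s),
                 conversion_sv_per_gy = num(report$conversion_sv_per_gy)))
  write.dcf(dcf, path)
  invisible(path)
}

#' @rdname write_dose_report
#' @export
read_dose_report <- function(path) {
  d <- as.list(read.dcf(path)[1, ])
  nums <- function(x) as.numeric(strsplit(x, " +")[[1]])
  rates <- nums(d$kerma_rates_mGy_s)
  names(rates) <- strsplit(d$scan_labels, " +")[[1]]
  total_dose(rates, nums(d$scan_times_s), nums(d$conversion_sv_per_gy))
}
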