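#' Filtered backprojection reconstruction
#'
#' Standard parallel-beam FBP of `-log(T)`: each projection is ramp
#' filtered in the Fourier domain (optionally Hann apodised), then
#' backprojected with linear interpolation.  Transmissions are floored at
#' `floor` before the log to guard against Poisson zeros at low dose.
#' Voxels outside the circular field of view are set to zero.
#'
#' @param scan A `ct_scan` from [polychromatic_projection()], or a bare
#'   transmission matrix (then `geometry` and `voxel_size_mm` are
#'   required).
#' @param geometry A [ct_geometry()] (taken from the scan if missing).
#' @param filter_name `"ramp"` (default) or `"hann"`.
#' @param voxel_size_mm Reconstruction voxel size; defaults to the scan's.
#' @param floor Transmission floor applied before the log.
#' @return Object of class `recon_slice`: an n x n matrix of linear
#'   attenuation (1/mm) with attributes `voxel_size_mm`, `scan_label`,
#'   `mean_energy` and `fov_mask`.
#' @export
fbp <- function(scan, geometry = NULL, filter_name = c("ramp", "hann"),
                voxel_size_mm = NULL, floor = 1e-6) {
  filter_name <- match.arg(filter_name)
  x <- as_sinogram(scan, geometry, voxel_size_mm)
  trans <- x$transmission
  bad <- which(!is.finite(trans) | trans < 0)
  if (length(bad))
    stop("non-finite or negative transmission in rays: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  p <- -log(pmax(trans, floor))
  q <- ramp_filter(p, x$voxel_size_mm, filter_name)
  rec <- backproject(q, x$geometry$angles_deg, ncol(p), x$voxel_size_mm)
  rec <- rec * pi / x$geometry$n_angles
  finalize_recon(rec, x)
}

as_sinogram <- function(scan, geometry, voxel_size_mm) {
  if (inherits(scan, "ct_scan"))
    return(list(transmission = scan$transmission, geometry = scan$geometry,
                voxel_size_mm = scan$voxel_size_mm,
                scan_label = scan$label, mean_energy = scan$mean_energy))
  if (is.null(geometry) || is.null(voxel_size_mm))
    stop("geometry and voxel_size_mm are required for a bare sinogram",
         call. = FALSE)
  list(transmission = scan, geometry = geometry,
       voxel_size_mm = voxel_size_mm, scan_label = "sinogram",
       mean_energy = NA_real_)
}

finalize_recon <- function(rec, x) {
  n <- ncol(rec)
  cc <- pixel_coords(n, 1)
  fov <- outer(cc^2, cc^2, `+`) <= (n / 2)^2
  rec[!fov] <- 0
  structure(rec, voxel_size_mm = x$voxel_size_mm,
            scan_label = x$scan_label, mean_energy = x$mean_energy,
            fov_mask = fov, class = c("recon_slice", "matrix", "array"))
}

# Band-limited ramp filter: frequency response taken as the DFT of the
# spatial-domain ramp kernel (Kak & Slaney), which avoids the DC bias of
# the ideal |f| response on zero-padded projections.
ramp_filter <- function(p, ds, filter_name) {
  n <- ncol(p)
  npad <- 2^ceiling(log2(2 * n))
  m <- c(0:(npad / 2), (npad / 2 - 1):1)        # circular offsets
  h <- numeric(npad)
  h[1] <- 1 / (4 * ds^2)
  odd <- m %% 2 == 1
  h[odd] <- -1 / (pi * m[odd] * ds)^2
  H <- Re(fft(h))
  if (filter_name == "hann") {
    freq <- m / (npad * ds)
    H <- H * 0.5 * (1 + cos(pi * freq / max(freq)))
  }
  pp <- rbind(t(p), matrix(0, npad - n, nrow(p)))  # npad x n_angles
  q <- Re(mvfft(mvfft(pp) * H, inverse = TRUE)) / npad * ds
  t(q[seq_len(n), , drop = FALSE])
}

# Backprojection with linear interpolation along the detector axis.
# q: n_angles x n filtered projections sampled at s = pixel_coords(n, ds).
backproject <- function(q, angles_deg, n, ds) {
  s <- pixel_coords(n, ds)
  cc <- pixel_coords(n, ds)
  x <- matrix(cc, n, n, byrow = TRUE); y <- matrix(cc, n, n)
  rec <- matrix(0, n, n)
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    sv <- x * cos(th) - y * sin(th)
    rec <- rec + matrix(approx(s, q[i, ], xout = as.vector(sv),
                               yleft = 0, yright = 0)$y, n, n)
  }
  rec
}

# Forward projector matched to line_integrals() for iterative use.
project_matrix <- function(m, angles_deg, vox) {
  sino <- matrix(0, length(angles_deg), nrow(m))
  for (i in seq_along(angles_deg))
    sino[i, ] <- colSums(rotate_bilinear(m, angles_deg[i])) * vox
  sino
}

# Pixel-driven sparse system matrix for iterative reconstruction: pixel
# values are spread linearly over the two nearest detector bins at each
# angle, scaled so that row sums approximate path lengths (mm).  Its exact
# transpose serves as the backprojector, which makes the SIRT normal
# operator symmetric and the iteration convergent.
system_matrix <- function(n, angles_deg, vox) {
  cc <- pixel_coords(n, vox)
  x <- rep(cc, each = n); y <- rep(cc, times = n)   # column-major pixels
  rows <- vector("list", 2 * length(angles_deg))
  cols <- vector("list", 2 * length(angles_deg))
  vals <- vector("list", 2 * length(angles_deg))
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    pos <- (x * cos(th) - y * sin(th) - cc[1]) / vox + 1
    i0 <- floor(pos); w <- pos - i0
    for (k in 0:1) {
      bin <- i0 + k
      wk <- if (k == 0) 1 - w else w
      ok <- which(bin >= 1 & bin <= n & wk > 0)
      j <- 2 * (i - 1) + k + 1
      rows[[j]] <- (i - 1L) * n + bin[ok]
      cols[[j]] <- ok
      vals[[j]] <- wk[ok] * vox
    }
  }
  Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), x = unlist(vals),
                       dims = c(length(angles_deg) * n, n * n))
}

#' Simultaneous iterative reconstruction (SIRT)
#'
#' Iterative least-squares reconstruction of `-log(T)`, provided as a
#' simple stand-in for the statistical iterative method used on the real
#' scans: `x <- x + relax * C * A'( R * (p - A x) )` with `A` a
#' pixel-driven sparse projector, `A'` its exact transpose, and `R`, `C`
#' the inverse row and column sums.  With `relax` in (0, 2) the residual
#' norm is non-increasing on consistent data; two consecutive residual
#' increases beyond round-off raise a convergence error.  Equivalence
#' with [fbp()] is expected at ROI level, not voxel level.
#'
#' @inheritParams fbp
#' @param n_iter Number of iterations (>= 1).
#' @param nonneg Clamp negative attenuation to zero after each step.
#' @param relax Relaxation factor in (0, 2).
#' @return A `recon_slice` with attribute `residuals` (per-iteration
#'   residual norms).
#' @export
sirt <- function(scan, geometry = NULL, n_iter = 50, nonneg = TRUE,
                 relax = 1, voxel_size_mm = NULL, floor = 1e-6) {
  stopifnot(n_iter >= 1, relax > 0, relax < 2)
  x <- as_sinogram(scan, geometry, voxel_size_mm)
  p <- -log(pmax(x$transmission, floor))
  n <- ncol(p); vox <- x$voxel_size_mm
  A <- system_matrix(n, x$geometry$angles_deg, vox)
  At <- Matrix::t(A)
  rs <- Matrix::rowSums(A); cs <- Matrix::colSums(A)
  R <- ifelse(rs > max(rs) * 0.01, 1 / rs, 0)
  C <- ifelse(cs > max(cs) * 0.01, 1 / cs, 0)
  pv <- as.vector(t(p))                      # angle-major ray order
  rec <- numeric(n * n)
  res <- numeric(n_iter)
  bad <- 0L
  for (it in seq_len(n_iter)) {
    r <- pv - as.vector(A %*% rec)
    res[it] <- sqrt(sum(r^2))
    grew <- it > 1 && res[it] > res[it - 1] * (1 + 1e-8)
    bad <- if (grew) bad + 1L else 0L
    if (bad >= 2L)
      stop("SIRT diverged: residual grew in two consecutive iterations",
           call. = FALSE)
    rec <- rec + relax * C * as.vector(At %*% (R * r))
    if (nonneg) rec[rec < 0] <- 0
  }
  out <- finalize_recon(matrix(rec, n, n), x)
  attr(out, "residuals") <- res
  out
}

#' ROI statistics on reconstructed or difference volumes
#'
#' Arithmetic mean and population standard deviation over the masked
#' voxels, the reporting convention for regional attenuation values.
#'
#' @param volume Numeric matrix (`recon_slice`, `kes_volume`, ...).
#' @param mask Logical matrix of the same shape, at least one `TRUE`.
#' @param region Region label for the output row.
#' @return A one-row data frame: `region`, `mean`, `sd`, `n_voxels`.
#' @export
roi_stats <- function(volume, mask, region = "roi") {
  if (!is.logical(mask) || !identical(dim(volume)[1:2], dim(mask)[1:2]))
    stop("mask must be a logical matrix matching the volume", call. = FALSE)
  v <- as.vector(volume)[as.vector(mask)]
  if (!length(v)) stop("empty ROI mask", call. = FALSE)
  data.frame(region = region, mean = mean(v),
             sd = sqrt(mean((v - mean(v))^2)), n_voxels = length(v))
}

#' Erode a region mask
#'
#' Shrinks a mask by `px` pixels (disc structuring element) so ROI
#' statistics exclude partial-edge voxels blurred by reconstruction.
#'
#' @param mask Logical matrix.
#' @param px Erosion radius in pixels.
#' @return Eroded logical matrix.
#' @export
erode_mask <- function(mask, px = 2) {
  if (px < 1) return(mask)
  m <- EBImage::erode(mask * 1, EBImage::makeBrush(2 * px + 1, "disc"))
  m > 0.5
}
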