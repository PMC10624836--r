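## Far-field forward model and dose bookkeeping.
##
## Coordinate convention used throughout: positions in nm, x to the right
## (columns), y down (rows); pixel (1,1) of a grid has its centre at the
## grid origin; a scan position marks the centre of the probe window, whose
## 0-based centre pixel is floor(n/2). For the forward model, sub-pixel
## positions are rounded to the nearest object pixel; interpolation is
## reserved for label extraction and stitching.

## 0-based start index (row or col) of an n-sized window centred at pos_nm
## on a grid with spacing px whose origin is at origin_nm.
window_start0 <- function(pos_nm, px, n, origin_nm = 0) {
  as.integer(round((pos_nm - origin_nm) / px)) - n %/% 2L
}

#' Simulate a ptychographic scan
#'
#' For each scan position, the exit wave is the probe times the local object
#' patch (object \eqn{= A e^{i\phi}}); its centred orthonormal 2-D Fourier
#' transform gives the far-field amplitude, and the intensity is scaled so
#' the expected photon count per frame is
#' `flux_scale * exposure_ms * sum(|psi|^2)`. With `poisson = TRUE`, frames
#' are integer Poisson draws at that expectation; otherwise the real-valued
#' expected counts are stored (so Parseval's identity holds exactly).
#'
#' @param phantom A [make_phantom()] object (its grid must use the probe's
#'   pixel size).
#' @param probe A [make_probe()] object.
#' @param plan A [make_spiral_scan()] plan; positions are interpreted
#'   relative to the phantom origin (pixel (1,1) centre at (0,0) nm).
#' @param geometry The [detector_geometry()] used (stored as metadata; the
#'   frame side is the probe window side).
#' @param exposure_ms Exposure time per frame in ms.
#' @param flux_scale Expected photons per unit probe power per ms. The
#'   default is calibrated so that the reference dense-scan scenario (963
#'   spiral points at 50 nm step with the 800 nm probe, 1 ms exposure)
#'   deposits an average dose near 2e4 photons/nm^2; doses are meaningful
#'   in ratio, not as absolute beamline calibration.
#' @param poisson Apply Poisson counting noise?
#' @param seed Seed for the Poisson draws.
#'
#' @return A `diffraction_stack`: `frames` (array N x N x n_points),
#'   `exposure_ms`, `flux_scale`, `plan`, `geometry`, `poisson`, `seed`.
#' @export
simulate_scan <- function(phantom, probe, plan, geometry,
                          exposure_ms = 1, flux_scale = 1e8,
                          poisson = TRUE, seed = 1L) {
  n <- nrow(probe$field)
  if (abs(probe$pixel_size_nm - phantom$pixel_size_nm) > 1e-9)
    stop_invalid("probe and phantom pixel sizes differ")
  px <- phantom$pixel_size_nm
  np <- plan$n_points
  obj <- phantom$amplitude * exp(1i * phantom$phase)
  nr <- nrow(obj); nc <- ncol(obj)
  frames <- array(0, dim = c(n, n, np))
  scale <- flux_scale * exposure_ms
  for (j in seq_len(np)) {
    c0 <- window_start0(plan$positions_nm[j, 1], px, n)  # 0-based col start
    r0 <- window_start0(plan$positions_nm[j, 2], px, n)  # 0-based row start
    if (r0 < 0 || c0 < 0 || r0 + n > nr || c0 + n > nc)
      stop_invalid("scan position %d falls outside the phantom grid", j)
    patch <- obj[r0 + seq_len(n), c0 + seq_len(n)]
    psi <- probe$field * patch
    I <- Mod(fft2c(psi))^2 * scale
    frames[, , j] <- I
  }
  if (poisson) {
    frames <- with_seed(seed, {
      array(stats::rpois(length(frames), lambda = as.vector(frames)),
            dim = dim(frames))
    })
  }
  structure(list(frames = frames, exposure_ms = exposure_ms,
                 flux_scale = flux_scale, plan = plan, geometry = geometry,
                 poisson = poisson, seed = seed),
            class = "diffraction_stack")
}

#' Accumulated photon dose map of a scan
#'
#' Deposits `flux_scale * exposure_ms * |P|^2` photons at each (rounded) scan
#' position onto a regular grid and divides by the pixel area, giving dose in
#' photons/nm^2. The average dose over the illuminated area (pixels receiving
#' more than 1% of the peak dose) is reported alongside.
#'
#' @param plan A `scan_plan`.
#' @param probe A `probe`.
#' @param flux_scale,exposure_ms Photon scaling, as in [simulate_scan()].
#' @param grid_spec Optional list with `origin_nm` (x, y) and `shape`
#'   (rows, cols); defaults to the scan bounding box padded by one probe
#'   window.
#' @return A `dose_image`: `grid` (photons/nm^2), `pixel_size_nm`,
#'   `origin_nm`, `average_dose`, `total_photons`.
#' @export
dose_map <- function(plan, probe, flux_scale = 1e8, exposure_ms = 1,
                     grid_spec = NULL) {
  if (plan$n_points < 1) stop_invalid("empty scan plan")
  n <- nrow(probe$field)
  px <- probe$pixel_size_nm
  pos <- plan$positions_nm
  if (is.null(grid_spec)) {
    origin <- c(floor(min(pos[, 1]) / px) * px - (n %/% 2 + 1) * px,
                floor(min(pos[, 2]) / px) * px - (n %/% 2 + 1) * px)
    shape <- c(ceiling((max(pos[, 2]) - origin[2]) / px) + n + 2,
               ceiling((max(pos[, 1]) - origin[1]) / px) + n + 2)
  } else {
    origin <- grid_spec$origin_nm; shape <- grid_spec$shape
  }
  grid <- matrix(0, shape[1], shape[2])
  footprint <- Mod(probe$field)^2 * flux_scale * exposure_ms / px^2
  for (j in seq_len(plan$n_points)) {
    c0 <- window_start0(pos[j, 1], px, n, origin[1])
    r0 <- window_start0(pos[j, 2], px, n, origin[2])
    if (r0 < 0 || c0 < 0 || r0 + n > shape[1] || c0 + n > shape[2])
      stop_invalid("dose grid does not contain position %d", j)
    grid[r0 + seq_len(n), c0 + seq_len(n)] <-
      grid[r0 + seq_len(n), c0 + seq_len(n)] + footprint
  }
  lit <- grid > 0.01 * max(grid)
  structure(list(grid = grid, pixel_size_nm = px, origin_nm = origin,
                 average_dose = mean(grid[lit]),
                 total_photons = sum(grid) * px^2),
            class = "dose_image")
}
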