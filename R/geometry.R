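#' Detector geometry
#'
#' Bundles the beam energy and detector parameters that fix the far-field
#' sampling of a ptychography experiment. The object-plane pixel size of any
#' reconstruction follows from these through [pixel_size_from_geometry()].
#'
#' @param energy_keV Photon energy in keV.
#' @param distance_m Sample--detector distance in metres.
#' @param n_pixels Side length of the (square) detector frame in pixels.
#' @param pixel_pitch_um Detector pixel size in micrometres.
#'
#' @return An object of class `detector_geometry` with the fields above plus
#'   the derived `wavelength_nm`.
#' @examples
#' g <- detector_geometry(10, 1.55, 512, 55)
#' pixel_size_from_geometry(g)  # 6.82 nm
#' @export
detector_geometry <- function(energy_keV, distance_m, n_pixels, pixel_pitch_um) {
  if (energy_keV <= 0 || distance_m <= 0 || n_pixels <= 0 || pixel_pitch_um <= 0)
    stop_invalid("all detector geometry fields must be positive")
  n_pixels <- as.integer(n_pixels)
  structure(
    list(energy_keV = energy_keV, distance_m = distance_m,
         n_pixels = n_pixels, pixel_pitch_um = pixel_pitch_um,
         wavelength_nm = 1.23984 / energy_keV),
    class = "detector_geometry")
}

#' Object-plane pixel size from the far-field sampling relation
#'
#' The reconstructed pixel size of far-field ptychography is
#' \eqn{\lambda z / (N p)} with wavelength \eqn{\lambda}, propagation distance
#' \eqn{z}, frame side \eqn{N} and detector pitch \eqn{p}.
#'
#' @param geometry A [detector_geometry()].
#' @return Pixel size in nanometres.
#' @export
pixel_size_from_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  lambda_nm <- geometry$wavelength_nm
  z_nm <- geometry$distance_m * 1e9
  p_nm <- geometry$pixel_pitch_um * 1e3
  lambda_nm * z_nm / (geometry$n_pixels * p_nm)
}

#' Overlap ratio of a spiral scan
#'
#' For a spiral scan with step size `S` and beam size `B`, the overlap ratio
#' is \eqn{1 - \sqrt{3} S / B}. It reaches 1 for a vanishing step and 0 at
#' \eqn{S = B/\sqrt{3}}, beyond which adjacent illuminated discs no longer
#' share area. Values are returned unclamped; non-positive ratios are flagged
#' via the `"no_overlap"` attribute.
#'
#' @param step_nm Spiral step size S (nm), non-negative.
#' @param beamsize_nm Beam size B (nm), positive.
#' @return The dimensionless overlap ratio, possibly negative, with attribute
#'   `no_overlap` set to `TRUE` when the ratio is \eqn{\le 0}.
#' @examples
#' overlap_ratio(50, 800)   # ~0.9
#' overlap_ratio(180, 800)  # ~0.6
#' @export
overlap_ratio <- function(step_nm, beamsize_nm) {
  if (beamsize_nm <= 0) stop_invalid("beamsize_nm must be positive")
  if (step_nm < 0) stop_invalid("step_nm must be non-negative")
  r <- 1 - sqrt(3) * step_nm / beamsize_nm
  attr(r, "no_overlap") <- r <= 0
  r
}

#' Spiral step size that realizes a target overlap ratio
#'
#' Inverse of [overlap_ratio()]: \eqn{S = B (1 - r) / \sqrt{3}}.
#'
#' @param ratio Target overlap ratio (\eqn{\le 1}).
#' @param beamsize_nm Beam size B in nm.
#' @return Step size in nm.
#' @export
step_for_overlap <- function(ratio, beamsize_nm) {
  if (beamsize_nm <= 0) stop_invalid("beamsize_nm must be positive")
  if (ratio > 1) stop_invalid("overlap ratio cannot exceed 1")
  beamsize_nm * (1 - ratio) / sqrt(3)
}

#' Raw data volume of a raster-scanned ptychography acquisition
#'
#' Number of scan positions (`area / step^2`) times pixels per frame times
#' bytes per pixel, in decimal units.
#'
#' @param area_mm2 Scanned area in square millimetres.
#' @param step_nm Scan step in nm.
#' @param pixels_per_frame Pixels in one detector frame.
#' @param bit_depth Bits per pixel.
#' @return Total volume in bytes.
#' @examples
#' data_volume(1, 100, 1e6, 16) / 1e12  # 200 TB
#' @export
data_volume <- function(area_mm2, step_nm, pixels_per_frame, bit_depth) {
  if (area_mm2 <= 0 || step_nm <= 0 || pixels_per_frame <= 0 || bit_depth <= 0)
    stop_invalid("all data_volume arguments must be positive")
  n_positions <- area_mm2 * 1e12 / step_nm^2
  n_positions * pixels_per_frame * bit_depth / 8
}
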