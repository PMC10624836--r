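#' Bundle per-position phase patches
#'
#' @param patches Array (n, n, k) of phase patches (rad) or a single matrix.
#' @param positions_nm k x 2 matrix of beam positions (x, y) in nm; each
#'   position marks the centre of its patch (0-based centre pixel
#'   `floor(n/2)`, matching the forward model and label conventions).
#' @param pixel_size_nm Patch grid spacing in nm.
#' @return A `patch_set`.
#' @export
patch_set <- function(patches, positions_nm, pixel_size_nm) {
  if (is.matrix(patches)) patches <- array(patches, dim = c(dim(patches), 1L))
  positions_nm <- matrix(positions_nm, ncol = 2)
  if (dim(patches)[3] != nrow(positions_nm))
    stop_invalid("one position per patch required")
  if (dim(patches)[3] < 1) stop_invalid("patch set must be non-empty")
  structure(list(patches = patches, positions_nm = positions_nm,
                 pixel_size_nm = pixel_size_nm),
            class = "patch_set")
}

#' Stitch per-position inferences into one sample image
#'
#' Each patch is bilinearly resampled onto a common regular grid (spacing =
#' patch pixel size, origin anchored to the first patch corner so that
#' pixel-aligned positions are placed verbatim) and the per-pixel
#' statistical average is taken. With `weighting = "probe_amplitude"` the
#' average is weighted by the probe modulus resampled along with each patch,
#' emphasising the well-illuminated centre of every inference. Pixels never
#' covered by a patch have zero weight and are `NaN` in the phase grid;
#' they are excluded from any downstream metric.
#'
#' @param patchset A [patch_set()].
#' @param weighting `"uniform"` or `"probe_amplitude"`.
#' @param probe A `probe` (required for the weighted variant; its grid must
#'   match the patch grid).
#' @return A `stitched_image`: `phase`, `weight`, `origin_nm`,
#'   `pixel_size_nm`, `weighting`.
#' @export
stitch <- function(patchset, weighting = c("uniform", "probe_amplitude"),
                   probe = NULL) {
  weighting <- match.arg(weighting)
  if (weighting == "probe_amplitude" && is.null(probe))
    stop_invalid("probe_amplitude weighting requires a probe")
  p <- patchset$pixel_size_nm
  n <- dim(patchset$patches)[1]
  k <- dim(patchset$patches)[3]
  c0 <- n %/% 2L
  pos <- patchset$positions_nm
  corner_x <- pos[, 1] - c0 * p   # nm coordinate of patch pixel (.,1)
  corner_y <- pos[, 2] - c0 * p
  # global origin: snap the bounding-box corner onto the absolute lattice
  # of multiples of the pixel size, so the grid (and hence the result) is
  # independent of patch order and pixel-aligned patches land verbatim
  ox <- floor(min(corner_x) / p + 1e-9) * p
  oy <- floor(min(corner_y) / p + 1e-9) * p
  W <- floor((max(corner_x) + (n - 1) * p - ox) / p + 1e-9) + 1L
  H <- floor((max(corner_y) + (n - 1) * p - oy) / p + 1e-9) + 1L

  num <- matrix(0, H, W); wsum <- matrix(0, H, W)
  wprobe <- if (weighting == "probe_amplitude") Mod(probe$field) else NULL
  for (j in seq_len(k)) {
    jc0 <- max(0L, ceiling((corner_x[j] - ox) / p - 1e-9))
    jr0 <- max(0L, ceiling((corner_y[j] - oy) / p - 1e-9))
    jc1 <- min(W - 1L, floor((corner_x[j] + (n - 1) * p - ox) / p + 1e-9))
    jr1 <- min(H - 1L, floor((corner_y[j] + (n - 1) * p - oy) / p + 1e-9))
    if (jc1 < jc0 || jr1 < jr0) next
    gx <- ox + (jc0:jc1) * p; gy <- oy + (jr0:jr1) * p
    u <- (gx - corner_x[j]) / p          # 0-based patch columns
    v <- (gy - corner_y[j]) / p          # 0-based patch rows
    nu <- length(u); nv <- length(v)
    uu <- matrix(rep(u, each = nv), nv, nu)
    vv <- matrix(rep(v, times = nu), nv, nu)
    vals <- matrix(bilinear_sample(patchset$patches[, , j], uu, vv), nv, nu)
    w <- if (is.null(wprobe)) (!is.na(vals)) * 1
         else matrix(bilinear_sample(wprobe, uu, vv), nv, nu)
    w[is.na(vals) | is.na(w)] <- 0
    vals[is.na(vals)] <- 0
    ri <- jr0 + seq_len(nv); ci <- jc0 + seq_len(nu)
    num[ri, ci] <- num[ri, ci] + vals * w
    wsum[ri, ci] <- wsum[ri, ci] + w
  }
  phase <- num / wsum
  phase[wsum == 0] <- NaN
  structure(list(phase = phase, weight = wsum, origin_nm = c(ox, oy),
                 pixel_size_nm = p, weighting = weighting),
            class = "stitched_image")
}

#' Resample a reference image onto a stitched image's grid
#'
#' Bilinear sampling of `img` (with its own origin and pixel size) at the
#' pixel centres of `stitched`; used to score stitched results against a
#' ground-truth phantom or reconstruction defined on a different grid.
#'
#' @param img Real matrix (e.g. a phantom phase).
#' @param origin_nm Origin (x, y) of `img` (nm at pixel (1,1) centre).
#' @param pixel_size_nm Grid spacing of `img`.
#' @param stitched A `stitched_image`.
#' @return Matrix congruent with `stitched$phase` (NA outside `img`).
#' @export
resample_to_stitched <- function(img, origin_nm, pixel_size_nm, stitched) {
  H <- nrow(stitched$phase); W <- ncol(stitched$phase)
  gx <- stitched$origin_nm[1] + (0:(W - 1)) * stitched$pixel_size_nm
  gy <- stitched$origin_nm[2] + (0:(H - 1)) * stitched$pixel_size_nm
  u <- (gx - origin_nm[1]) / pixel_size_nm
  v <- (gy - origin_nm[2]) / pixel_size_nm
  uu <- matrix(rep(u, each = H), H, W)
  vv <- matrix(rep(v, times = W), H, W)
  matrix(bilinear_sample(img, uu, vv), H, W)
}
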