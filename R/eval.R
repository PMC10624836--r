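#' Structural-similarity accuracy between two phase images
#'
#' SSIM with an 11-pixel Gaussian window (sigma 1.5) and the standard
#' stability constants K1 = 0.01, K2 = 0.03; the dynamic range is the
#' max-min of the reference (`phase_b`) over the mask. Because ptychographic
#' phases carry an arbitrary global offset, `phase_a` is first shifted by
#' the mean masked phase difference when `align_global_phase` is `TRUE`.
#' The score is reported as a percentage ("accuracy"), so two identical
#' images (or images differing only by a constant, when aligning) give 100.
#'
#' @param phase_a Phase image under test (rad).
#' @param phase_b Reference phase image (rad), congruent grid.
#' @param align_global_phase Remove the mean masked difference first?
#' @param mask Logical matrix of valid pixels (default: both finite).
#' @return An `accuracy_report`: `ssim_pct`, `offset_rad` (the removed
#'   global offset), `coverage` (masked fraction).
#' @export
ssim_accuracy <- function(phase_a, phase_b, align_global_phase = TRUE,
                          mask = NULL) {
  if (!all(dim(phase_a) == dim(phase_b)))
    stop_invalid("phase images must be congruent")
  if (is.null(mask)) mask <- is.finite(phase_a) & is.finite(phase_b)
  if (!any(mask)) stop_invalid("empty mask")
  offset <- 0
  if (align_global_phase) {
    offset <- mean(phase_a[mask] - phase_b[mask])
    phase_a <- phase_a - offset
  }
  # fill invalid pixels with masked means so they do not leak into windows
  a <- phase_a; b <- phase_b
  a[!mask] <- mean(phase_a[mask]); b[!mask] <- mean(phase_b[mask])
  L <- diff(range(b[mask]))
  # degenerate flat reference: fall back to the absolute scale of the data
  if (L <= 0) L <- max(abs(a[mask]), abs(b[mask]), 1e-12)
  s <- ssim_map(a, b, data_range = L)
  structure(list(ssim_pct = 100 * mean(s[mask]), offset_rad = offset,
                 coverage = mean(mask)),
            class = "accuracy_report")
}

## SSIM map with Gaussian weighting (11 taps, sigma 1.5), replicate borders.
ssim_map <- function(a, b, data_range, K1 = 0.01, K2 = 0.03, sigma = 1.5) {
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  f <- function(x) gaussian_blur(x, sigma)
  mu_a <- f(a); mu_b <- f(b)
  var_a <- f(a * a) - mu_a^2
  var_b <- f(b * b) - mu_b^2
  cov_ab <- f(a * b) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
}

#' Sparse-sampling (overlap) sweep
#'
#' Starting from a scan acquired at high overlap, positions are subsampled
#' (every k-th spiral point, k matched to the target spacing) to realize
#' each target overlap ratio. For each subset a fresh iterative
#' reconstruction is run, the model's single-shot inferences on the same
#' subset are stitched, and both are scored by [ssim_accuracy()] against the
#' ground truth. Dose falls quadratically with the effective step, so the
#' mean dose of each subset is reported alongside.
#'
#' @param full_stack Diffraction stack of the full (dense) scan.
#' @param plan Its scan plan.
#' @param ground_truth A `phantom`, or a list with `phase`, `origin_nm`,
#'   `pixel_size_nm`.
#' @param model A trained `ptycho_model` (or `NULL` to skip the AI column).
#' @param rpie_opts [rpie_options()] for the per-subset reconstructions (or
#'   `NULL` to skip the iterative column).
#' @param target_ratios Decreasing overlap ratios within \[0, full-scan
#'   ratio\].
#' @param probe The probe (reconstruction init and dose bookkeeping).
#' @return A data.frame with columns `overlap_ratio`, `ssim_ai_pct`,
#'   `ssim_iterative_pct`, `step_nm`, `n_points`, `mean_dose`.
#' @export
overlap_sweep <- function(full_stack, plan, ground_truth, model, rpie_opts,
                          target_ratios, probe) {
  gt <- if (inherits(ground_truth, "phantom"))
    list(phase = ground_truth$phase, origin_nm = c(0, 0),
         pixel_size_nm = ground_truth$pixel_size_nm)
  else ground_truth
  rows <- lapply(target_ratios, function(ratio) {
    target_step <- max(plan$step_nm, step_for_overlap(ratio, plan$beamsize_nm))
    sub <- subsample_plan(plan, target_step)
    stack_s <- full_stack
    stack_s$frames <- full_stack$frames[, , sub$keep, drop = FALSE]
    stack_s$plan <- sub$plan
    ai <- it <- NA_real_
    if (!is.null(model)) {
      batch <- preprocess_frames(stack_s$frames, 1, model)
      pred <- infer_with_norm(model, batch)
      st <- stitch(patch_set(pred, sub$plan$positions_nm, gt$pixel_size_nm))
      ref <- resample_to_stitched(gt$phase, gt$origin_nm, gt$pixel_size_nm, st)
      m <- is.finite(st$phase) & is.finite(ref)
      ai <- ssim_accuracy(st$phase, ref, mask = m)$ssim_pct
    }
    if (!is.null(rpie_opts)) {
      rec <- rpie_reconstruct(stack_s, sub$plan, probe, rpie_opts)
      covered <- stitch(patch_set(
        array(0, dim = c(dim(full_stack$frames)[1:2], sub$plan$n_points)),
        sub$plan$positions_nm, rec$pixel_size_nm))
      refc <- resample_to_stitched(gt$phase, gt$origin_nm, gt$pixel_size_nm,
                                   covered)
      recc <- resample_to_stitched(rec$phase, rec$origin_nm,
                                   rec$pixel_size_nm, covered)
      m <- is.finite(covered$phase) & is.finite(refc) & is.finite(recc)
      it <- ssim_accuracy(recc, refc, mask = m)$ssim_pct
    }
    dm <- dose_map(sub$plan, probe, full_stack$flux_scale,
                   full_stack$exposure_ms)
    data.frame(overlap_ratio = ratio, ssim_ai_pct = ai,
               ssim_iterative_pct = it, step_nm = sub$plan$step_nm,
               n_points = sub$plan$n_points, mean_dose = dm$average_dose)
  })
  do.call(rbind, rows)
}

#' Fourier ring correlation resolution estimate
#'
#' Ring-wise normalized cross-correlation of the Fourier transforms of two
#' independent reconstructions of the same region. The resolution is the
#' inverse of the spatial frequency at which the curve first drops below the
#' threshold: the 1/2-bit information criterion by default, or a fixed 0.5.
#' Curves that never cross report the Nyquist limit (2 pixels).
#'
#' @param recon_a,recon_b Real matrices (phases) on congruent grids, side
#'   >= 64 px.
#' @param pixel_size_nm Grid spacing in nm.
#' @param threshold_rule `"half-bit"` or `"fixed-0.5"`.
#' @return An `frc_curve`: data.frame (`freq_nm1`, `frc`, `threshold`) plus
#'   attribute-style fields `resolution_nm`.
#' @export
frc_resolution <- function(recon_a, recon_b, pixel_size_nm,
                           threshold_rule = c("half-bit", "fixed-0.5")) {
  threshold_rule <- match.arg(threshold_rule)
  if (!all(dim(recon_a) == dim(recon_b)))
    stop_invalid("inputs must be congruent")
  N <- nrow(recon_a)
  if (N < 64 || ncol(recon_a) < 64)
    stop_invalid("region too small for a resolution estimate (< 64 px)")
  Fa <- fftshift2(stats::fft(recon_a))
  Fb <- fftshift2(stats::fft(recon_b))
  cc <- floor(dim(recon_a) / 2) + 1  # DC after fftshift
  ii <- row(Fa) - cc[1]; jj <- col(Fa) - cc[2]
  r <- round(sqrt(ii^2 + jj^2))
  rmax <- floor(min(dim(recon_a)) / 2) - 1L
  num <- rep(0, rmax + 1); pa <- rep(0, rmax + 1); pb <- rep(0, rmax + 1)
  nring <- rep(0, rmax + 1)
  sel <- r <= rmax
  rr <- r[sel] + 1L
  num <- as.numeric(tapply(Re(Fa[sel] * Conj(Fb[sel])), rr, sum))
  pa <- as.numeric(tapply(Mod(Fa[sel])^2, rr, sum))
  pb <- as.numeric(tapply(Mod(Fb[sel])^2, rr, sum))
  nring <- as.numeric(table(rr))
  frc <- num / sqrt(pa * pb)
  thr <- if (threshold_rule == "half-bit") {
    (0.2071 + 1.9102 / sqrt(nring)) / (1.2071 + 0.9102 / sqrt(nring))
  } else rep(0.5, length(frc))
  freq <- (0:rmax) / (N * pixel_size_nm)   # cycles per nm
  below <- which(frc < thr & seq_along(frc) > 1L)
  if (!length(below)) {
    res <- 2 * pixel_size_nm
  } else {
    k <- below[1]
    f0 <- freq[k - 1]; f1 <- freq[k]
    d0 <- frc[k - 1] - thr[k - 1]; d1 <- frc[k] - thr[k]
    fc <- if (d0 == d1) f1 else f0 + d0 / (d0 - d1) * (f1 - f0)
    res <- max(1 / fc, 2 * pixel_size_nm)
  }
  structure(list(curve = data.frame(freq_nm1 = freq, frc = frc,
                                    threshold = thr, n_ring = nring),
                 resolution_nm = res, threshold_rule = threshold_rule,
                 pixel_size_nm = pixel_size_nm),
            class = "frc_curve")
}

#' Phase line profile along a segment
#'
#' Samples one or two phase images along the straight segment from
#' `from_nm` to `to_nm` (bilinear interpolation), the comparison usually
#' drawn between a stitched inference and an iterative reconstruction.
#'
#' @param images Named list of matrices (e.g. `list(ai = ..., iterative =
#'   ...)`), all on the same grid.
#' @param from_nm,to_nm Segment endpoints (x, y) in nm.
#' @param origin_nm Grid origin of the images.
#' @param pixel_size_nm Grid spacing.
#' @param n Number of samples along the segment.
#' @return A data.frame: `distance_nm` plus one column per image.
#' @export
line_profile <- function(images, from_nm, to_nm, origin_nm = c(0, 0),
                         pixel_size_nm = 1, n = 200) {
  if (is.matrix(images)) images <- list(phase = images)
  t <- seq(0, 1, length.out = n)
  x <- from_nm[1] + t * (to_nm[1] - from_nm[1])
  y <- from_nm[2] + t * (to_nm[2] - from_nm[2])
  u <- (x - origin_nm[1]) / pixel_size_nm
  v <- (y - origin_nm[2]) / pixel_size_nm
  out <- data.frame(distance_nm = t * sqrt(sum((to_nm - from_nm)^2)))
  for (nm in names(images)) out[[nm]] <- bilinear_sample(images[[nm]], u, v)
  out
}
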