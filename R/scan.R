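#' Constant-arc-length Archimedean spiral scan
#'
#' Generates scan positions on the spiral \eqn{r = a\theta} with
#' \eqn{a = S/2\pi}, stepped so that the chord between consecutive points is
#' the step size `S`. The turn-to-turn pitch then also equals `S`, giving the
#' near-uniform sampling density typical of ptychographic spiral scans: the
#' median nearest-neighbour spacing matches `S` closely.
#'
#' @param n_points Number of scan positions (>= 1).
#' @param step_nm Step size S between consecutive points, nm.
#' @param beamsize_nm Beam size B on the sample, nm (metadata; sets the
#'   overlap ratio together with `step_nm`).
#' @param center_nm Length-2 numeric, spiral centre (x, y) in nm.
#'
#' @return A `scan_plan`: list with `positions_nm` (n x 2 matrix, columns
#'   x, y; x right, y down), `step_nm`, `beamsize_nm`, `n_points`.
#' @examples
#' plan <- make_spiral_scan(963, 50, 800)
#' plan$n_points
#' @export
make_spiral_scan <- function(n_points, step_nm, beamsize_nm = 800,
                             center_nm = c(0, 0)) {
  if (n_points < 1) stop_invalid("n_points must be >= 1")
  if (step_nm <= 0) stop_invalid("step_nm must be positive")
  n_points <- as.integer(n_points)
  a <- step_nm / (2 * pi)
  theta <- numeric(n_points)
  th <- 0
  for (k in seq_len(n_points)[-1]) {
    # circle-approximation increment, refined so the chord length equals S
    dth <- step_nm / sqrt(a^2 + (a * th)^2)
    for (rep in 1:4) {
      r1 <- a * th; r2 <- a * (th + dth)
      chord <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(dth))
      if (chord > 0) dth <- dth * step_nm / chord
    }
    th <- th + dth
    theta[k] <- th
  }
  r <- a * theta
  pos <- cbind(x_nm = center_nm[1] + r * cos(theta),
               y_nm = center_nm[2] + r * sin(theta))
  structure(list(positions_nm = pos, step_nm = step_nm,
                 beamsize_nm = beamsize_nm, n_points = n_points),
            class = "scan_plan")
}

#' Nearest-neighbour spacings of a scan plan
#'
#' @param plan A `scan_plan`.
#' @return Numeric vector: for each position, the distance to its nearest
#'   other position (nm).
#' @export
nearest_neighbor_spacing <- function(plan) {
  p <- plan$positions_nm
  if (nrow(p) < 2) return(numeric(0))
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Subsample a scan plan to a sparser effective step
#'
#' Keeps every k-th point of the (ordered) spiral with
#' \eqn{k = (S_{target}/S)^2}: the areal density of a spiral scales with
#' \eqn{S^{-2}}, so this realizes the density (and hence dose) of a spiral
#' acquired directly at the target step — the bookkeeping used by the
#' sparse-sampling analysis, where the dose drops by the squared step ratio.
#' The subsampled pattern is anisotropic, so its measured median
#' nearest-neighbour spacing (returned as `achieved_nn_nm`) can differ from
#' the nominal effective step.
#'
#' @param plan A `scan_plan`.
#' @param target_step_nm Desired effective step size (>= plan step).
#' @return A list: `plan` (the subsampled `scan_plan`, `step_nm` set to the
#'   nominal effective step), `keep` (indices kept), `k`, `achieved_nn_nm`.
#' @export
subsample_plan <- function(plan, target_step_nm) {
  if (target_step_nm < plan$step_nm)
    stop_invalid("target step must be >= the plan's step")
  k <- max(1L, as.integer(round((target_step_nm / plan$step_nm)^2)))
  keep <- seq(1L, plan$n_points, by = k)
  sub <- plan
  sub$positions_nm <- plan$positions_nm[keep, , drop = FALSE]
  sub$n_points <- length(keep)
  sub$step_nm <- plan$step_nm * sqrt(k)
  achieved <- if (sub$n_points >= 2)
    stats::median(nearest_neighbor_spacing(sub)) else NA_real_
  list(plan = sub, keep = keep, k = k, achieved_nn_nm = achieved)
}
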