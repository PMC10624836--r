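#' Options for the regularized Ptychographic Iterative Engine
#'
#' @param iterations Number of full sweeps over the scan (default 500).
#' @param alpha Object relaxation in (0, 1]: the rPIE object-update
#'   denominator mixes the local \eqn{|P|^2} with its maximum as
#'   \eqn{(1-\alpha)|P|^2 + \alpha \max |P|^2}; smaller alpha is more
#'   aggressive where the probe is weak.
#' @param beta Probe relaxation in \[0, 1\]; 0 freezes the probe entirely.
#' @param n_modes Number of mutually incoherent probe modes.
#' @param probe_update_start Iteration after which probe updates begin.
#' @param random_object_init Start from unity transmission with seeded
#'   U(-0.1, 0.1) rad phase noise instead of plain unity.
#' @param seed Seed controlling position visit order and any random
#'   initialization.
#' @return An `rpie_options` list.
#' @export
rpie_options <- function(iterations = 500L, alpha = 0.25, beta = 0.9,
                         n_modes = 3L, probe_update_start = 10L,
                         random_object_init = FALSE, seed = 1L) {
  if (iterations < 1) stop_invalid("iterations must be >= 1")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  if (beta < 0 || beta > 1) stop_invalid("beta must be in [0, 1]")
  structure(list(iterations = as.integer(iterations), alpha = alpha,
                 beta = beta, n_modes = as.integer(n_modes),
                 probe_update_start = as.integer(probe_update_start),
                 random_object_init = random_object_init,
                 seed = as.integer(seed)),
            class = "rpie_options")
}

## Build initial probe modes: the supplied probe plus orthogonalized seeded
## noise modes at -20 dB relative power.
init_probe_modes <- function(probe_field, n_modes, seed) {
  modes <- list(probe_field)
  if (n_modes > 1) {
    n <- nrow(probe_field)
    noise <- with_seed(child_seed(seed, 77), {
      lapply(seq_len(n_modes - 1L), function(m) {
        matrix(stats::rnorm(n * n), n, n) + 1i * matrix(stats::rnorm(n * n), n, n)
      })
    })
    env <- gaussian_blur(Mod(probe_field), 2)
    for (m in seq_along(noise)) {
      f <- noise[[m]] * env
      f <- f / sqrt(sum(Mod(f)^2)) * sqrt(sum(Mod(probe_field)^2)) * 0.1
      modes[[m + 1L]] <- f
    }
    modes <- orthogonalize_modes(modes)
  }
  modes
}

## Gram-Schmidt orthogonalization of probe modes (power ordering kept).
orthogonalize_modes <- function(modes) {
  for (m in seq_along(modes)) {
    if (m > 1) {
      for (k in seq_len(m - 1L)) {
        proj <- sum(Conj(modes[[k]]) * modes[[m]]) / sum(Mod(modes[[k]])^2)
        modes[[m]] <- modes[[m]] - proj * modes[[k]]
      }
    }
  }
  modes
}

#' Reconstruct a scan with rPIE
#'
#' Sequential projection solver: at each position the exit waves
#' \eqn{\psi_m = P_m O} are propagated to the detector, the measured modulus
#' \eqn{\sqrt{I}} replaces the model modulus (distributed across modes in
#' proportion to per-mode intensity), and the back-propagated difference
#' drives the rPIE object update and (optionally) the PIE probe update. The
#' position visit order is reshuffled every iteration from the seed.
#'
#' @param stack A [simulate_scan()] stack (or one read from disk).
#' @param plan Scan plan matching the stack (defaults to `stack$plan`).
#' @param probe_init A `probe` whose field is power-normalized.
#' @param options An [rpie_options()] list.
#' @param object_init Optional complex matrix to start from (its dimensions
#'   define the object grid); defaults to unity transmission on a grid
#'   covering all probe windows.
#'
#' @return A list of class `recon_result`: `object` (complex matrix),
#'   `phase`, `amplitude`, `probe_modes`, `pixel_size_nm`, `origin_nm`,
#'   `trace` (per-iteration normalized data error), `options`.
#' @export
rpie_reconstruct <- function(stack, plan = stack$plan, probe_init, options,
                             object_init = NULL) {
  frames <- stack$frames
  n <- dim(frames)[1]
  np <- dim(frames)[3]
  if (np != plan$n_points) stop_invalid("stack and plan sizes differ")
  if (nrow(probe_init$field) != n) stop_invalid("probe and frame sides differ")
  px <- probe_init$pixel_size_nm
  pos <- plan$positions_nm

  if (is.null(object_init)) {
    origin <- c(floor(min(pos[, 1]) / px) * px - (n %/% 2 + 2) * px,
                floor(min(pos[, 2]) / px) * px - (n %/% 2 + 2) * px)
    nrow_o <- ceiling((max(pos[, 2]) - origin[2]) / px) + n + 4
    ncol_o <- ceiling((max(pos[, 1]) - origin[1]) / px) + n + 4
    object <- matrix(1 + 0i, nrow_o, ncol_o)
    if (options$random_object_init) {
      ph <- with_seed(child_seed(options$seed, 11),
                      matrix(stats::runif(nrow_o * ncol_o, -0.1, 0.1),
                             nrow_o, ncol_o))
      object <- exp(1i * ph)
    }
  } else {
    object <- object_init
    origin <- attr(object_init, "origin_nm")
    if (is.null(origin)) origin <- c(0, 0)
  }
  nr <- nrow(object); nc <- ncol(object)

  r0s <- vapply(seq_len(np), function(j)
    window_start0(pos[j, 2], px, n, origin[2]), integer(1))
  c0s <- vapply(seq_len(np), function(j)
    window_start0(pos[j, 1], px, n, origin[1]), integer(1))
  if (any(r0s < 0 | c0s < 0 | r0s + n > nr | c0s + n > nc))
    stop_invalid("position %d outside the object grid",
                 which(r0s < 0 | c0s < 0 | r0s + n > nr | c0s + n > nc)[1])

  modes <- init_probe_modes(probe_init$field, options$n_modes, options$seed)
  nm <- length(modes)
  scale <- stack$flux_scale * stack$exposure_ms
  sqrtI <- sqrt(pmax(frames, 0) / scale)     # measured modulus, probe units
  total_I <- sum(sqrtI^2)
  trace <- numeric(options$iterations)
  eps <- 1e-12

  for (it in seq_len(options$iterations)) {
    order_j <- with_seed(child_seed(options$seed, it), sample.int(np))
    err_it <- 0
    for (j in order_j) {
      ri <- r0s[j] + seq_len(n); ci <- c0s[j] + seq_len(n)
      Opatch <- object[ri, ci]
      psi <- lapply(modes, function(P) P * Opatch)
      Psi <- lapply(psi, fft2c)
      Imod <- Reduce(`+`, lapply(Psi, function(F) Mod(F)^2))
      err_it <- err_it + sum((sqrtI[, , j] - sqrt(Imod))^2)
      fac <- sqrtI[, , j] / sqrt(pmax(Imod, eps))
      dpsi <- lapply(seq_len(nm), function(m) ifft2c(Psi[[m]] * fac) - psi[[m]])
      Psum2 <- Reduce(`+`, lapply(modes, function(P) Mod(P)^2))
      denom <- (1 - options$alpha) * Psum2 + options$alpha * max(Psum2)
      num <- Reduce(`+`, lapply(seq_len(nm), function(m)
        Conj(modes[[m]]) * dpsi[[m]]))
      object[ri, ci] <- Opatch + num / denom
      if (options$beta > 0 && it > options$probe_update_start) {
        Omax2 <- max(Mod(Opatch)^2)
        for (m in seq_len(nm)) {
          modes[[m]] <- modes[[m]] +
            options$beta * Conj(Opatch) * dpsi[[m]] / pmax(Omax2, eps)
        }
      }
    }
    if (nm > 1 && options$beta > 0 && it > options$probe_update_start)
      modes <- orthogonalize_modes(modes)
    trace[it] <- err_it / total_I
    if (!all(is.finite(object)))
      stop_invalid("numerical failure (non-finite object) at iteration %d", it)
  }

  structure(list(object = object, phase = Arg(object),
                 amplitude = Mod(object), probe_modes = modes,
                 pixel_size_nm = px, origin_nm = origin,
                 trace = trace, options = options),
            class = "recon_result")
}

#' Normalized modulus-mismatch data error
#'
#' \eqn{\sum (\sqrt{I_{meas}} - |\Psi_{model}|)^2 / \sum I_{meas}} over all
#' frames, evaluated for a reconstruction state against a stack. Zero for a
#' perfect model of noiseless data; 1 for an all-zero model.
#'
#' @param state A `recon_result` (or a list with `object`, `probe_modes`,
#'   `pixel_size_nm`, `origin_nm`).
#' @param stack The diffraction stack.
#' @param plan Scan plan (defaults to `stack$plan`).
#' @return Scalar data error.
#' @export
data_error <- function(state, stack, plan = stack$plan) {
  frames <- stack$frames
  n <- dim(frames)[1]; np <- dim(frames)[3]
  px <- state$pixel_size_nm
  origin <- state$origin_nm
  scale <- stack$flux_scale * stack$exposure_ms
  sqrtI <- sqrt(pmax(frames, 0) / scale)
  err <- 0
  for (j in seq_len(np)) {
    r0 <- window_start0(stack$plan$positions_nm[j, 2], px, n, origin[2])
    c0 <- window_start0(stack$plan$positions_nm[j, 1], px, n, origin[1])
    Opatch <- state$object[r0 + seq_len(n), c0 + seq_len(n)]
    Imod <- Reduce(`+`, lapply(state$probe_modes, function(P)
      Mod(fft2c(P * Opatch))^2))
    err <- err + sum((sqrtI[, , j] - sqrt(Imod))^2)
  }
  err / sum(sqrtI^2)
}
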