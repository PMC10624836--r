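## Internal numerics shared across modules: centered orthonormal FFTs,
## bilinear sampling on matrices, small kernels and RNG helpers.

#' @useDynLib ptychostream, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

## fftshift/ifftshift for matrices (even or odd sides)
fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2))),
    c(seq(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2))), drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(d[1] - floor(d[1] / 2) + 1L, d[1]), seq_len(d[1] - floor(d[1] / 2))),
    c(seq(d[2] - floor(d[2] / 2) + 1L, d[2]), seq_len(d[2] - floor(d[2] / 2))),
    drop = FALSE]
}

## Centered, orthonormal 2-D Fourier transform: the detector-plane field of an
## exit wave sampled on the probe window. Orthonormal scaling preserves power
## (Parseval), which the photon bookkeeping of the forward model relies on.
fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

## Bilinear sampling of matrix `img` at fractional 0-based coordinates
## (u = column, v = row). Points outside the grid return NA.
bilinear_sample <- function(img, u, v) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- u >= 0 & u <= nc - 1 & v >= 0 & v <= nr - 1 & !is.na(u) & !is.na(v)
  out <- rep(NA_real_, length(u))
  if (!any(ok)) return(out)
  u <- u[ok]; v <- v[ok]
  j0 <- pmin(floor(u), nc - 2); i0 <- pmin(floor(v), nr - 2)
  fu <- u - j0; fv <- v - i0
  i1 <- i0 + 1L; j1 <- j0 + 1L  # 1-based row/col of the top-left corner
  idx <- function(i, j) img[cbind(i, j)]
  out[ok] <- (1 - fu) * (1 - fv) * idx(i1, j1) +
    fu * (1 - fv) * idx(i1, j1 + 1L) +
    (1 - fu) * fv * idx(i1 + 1L, j1) +
    fu * fv * idx(i1 + 1L, j1 + 1L)
  out
}

## Separable Gaussian filter with replicated edges ("same" output size).
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(m) {
    # replicate-pad rows then convolve each column with k
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- apply(mp, 2L, function(col) {
      stats::convolve(col, rev(k), type = "filter")
    })
    matrix(out, nrow = nrow(m))
  }
  t(pad_conv(t(pad_conv(img))))
}

## Local RNG scope: runs `expr` under a given seed without disturbing the
## caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a reproducible child seed (kept below 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * k) %% 2147483647)
}
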