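#' Synthetic phase phantoms
#'
#' Phantoms emulate test structures etched into a membrane: the phase shift
#' takes one of two levels (etched / not etched) within a declared range, and
#' the transition is smoothed over about one pixel as a physical etch edge
#' would appear at finite resolution. `"random_etch"` thresholds smoothed
#' random noise into blob-like features; `"letters"` stamps glyphs rendered
#' from a built-in 5x7 bitmap font at random positions and scales, giving
#' features unlike the random-etch training textures.
#'
#' @param shape Length-2 integer (rows, cols) of the phantom grid.
#' @param pixel_size_nm Grid spacing in nm.
#' @param phase_range Length-2 numeric (lo, hi), both inside (-pi, pi); the
#'   two etch levels. Phase wrapping is not modelled.
#' @param style `"random_etch"` or `"letters"`.
#' @param seed Integer seed; phantoms are reproducible bit-for-bit.
#' @param feature_nm Characteristic feature size in nm (blob scale / glyph
#'   stroke scale).
#'
#' @return A `phantom`: `phase` (matrix, rad), `amplitude` (matrix in (0,1]),
#'   `pixel_size_nm`, `phase_range`.
#' @examples
#' ph <- make_phantom(c(128, 128), 8, c(-0.4, 0), seed = 7)
#' range(ph$phase)
#' @export
make_phantom <- function(shape, pixel_size_nm, phase_range = c(-0.4, 0),
                         style = c("random_etch", "letters"), seed = 1L,
                         feature_nm = 12 * pixel_size_nm) {
  style <- match.arg(style)
  lo <- phase_range[1]; hi <- phase_range[2]
  if (lo >= hi) stop_invalid("phase_range must satisfy lo < hi")
  if (lo <= -pi || hi >= pi)
    stop_invalid("phase_range must lie strictly inside (-pi, pi)")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  feature_px <- max(2, feature_nm / pixel_size_nm)

  mask <- with_seed(seed, {
    if (style == "random_etch") {
      z <- matrix(stats::rnorm(nr * nc), nr, nc)
      zs <- gaussian_blur(z, feature_px / 2)
      (zs > stats::median(zs)) * 1
    } else {
      letters_mask(nr, nc, feature_px)
    }
  })
  # soften etch edges over ~1 px, then map [0,1] -> [lo,hi]
  mask <- gaussian_blur(mask, 0.8)
  mask <- pmin(pmax(mask, 0), 1)
  phase <- lo + mask * (hi - lo)
  structure(list(phase = phase,
                 amplitude = matrix(1, nr, nc),
                 pixel_size_nm = pixel_size_nm,
                 phase_range = c(lo, hi)),
            class = "phantom")
}

## 5x7 bitmaps for a small glyph set; rows are strings of . and #.
glyph_font <- function() {
  list(
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
    H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    N = c("#...#", "##..#", "##..#", "#.#.#", "#..##", "#..##", "#...#"),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    X = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
    Y = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
    Z = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"))
}

glyph_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(s) {
    as.integer(strsplit(s, "")[[1]] == "#")
  }))
}

## Stamp glyphs (nearest-neighbour upscaled) at random non-aligned positions
## until roughly a third of the canvas is covered.
letters_mask <- function(nr, nc, stroke_px) {
  m <- matrix(0, nr, nc)
  font <- glyph_font()
  n_stamps <- max(3L, ceiling(nr * nc / (stroke_px^2 * 35 * 3)))
  for (s in seq_len(n_stamps)) {
    g <- glyph_matrix(font[[sample(length(font), 1L)]])
    sc <- stroke_px * stats::runif(1, 0.7, 1.6)
    gh <- max(2L, round(nrow(g) * sc)); gw <- max(2L, round(ncol(g) * sc))
    big <- g[pmin(nrow(g), ceiling(seq_len(gh) / sc)),
             pmin(ncol(g), ceiling(seq_len(gw) / sc)), drop = FALSE]
    if (gh >= nr || gw >= nc) next
    i0 <- sample.int(nr - gh, 1L); j0 <- sample.int(nc - gw, 1L)
    m[i0 + seq_len(gh) - 1L, j0 + seq_len(gw) - 1L] <-
      pmax(m[i0 + seq_len(gh) - 1L, j0 + seq_len(gw) - 1L], big)
  }
  m
}
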