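## On-disk formats.
##
## Phase images and frame stacks are stored as 32-bit float TIFF (written by
## a small native writer because the CRAN tiff package only stores values in
## [0, 1]; files use the plain single-strip little-endian layout and read
## back identically through libtiff). Scan positions travel as CSV
## (index,x_nm,y_nm), stack metadata as a JSON sidecar, campaign configs as
## YAML, model checkpoints as single-file RDS archives.

tiff_tag <- function(con, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L && count == 1L) {  # SHORT padded to 4 bytes
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write images as 32-bit float TIFF
#'
#' Multi-page grayscale TIFF with IEEE float samples; values are stored
#' exactly as given (float32 precision), so integer photon counts below
#' 2^24 round-trip bit-exactly.
#'
#' @param images A matrix, an array (H, W, n), or a list of matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  offset <- 8L
  writeBin(as.integer(offset + 0L), con, size = 4, endian = "little")
  # layout per page: [IFD][strip]
  for (k in seq_along(images)) {
    img <- images[[k]]
    H <- nrow(img); W <- ncol(img)
    strip_off <- offset + ifd_size
    strip_bytes <- 4L * H * W
    next_ifd <- if (k < length(images)) strip_off + strip_bytes else 0L
    writeBin(n_tags, con, size = 2, endian = "little")
    tiff_tag(con, 256, 3, 1, W)            # ImageWidth
    tiff_tag(con, 257, 3, 1, H)            # ImageLength
    tiff_tag(con, 258, 3, 1, 32)           # BitsPerSample
    tiff_tag(con, 259, 3, 1, 1)            # Compression: none
    tiff_tag(con, 262, 3, 1, 1)            # Photometric: min-is-black
    tiff_tag(con, 273, 4, 1, strip_off)    # StripOffsets
    tiff_tag(con, 277, 3, 1, 1)            # SamplesPerPixel
    tiff_tag(con, 278, 3, 1, H)            # RowsPerStrip
    tiff_tag(con, 279, 4, 1, strip_bytes)  # StripByteCounts
    tiff_tag(con, 339, 3, 1, 3)            # SampleFormat: IEEE float
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    # row-major pixel order; force double so writeBin emits IEEE floats
    # (integer input would otherwise be written as int32 bytes)
    writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
    offset <- strip_off + strip_bytes
  }
  invisible(path)
}

#' Read a 32-bit float TIFF written by [write_float_tiff()]
#'
#' @param path File path.
#' @param simplify Return a single matrix when the file has one page?
#' @return A matrix or a list of matrices.
#' @export
read_float_tiff <- function(path, simplify = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 2) != "II") stop_invalid("%s: not a little-endian TIFF", path)
  readBin(con, "integer", 1, size = 2, endian = "little")
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = "little")
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n <- readBin(con, "integer", 1, size = 2, endian = "little")
    tags <- list()
    for (i in seq_len(n)) {
      id <- readBin(con, "integer", 1, size = 2, endian = "little")
      type <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      val <- if (type == 3L) {
        v <- readBin(con, "integer", 1, size = 2, endian = "little")
        readBin(con, "integer", 1, size = 2, endian = "little")
        v
      } else readBin(con, "integer", 1, size = 4, endian = "little")
      tags[[as.character(id)]] <- val
    }
    ifd_next <- readBin(con, "integer", 1, size = 4, endian = "little")
    H <- tags[["257"]]; W <- tags[["256"]]
    if (!identical(tags[["339"]], 3L) || !identical(tags[["258"]], 32L))
      stop_invalid("%s: dataset is not 32-bit float (tag SampleFormat)", path)
    seek(con, tags[["273"]])
    v <- readBin(con, "numeric", H * W, size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(v, H, W, byrow = TRUE)
    ifd_off <- ifd_next
  }
  if (simplify && length(pages) == 1L) pages[[1]] else pages
}

#' Write scan positions as CSV
#'
#' Columns `index,x_nm,y_nm` with a header row.
#'
#' @param plan A `scan_plan` (or an n x 2 position matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(plan, path) {
  pos <- if (inherits(plan, "scan_plan")) plan$positions_nm else plan
  df <- data.frame(index = seq_len(nrow(pos)) - 1L,
                   x_nm = pos[, 1], y_nm = pos[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("index", "x_nm", "y_nm") %in% names(df)))
    stop_invalid("%s: missing column(s) %s", path,
                 paste(setdiff(c("index", "x_nm", "y_nm"), names(df)),
                       collapse = ", "))
  as.matrix(df[order(df$index), c("x_nm", "y_nm")])
}

#' Write / read a diffraction stack
#'
#' A stack directory holds `frames.tif` (multi-page 32-bit float),
#' `positions.csv` and `meta.json` (geometry, exposure, flux, seed, scan
#' parameters). Integer count frames round-trip bit-exactly.
#'
#' @param stack A `diffraction_stack`.
#' @param dir Directory to create/write.
#' @return `dir` (write) or a `diffraction_stack` (read).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_float_tiff(stack$frames, file.path(dir, "frames.tif"))
  write_positions_csv(stack$plan, file.path(dir, "positions.csv"))
  g <- stack$geometry
  meta <- list(energy_keV = g$energy_keV, distance_m = g$distance_m,
               n_pixels = g$n_pixels, pixel_pitch_um = g$pixel_pitch_um,
               exposure_ms = stack$exposure_ms, flux_scale = stack$flux_scale,
               poisson = stack$poisson, seed = stack$seed,
               step_nm = stack$plan$step_nm,
               beamsize_nm = stack$plan$beamsize_nm)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  pages <- read_float_tiff(file.path(dir, "frames.tif"), simplify = FALSE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  pos <- read_positions_csv(file.path(dir, "positions.csv"))
  plan <- structure(list(positions_nm = pos, step_nm = meta$step_nm,
                         beamsize_nm = meta$beamsize_nm,
                         n_points = nrow(pos)),
                    class = "scan_plan")
  geometry <- detector_geometry(meta$energy_keV, meta$distance_m,
                                meta$n_pixels, meta$pixel_pitch_um)
  structure(list(frames = frames, exposure_ms = meta$exposure_ms,
                 flux_scale = meta$flux_scale, plan = plan,
                 geometry = geometry, poisson = meta$poisson,
                 seed = meta$seed),
            class = "diffraction_stack")
}

#' Write a reconstruction as TIFF + JSON sidecar
#'
#' @param recon A `recon_result`.
#' @param dir Output directory (`phase.tif`, `amplitude.tif`, `meta.json`).
#' @return `dir`, invisibly.
#' @export
write_recon <- function(recon, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_float_tiff(recon$phase, file.path(dir, "phase.tif"))
  write_float_tiff(recon$amplitude, file.path(dir, "amplitude.tif"))
  meta <- list(pixel_size_nm = recon$pixel_size_nm,
               origin_nm = recon$origin_nm,
               final_error = utils::tail(recon$trace, 1),
               options = unclass(recon$options))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Model checkpoints
#'
#' A checkpoint is a single-file archive holding the weights, the network
#' spec, the input normalization constant and the version tag; loading it
#' restores bit-identical inference.
#'
#' @param model A `ptycho_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `ptycho_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ptycho_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ptycho_model"))
    stop_invalid("%s is not a model checkpoint", path)
  model
}

#' Write / read a campaign configuration (YAML)
#'
#' @param config A [campaign_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `campaign_config` (read); configurations
#'   round-trip losslessly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(campaign_config, raw)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
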