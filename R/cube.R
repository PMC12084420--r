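# Hyperspectral cube container and acquisition settings.

#' Acquisition settings of a hyperspectral SRS image
#'
#' @param zoom unitless zoom factor (> 0), typically 1 or 2.
#' @param pump_power,stokes_power laser powers in arbitrary but consistent
#'   units; either a scalar or one value per acquisition region.
#' @param bit_depth detector bit depth (default 12; maximum representable
#'   value is `2^bit_depth - 1`).
#' @return An `srs_settings` object.
#' @export
acquisition_settings <- function(zoom = 1, pump_power = 1, stokes_power = 1,
                                 bit_depth = 12) {
  if (zoom <= 0) stop("zoom must be > 0")
  if (any(pump_power <= 0) || any(stokes_power <= 0))
    stop("laser powers must be > 0")
  if (bit_depth < 8) stop("bit_depth must be >= 8")
  structure(list(zoom = zoom, pump_power = as.numeric(pump_power),
                 stokes_power = as.numeric(stokes_power),
                 bit_depth = as.integer(bit_depth)),
            class = "srs_settings")
}

max_value <- function(settings) 2^settings$bit_depth - 1

#' Construct a hyperspectral cube
#'
#' @param data H x W x C array of non-negative integers within the
#'   bit-depth range.
#' @param axis `srs_axis` whose channel count matches `dim(data)[3]`.
#' @param settings `srs_settings` for the acquisition.
#' @return An `srs_cube` object.
#' @export
srs_cube <- function(data, axis, settings = acquisition_settings()) {
  data <- unclass(data)
  if (length(dim(data)) != 3)
    stop("cube data must be an H x W x C array")
  if (dim(data)[3] != n_channels(axis))
    stop("cube has ", dim(data)[3], " channels; axis has ", n_channels(axis))
  if (min(data) < 0 || max(data) > max_value(settings))
    stop("cube values must lie in [0, ", max_value(settings), "]")
  structure(list(data = data, axis = axis, settings = settings),
            class = "srs_cube")
}

#' @export
print.srs_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("srs_cube: %d x %d pixels, %d channels, %d-bit, zoom %gx\n",
              d[1], d[2], d[3], x$settings$bit_depth, x$settings$zoom))
  invisible(x)
}

#' Write / read a hyperspectral cube as multi-page TIFF plus YAML sidecar
#'
#' Channels are stored as 16-bit TIFF pages in axis order; zoom, laser
#' powers, bit depth and the region table go into a YAML sidecar so the
#' axis and settings round-trip exactly.
#'
#' @param cube an `srs_cube`.
#' @param path TIFF file path; the sidecar is written to
#'   `paste0(path, ".yaml")` unless `sidecar` is given.
#' @param sidecar sidecar YAML path.
#' @return `write_cube` returns `path` invisibly; `read_cube` an
#'   `srs_cube`.
#' @export
write_cube <- function(cube, path, sidecar = paste0(path, ".yaml")) {
  d <- dim(cube$data)
  pages <- lapply(seq_len(d[3]), function(k) cube$data[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(
    regions = unname(lapply(seq_len(nrow(cube$axis$regions)), function(i)
      as.numeric(cube$axis$regions[i, ]))),
    zoom = cube$settings$zoom,
    pump_power = cube$settings$pump_power,
    stokes_power = cube$settings$stokes_power,
    bit_depth = cube$settings$bit_depth), sidecar)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, sidecar = paste0(path, ".yaml")) {
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  data <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- round(pages[[k]] * 65535)
  srs_cube(data, build_spectral_axis(meta$regions),
           acquisition_settings(meta$zoom, unlist(meta$pump_power),
                                unlist(meta$stokes_power), meta$bit_depth))
}
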