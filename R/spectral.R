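# Spectral axis, spectra, reference-set assembly.

#' Component order used throughout the package
#'
#' The fixed column order of reference matrices and weight images:
#' TAG (triacylglycerol), CE (cholesteryl ester), cellular background,
#' water background.
#'
#' @return Character vector of length 4.
#' @export
srs_components <- function() c("TAG", "CE", "cellular_bg", "water_bg")

#' Build a wavenumber axis from acquisition regions
#'
#' Hyperspectral SRS stacks are acquired in a small number of contiguous
#' Raman-shift regions, each sampled on a regular grid. The axis is the
#' concatenation of the per-region grids in acquisition order. A wavenumber
#' shared by two adjacent regions (e.g. 2950 cm^-1 when the CH-stretch
#' window is split at 2950) is deliberately retained as two distinct
#' channels, one per region, because each is a separately acquired image
#' plane; the default three-region lipid axis therefore has 3 x 51 = 153
#' channels.
#'
#' @param regions list of numeric length-3 vectors `c(start, end, step)`
#'   in cm^-1, in acquisition order.
#' @return An object of class `srs_axis` with fields `wavenumbers`
#'   (channel centers, cm^-1), `region_index` (integer region id per
#'   channel) and `regions` (a data.frame with columns start, end, step).
#' @examples
#' ax <- build_spectral_axis(srs_default_regions())
#' length(ax$wavenumbers) # 153
#' @export
build_spectral_axis <- function(regions) {
  if (!is.list(regions) || length(regions) == 0)
    stop("'regions' must be a non-empty list of c(start, end, step) vectors")
  wn <- list(); ridx <- list()
  for (i in seq_along(regions)) {
    r <- as.numeric(regions[[i]])
    if (length(r) != 3 || anyNA(r))
      stop("region ", i, ": expected c(start, end, step)")
    start <- r[1]; end <- r[2]; step <- r[3]
    if (step <= 0) stop("region ", i, ": step must be > 0")
    if (end <= start) stop("region ", i, ": end must exceed start")
    n <- (end - start) / step
    if (abs(n - round(n)) > 1e-9)
      stop("region ", i, " (", start, "-", end, " cm^-1): range not divisible by step ", step)
    wn[[i]] <- start + step * (0:round(n))
    ridx[[i]] <- rep.int(i, round(n) + 1L)
  }
  structure(list(
    wavenumbers = unlist(wn),
    region_index = as.integer(unlist(ridx)),
    regions = data.frame(
      start = vapply(regions, function(r) as.numeric(r[1]), 0),
      end = vapply(regions, function(r) as.numeric(r[2]), 0),
      step = vapply(regions, function(r) as.numeric(r[3]), 0))
  ), class = "srs_axis")
}

#' Default lipid-imaging acquisition regions
#'
#' Three regions at 3 cm^-1 step: the fingerprint window 1625-1775 cm^-1
#' and the CH-stretch window split as 2800-2950 and 2950-3100 cm^-1,
#' yielding a 153-channel axis.
#'
#' @return List of three `c(start, end, step)` vectors.
#' @export
srs_default_regions <- function() {
  list(c(1625, 1775, 3), c(2800, 2950, 3), c(2950, 3100, 3))
}

n_channels <- function(axis) length(axis$wavenumbers)

axes_identical <- function(a, b) {
  isTRUE(all.equal(a$wavenumbers, b$wavenumbers)) &&
    identical(a$region_index, b$region_index)
}

#' @export
print.srs_axis <- function(x, ...) {
  cat("srs_axis:", n_channels(x), "channels in", nrow(x$regions), "regions\n")
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  region %d: %g-%g cm^-1, step %g\n", i,
                x$regions$start[i], x$regions$end[i], x$regions$step[i]))
  invisible(x)
}

#' Construct a spectrum on an axis
#'
#' @param values numeric per-channel intensities (stimulated Raman loss units).
#' @param axis an `srs_axis`.
#' @param kind one of "TAG", "CE", "cellular_bg", "water_bg", "raw",
#'   "cover_glass".
#' @return An `srs_spectrum` object.
#' @export
srs_spectrum <- function(values, axis,
                         kind = c("raw", "TAG", "CE", "cellular_bg",
                                  "water_bg", "cover_glass")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != n_channels(axis))
    stop("spectrum length ", length(values), " does not match axis (",
         n_channels(axis), " channels)")
  structure(list(values = values, axis = axis, kind = kind),
            class = "srs_spectrum")
}

#' @export
print.srs_spectrum <- function(x, ...) {
  cat("srs_spectrum (", x$kind, "): ", n_channels(x$axis), " channels, range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Capped spectral subtraction
#'
#' Subtracts `b` from `a` channel-wise, capping at 0 so the result stays
#' non-negative (SRS intensities are non-negative; the cap avoids
#' propagating negative background-over-subtraction).
#'
#' @param a,b `srs_spectrum` objects on the same axis.
#' @return `srs_spectrum` with values `pmax(a - b, 0)` and `a`'s kind.
#' @export
subtract_capped <- function(a, b) {
  if (!axes_identical(a$axis, b$axis))
    stop("spectra are on different axes")
  srs_spectrum(pmax(a$values - b$values, 0), a$axis, kind = a$kind)
}

# Flatten an H x W x C cube into the (H*W) x C pixel-by-channel matrix D.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Cover-glass background spectrum of a cube
#'
#' The acquisition-specific cover-glass/water background is estimated from
#' the `n_lowest` pixels with the lowest channel-mean intensity; their mean
#' spectrum is returned. When `n_lowest` is left at its default and the
#' image is small, it is clamped to 10% of the pixel count (with a
#' message); an explicitly supplied `n_lowest` larger than the pixel count
#' is an error.
#'
#' @param cube an `srs_cube`.
#' @param n_lowest number of lowest-mean pixels to average (default 2000).
#' @return `srs_spectrum` of kind "cover_glass".
#' @export
cover_glass_background <- function(cube, n_lowest = 2000) {
  D <- cube_matrix(cube)
  N <- nrow(D)
  if (missing(n_lowest) && n_lowest > 0.1 * N) {
    n_lowest <- max(1L, floor(0.1 * N))
    message("cover_glass_background: small image, using n_lowest = ", n_lowest)
  }
  if (n_lowest < 1) stop("n_lowest must be >= 1")
  if (N < n_lowest)
    stop("cube has ", N, " pixels, fewer than n_lowest = ", n_lowest)
  means <- rowMeans(D)
  sel <- order(means)[seq_len(n_lowest)]
  srs_spectrum(colMeans(D[sel, , drop = FALSE]), cube$axis, kind = "cover_glass")
}

#' Mean-collapse a cube after capped background subtraction
#'
#' Produces the 2D intensity image used for segmentation and
#' visualization: per pixel, the background spectrum is subtracted
#' (capped at 0) and the result averaged over channels. This image is
#' never used for spectral decomposition, which operates on raw spectra.
#'
#' @param cube an `srs_cube`.
#' @param background `srs_spectrum` on the cube's axis, or NULL for a
#'   plain channel-mean image.
#' @return numeric H x W matrix.
#' @export
mean_collapse <- function(cube, background = NULL) {
  D <- cube_matrix(cube)
  if (!is.null(background)) {
    if (!axes_identical(cube$axis, background$axis))
      stop("background is on a different axis than the cube")
    D <- pmax(sweep(D, 2L, background$values, "-"), 0)
  }
  matrix(rowMeans(D), nrow = dim(cube$data)[1], ncol = dim(cube$data)[2])
}

# Normalize a ROI specification (integer label matrix, or a list of n x 2
# (row, col) coordinate matrices) to a list of linear pixel-index vectors.
roi_pixel_sets <- function(roi, dims) {
  if (is.matrix(roi) && !is.list(roi) && nrow(roi) == dims[1] &&
      ncol(roi) == dims[2]) {
    ids <- sort(unique(roi[roi > 0]))
    return(lapply(ids, function(k) which(roi == k)))
  }
  if (is.list(roi)) {
    return(lapply(roi, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 2) stop("coordinate ROI must have two columns (row, col)")
      as.integer((m[, 2] - 1L) * dims[1] + m[, 1])
    }))
  }
  stop("ROI must be a label matrix matching the image or a list of (row, col) matrices")
}

roi_mean_spectrum <- function(cube, rois, component) {
  sets <- roi_pixel_sets(rois, dim(cube$data)[1:2])
  if (length(sets) == 0 || sum(lengths(sets)) == 0)
    stop("empty ROI set for component '", component, "'")
  D <- cube_matrix(cube)
  px <- unlist(sets)
  list(values = colMeans(D[px, , drop = FALSE]), n_rois = length(sets))
}

#' Assemble the reference-spectrum matrix S
#'
#' Builds the channels x 4 reference matrix from manually selected ROIs:
#' TAG from droplets of oleic-acid-loaded cells, CE from droplets of
#' cholesterol-loaded cells, cellular background from cytoplasmic regions
#' of lipid-starved cells, and water background from cell-free regions.
#' Each component is the mean spectrum over its pooled ROI pixels; the
#' cellular-background component is then subtracted (capped at 0) from the
#' TAG and CE columns so they represent droplet lipid over the membrane
#' background. Reference spectra are kept on the raw intensity scale: the
#' decomposition weights serve as absolute lipid-amount proxies, so no
#' per-spectrum normalization is applied.
#'
#' @param tag_cube,ce_cube,starved_cube `srs_cube`s sharing one axis.
#' @param tag_rois,ce_rois,cyto_rois,water_rois ROI specifications (label
#'   matrix or list of (row, col) coordinate matrices) on the
#'   corresponding cube.
#' @param water_cube cube from which water ROIs are taken (defaults to
#'   `starved_cube`).
#' @return An `srs_refset`: list with `S` (channels x 4 matrix, columns
#'   `srs_components()`), `axis`, and `provenance` (ROI counts).
#' @export
extract_reference_set <- function(tag_cube, tag_rois, ce_cube, ce_rois,
                                  starved_cube, cyto_rois, water_rois,
                                  water_cube = starved_cube) {
  for (cb in list(ce_cube, starved_cube, water_cube))
    if (!axes_identical(tag_cube$axis, cb$axis))
      stop("all cubes must share one spectral axis")
  tag <- roi_mean_spectrum(tag_cube, tag_rois, "TAG")
  ce <- roi_mean_spectrum(ce_cube, ce_rois, "CE")
  cyto <- roi_mean_spectrum(starved_cube, cyto_rois, "cellular_bg")
  water <- roi_mean_spectrum(water_cube, water_rois, "water_bg")
  for (chk in list(c("TAG", tag$n_rois, 5, 12), c("CE", ce$n_rois, 5, 12),
                   c("cellular_bg", cyto$n_rois, 4, 7),
                   c("water_bg", water$n_rois, 2, 4))) {
    n <- as.numeric(chk[2])
    if (n < as.numeric(chk[3]) || n > as.numeric(chk[4]))
      message("extract_reference_set: ", chk[1], " built from ", n,
              " ROIs (recommended ", chk[3], "-", chk[4], ")")
  }
  S <- cbind(TAG = pmax(tag$values - cyto$values, 0),
             CE = pmax(ce$values - cyto$values, 0),
             cellular_bg = cyto$values,
             water_bg = water$values)
  reference_set(S, tag_cube$axis,
                provenance = c(TAG = tag$n_rois, CE = ce$n_rois,
                               cellular_bg = cyto$n_rois,
                               water_bg = water$n_rois))
}

#' Construct a reference set from a ready-made matrix
#'
#' @param S channels x 4 non-negative matrix, columns in
#'   `srs_components()` order.
#' @param axis `srs_axis` with matching channel count.
#' @param provenance optional named integer vector of source-ROI counts.
#' @return `srs_refset` object.
#' @export
reference_set <- function(S, axis, provenance = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != n_channels(axis))
    stop("S has ", nrow(S), " rows; axis has ", n_channels(axis), " channels")
  if (ncol(S) != 4) stop("S must have 4 columns")
  if (any(S < 0)) stop("reference spectra must be non-negative")
  colnames(S) <- srs_components()
  structure(list(S = S, axis = axis, provenance = provenance),
            class = "srs_refset")
}

#' @export
print.srs_refset <- function(x, ...) {
  cat("srs_refset:", nrow(x$S), "channels x 4 components\n")
  cat("  column maxima:", paste(signif(apply(x$S, 2, max), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a reference set as CSV
#'
#' The CSV holds one wavenumber column and the four component columns;
#' region definitions go into `#`-prefixed header lines so the axis can be
#' rebuilt. Values are written with 17 significant digits, giving a
#' bit-exact double round trip.
#'
#' @param refs an `srs_refset`.
#' @param path output file.
#' @return `write_reference_set` returns `path` invisibly;
#'   `read_reference_set` returns an `srs_refset`.
#' @export
write_reference_set <- function(refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(refs$axis$regions)))
    writeLines(sprintf("# region %.17g %.17g %.17g",
                       refs$axis$regions$start[i], refs$axis$regions$end[i],
                       refs$axis$regions$step[i]), con)
  if (!is.null(refs$provenance))
    writeLines(paste0("# provenance ",
                      paste(refs$provenance, collapse = " ")), con)
  df <- data.frame(wavenumber = refs$axis$wavenumbers, refs$S,
                   check.names = FALSE)
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  reg_lines <- grep("^# region ", hdr, value = TRUE)
  regions <- lapply(reg_lines, function(l)
    as.numeric(strsplit(sub("^# region ", "", l), " ")[[1]]))
  prov <- NULL
  pl <- grep("^# provenance ", hdr, value = TRUE)
  if (length(pl) == 1) {
    prov <- as.integer(strsplit(sub("^# provenance ", "", pl), " ")[[1]])
    names(prov) <- srs_components()
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, check.names = FALSE)
  axis <- build_spectral_axis(regions)
  reference_set(as.matrix(df[, srs_components()]), axis, provenance = prov)
}
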