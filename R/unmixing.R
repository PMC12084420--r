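# Per-pixel non-negative least-squares unmixing, saturation masking,
# settings normalization and false-color rendering.

# Lawson-Hanson active-set NNLS on the normal equations:
# minimize ||S w - d||_2 s.t. w >= 0, given G = S'S and b = S'd.
# With 4 components the active-set loop is at most a handful of 4x4 solves.
nnls_gram <- function(G, b, tol = NULL) {
  p <- length(b)
  if (is.null(tol)) tol <- 1e-12 * max(abs(b), 1)
  P <- rep(FALSE, p)
  w <- numeric(p)
  grad <- b
  for (outer in seq_len(10 * p)) {
    cand <- which(!P)
    if (length(cand) == 0 || max(grad[cand]) <= tol) break
    P[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      z <- numeric(p)
      z[P] <- solve(G[P, P, drop = FALSE], b[P])
      if (all(z[P] > 0)) { w <- z; break }
      inP <- which(P)
      neg <- inP[z[inP] <= 0]
      alpha <- min(w[neg] / (w[neg] - z[neg]))
      w <- w + alpha * (z - w)
      drop_set <- inP[w[inP] <= tol]
      P[drop_set] <- FALSE
      w[!P] <- 0
    }
    grad <- b - as.vector(G %*% w)
  }
  w
}

check_refs <- function(S) {
  if (any(colSums(S^2) == 0))
    stop("degenerate reference: component '",
         colnames(S)[which(colSums(S^2) == 0)[1]], "' is all zero")
}

#' Non-negative least-squares decomposition of one pixel spectrum
#'
#' Solves `min ||S w - d||_2` subject to `w >= 0` by a Lawson-Hanson
#' active-set iteration on the normal equations. With the four-component
#' reference matrix this is exact (finite termination).
#'
#' @param d numeric pixel spectrum (length = rows of `S`).
#' @param S reference matrix (channels x components), e.g. `refs$S`.
#' @return named non-negative weight vector, one entry per component.
#' @export
nnls_pixel <- function(d, S) {
  S <- as.matrix(S)
  if (length(d) != nrow(S))
    stop("spectrum length ", length(d), " does not match reference rows ", nrow(S))
  check_refs(S)
  w <- nnls_gram(crossprod(S), as.vector(crossprod(S, d)))
  names(w) <- colnames(S)
  w
}

#' Decompose a hyperspectral cube into component weight planes
#'
#' Applies [nnls_pixel()] to every pixel spectrum of the cube against the
#' reference set, yielding the H x W x 4 weight image whose TAG and CE
#' planes are the SRS lipid intensities. Raw spectra are decomposed as-is:
#' the cellular-background component of the model performs a pixel-wise
#' scaled background subtraction implicitly, so no explicit subtraction is
#' applied beforehand. Pixels are independent, and the unconstrained
#' least-squares solution is used directly wherever it is already
#' feasible (identical result, no iteration needed).
#'
#' @param cube an `srs_cube`.
#' @param refs an `srs_refset` on the cube's axis.
#' @param saturation logical: also compute the lock-in saturation mask via
#'   [detect_saturation()] with default thresholds.
#' @return An `srs_weights` object: `W` (H x W x 4 array),
#'   `saturation` (H x W logical), `settings`, `normalized_to` (NULL until
#'   [normalize_weights()] is applied).
#' @export
decompose_cube <- function(cube, refs, saturation = TRUE) {
  if (!axes_identical(cube$axis, refs$axis))
    stop("cube and reference set are on different axes")
  S <- refs$S
  check_refs(S)
  D <- cube_matrix(cube)
  G <- crossprod(S)
  B <- crossprod(S, t(D)) # 4 x N
  W <- solve(G, B)        # unconstrained solution, exact when feasible
  redo <- which(apply(W < -1e-12 * max(abs(B), 1), 2, any))
  for (i in redo) W[, i] <- nnls_gram(G, B[, i])
  W[W < 0] <- 0
  d <- dim(cube$data)
  Warr <- array(t(W), c(d[1], d[2], 4),
                dimnames = list(NULL, NULL, srs_components()))
  sat <- if (saturation) detect_saturation(cube) else
    matrix(FALSE, d[1], d[2])
  structure(list(W = Warr, saturation = sat, settings = cube$settings,
                 normalized_to = NULL), class = "srs_weights")
}

#' @export
print.srs_weights <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("srs_weights: %d x %d pixels, 4 components; %d saturated px; %s\n",
              d[1], d[2], sum(x$saturation),
              if (is.null(x$normalized_to)) "unnormalized" else "normalized"))
  invisible(x)
}

#' Flag lock-in-saturated pixels
#'
#' A pixel is saturated when its spectrum shows a flat, high plateau:
#' some sliding window spanning `window_cm` (12 cm^-1, i.e. 5 consecutive
#' channels at the 3 cm^-1 step) has sample standard deviation below
#' `std_thresh` while all its values exceed `value_thresh` (3500, about
#' 85% of the 12-bit maximum 4095). Windows never cross acquisition-region
#' boundaries, since a wavenumber window across a region gap is not a
#' contiguous spectral range.
#'
#' @param cube an `srs_cube`.
#' @param window_cm window width in cm^-1 (default 12).
#' @param std_thresh flatness threshold on the windowed sample standard
#'   deviation (default 50).
#' @param value_thresh intensity floor for a saturated window (default 3500).
#' @return H x W logical matrix.
#' @export
detect_saturation <- function(cube, window_cm = 12, std_thresh = 50,
                              value_thresh = 3500) {
  D <- cube_matrix(cube)
  flag <- rep(FALSE, nrow(D))
  for (r in seq_len(nrow(cube$axis$regions))) {
    ch <- which(cube$axis$region_index == r)
    step <- cube$axis$regions$step[r]
    wlen <- max(2L, as.integer(round(window_cm / step)) + 1L)
    if (length(ch) < wlen) next
    for (s in seq_len(length(ch) - wlen + 1L)) {
      sub <- D[, ch[s:(s + wlen - 1L)], drop = FALSE]
      m <- rowMeans(sub)
      v <- (rowSums(sub^2) - wlen * m^2) / (wlen - 1)
      lowstd <- sqrt(pmax(v, 0)) < std_thresh
      high <- do.call(pmin, as.data.frame(sub)) > value_thresh
      flag <- flag | (lowstd & high)
    }
  }
  matrix(flag, dim(cube$data)[1], dim(cube$data)[2])
}

# Region index in which each reference component has its spectral maximum;
# used to pick the per-region laser powers that dominate that component.
component_regions <- function(refs) {
  apply(refs$S, 2, function(col) refs$axis$region_index[which.max(col)])
}

power_at <- function(p, region) if (length(p) == 1) p else p[region]

#' Linearly adjust weights to a common acquisition setting
#'
#' SRS signal is linear in pump x Stokes power, so weights acquired under
#' different laser settings are made comparable by the factor
#' `(pump_target * stokes_target) / (pump * stokes)`, evaluated for the
#' region where each component's reference spectrum peaks (relevant when
#' powers differ per region), together with a zoom correction
#' `(zoom_target / zoom)^zoom_exponent` (exponent 0 by default: zoom is
#' treated as purely geometric).
#'
#' @param wi an `srs_weights` object.
#' @param settings acquisition settings the weights were measured under
#'   (defaults to those recorded in `wi`).
#' @param target settings to normalize to.
#' @param refs reference set; required only when per-region powers differ,
#'   to locate each component's dominant region.
#' @param zoom_exponent exponent of the zoom correction (default 0).
#' @return `srs_weights` with scaled planes and `normalized_to = target`.
#' @export
normalize_weights <- function(wi, settings = wi$settings, target,
                              refs = NULL, zoom_exponent = 0) {
  if (any(settings$pump_power <= 0) || any(settings$stokes_power <= 0) ||
      any(target$pump_power <= 0) || any(target$stokes_power <= 0))
    stop("laser powers must be > 0")
  nr <- max(length(settings$pump_power), length(settings$stokes_power),
            length(target$pump_power), length(target$stokes_power))
  comp_region <- if (nr > 1) {
    if (is.null(refs))
      stop("per-region powers supplied; 'refs' is needed to locate components")
    component_regions(refs)
  } else rep(1L, 4)
  out <- wi
  for (k in 1:4) {
    r <- comp_region[k]
    f <- (power_at(target$pump_power, r) * power_at(target$stokes_power, r)) /
      (power_at(settings$pump_power, r) * power_at(settings$stokes_power, r)) *
      (target$zoom / settings$zoom)^zoom_exponent
    out$W[, , k] <- wi$W[, , k] * f
  }
  out$settings <- target
  out$normalized_to <- target
  out
}

#' Render a false-color lipid image
#'
#' TAG maps to magenta and CE to green, each scaled linearly and clipped
#' at `clip_fraction` times the maximum lipid intensity of the image.
#' Pixels outside the segmented cells and saturated pixels are colored
#' gray, since their weights are not interpretable as lipid amounts.
#'
#' @param wi an `srs_weights` object.
#' @param masks optional `srs_masks`; when given, pixels with cell label 0
#'   are grayed out.
#' @param clip_fraction upper display limit as a fraction of the maximum
#'   lipid weight; the conventional choices are 0.2-0.5.
#' @param gray gray level for masked pixels (default 0.5).
#' @return H x W x 3 numeric array (RGB in [0, 1]).
#' @export
render_falsecolor <- function(wi, masks = NULL, clip_fraction = 0.3,
                              gray = 0.5) {
  if (clip_fraction <= 0) stop("clip_fraction must be > 0")
  tag <- wi$W[, , "TAG"]; ce <- wi$W[, , "CE"]
  top <- clip_fraction * max(tag, ce, 1e-12)
  tagn <- pmin(tag / top, 1); cen <- pmin(ce / top, 1)
  d <- dim(tag)
  rgb <- array(0, c(d, 3))
  rgb[, , 1] <- tagn; rgb[, , 3] <- tagn   # magenta
  rgb[, , 2] <- cen                        # green
  grayed <- wi$saturation
  if (!is.null(masks)) grayed <- grayed | (masks$cells == 0)
  for (k in 1:3) { p <- rgb[, , k]; p[grayed] <- gray; rgb[, , k] <- p }
  rgb
}

#' Write / read weight images as 32-bit float TIFF
#'
#' Pages are the four component planes followed by the saturation mask;
#' planes are stored divided by a common scale recorded in the YAML
#' sidecar (float TIFF pages hold values in [0, 1]).
#'
#' @param wi an `srs_weights` object.
#' @param path TIFF path; sidecar defaults to `paste0(path, ".yaml")`.
#' @param sidecar sidecar YAML path.
#' @return `write_weights` returns `path` invisibly; `read_weights` an
#'   `srs_weights`.
#' @export
write_weights <- function(wi, path, sidecar = paste0(path, ".yaml")) {
  scale <- max(wi$W, 1)
  pages <- c(lapply(1:4, function(k) wi$W[, , k] / scale),
             list(wi$saturation * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(scale = scale,
                        normalized = !is.null(wi$normalized_to),
                        zoom = wi$settings$zoom,
                        pump_power = wi$settings$pump_power,
                        stokes_power = wi$settings$stokes_power,
                        bit_depth = wi$settings$bit_depth), sidecar)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path, sidecar = paste0(path, ".yaml")) {
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  W <- array(0, c(d, 4), dimnames = list(NULL, NULL, srs_components()))
  for (k in 1:4) W[, , k] <- pages[[k]] * meta$scale
  settings <- acquisition_settings(meta$zoom, unlist(meta$pump_power),
                                   unlist(meta$stokes_power), meta$bit_depth)
  structure(list(W = W, saturation = pages[[5]] > 0.5, settings = settings,
                 normalized_to = if (isTRUE(meta$normalized)) settings),
            class = "srs_weights")
}

#' Write a false-color rendering as PNG
#'
#' @param rgb H x W x 3 array from [render_falsecolor()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_falsecolor_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
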