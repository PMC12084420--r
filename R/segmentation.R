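# Nucleus / cell / lipid-droplet segmentation and NE-LD classification.
# Standard morphology (blur, Otsu, watershed, seeded propagation, labeling)
# is delegated to EBImage; the a trous spot detector is implemented here.

# EBImage returns S4 Image objects; strip to a plain matrix.
ebi_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

as_label_matrix <- function(x) {
  m <- round(ebi_mat(x))
  storage.mode(m) <- "integer"
  m
}

relabel_sequential <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

#' Segment nuclei from a nuclear-stain image
#'
#' Classical pipeline for high-contrast nuclear stains: Gaussian
#' smoothing, automatic (Otsu) bimodal threshold, hole filling,
#' distance-transform watershed to split touching nuclei, and removal of
#' objects below `min_area_px`.
#'
#' @param nuclear_stain single-channel numeric matrix.
#' @param min_area_px minimum object area in pixels (default 64).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclear_stain, min_area_px = 64, sigma = 2) {
  img <- as.matrix(nuclear_stain)
  if (max(img) <= min(img)) return(as_label_matrix(img * 0))
  x <- (img - min(img)) / (max(img) - min(img))
  xs <- ebi_mat(EBImage::gblur(EBImage::Image(x), sigma = sigma))
  mask <- xs > EBImage::otsu(EBImage::Image(xs))
  mask <- ebi_mat(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- as_label_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  areas <- tabulate(labels[labels > 0])
  small <- which(areas < min_area_px)
  labels[labels %in% small] <- 0L
  relabel_sequential(labels)
}

#' Grow cell regions outward from nucleus seeds
#'
#' Seeded region growing in the style of CellProfiler's IdentifySecondary
#' "Propagation" method (EBImage's `propagate`): each foreground pixel of
#' the intensity image is assigned to the nucleus seed reachable at the
#' lowest cost, where the cost mixes Euclidean step length (weighted by
#' `regularization`) with local intensity differences, so cell boundaries
#' settle on intensity ridges/valleys between cells.
#'
#' @param nuclei integer label matrix of nucleus seeds.
#' @param intensity 2D image guiding the propagation (e.g. a
#'   mean-collapsed SRS image).
#' @param regularization lambda >= 0; large values approach a Voronoi
#'   partition of the foreground, 0 follows intensity structure only.
#' @param mask optional logical foreground mask; by default an Otsu
#'   threshold of the log-transformed intensity (robust to the long
#'   bright tail of droplet pixels), always including the seed pixels.
#' @return integer label matrix of cells; every nucleus pixel keeps its
#'   label.
#' @export
propagate_cells <- function(nuclei, intensity, regularization = 0.05,
                            mask = NULL) {
  nuclei <- as_label_matrix(nuclei)
  if (all(nuclei == 0)) return(nuclei)
  img <- as.matrix(intensity)
  rng <- max(img) - min(img)
  x <- if (rng > 0) (img - min(img)) / rng else img * 0
  if (is.null(mask)) {
    xl <- log1p(img - min(img))
    if (max(xl) > 0) xl <- xl / max(xl)
    mask <- xl > EBImage::otsu(EBImage::Image(xl))
  }
  mask <- mask | nuclei > 0
  as_label_matrix(EBImage::propagate(EBImage::Image(x),
                                     EBImage::Image(nuclei),
                                     mask = EBImage::Image(mask * 1),
                                     lambda = regularization))
}

# One level of the a trous B3-spline smoothing: separable convolution with
# [1,4,6,4,1]/16, kernel taps spread 'step' pixels apart, edges replicated.
b3_smooth <- function(m, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2L, -1L, 0L, 1L, 2L) * step
  shift_rows <- function(m, k) {
    idx <- pmin(pmax(seq_len(nrow(m)) + k, 1L), nrow(m))
    m[idx, , drop = FALSE]
  }
  shift_cols <- function(m, k) {
    idx <- pmin(pmax(seq_len(ncol(m)) + k, 1L), ncol(m))
    m[, idx, drop = FALSE]
  }
  tmp <- 0
  for (i in seq_along(offs)) tmp <- tmp + w[i] * shift_rows(m, offs[i])
  out <- 0
  for (i in seq_along(offs)) out <- out + w[i] * shift_cols(tmp, offs[i])
  out
}

#' A trous wavelet decomposition of an image
#'
#' Undecimated B3-spline wavelet transform: smoothed approximations
#' `c_j = B3_j * c_{j-1}` with hole spacing `2^(j-1)`, detail planes
#' `w_j = c_{j-1} - c_j`. The image equals the sum of all detail planes
#' plus the final approximation.
#'
#' @param image numeric matrix.
#' @param levels number of detail planes (>= 1).
#' @return list with `planes` (list of detail matrices) and `residual`.
#' @export
atrous_decompose <- function(image, levels) {
  if (levels < 1) stop("levels must be >= 1")
  c_prev <- as.matrix(image)
  planes <- vector("list", levels)
  for (j in seq_len(levels)) {
    c_next <- b3_smooth(c_prev, 2L^(j - 1L))
    planes[[j]] <- c_prev - c_next
    c_prev <- c_next
  }
  list(planes = planes, residual = c_prev)
}

#' Detect lipid droplets by multi-level a trous spot detection
#'
#' Detail planes 2..levels of the a trous transform are thresholded at
#' `k_mad` times their median absolute deviation; the pixel-wise AND of
#' the thresholded planes keeps spot-scale structures supported across
#' scales (plane 1, mostly pixel noise, is skipped). Because step edges
#' (cell borders) also respond across wavelet scales, the mask is
#' additionally gated by a white top-hat (image minus its morphological
#' opening with a disc of `tophat_diameter` pixels): flat regions and
#' straight or gently curved steps open to themselves and give zero
#' top-hat, while blobs smaller than the disc survive. Touching
#' detections are split by a watershed on the summed positive wavelet
#' response, and components of at least `min_px` pixels become droplet
#' labels.
#'
#' @param image 2D collapsed intensity image.
#' @param levels number of wavelet levels (default 3; detail scales up
#'   to ~2^levels pixels, matching micron-scale droplets).
#' @param k_mad threshold multiplier on the per-plane MAD (default 5;
#'   the MAD of a structured plane overstates the noise scale, so the
#'   effective z-score is lower).
#' @param min_px minimum droplet area in pixels (default 4).
#' @param tophat_diameter disc diameter of the top-hat opening in pixels;
#'   should exceed the largest droplet diameter (default 13).
#' @param split_tolerance watershed merge tolerance, in intensity units
#'   of the wavelet response (default 10).
#' @return integer label matrix of droplets.
#' @export
detect_droplets_atrous <- function(image, levels = 3, k_mad = 5, min_px = 4,
                                   tophat_diameter = 13,
                                   split_tolerance = 10) {
  image <- as.matrix(image)
  dec <- atrous_decompose(image, levels)
  use <- if (levels >= 2) 2:levels else 1
  mask <- NULL
  for (j in use) {
    p <- dec$planes[[j]]
    m <- p > k_mad * stats::mad(p)
    mask <- if (is.null(mask)) m else mask & m
  }
  mask[!is.finite(mask)] <- FALSE
  top <- max(image)
  if (top > 0 && any(mask)) {
    opened <- ebi_mat(EBImage::opening(
      EBImage::Image(image / top),
      EBImage::makeBrush(as.integer(tophat_diameter), "disc"))) * top
    tophat <- image - opened
    mask <- mask & (tophat > pmax(k_mad * stats::mad(tophat), 1e-6))
  }
  if (!any(mask)) return(as_label_matrix(mask * 0))
  resp <- 0
  for (j in use) resp <- resp + pmax(dec$planes[[j]], 0)
  labels <- as_label_matrix(EBImage::watershed(EBImage::Image(resp * mask),
                                               tolerance = split_tolerance))
  areas <- tabulate(labels[labels > 0])
  labels[labels %in% which(areas < min_px)] <- 0L
  relabel_sequential(labels)
}

#' Classify droplets as nuclear-envelope-associated (NE-LD)
#'
#' A droplet is an NE-LD when its mask overlaps the nuclear mask by at
#' least one pixel (partial overlap counts).
#'
#' @param droplets droplet label matrix.
#' @param nuclei nucleus label matrix of the same shape.
#' @return named logical vector over droplet labels present.
#' @export
classify_ne_droplets <- function(droplets, nuclei) {
  if (!all(dim(droplets) == dim(nuclei)))
    stop("droplets and nuclei must have the same shape")
  ids <- sort(unique(droplets[droplets > 0]))
  if (length(ids) == 0) return(setNames(logical(0), character(0)))
  ov <- tabulate(droplets[droplets > 0 & nuclei > 0], nbins = max(ids))
  setNames(ov[ids] > 0, ids)
}

#' Remove cells below a physical diameter threshold
#'
#' Cells whose equivalent-circle diameter `2 * sqrt(area / pi) *
#' pixel_size_um` falls below `min_diameter_um` are removed (used to
#' filter non-differentiated cells at the conventional 20 um cutoff).
#'
#' @param cells cell label matrix.
#' @param min_diameter_um diameter threshold in micrometers (default 20).
#' @param pixel_size_um pixel size in micrometers.
#' @return label matrix with small cells set to background (labels of the
#'   surviving cells are preserved).
#' @export
filter_small_cells <- function(cells, min_diameter_um = 20, pixel_size_um) {
  cells <- as_label_matrix(cells)
  if (all(cells == 0)) return(cells)
  areas <- tabulate(cells[cells > 0])
  diam <- 2 * sqrt(areas / pi) * pixel_size_um
  cells[cells %in% which(diam < min_diameter_um & areas > 0)] <- 0L
  cells
}

#' Assign droplets to cells
#'
#' Majority overlap with the cell label image; droplets with no cell
#' overlap are assigned to the nearest cell within `max_dist_px` of their
#' centroid, otherwise dropped (NA, with a message).
#'
#' @param droplets droplet label matrix.
#' @param cells cell label matrix.
#' @param max_dist_px rescue radius in pixels (default 5).
#' @return named integer vector: cell id (or NA) per droplet label.
#' @export
assign_droplets_to_cells <- function(droplets, cells, max_dist_px = 5) {
  ids <- sort(unique(droplets[droplets > 0]))
  out <- setNames(rep(NA_integer_, length(ids)), ids)
  if (length(ids) == 0) return(out)
  cell_px <- which(cells > 0, arr.ind = TRUE)
  for (i in seq_along(ids)) {
    px <- which(droplets == ids[i])
    cl <- cells[px]
    cl <- cl[cl > 0]
    if (length(cl) > 0) {
      out[i] <- as.integer(names(which.max(table(cl))))
    } else if (nrow(cell_px) > 0) {
      cen <- c(mean((px - 1) %% nrow(droplets) + 1),
               mean((px - 1) %/% nrow(droplets) + 1))
      d2 <- (cell_px[, 1] - cen[1])^2 + (cell_px[, 2] - cen[2])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= max_dist_px)
        out[i] <- cells[cell_px[j, 1], cell_px[j, 2]]
    }
  }
  if (anyNA(out))
    message("assign_droplets_to_cells: ", sum(is.na(out)),
            " droplet(s) without a cell within ", max_dist_px, " px dropped")
  out
}

#' Bundle segmentation masks
#'
#' @param nuclei,cells,droplets integer label matrices of one shape.
#' @param pixel_size_um pixel size in micrometers.
#' @return An `srs_masks` object.
#' @export
segmentation_masks <- function(nuclei, cells, droplets, pixel_size_um = 1) {
  nuclei <- as_label_matrix(nuclei); cells <- as_label_matrix(cells)
  droplets <- as_label_matrix(droplets)
  if (!all(dim(nuclei) == dim(cells)) || !all(dim(cells) == dim(droplets)))
    stop("mask shapes differ")
  structure(list(nuclei = nuclei, cells = cells, droplets = droplets,
                 pixel_size_um = pixel_size_um), class = "srs_masks")
}

#' Write / read a label image as 16-bit TIFF
#'
#' @param labels integer label matrix (values < 65536).
#' @param path TIFF path.
#' @return `write_label_image` returns `path` invisibly;
#'   `read_label_image` an integer matrix.
#' @export
write_label_image <- function(labels, path) {
  if (max(labels) > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(as.matrix(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  as_label_matrix(round(tiff::readTIFF(path) * 65535))
}
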