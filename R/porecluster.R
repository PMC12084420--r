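# Nuclear-pore spot detection and neighborhood-graph clustering.

#' Construct a pore coordinate set
#'
#' @param coords n x 2 or n x 3 numeric matrix of pore positions in um.
#' @param nucleus_measure nuclear surface area (um^2, 2D context) or
#'   volume (um^3, 3D context); optional.
#' @return An `srs_pores` object with fields coords, dim, n_pores,
#'   nucleus_measure.
#' @export
pore_set <- function(coords, nucleus_measure = NA_real_) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0 && !all(is.finite(coords)))
    stop("pore coordinates must be finite")
  if (nrow(coords) > 0 && !ncol(coords) %in% 2:3)
    stop("coords must have 2 or 3 columns")
  structure(list(coords = coords,
                 dim = if (nrow(coords) == 0) 2L else ncol(coords),
                 n_pores = nrow(coords),
                 nucleus_measure = nucleus_measure),
            class = "srs_pores")
}

#' Cluster pores by a distance-thresholded neighborhood graph
#'
#' Builds a graph with pores as nodes and edges between pores closer than
#' the effective threshold; connected components are the clusters. When a
#' reference nucleus measure is supplied, the threshold is adjusted for
#' nucleus size as `base_threshold_um * (nucleus_measure /
#' ref_measure)^exponent` with exponent `1/dim` by default (a length
#' scale proportional to the dim-th root of area/volume); with
#' `ref_measure = NULL` the threshold is used fixed, the convention for
#' 2D analyses.
#'
#' @param pores an `srs_pores` object.
#' @param base_threshold_um base distance threshold in um (> 0).
#' @param ref_measure reference nucleus measure, or NULL for a fixed
#'   threshold.
#' @param exponent size-adjustment exponent (default `1/pores$dim`).
#' @return list with `labels` (integer cluster id per pore, numbered by
#'   first occurrence), `n_clusters`, `cluster_sizes`,
#'   `effective_threshold_um`.
#' @export
cluster_pores <- function(pores, base_threshold_um, ref_measure = NULL,
                          exponent = 1 / pores$dim) {
  if (base_threshold_um <= 0) stop("base_threshold_um must be > 0")
  thr <- base_threshold_um
  if (!is.null(ref_measure)) {
    if (!is.finite(pores$nucleus_measure))
      stop("pore set has no nucleus_measure to adjust the threshold with")
    thr <- base_threshold_um * (pores$nucleus_measure / ref_measure)^exponent
  }
  n <- pores$n_pores
  if (n == 0)
    return(list(labels = integer(0), n_clusters = 0L,
                cluster_sizes = integer(0), effective_threshold_um = thr))
  adj <- as.matrix(stats::dist(pores$coords)) < thr
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  labels <- as.integer(match(memb, unique(memb))) # renumber by first occurrence
  list(labels = labels, n_clusters = max(labels),
       cluster_sizes = tabulate(labels), effective_threshold_um = thr)
}

#' Detect nuclear pores in a 2D image
#'
#' Spot detection via the shared a trous detector (suitable for raw
#' NUP-GFP-style channels or externally produced pixel-classification
#' probability images), returning spot centroids in um. Two spots closer
#' than the detector's resolution merge into one centroid.
#'
#' @param pore_channel 2D image.
#' @param pixel_size_um pixel size in um (default 1).
#' @param levels,k_mad,min_px a trous detector parameters (see
#'   [detect_droplets_atrous()]); pore-scale defaults.
#' @return An `srs_pores` object with 0-based pixel-centered coordinates
#'   (x = column, y = row) scaled to um.
#' @export
detect_pores_2d <- function(pore_channel, pixel_size_um = 1, levels = 3,
                            k_mad = 3, min_px = 2) {
  labels <- detect_droplets_atrous(pore_channel, levels = levels,
                                   k_mad = k_mad, min_px = min_px)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(pore_set(matrix(numeric(0), 0, 2)))
  px <- which(labels > 0, arr.ind = TRUE)
  g <- labels[labels > 0]
  cx <- rowsum(px[, 2] - 1, g)[, 1] / tabulate(g)[ids]
  cy <- rowsum(px[, 1] - 1, g)[, 1] / tabulate(g)[ids]
  pore_set(cbind(x_um = cx * pixel_size_um, y_um = cy * pixel_size_um))
}

#' Pore surface density
#'
#' @param n_pores pore count.
#' @param surface_area_um2 nuclear surface area in um^2 (> 0).
#' @return pores per um^2.
#' @export
pore_density <- function(n_pores, surface_area_um2) {
  if (surface_area_um2 <= 0) stop("surface area must be > 0")
  n_pores / surface_area_um2
}

#' Read / write pore coordinates as CSV
#'
#' Columns x_um, y_um and optionally z_um.
#'
#' @param pores an `srs_pores` object.
#' @param path CSV path.
#' @return `write_pore_csv` returns `path` invisibly; `read_pore_csv` an
#'   `srs_pores`.
#' @export
write_pore_csv <- function(pores, path) {
  cols <- c("x_um", "y_um", "z_um")[seq_len(pores$dim)]
  df <- as.data.frame(pores$coords)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pore_csv
#' @export
read_pore_csv <- function(path) {
  df <- utils::read.csv(path)
  pore_set(as.matrix(df[, intersect(c("x_um", "y_um", "z_um"), names(df))]))
}
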