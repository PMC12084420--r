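# Subcellular-distribution metrics: nuclear proximity, nuc/cyto
# translocation ratio, focus-slice selection, photoconversion ratio.

# Euclidean distance of every pixel to the nearest TRUE pixel of `target`.
distance_to <- function(target) {
  if (!any(target)) return(matrix(Inf, nrow(target), ncol(target)))
  ebi_mat(EBImage::distmap(EBImage::Image((!target) * 1)))
}

# Outer contour of a mask: mask pixels 4-adjacent to a non-mask pixel or
# on the image border.
mask_contour <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  inner <- pad[2:(n + 1), 2:(m + 1)] & pad[1:n, 2:(m + 1)] &
    pad[3:(n + 2), 2:(m + 1)] & pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  mask & !inner
}

#' Intensity-weighted nuclear-proximity score
#'
#' Summarizes where a fluorescence signal sits between the nucleus and
#' the plasma membrane: `sum_k (i_k / I) * d_PM,k / (d_N,k + d_PM,k)`
#' over cell pixels k, where `d_N` is the Euclidean distance to the
#' nucleus mask and `d_PM` the distance to the outer contour of the cell
#' mask. The score is 1 when all intensity is in the nucleus (d_N = 0)
#' and 0 when all intensity sits on the cell-mask contour (d_PM = 0);
#' pixels with d_N = d_PM = 0 count as nuclear (weight 1). The score is
#' invariant to uniform intensity scaling.
#'
#' @param intensity 2D fluorescence image.
#' @param nucleus_mask logical (or 0/1) nucleus mask.
#' @param cell_mask logical cell mask containing the nucleus mask.
#' @return scalar in [0, 1].
#' @export
nuclear_proximity <- function(intensity, nucleus_mask, cell_mask) {
  intensity <- as.matrix(intensity)
  nuc <- as.matrix(nucleus_mask) > 0
  cell <- as.matrix(cell_mask) > 0
  if (any(nuc & !cell)) stop("cell mask must contain the nucleus mask")
  I <- sum(intensity[cell])
  if (I <= 0) stop("total intensity in the cell is zero")
  d_n <- distance_to(nuc)
  d_pm <- distance_to(mask_contour(cell))
  frac <- ifelse(d_n == 0, 1, d_pm / (d_n + d_pm))
  sum((intensity[cell] / I) * frac[cell])
}

#' Well-level background intensity outside all cells
#'
#' @param intensity 2D image.
#' @param cells cell label matrix (0 = outside every cell).
#' @param method "mean" (default) or "median" of the outside-cell pixels.
#' @return scalar background level.
#' @export
well_background <- function(intensity, cells, method = c("mean", "median")) {
  method <- match.arg(method)
  out <- as.matrix(intensity)[as.matrix(cells) == 0]
  if (length(out) == 0) stop("no pixels outside cells")
  if (method == "mean") mean(out) else stats::median(out)
}

#' Background-subtracted nuclear/cytoplasmic translocation ratio
#'
#' The translocation readout for a single cell: mean nuclear intensity
#' over mean cytoplasmic (cell minus nucleus) intensity, both after
#' subtracting the well-level outside-cell background. A non-positive
#' background-subtracted cytoplasmic mean flags the record invalid
#' (ratio NA) rather than producing a nonsensical ratio.
#'
#' @param intensity 2D image.
#' @param nucleus_mask,cell_mask logical masks for one cell.
#' @param background well-level background (e.g. from
#'   [well_background()]).
#' @param baseline_mean optional mean ratio of the baseline condition;
#'   when given, `ratio_rel_baseline = ratio / baseline_mean`.
#' @param cell_id optional identifier copied into the record.
#' @return one-row data.frame: cell_id, nuc_mean, cyto_mean, background,
#'   ratio, ratio_rel_baseline, valid.
#' @export
nuccyto_translocation <- function(intensity, nucleus_mask, cell_mask,
                                  background, baseline_mean = NULL,
                                  cell_id = NA_integer_) {
  intensity <- as.matrix(intensity)
  nuc <- as.matrix(nucleus_mask) > 0
  cell <- as.matrix(cell_mask) > 0
  cyto <- cell & !nuc
  if (!any(cyto)) stop("cytoplasmic area is empty")
  if (!any(nuc)) stop("nuclear area is empty")
  nuc_mean <- mean(intensity[nuc])
  cyto_mean <- mean(intensity[cyto])
  den <- cyto_mean - background
  valid <- den > 0
  ratio <- if (valid) (nuc_mean - background) / den else NA_real_
  data.frame(cell_id = cell_id, nuc_mean = nuc_mean, cyto_mean = cyto_mean,
             background = background, ratio = ratio,
             ratio_rel_baseline = if (!is.null(baseline_mean))
               ratio / baseline_mean else NA_real_,
             valid = valid)
}

#' Reduce a z-stack to a 2D image per channel
#'
#' Either selects, for all channels, the slice where the reference
#' channel (typically the nuclear stain) has its highest total intensity
#' (ties break to the lowest index), or collapses each channel by
#' maximum-intensity projection.
#'
#' @param stacks named list of H x W x Z arrays (channels).
#' @param reference H x W x Z array guiding slice selection (ignored in
#'   projection mode).
#' @param mode "best_slice" or "max_projection".
#' @return named list of H x W matrices; attribute `slice` holds the
#'   chosen index in best_slice mode.
#' @export
select_focus_slice <- function(stacks, reference = NULL,
                               mode = c("best_slice", "max_projection")) {
  mode <- match.arg(mode)
  if (length(stacks) == 0) stop("empty stack list")
  nz <- dim(stacks[[1]])[3]
  if (is.null(nz) || nz < 1) stop("stacks must be H x W x Z arrays")
  if (mode == "best_slice") {
    if (is.null(reference)) stop("best_slice mode needs a reference stack")
    if (dim(reference)[3] != nz) stop("slice counts differ")
    totals <- apply(reference, 3, sum)
    idx <- which.max(totals) # which.max takes the first maximum
    out <- lapply(stacks, function(s) s[, , idx])
    attr(out, "slice") <- idx
    out
  } else {
    lapply(stacks, function(s) apply(s, c(1, 2), max))
  }
}

#' Photoconversion (Dendra2-style) nuclear-entry ratio
#'
#' Red fluorescence measured in a nuclear region after photoconversion,
#' normalized by the green fluorescence measured pre-conversion at the
#' photoconverted region. Vectorized over time points.
#'
#' @param red_nuc_roi_mean numeric vector of red-channel nuclear ROI
#'   means.
#' @param green_preconv_roi_mean positive scalar (or vector) of
#'   pre-conversion green ROI means.
#' @return numeric vector of ratios.
#' @export
dendra2_ratio <- function(red_nuc_roi_mean, green_preconv_roi_mean) {
  if (any(green_preconv_roi_mean <= 0))
    stop("pre-conversion green mean must be > 0")
  red_nuc_roi_mean / green_preconv_roi_mean
}
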