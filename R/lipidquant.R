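# Per-droplet and per-cell lipid statistics.

#' Per-droplet lipid records
#'
#' For every segmented droplet, sums the TAG and CE weight planes over the
#' droplet pixels (the droplet's SRS lipid intensities), computes the CE
#' fraction CE/(CE+TAG), the NE flag, and the fraction of saturated
#' pixels. Droplets whose saturated-pixel fraction reaches
#' `max_saturated_fraction` (default 0.20, i.e. only droplets with less
#' than 20% saturated pixels are kept) are excluded from the returned
#' table. When quantities are compared across acquisitions, the weight
#' image must first be adjusted to a common setting with
#' [normalize_weights()].
#'
#' @param wi an `srs_weights` object.
#' @param masks an `srs_masks` object on the same pixel grid.
#' @param max_saturated_fraction exclusion threshold on the saturated
#'   pixel fraction (default 0.20).
#' @return data.frame with columns droplet_id, cell_id, is_ne,
#'   pixel_count, tag_sum, ce_sum, ce_fraction, saturated_fraction,
#'   equivalent_radius_um. The `normalized` attribute records whether the
#'   weights had been settings-normalized.
#' @export
droplet_records <- function(wi, masks, max_saturated_fraction = 0.20) {
  if (!all(dim(wi$W)[1:2] == dim(masks$droplets)))
    stop("weight image and masks have different shapes")
  lab <- masks$droplets
  ids <- sort(unique(lab[lab > 0]))
  empty <- data.frame(droplet_id = integer(0), cell_id = integer(0),
                      is_ne = logical(0), pixel_count = integer(0),
                      tag_sum = numeric(0), ce_sum = numeric(0),
                      ce_fraction = numeric(0),
                      saturated_fraction = numeric(0),
                      equivalent_radius_um = numeric(0))
  if (length(ids) == 0) return(empty)
  px <- which(lab > 0)
  g <- lab[px]
  tag <- rowsum(as.numeric(wi$W[, , "TAG"][px]), g)
  ce <- rowsum(as.numeric(wi$W[, , "CE"][px]), g)
  nsat <- rowsum(as.numeric(wi$saturation[px]), g)
  area <- rowsum(rep(1, length(px)), g)
  ne <- classify_ne_droplets(lab, masks$nuclei)
  cell <- assign_droplets_to_cells(lab, masks$cells)
  denom <- tag[, 1] + ce[, 1]
  rec <- data.frame(
    droplet_id = ids,
    cell_id = as.integer(cell[as.character(ids)]),
    is_ne = as.logical(ne[as.character(ids)]),
    pixel_count = as.integer(area[, 1]),
    tag_sum = tag[, 1],
    ce_sum = ce[, 1],
    ce_fraction = ifelse(denom > 0, ce[, 1] / denom, NA_real_),
    saturated_fraction = nsat[, 1] / area[, 1],
    equivalent_radius_um = sqrt(area[, 1] / pi) * masks$pixel_size_um,
    row.names = NULL)
  out <- rec[rec$saturated_fraction < max_saturated_fraction, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normalized") <- !is.null(wi$normalized_to)
  out
}

#' Per-cell lipid summaries
#'
#' Aggregates droplet records per cell and adds whole-cell totals (sums
#' over all pixels of the cell mask, including the diffuse membrane
#' pool outside droplets). `fraction_ne` is the NE-droplet share of the
#' cell's droplets; `ce_in_ne_fraction` is CE in NE-LDs over CE in all
#' LDs of that cell. Both are NA for cells without droplets.
#'
#' @param records data.frame from [droplet_records()].
#' @param wi the `srs_weights` the records came from.
#' @param masks the `srs_masks` the records came from.
#' @return data.frame with one row per cell label, columns cell_id,
#'   n_droplets, n_ne_droplets, ld_tag_sum, ld_ce_sum, cell_tag_sum,
#'   cell_ce_sum, fraction_ne, ce_in_ne_fraction.
#' @export
cell_summaries <- function(records, wi, masks) {
  cells <- masks$cells
  ids <- sort(unique(cells[cells > 0]))
  tagp <- wi$W[, , "TAG"]; cep <- wi$W[, , "CE"]
  out <- data.frame(cell_id = ids, n_droplets = 0L, n_ne_droplets = 0L,
                    ld_tag_sum = 0, ld_ce_sum = 0, cell_tag_sum = 0,
                    cell_ce_sum = 0, fraction_ne = NA_real_,
                    ce_in_ne_fraction = NA_real_)
  for (i in seq_along(ids)) {
    cp <- cells == ids[i]
    out$cell_tag_sum[i] <- sum(tagp[cp])
    out$cell_ce_sum[i] <- sum(cep[cp])
    r <- records[!is.na(records$cell_id) & records$cell_id == ids[i], ,
                 drop = FALSE]
    out$n_droplets[i] <- nrow(r)
    out$n_ne_droplets[i] <- sum(r$is_ne)
    out$ld_tag_sum[i] <- sum(r$tag_sum)
    out$ld_ce_sum[i] <- sum(r$ce_sum)
    if (nrow(r) > 0) {
      out$fraction_ne[i] <- sum(r$is_ne) / nrow(r)
      if (sum(r$ce_sum) > 0)
        out$ce_in_ne_fraction[i] <- sum(r$ce_sum[r$is_ne]) / sum(r$ce_sum)
    }
  }
  out
}

#' Droplet size x CE-fraction histogram
#'
#' Counts droplets in a 2D grid of equivalent-radius bins and CE-fraction
#' bins. Records falling outside the supplied edges land in open
#' underflow/overflow bins so every record is counted.
#'
#' @param records data.frame from [droplet_records()].
#' @param radius_bin_edges_um increasing radius bin edges (um).
#' @param ce_bin_edges increasing CE-fraction bin edges.
#' @return integer matrix (radius bins x CE bins) with interval labels;
#'   first/last rows and columns are the open end bins.
#' @export
size_ce_histogram <- function(records, radius_bin_edges_um,
                              ce_bin_edges = seq(0, 1, 0.25)) {
  for (e in list(radius_bin_edges_um, ce_bin_edges))
    if (is.unsorted(e, strictly = TRUE)) stop("bin edges must be increasing")
  bin_labels <- function(edges) c(paste0("<", edges[1]),
                                  paste0("[", edges[-length(edges)], ",",
                                         edges[-1], ")"),
                                  paste0(">=", edges[length(edges)]))
  nr <- length(radius_bin_edges_um) + 1L
  nc <- length(ce_bin_edges) + 1L
  h <- matrix(0L, nr, nc,
              dimnames = list(bin_labels(radius_bin_edges_um),
                              bin_labels(ce_bin_edges)))
  if (nrow(records) == 0) return(h)
  ri <- findInterval(records$equivalent_radius_um, radius_bin_edges_um) + 1L
  ci <- findInterval(records$ce_fraction, ce_bin_edges) + 1L
  ci[is.na(ci)] <- 1L
  for (k in seq_len(nrow(records)))
    h[ri[k], ci[k]] <- h[ri[k], ci[k]] + 1L
  h
}

#' Anchor-normalize SRS and biochemical lipid tables
#'
#' SRS weights and thin-layer-chromatography masses live on unrelated
#' scales; to compare them, each table is divided by its own CE value at
#' a shared anchor condition (conventionally the double-loaded,
#' cholesterol + oleic acid, condition). After normalization the anchor
#' CE equals 1 in both tables by construction and all within-table ratios
#' are preserved; applying the operation twice changes nothing.
#'
#' @param srs_by_condition,tlc_by_condition data.frames with a
#'   `condition` column and numeric columns including `CE`.
#' @param anchor condition id present in both tables.
#' @return list with normalized `srs` and `tlc` data.frames.
#' @export
anchor_normalize <- function(srs_by_condition, tlc_by_condition, anchor) {
  norm1 <- function(df) {
    i <- which(df$condition == anchor)
    if (length(i) == 0) stop("anchor condition '", anchor, "' not present")
    a <- mean(df$CE[i])
    if (!is.finite(a) || a <= 0)
      stop("anchor CE value must be > 0")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- df[num] / a
    df
  }
  list(srs = norm1(srs_by_condition), tlc = norm1(tlc_by_condition))
}

#' Compare NE-LDs with cytoplasmic LDs
#'
#' Two-group comparison of a per-droplet variable (default the CE
#' fraction) between nuclear-envelope-associated and cytoplasmic
#' droplets: Welch's t-test for intensity-type variables, or a
#' Mann-Whitney U test. When both groups are essentially constant the
#' Welch statistic is computed with the standard error floored at machine
#' epsilon so the degenerate case yields a finite result.
#'
#' @param records data.frame from [droplet_records()].
#' @param variable column to compare (default "ce_fraction").
#' @param test "t" (Welch) or "wilcox" (Mann-Whitney U).
#' @return list with mean_ne, mean_cyto, difference, statistic, p_value,
#'   n_ne, n_cyto, method.
#' @export
compare_ne_vs_cyto <- function(records, variable = "ce_fraction",
                               test = c("t", "wilcox")) {
  test <- match.arg(test)
  x <- records[[variable]][records$is_ne]
  y <- records[[variable]][!records$is_ne]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both droplet groups need at least 2 finite values")
  if (test == "t") {
    res <- tryCatch(stats::t.test(x, y),
                    error = function(e) {
      se <- max(sqrt(stats::var(x) / length(x) + stats::var(y) / length(y)),
                .Machine$double.eps)
      stat <- (mean(x) - mean(y)) / se
      df <- length(x) + length(y) - 2
      list(statistic = c(t = stat),
           p.value = 2 * stats::pt(-abs(stat), df),
           method = "Welch Two Sample t-test (epsilon-floored)")
    })
  } else {
    res <- stats::wilcox.test(x, y, exact = FALSE)
  }
  list(mean_ne = mean(x), mean_cyto = mean(y),
       difference = mean(x) - mean(y),
       statistic = unname(res$statistic), p_value = res$p.value,
       n_ne = length(x), n_cyto = length(y), method = res$method)
}
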