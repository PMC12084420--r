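# Synthetic hyperspectral scene generator with known ground truth.

lorentz <- function(x, center, width, amp) amp * width^2 / ((x - center)^2 + width^2)

# Declared component peak model (center cm^-1, half-width cm^-1, amplitude).
# The dominant CH2 symmetric-stretch anchors are 2857 cm^-1 (acyl chains,
# TAG) and 2875 cm^-1 (sterol ring, CE); the remaining bands (ester
# carbonyl ~1745, sterol-region ~1670, broad cellular CH, water O-H tail)
# are a plausible declared model, kept fixed so tests are stable.
component_peak_model <- function() {
  list(
    TAG = list(peaks = rbind(c(2857, 11, 1.00), c(2895, 28, 0.30),
                             c(2930, 15, 0.22), c(1745, 10, 0.30),
                             c(3005, 14, 0.08)), baseline = 0),
    CE = list(peaks = rbind(c(2875, 11, 1.00), c(2850, 22, 0.25),
                            c(2905, 18, 0.35), c(1670, 12, 0.35),
                            c(1740, 9, 0.15)), baseline = 0),
    cellular_bg = list(peaks = rbind(c(2920, 60, 0.28), c(2850, 45, 0.12)),
                       baseline = 0.03),
    water_bg = list(peaks = rbind(c(3300, 180, 1.00), c(1640, 60, 0.10)),
                    baseline = 0.02))
}

#' Generate the four component reference spectra
#'
#' Evaluates the Lorentzian-sum peak model of each component on the axis:
#' TAG dominated by the 2857 cm^-1 CH2 band plus the 1745 cm^-1 carbonyl,
#' CE by the 2875 cm^-1 sterol-ring band plus a 1670-region band, a broad
#' low cellular background, and a water background with a broad O-H tail
#' above 3000 cm^-1. The four spectra are linearly independent by
#' construction; the condition number of the resulting matrix is attached
#' as an attribute.
#'
#' @param axis an `srs_axis`.
#' @param seed optional integer; when given, peak amplitudes are jittered
#'   by up to `jitter_frac` to emulate acquisition-to-acquisition
#'   variation.
#' @param jitter_frac relative amplitude jitter (default 0.02).
#' @return named list of four `srs_spectrum` objects (unit amplitude
#'   scale), with attribute `condition_number`.
#' @export
make_component_spectra <- function(axis, seed = NULL, jitter_frac = 0.02) {
  model <- component_peak_model()
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(model), function(comp) {
    pk <- model[[comp]]$peaks
    amp <- pk[, 3]
    if (!is.null(seed))
      amp <- amp * stats::runif(length(amp), 1 - jitter_frac, 1 + jitter_frac)
    v <- rep(model[[comp]]$baseline, n_channels(axis))
    for (i in seq_len(nrow(pk)))
      v <- v + lorentz(axis$wavenumbers, pk[i, 1], pk[i, 2], amp[i])
    srs_spectrum(v, axis, kind = comp)
  })
  names(out) <- names(model)
  S <- vapply(out, function(s) s$values, numeric(n_channels(axis)))
  attr(out, "condition_number") <- kappa(S, exact = TRUE)
  out
}

#' Assemble spectra into a reference set
#'
#' @param spectra named list with the four components (e.g. from
#'   [make_component_spectra()]), values on one shared axis.
#' @param amp_scale multiplier taking the unit-amplitude model to the
#'   intensity scale of the generated cubes (default 1).
#' @return An `srs_refset`.
#' @export
as_reference_set <- function(spectra, amp_scale = 1) {
  axis <- spectra[[1]]$axis
  S <- vapply(srs_components(), function(k) spectra[[k]]$values * amp_scale,
              numeric(n_channels(axis)))
  reference_set(S, axis)
}

#' Scene layout configuration
#'
#' Defaults describe a desk-scale field emulating lipid-loaded epithelial
#' cells: a 256 x 256 12-bit image with 6 cells, 8 droplets per cell of
#' which a quarter sit on the nuclear envelope, per-droplet CE fractions
#' drawn from normal distributions whose NE mean is offset +0.1 above the
#' cytoplasmic mean (sd 0.05), and amplitudes chosen so the cube stays
#' clear of 12-bit clipping.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of cells (laid out on a grid).
#' @param droplets_per_cell droplets per cell.
#' @param ne_fraction fraction of each cell's droplets placed on the
#'   nucleus boundary.
#' @param ce_mean_cyto,ce_mean_ne,ce_sd CE-fraction distribution
#'   parameters for cytoplasmic and NE droplets.
#' @param droplet_radius_px inclusive integer radius range.
#' @param droplet_amp per-pixel total lipid concentration range (counts).
#' @param cell_bg_amp cellular-background concentration inside cells.
#' @param water_amp water-background concentration.
#' @param nucleus_bg_frac cellular-background factor inside nuclei
#'   (nuclei image dark in SRS).
#' @param diffuse_ce_amp optional diffuse cytoplasmic CE concentration
#'   (membrane pool); 0 disables.
#' @param core_shell logical: give droplets a CE-rich shell around a
#'   TAG-rich core instead of a uniform composition.
#' @param pixel_size_um pixel size in um.
#' @param bit_depth detector bit depth.
#' @param max_place_tries placement retries per droplet before failing.
#' @return list of layout parameters.
#' @export
scene_layout <- function(width = 256, height = 256, n_cells = 6,
                         droplets_per_cell = 8, ne_fraction = 0.25,
                         ce_mean_cyto = 0.35, ce_mean_ne = 0.45,
                         ce_sd = 0.05, droplet_radius_px = c(2, 5),
                         droplet_amp = c(800, 1600), cell_bg_amp = 600,
                         water_amp = 300, nucleus_bg_frac = 0.35,
                         diffuse_ce_amp = 0, core_shell = FALSE,
                         pixel_size_um = 0.25, bit_depth = 12,
                         max_place_tries = 400) {
  as.list(environment())
}

disk_pixels <- function(row, col, r, H, W) {
  rr <- max(1, row - r):min(H, row + r)
  cc <- max(1, col - r):min(W, col + r)
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - row)^2 + (g$col - col)^2 <= r^2, , drop = FALSE]
  cbind(g$row, g$col)
}

#' Render a synthetic hyperspectral scene with ground truth
#'
#' Builds per-pixel concentration maps for the four components (droplet
#' disks of known TAG/CE content, dark elliptical nuclei, cellular and
#' water background), multiplies them with the component spectra, and
#' quantizes to the bit depth. NE droplets are centered on the nucleus
#' boundary so their masks partially overlap the nuclear mask; droplets
#' never overlap each other. The returned truth holds the concentration
#' maps, per-droplet table, label masks and a companion nuclear-stain
#' image for nucleus segmentation.
#'
#' @param layout list from [scene_layout()].
#' @param spectra component spectra from [make_component_spectra()].
#' @param seed integer RNG seed; the call is reproducible.
#' @return list with `cube` (an `srs_cube`), `truth` (concentrations
#'   H x W x 4, droplets data.frame, nuclei / cells / droplet_labels
#'   masks, nuclear_stain, n_clipped) and `refs` (the matching
#'   `srs_refset`).
#' @export
render_scene <- function(layout = scene_layout(),
                         spectra = make_component_spectra(
                           build_spectral_axis(srs_default_regions())),
                         seed = 1) {
  set.seed(seed)
  H <- layout$height; W <- layout$width
  axis <- spectra[[1]]$axis

  # --- cells and nuclei on a grid ---
  ncg <- ceiling(sqrt(layout$n_cells * W / H))
  nrg <- ceiling(layout$n_cells / ncg)
  sx <- W / ncg; sy <- H / nrg
  cell_r <- 0.42 * min(sx, sy)
  centers <- cbind(
    row = rep(sy * (seq_len(nrg) - 0.5), each = ncg),
    col = rep(sx * (seq_len(ncg) - 0.5), times = nrg))[seq_len(layout$n_cells), , drop = FALSE]
  centers <- centers + matrix(stats::runif(2 * layout$n_cells, -2, 2), ncol = 2)

  rowg <- matrix(seq_len(H), H, W)
  colg <- matrix(seq_len(W), H, W, byrow = TRUE)
  cells <- matrix(0L, H, W); nuclei <- matrix(0L, H, W)
  nuc_par <- vector("list", layout$n_cells)
  for (i in seq_len(layout$n_cells)) {
    d2 <- (rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2
    cells[d2 <= cell_r^2 & cells == 0] <- i
    a <- 0.45 * cell_r; b <- 0.33 * cell_r
    th <- stats::runif(1, 0, pi)
    dr <- rowg - centers[i, 1]; dc <- colg - centers[i, 2]
    u <- dr * cos(th) + dc * sin(th); v <- -dr * sin(th) + dc * cos(th)
    nuclei[(u / a)^2 + (v / b)^2 <= 1] <- i
    nuc_par[[i]] <- list(a = a, b = b, th = th, center = centers[i, ])
  }

  # --- droplet placement ---
  occupied <- matrix(FALSE, H, W)
  droplet_labels <- matrix(0L, H, W)
  drops <- list(); did <- 0L; fails <- 0L
  rmin <- layout$droplet_radius_px[1]; rmax <- layout$droplet_radius_px[2]
  for (i in seq_len(layout$n_cells)) {
    n_ne <- round(layout$ne_fraction * layout$droplets_per_cell)
    kinds <- c(rep(TRUE, n_ne), rep(FALSE, layout$droplets_per_cell - n_ne))
    np <- nuc_par[[i]]
    for (ne in kinds) {
      r <- sample(rmin:rmax, 1)
      placed <- FALSE
      for (try in seq_len(layout$max_place_tries)) {
        if (ne) {
          phi <- stats::runif(1, 0, 2 * pi)
          u <- np$a * cos(phi); v <- np$b * sin(phi)
          row <- round(np$center[1] + u * cos(np$th) - v * sin(np$th))
          col <- round(np$center[2] + u * sin(np$th) + v * cos(np$th))
        } else {
          rad <- sqrt(stats::runif(1)) * (cell_r - r - 2)
          ang <- stats::runif(1, 0, 2 * pi)
          row <- round(centers[i, 1] + rad * sin(ang))
          col <- round(centers[i, 2] + rad * cos(ang))
          dr <- row - np$center[1]; dc <- col - np$center[2]
          u <- dr * cos(np$th) + dc * sin(np$th)
          v <- -dr * sin(np$th) + dc * cos(np$th)
          # keep cytoplasmic droplets clear of the nucleus by > r
          if ((u / (np$a + r + 1))^2 + (v / (np$b + r + 1))^2 <= 1) next
        }
        if (row - r < 1 || row + r > H || col - r < 1 || col + r > W) next
        px <- disk_pixels(row, col, r, H, W)
        if (any(occupied[px])) next
        did <- did + 1L
        occupied[px] <- TRUE
        droplet_labels[px] <- did
        cef <- min(max(stats::rnorm(1,
          if (ne) layout$ce_mean_ne else layout$ce_mean_cyto,
          layout$ce_sd), 0), 1)
        amp <- stats::runif(1, layout$droplet_amp[1], layout$droplet_amp[2])
        drops[[did]] <- list(id = did, cell = i, row = row, col = col,
                             r = r, ne = ne, cef = cef, amp = amp, px = px)
        placed <- TRUE
        break
      }
      if (!placed) fails <- fails + 1L
    }
  }
  if (fails > 0)
    stop("render_scene: ", fails, " of ",
         layout$n_cells * layout$droplets_per_cell,
         " droplets could not be placed without overlap; ",
         "reduce droplets_per_cell or radii")

  # --- concentration maps ---
  tag_map <- matrix(0, H, W); ce_map <- matrix(0, H, W)
  for (d in drops) {
    if (layout$core_shell) {
      dist <- sqrt((d$px[, 1] - d$row)^2 + (d$px[, 2] - d$col)^2)
      shell <- (dist / max(d$r, 1)) / (2 / 3) # disk mean 1
      cef_px <- pmin(1, d$cef * shell)
    } else cef_px <- d$cef
    tag_map[d$px] <- d$amp * (1 - cef_px)
    ce_map[d$px] <- d$amp * cef_px
  }
  cell_map <- matrix(0, H, W)
  cell_map[cells > 0] <- layout$cell_bg_amp
  cell_map[nuclei > 0] <- layout$cell_bg_amp * layout$nucleus_bg_frac
  if (layout$diffuse_ce_amp > 0)
    ce_map[cells > 0 & nuclei == 0 & !occupied] <-
      ce_map[cells > 0 & nuclei == 0 & !occupied] + layout$diffuse_ce_amp
  water_map <- matrix(layout$water_amp, H, W)
  water_map[cells > 0] <- layout$water_amp * 0.7

  conc <- array(c(tag_map, ce_map, cell_map, water_map), c(H, W, 4),
                dimnames = list(NULL, NULL, srs_components()))
  S <- vapply(srs_components(), function(k) spectra[[k]]$values,
              numeric(n_channels(axis)))
  D <- matrix(conc, nrow = H * W) %*% t(S)
  cap <- 2^layout$bit_depth - 1
  n_clipped <- sum(D > cap)
  data <- array(pmin(pmax(round(D), 0), cap), c(H, W, n_channels(axis)))

  droplets <- do.call(rbind, lapply(drops, function(d) {
    tg <- sum(tag_map[d$px]); cv <- sum(ce_map[d$px])
    data.frame(droplet_id = d$id, cell_id = d$cell, row0 = d$row - 1L,
               col0 = d$col - 1L, radius_px = d$r, is_ne = d$ne,
               ce_fraction_target = d$cef, tag_total = tg, ce_total = cv,
               ce_fraction_true = cv / (tg + cv))
  }))

  stain <- b3_smooth(b3_smooth((nuclei > 0) * 3000, 1L), 2L) +
    matrix(stats::rnorm(H * W, 0, 30), H, W)

  cube <- srs_cube(data, axis,
                   acquisition_settings(bit_depth = layout$bit_depth))
  list(cube = cube,
       truth = list(concentrations = conc, droplets = droplets,
                    nuclei = nuclei, cells = cells,
                    droplet_labels = droplet_labels, nuclear_stain = stain,
                    pixel_size_um = layout$pixel_size_um,
                    n_clipped = n_clipped),
       refs = as_reference_set(spectra))
}

#' Corrupt a cube with noise and lock-in saturation
#'
#' Adds Gaussian noise with sigma equal to `noise_sigma_frac` times the
#' cube maximum and re-quantizes within the bit-depth range. With
#' `saturate = TRUE`, the spectra of the pixels of the selected droplets
#' are scaled up and clipped to a flat plateau just below the detector
#' maximum, emulating lock-in saturation so [detect_saturation()] flags
#' them.
#'
#' @param cube an `srs_cube`.
#' @param noise_sigma_frac noise sigma as a fraction of the cube maximum
#'   (0 to 0.2).
#' @param saturate logical; saturate selected droplets.
#' @param seed RNG seed.
#' @param droplet_labels droplet label matrix (required when
#'   `saturate = TRUE`).
#' @param saturate_ids droplet ids to saturate (default: first label).
#' @param plateau plateau level (default 3900 counts).
#' @return a new `srs_cube`.
#' @export
corrupt_cube <- function(cube, noise_sigma_frac = 0.02, saturate = FALSE,
                         seed = 1, droplet_labels = NULL,
                         saturate_ids = NULL, plateau = 3900) {
  if (noise_sigma_frac < 0 || noise_sigma_frac > 0.2)
    stop("noise_sigma_frac must be in [0, 0.2]")
  set.seed(seed)
  data <- cube$data
  cap <- max_value(cube$settings)
  if (noise_sigma_frac > 0) {
    sigma <- noise_sigma_frac * max(data)
    data <- data + array(stats::rnorm(length(data), 0, sigma), dim(data))
  }
  data <- pmin(pmax(round(data), 0), cap)
  if (saturate) {
    if (is.null(droplet_labels))
      stop("saturate = TRUE needs droplet_labels")
    if (is.null(saturate_ids))
      saturate_ids <- min(droplet_labels[droplet_labels > 0])
    D <- matrix(data, nrow = prod(dim(data)[1:2]))
    px <- which(droplet_labels %in% saturate_ids)
    for (p in px) {
      v <- D[p, ]
      D[p, ] <- pmin(round(v * 2 * plateau / max(v, 1)), plateau)
    }
    data <- array(D, dim(data))
  }
  srs_cube(data, cube$axis, cube$settings)
}

#' Precision / recall of droplet detection against ground truth
#'
#' Matches predicted droplets to ground-truth droplets one-to-one,
#' greedily by descending intersection-over-union, counting a pair as a
#' match when IoU >= `iou_min`.
#'
#' @param pred,truth droplet label matrices of one shape.
#' @param iou_min matching threshold (default 0.3).
#' @return list with precision, recall, n_pred, n_truth, n_matched.
#' @export
evaluate_droplet_detection <- function(pred, truth, iou_min = 0.3) {
  pids <- sort(unique(pred[pred > 0])); tids <- sort(unique(truth[truth > 0]))
  if (length(pids) == 0 || length(tids) == 0)
    return(list(precision = NA_real_, recall = NA_real_,
                n_pred = length(pids), n_truth = length(tids), n_matched = 0L))
  both <- pred > 0 & truth > 0
  inter <- table(factor(pred[both], levels = pids),
                 factor(truth[both], levels = tids))
  pa <- tabulate(pred[pred > 0], nbins = max(pids))[pids]
  ta <- tabulate(truth[truth > 0], nbins = max(tids))[tids]
  iou <- inter / (outer(pa, ta, "+") - inter)
  pairs <- which(iou >= iou_min, arr.ind = TRUE)
  pairs <- pairs[order(iou[pairs], decreasing = TRUE), , drop = FALSE]
  used_p <- logical(length(pids)); used_t <- logical(length(tids)); m <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_p[i] && !used_t[j]) { used_p[i] <- TRUE; used_t[j] <- TRUE; m <- m + 1L }
  }
  list(precision = m / length(pids), recall = m / length(tids),
       n_pred = length(pids), n_truth = length(tids), n_matched = m)
}
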