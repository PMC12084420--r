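# Independent oracles and fixture builders shared across tests.

# Exhaustive NNLS oracle: solve unconstrained least squares on every
# support subset of the columns, keep feasible solutions, return the one
# with minimal residual. Independent of the package's active-set path.
oracle_nnls <- function(d, S, tol = 1e-10) {
  p <- ncol(S)
  best <- list(res = sqrt(sum(d^2)), w = numeric(p))
  for (m in seq_len(2^p - 1)) {
    J <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    wj <- tryCatch(qr.solve(S[, J, drop = FALSE], d), error = function(e) NULL)
    if (is.null(wj) || any(wj < -tol)) next
    w <- numeric(p)
    w[J] <- pmax(wj, 0)
    res <- sqrt(sum((S %*% w - d)^2))
    if (res < best$res) best <- list(res = res, w = w)
  }
  best
}

# All-pairs union-find clustering oracle (labels numbered by first
# occurrence, matching cluster_pores()).
oracle_clusters <- function(coords, thr) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < thr) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[min(ri, rj)] <- max(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Toy circular cell with an elliptical nucleus, plus the cell-mask
# contour computed here by direct neighbour inspection (independently of
# the package's contour convention).
toy_cell <- function(n = 41, cell_r = 18, nuc_r = 6) {
  cen <- (n + 1) / 2
  d2 <- (row(matrix(0, n, n)) - cen)^2 + (col(matrix(0, n, n)) - cen)^2
  cell <- d2 <= cell_r^2
  nuc <- d2 <= nuc_r^2
  contour <- cell & FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!cell[i, j]) next
    edge <- i == 1 || j == 1 || i == n || j == n ||
      !cell[i - 1, j] || !cell[i + 1, j] || !cell[i, j - 1] || !cell[i, j + 1]
    if (edge) contour[i, j] <- TRUE
  }
  list(cell = cell, nucleus = nuc, contour = contour)
}

# A small 12-channel single-region axis for per-pixel solver tests.
small_axis <- function() build_spectral_axis(list(c(2800, 2833, 3)))

# A cube in which every pixel carries the same given spectrum.
uniform_cube <- function(values, axis, H = 2, W = 2,
                         settings = acquisition_settings()) {
  srs_cube(array(rep(values, each = H * W), c(H, W, length(values))),
           axis, settings)
}

# Noise-free cube synthesized from concentration maps and spectra,
# without bit-depth quantization (float data), for exact-recovery tests.
cube_from_conc <- function(conc, spectra) {
  axis <- spectra[[1]]$axis
  S <- vapply(srs_components(), function(k) spectra[[k]]$values,
              numeric(length(axis$wavenumbers)))
  d <- dim(conc)
  D <- matrix(conc, nrow = d[1] * d[2]) %*% t(S)
  srs_cube(array(D, c(d[1], d[2], nrow(S))), axis)
}
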