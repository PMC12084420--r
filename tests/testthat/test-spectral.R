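test_that("spectral axis concatenates regions and keeps duplicated boundaries", {
  ax <- build_spectral_axis(srs_default_regions())
  expect_length(ax$wavenumbers, 153)
  expect_equal(as.vector(table(ax$region_index)), c(51, 51, 51))

  ax3 <- build_spectral_axis(list(c(2800, 2806, 3)))
  expect_equal(ax3$wavenumbers, c(2800, 2803, 2806))

  ax2 <- build_spectral_axis(list(c(2800, 2950, 3), c(2950, 3100, 3)))
  expect_length(ax2$wavenumbers, 102)
  expect_equal(sum(ax2$wavenumbers == 2950), 2)

  # within-region grids increase by the step and include both endpoints
  for (r in 1:3) {
    w <- ax$wavenumbers[ax$region_index == r]
    expect_equal(diff(w), rep(3, 50))
    expect_equal(range(w), unlist(srs_default_regions()[[r]][1:2]))
  }
  expect_error(build_spectral_axis(list(c(2800, 2807, 3))), "divisible")
  expect_error(build_spectral_axis(list(c(2800, 2790, 3))), "exceed")
})

test_that("capped subtraction is non-negative and exact where a >= b", {
  ax <- build_spectral_axis(list(c(2800, 2803, 3)))
  a <- srs_spectrum(c(5, 1), ax)
  b <- srs_spectrum(c(2, 3), ax)
  expect_equal(subtract_capped(a, b)$values, c(3, 0))
  expect_equal(subtract_capped(a, a)$values, c(0, 0))

  ax3 <- build_spectral_axis(list(c(2800, 2806, 3)))
  expect_equal(subtract_capped(srs_spectrum(c(10, 10, 10), ax3),
                               srs_spectrum(c(1, 2, 30), ax3))$values,
               c(9, 8, 0))
  # subtracting zero is the identity
  z <- srs_spectrum(c(0, 0, 0), ax3)
  x <- srs_spectrum(c(4, 0, 7), ax3)
  expect_equal(subtract_capped(x, z)$values, x$values)
  expect_error(subtract_capped(a, x), "different axes")
  # property: output >= 0 and equals a-b wherever a >= b
  set.seed(11)
  for (k in 1:20) {
    va <- runif(3, 0, 10); vb <- runif(3, 0, 10)
    out <- subtract_capped(srs_spectrum(va, ax3), srs_spectrum(vb, ax3))$values
    expect_true(all(out >= 0))
    expect_equal(out[va >= vb], (va - vb)[va >= vb])
  }
})

test_that("cover-glass background averages the lowest-mean pixels", {
  ax <- small_axis()
  v <- seq_len(12)
  cube <- uniform_cube(v, ax, H = 3, W = 3)
  bg <- cover_glass_background(cube, n_lowest = 4)
  expect_equal(bg$values, v)
  expect_identical(bg$kind, "cover_glass")

  # 4-pixel cube with distinct means: mean of the two lowest-mean pixels
  data <- array(0, c(2, 2, 12))
  base <- rbind(rep(1, 12), rep(2, 12), rep(3, 12), rep(4, 12))
  for (p in 1:4) data[(p - 1) %% 2 + 1, (p - 1) %/% 2 + 1, ] <- base[p, ]
  cube4 <- srs_cube(data, ax)
  expect_equal(cover_glass_background(cube4, n_lowest = 2)$values,
               colMeans(base[1:2, ]))

  # exactly n_lowest all-zero pixels -> zero spectrum
  data[1, 1, ] <- 0; data[2, 1, ] <- 0
  expect_equal(cover_glass_background(srs_cube(data, ax), n_lowest = 2)$values,
               rep(0, 12))

  # permutation invariance of pixel order
  set.seed(5)
  dat <- array(runif(4 * 4 * 12, 0, 100), c(4, 4, 12))
  cube_a <- srs_cube(dat, ax)
  perm <- sample(16)
  D <- matrix(dat, 16, 12)[perm, ]
  cube_b <- srs_cube(array(D, c(4, 4, 12)), ax)
  expect_equal(cover_glass_background(cube_a, n_lowest = 5)$values,
               cover_glass_background(cube_b, n_lowest = 5)$values)

  expect_error(cover_glass_background(cube4, n_lowest = 10), "fewer")
})

test_that("mean collapse subtracts background per pixel, capped at zero", {
  ax <- build_spectral_axis(list(c(2800, 2806, 3)))
  cube <- uniform_cube(c(4, 0, 8), ax, H = 2, W = 1)
  expect_equal(mean_collapse(cube), matrix(4, 2, 1))
  bg <- srs_spectrum(c(1, 1, 1), ax)
  expect_equal(mean_collapse(cube, bg), matrix(10 / 3, 2, 1))
  # pixel equal to background collapses to 0
  expect_equal(mean_collapse(uniform_cube(c(1, 1, 1), ax, 2, 2), bg),
               matrix(0, 2, 2))
})

test_that("reference-set extraction pools ROI pixels and subtracts cellular background", {
  ax <- small_axis()
  t_spec <- c(8, 6, 4, 2, rep(1, 8))
  tag_cube <- uniform_cube(t_spec, ax, 4, 4)
  ce_cube <- uniform_cube(rev(t_spec), ax, 4, 4)
  starved <- uniform_cube(rep(0, 12), ax, 4, 4)
  roi <- matrix(0L, 4, 4); roi[1:2, 1:2] <- 1L
  refs <- extract_reference_set(tag_cube, roi, ce_cube, roi, starved, roi, roi)
  expect_equal(unname(refs$S[, "TAG"]), t_spec)

  # TAG ROI mean equal to the cellular background -> all-zero TAG column
  refs0 <- extract_reference_set(tag_cube, roi, ce_cube, roi,
                                 tag_cube, roi, roi)
  expect_equal(unname(refs0$S[, "TAG"]), rep(0, 12))

  # two droplets [2,4] and [4,8] with bg [1,1]: mean then capped subtraction
  ax2 <- build_spectral_axis(list(c(2800, 2803, 3)))
  data <- array(1, c(2, 2, 2))
  data[1, 1, ] <- c(2, 4); data[2, 1, ] <- c(4, 8)
  tc <- srs_cube(data, ax2)
  rois <- list(cbind(1, 1), cbind(2, 1))
  bgc <- uniform_cube(c(1, 1), ax2, 2, 2)
  refs2 <- extract_reference_set(tc, rois, tc, rois, bgc,
                                 list(cbind(1, 1)), list(cbind(2, 2)))
  expect_equal(unname(refs2$S[, "TAG"]), c(2, 5))
  expect_equal(unname(refs2$provenance["TAG"]), 2L)

  expect_true(all(refs$S >= 0))
  expect_error(
    extract_reference_set(tag_cube, matrix(0L, 4, 4), ce_cube, roi,
                          starved, roi, roi),
    "TAG")
})

test_that("ROI-mean TAG spectra decompose almost entirely onto the TAG component", {
  ax <- build_spectral_axis(srs_default_regions())
  sp <- make_component_spectra(ax)
  H <- 4; W <- 4
  mk <- function(mix) {
    v <- Reduce(`+`, Map(function(k, a) a * sp[[k]]$values,
                         srs_components(), mix))
    uniform_cube(v * 100, ax, H, W)
  }
  roi <- matrix(0L, H, W); roi[1:2, 1:2] <- 1L
  tag_cube <- mk(c(8, 0, 1, 0.3))
  ce_cube <- mk(c(0, 8, 1, 0.3))
  starved <- mk(c(0, 0, 1, 0.3))
  water <- mk(c(0, 0, 0, 0.3))
  refs <- extract_reference_set(tag_cube, roi, ce_cube, roi, starved, roi,
                                water_rois = roi, water_cube = water)
  expect_true(all(refs$S >= 0))
  d <- cover_glass_background(tag_cube, n_lowest = 1)$values
  w <- nnls_pixel(d, refs$S)
  expect_gt(w["TAG"] / (w["TAG"] + w["CE"]), 0.99)
})

test_that("reference-set CSV round trip is bit exact", {
  ax <- build_spectral_axis(srs_default_regions())
  refs <- as_reference_set(make_component_spectra(ax, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_set(refs, path)
  back <- read_reference_set(path)
  expect_identical(back$S, refs$S)
  expect_identical(back$axis$wavenumbers, ax$wavenumbers)
})
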