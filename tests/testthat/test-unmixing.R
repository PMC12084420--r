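test_that("per-pixel NNLS matches the exhaustive active-set oracle", {
  set.seed(42)
  for (i in 1:120) {
    S <- matrix(runif(12 * 4), 12, 4)
    d <- if (i %% 3 == 0) S %*% runif(4, 0, 2) + rnorm(12, 0, 0.2) else
      runif(12, 0, 3)
    d <- pmax(as.vector(d), 0)
    w <- nnls_pixel(d, S)
    orc <- oracle_nnls(d, S)
    expect_lte(sqrt(sum((S %*% w - d)^2)), orc$res + 1e-9)
    expect_true(all(w >= 0))
  }
})

test_that("per-pixel NNLS agrees with an independent solver on reference-like problems", {
  skip_if_not_installed("pracma")
  ax <- build_spectral_axis(srs_default_regions())
  S <- as_reference_set(make_component_spectra(ax))$S
  set.seed(9)
  for (i in 1:10) {
    d <- pmax(as.vector(S %*% runif(4, 0, 500)) + rnorm(153, 0, 5), 0)
    w <- nnls_pixel(d, S)
    w2 <- pracma::lsqnonneg(S, d)$x
    expect_equal(unname(w), w2, tolerance = 1e-6)
  }
})

test_that("NNLS reproduces exactly representable spectra and rejects degenerate references", {
  ax <- build_spectral_axis(srs_default_regions())
  S <- as_reference_set(make_component_spectra(ax))$S
  w <- nnls_pixel(2.5 * S[, "TAG"], S)
  expect_equal(unname(w), c(2.5, 0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(nnls_pixel(rep(0, 153), S)), rep(0, 4))
  S0 <- S; S0[, 2] <- 0
  expect_error(nnls_pixel(rep(1, 153), S0), "degenerate")
  # residual optimality: perturbing any positive weight increases the residual
  set.seed(2)
  d <- pmax(as.vector(S %*% c(2, 0.5, 1, 0.2)) + rnorm(153, 0, 2), 0)
  w <- nnls_pixel(d, S)
  res <- sqrt(sum((S %*% w - d)^2))
  for (k in which(w > 1e-8)) for (eps in c(-1e-4, 1e-4)) {
    wp <- w; wp[k] <- wp[k] + eps
    expect_gt(sqrt(sum((S %*% wp - d)^2)), res)
  }
})

test_that("cube decomposition recovers concentrations and scales linearly", {
  ax <- build_spectral_axis(srs_default_regions())
  sp <- make_component_spectra(ax)
  refs <- as_reference_set(sp)
  # every pixel equal to the TAG column -> TAG plane 1, others 0
  cube <- uniform_cube(refs$S[, "TAG"], ax, 3, 3)
  wi <- decompose_cube(cube, refs, saturation = FALSE)
  expect_equal(wi$W[, , "TAG"], matrix(1, 3, 3), tolerance = 1e-10)
  expect_equal(max(abs(wi$W[, , -1])), 0, tolerance = 1e-10)

  # noise-free float scene: per-pixel recovery to 1e-6 relative
  set.seed(31)
  conc <- array(runif(6 * 6 * 4, 0, 800), c(6, 6, 4))
  fc <- cube_from_conc(conc, sp)
  rec <- decompose_cube(fc, refs, saturation = FALSE)
  expect_lt(max(abs(rec$W - conc)) / max(conc), 1e-6)

  # scale equivariance: decompose(alpha d) = alpha decompose(d)
  fc2 <- srs_cube(fc$data * 2, ax, fc$settings)
  rec2 <- decompose_cube(fc2, refs, saturation = FALSE)
  expect_equal(rec2$W, 2 * rec$W, tolerance = 1e-9)
})

test_that("saturation rule flags flat high plateaus within one region", {
  ax <- build_spectral_axis(srs_default_regions())
  flag1 <- detect_saturation(uniform_cube(rep(4000, 153), ax, 1, 1))
  expect_true(flag1[1, 1])
  expect_false(detect_saturation(uniform_cube(rep(1000, 153), ax, 1, 1))[1, 1])

  # one 5-channel window [3600..3640] (sd ~15.8), everything else low
  v <- rep(100, 153)
  v[60:64] <- c(3600, 3610, 3620, 3630, 3640)
  expect_equal(sd(v[60:64]), 15.81, tolerance = 1e-3)
  expect_true(detect_saturation(uniform_cube(v, ax, 1, 1))[1, 1])

  # sd at exactly 50 or value at exactly 3500 does not flag
  v2 <- rep(100, 153)
  v2[60:64] <- 3500
  expect_false(detect_saturation(uniform_cube(v2, ax, 1, 1))[1, 1])

  # a plateau split across the region-1/region-2 gap is not a window
  v3 <- rep(c(100, 900), length.out = 153)
  v3[50:51] <- 4000  # last two channels of region 1
  v3[52:53] <- 4000  # first two channels of region 2
  expect_false(detect_saturation(uniform_cube(v3, ax, 1, 1))[1, 1])
  # ...but five flat channels inside region 2 are
  v3[52:56] <- 4000
  expect_true(detect_saturation(uniform_cube(v3, ax, 1, 1))[1, 1])
})

test_that("settings normalization is linear in pump x Stokes power and composes", {
  ax <- small_axis()
  sp_axis_cube <- uniform_cube(rep(100, 12), ax, 2, 2)
  refs <- reference_set(matrix(runif(48, 0.1, 1), 12, 4), ax)
  wi <- decompose_cube(sp_axis_cube, refs, saturation = FALSE)

  a <- acquisition_settings(pump_power = 2, stokes_power = 3)
  expect_equal(normalize_weights(wi, a, a)$W, wi$W)

  half <- acquisition_settings(pump_power = 1, stokes_power = 3)
  expect_equal(normalize_weights(wi, half, a)$W, 2 * wi$W)

  b <- acquisition_settings(pump_power = 5, stokes_power = 1)
  c3 <- acquisition_settings(pump_power = 4, stokes_power = 7)
  via_b <- normalize_weights(normalize_weights(wi, a, b), b, c3)
  direct <- normalize_weights(wi, a, c3)
  expect_equal(via_b$W, direct$W, tolerance = 1e-12)
  expect_error(normalize_weights(wi, a, acquisition_settings(pump_power = 1e-9)),
               NA) # positive powers fine
  expect_false(is.null(normalize_weights(wi, a, b)$normalized_to))

  # per-region powers pick each component's dominant region
  pr <- acquisition_settings(pump_power = c(1, 2, 4), stokes_power = 1)
  tr <- acquisition_settings(pump_power = c(1, 1, 1), stokes_power = 1)
  refs3 <- as_reference_set(make_component_spectra(
    build_spectral_axis(srs_default_regions())))
  wi153 <- decompose_cube(
    uniform_cube(refs3$S[, "TAG"] * 100, refs3$axis, 2, 2), refs3,
    saturation = FALSE)
  nw <- normalize_weights(wi153, pr, tr, refs = refs3)
  expect_equal(nw$W[, , "TAG"], wi153$W[, , "TAG"] / 2) # TAG peaks in region 2
  expect_error(normalize_weights(wi153, pr, tr), "refs")
})

test_that("false-color rendering clips, and grays out saturated or unsegmented pixels", {
  W <- array(0, c(2, 3, 4), dimnames = list(NULL, NULL, srs_components()))
  W[1, 1, "TAG"] <- 10          # pure TAG at max
  W[1, 2, "CE"] <- 10           # pure CE
  W[1, 3, "TAG"] <- 10          # will be marked saturated
  W[2, 1, "TAG"] <- 6           # above the 0.5 clip -> same as max
  sat <- matrix(FALSE, 2, 3); sat[1, 3] <- TRUE
  wi <- structure(list(W = W, saturation = sat,
                       settings = acquisition_settings(),
                       normalized_to = NULL), class = "srs_weights")
  rgb <- render_falsecolor(wi, clip_fraction = 0.5)
  expect_equal(rgb[1, 1, ], c(1, 0, 1))        # magenta
  expect_equal(rgb[1, 2, ], c(0, 1, 0))        # green
  expect_equal(rgb[1, 3, ], rep(0.5, 3))       # saturated -> gray
  expect_equal(rgb[2, 1, ], rgb[1, 1, ])       # clipped equal to max
  masks <- segmentation_masks(matrix(0L, 2, 3), matrix(0L, 2, 3),
                              matrix(0L, 2, 3))
  rgb2 <- render_falsecolor(wi, masks, clip_fraction = 0.5)
  expect_equal(rgb2[1, 1, ], rep(0.5, 3))      # outside segmentation -> gray
  expect_error(render_falsecolor(wi, clip_fraction = 0), "clip_fraction")
})
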