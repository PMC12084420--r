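mini_weights <- function(tag, ce, sat = NULL) {
  d <- dim(tag)
  W <- array(0, c(d, 4), dimnames = list(NULL, NULL, srs_components()))
  W[, , "TAG"] <- tag; W[, , "CE"] <- ce
  structure(list(W = W,
                 saturation = if (is.null(sat)) matrix(FALSE, d[1], d[2]) else sat,
                 settings = acquisition_settings(), normalized_to = NULL),
            class = "srs_weights")
}

test_that("droplet records sum lipid weights and apply the saturation filter", {
  tag <- matrix(0, 10, 10); ce <- matrix(0, 10, 10)
  dro <- matrix(0L, 10, 10)
  dro[2:3, 2:3] <- 1L               # 4 px, (tag, ce) = (1, 3)
  tag[2:3, 2:3] <- 1; ce[2:3, 2:3] <- 3
  dro[6:7, 6:7] <- 2L               # 25% saturated -> excluded
  tag[6:7, 6:7] <- 1
  dro[9, 2:4] <- 3L                 # tag 0, ce > 0 -> CE fraction 1
  ce[9, 2:4] <- 2
  sat <- matrix(FALSE, 10, 10); sat[6, 6] <- TRUE
  cells <- matrix(1L, 10, 10)
  masks <- segmentation_masks(matrix(0L, 10, 10), cells, dro,
                              pixel_size_um = 0.5)
  rec <- droplet_records(mini_weights(tag, ce, sat), masks)
  expect_equal(nrow(rec), 2)
  r1 <- rec[rec$droplet_id == 1, ]
  expect_equal(r1$tag_sum, 4)
  expect_equal(r1$ce_sum, 12)
  expect_equal(r1$ce_fraction, 0.75)
  expect_equal(r1$equivalent_radius_um, sqrt(4 / pi) * 0.5)
  expect_false(2 %in% rec$droplet_id)
  expect_equal(rec$ce_fraction[rec$droplet_id == 3], 1)

  # a droplet with exactly 20% saturated pixels is excluded ("less than 20%")
  dro2 <- matrix(0L, 10, 10); dro2[1, 1:5] <- 1L
  sat2 <- matrix(FALSE, 10, 10); sat2[1, 1] <- TRUE
  m2 <- segmentation_masks(matrix(0L, 10, 10), cells, dro2)
  expect_equal(nrow(droplet_records(mini_weights(tag, ce, sat2), m2)), 0)

  # CE fraction is invariant under joint rescaling of both planes
  rec_s <- droplet_records(mini_weights(tag * 7, ce * 7, sat), masks)
  expect_equal(rec_s$ce_fraction, rec$ce_fraction)
  # droplet sums never exceed whole-image totals
  expect_lte(sum(rec$tag_sum), sum(tag))
  expect_lte(sum(rec$ce_sum), sum(ce))
})

test_that("cell summaries add droplet and whole-cell pools", {
  tag <- matrix(0, 12, 12); ce <- matrix(0.5, 12, 12) # diffuse CE everywhere
  dro <- matrix(0L, 12, 12)
  dro[2:3, 2:3] <- 1L; ce[2:3, 2:3] <- 2; tag[2:3, 2:3] <- 2
  dro[8:9, 8:9] <- 2L; ce[8:9, 8:9] <- 3; tag[8:9, 8:9] <- 1
  nuc <- matrix(0L, 12, 12); nuc[1:4, 1:4] <- 1L  # droplet 1 is NE
  cells <- matrix(1L, 12, 12)
  masks <- segmentation_masks(nuc, cells, dro)
  wi <- mini_weights(tag, ce)
  rec <- droplet_records(wi, masks)
  s <- cell_summaries(rec, wi, masks)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_droplets, 2L)
  expect_equal(s$n_ne_droplets, 1L)
  expect_equal(s$ld_ce_sum, 4 * 2 + 4 * 3)
  expect_gt(s$cell_ce_sum, s$ld_ce_sum)  # membrane CE pool outside droplets
  expect_equal(s$fraction_ne, 0.5)
  expect_equal(s$ce_in_ne_fraction, 8 / 20)

  # a cell without droplets yields missing ratio metrics
  cells2 <- cells; cells2[, 7:12] <- 2L; cells2[, 1:6] <- 1L
  dro1 <- dro; dro1[dro1 == 2L] <- 0L
  m2 <- segmentation_masks(nuc, cells2, dro1)
  s2 <- cell_summaries(droplet_records(wi, m2), wi, m2)
  expect_true(is.na(s2$fraction_ne[s2$cell_id == 2]))
})

test_that("size x CE histogram bins records with open end bins", {
  rec <- data.frame(equivalent_radius_um = c(0.3, 0.5, 1.1),
                    ce_fraction = c(0.1, 0.5, 0.9))
  h <- size_ce_histogram(rec, c(0, 0.4, 0.8, 1.2), c(0, 0.5, 1))
  core <- h[2:4, ]
  expect_equal(unname(rowSums(core)), c(1, 1, 1))
  expect_equal(sum(h), nrow(rec))

  expect_equal(sum(size_ce_histogram(rec[0, ], c(0, 1))), 0)

  rec1 <- data.frame(equivalent_radius_um = rep(0.2, 5),
                     ce_fraction = rep(0.3, 5))
  h1 <- size_ce_histogram(rec1, c(0, 0.4), c(0, 0.5, 1))
  expect_equal(max(h1), 5)
  expect_equal(sum(h1 > 0), 1)
  # records beyond the last edge land in the overflow bin
  h2 <- size_ce_histogram(data.frame(equivalent_radius_um = 9,
                                     ce_fraction = 2),
                          c(0, 0.4), c(0, 0.5, 1))
  expect_equal(h2[nrow(h2), ncol(h2)], 1L)
  expect_error(size_ce_histogram(rec, c(1, 0.4)), "increasing")
})

test_that("anchor normalization equalizes the anchor CE and is idempotent", {
  srs <- data.frame(condition = c("double", "other"), CE = c(10, 5),
                    TAG = c(4, 8))
  tlc <- data.frame(condition = c("double", "other"), CE = c(200, 100),
                    TAG = c(50, 25))
  n <- anchor_normalize(srs, tlc, "double")
  expect_equal(n$srs$CE, c(1, 0.5))
  expect_equal(n$tlc$CE, c(1, 0.5))
  expect_equal(n$srs$CE[1], n$tlc$CE[1])  # anchors match exactly
  # within-table ratios preserved
  expect_equal(n$srs$TAG / srs$TAG, rep(1 / 10, 2))
  n2 <- anchor_normalize(n$srs, n$tlc, "double")
  expect_equal(n2, n)
  expect_error(anchor_normalize(srs, tlc, "absent"), "not present")
  srs0 <- srs; srs0$CE[1] <- 0
  expect_error(anchor_normalize(srs0, tlc, "double"), "> 0")
})

test_that("NE vs cytoplasmic CE-fraction comparison behaves on known groups", {
  rec_same <- data.frame(is_ne = rep(c(TRUE, FALSE), each = 20),
                         ce_fraction = rep(seq(0.2, 0.6, length.out = 20), 2))
  same <- compare_ne_vs_cyto(rec_same)
  expect_equal(same$difference, 0)
  expect_gt(same$p_value, 0.99)

  rec_const <- data.frame(is_ne = rep(c(TRUE, FALSE), each = 50),
                          ce_fraction = rep(c(0.6, 0.4), each = 50))
  cst <- compare_ne_vs_cyto(rec_const)
  expect_equal(cst$difference, 0.2)
  expect_lt(cst$p_value, 0.001)

  set.seed(8)
  rec_sim <- data.frame(
    is_ne = rep(c(TRUE, FALSE), each = 40),
    ce_fraction = c(rnorm(40, 0.45, 0.05), rnorm(40, 0.35, 0.05)))
  sim <- compare_ne_vs_cyto(rec_sim)
  expect_gt(sim$mean_ne, sim$mean_cyto)
  expect_lt(sim$p_value, 0.05)
  wil <- compare_ne_vs_cyto(rec_sim, test = "wilcox")
  expect_lt(wil$p_value, 0.05)
  expect_error(compare_ne_vs_cyto(rec_sim[c(1, 41, 42), ]), "at least 2")
})
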