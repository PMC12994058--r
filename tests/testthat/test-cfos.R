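test_that("a signal-free image yields no objects", {
  blank <- simulate_cfos_image(128, 128, data.frame(x = numeric(0),
                                                    y = numeric(0),
                                                    radius = numeric(0)),
                               noise_sd = 0.02, seed = 2)
  expect_equal(n_objects(detect_nuclei(blank$image[, , 1])), 0L)
  expect_equal(n_objects(detect_nuclei(matrix(0, 32, 32))), 0L)
})

test_that("noise-free detection recovers planted spot counts exactly", {
  sp <- simulate_spot_field(50, 512, 512, radius = 4, min_distance = 14,
                            seed = 5)
  sim <- simulate_cfos_image(512, 512, sp, noise_sd = 0, seed = 6)
  expect_equal(n_objects(detect_nuclei(sim$image[, , 1])), 50L)
})

test_that("watershed splits a fused two-spot blob at its two maxima", {
  sp <- data.frame(x = c(60, 66), y = c(60, 60), radius = 4, cfos = TRUE)
  sim <- simulate_cfos_image(128, 128, sp, noise_sd = 0)
  m <- detect_nuclei(sim$image[, , 1], spot_params(maxima_min_distance = 2))
  expect_equal(n_objects(m), 2L)
})

test_that("detection stays within 5% under 20% peak noise", {
  sp <- simulate_spot_field(60, 512, 512, radius = 4, min_distance = 14,
                            seed = 7)
  sim <- simulate_cfos_image(512, 512, sp, noise_sd = 0.2, seed = 8)
  got <- n_objects(detect_nuclei(sim$image[, , 1]))
  expect_lte(abs(got - 60) / 60, 0.05)
})

test_that("mask combination is a footprint-overlap filter on the AND", {
  sp <- simulate_spot_field(25, 256, 256, radius = 4, min_distance = 14,
                            cfos_fraction = 0.6, seed = 9)
  sim <- simulate_cfos_image(256, 256, sp, noise_sd = 0)
  m1 <- detect_nuclei(sim$image[, , 1])
  m2 <- detect_nuclei(sim$image[, , 2])
  comb <- combine_masks(m1, m2)
  expect_equal(n_objects(comb), sum(sp$cfos))
  # identical masks: identity up to relabelling
  same <- combine_masks(m1, m1)
  expect_equal(n_objects(same), n_objects(m1))
  expect_identical(same > 0, m1 > 0)
  # disjoint masks: empty
  shifted <- matrix(0L, 256, 256)
  expect_equal(n_objects(combine_masks(m1, shifted)), 0L)
  # never increases the object count
  expect_lte(n_objects(comb), n_objects(m1))
  expect_error(combine_masks(m1, matrix(0, 10, 10)), "shape")
})

test_that("per-pixel AND equals the bitwise oracle on random masks", {
  set.seed(61)
  for (i in 1:20) {
    a <- matrix(rbinom(400, 1, 0.4), 20, 20)
    b <- matrix(rbinom(400, 1, 0.4), 20, 20)
    got <- mask_and(a, b)
    want <- matrix(as.logical(a) & as.logical(b), 20, 20)
    expect_identical(got, want)
  }
})

test_that("ROI counting assigns objects by centroid and scales by area", {
  mask <- matrix(0L, 100, 100)
  # 100 single-label objects of 1 px on a grid
  xs <- rep(seq(5, 95, by = 10), 10)
  ys <- rep(seq(5, 95, by = 10), each = 10)
  mask[cbind(xs, ys)] <- seq_len(100)
  roi <- matrix(1L, 100, 100)
  # pixel chosen so the ROI is exactly 0.5 mm^2: 10^4 px * s^2 = 0.5 mm^2
  px_um <- sqrt(0.5 / 1e4) * 1000
  d <- count_in_roi(mask, roi, pixel_size_um = px_um)
  expect_equal(d$count, 100L)
  expect_equal(d$density, 200, tolerance = 1e-9)
  # empty ROI label: zero count, zero density
  roi2 <- roi; roi2[, 51:100] <- 2L; mask2 <- mask; mask2[, 51:100] <- 0L
  d2 <- count_in_roi(mask2, roi2, pixel_size_um = px_um)
  expect_equal(d2$count[d2$roi == 2], 0L)
  expect_equal(d2$density[d2$roi == 2], 0)
  expect_error(count_in_roi(mask, roi, 0), "> 0")
  expect_error(count_in_roi(mask, roi[1:50, ], 1), "shape")
})

test_that("ROI counts match a centroid-in-region oracle on random scenes", {
  set.seed(67)
  for (i in 1:10) {
    sp <- simulate_spot_field(30, 256, 256, radius = 3, min_distance = 10,
                              seed = i)
    sim <- simulate_cfos_image(256, 256, sp, noise_sd = 0)
    m <- detect_nuclei(sim$image[, , 1], spot_params(maxima_min_distance = 4))
    roi <- matrix(1L, 256, 256); roi[129:256, ] <- 2L
    d <- count_in_roi(m, roi, pixel_size_um = 2)
    idx <- which(m > 0, arr.ind = TRUE)
    cx <- round(tapply(idx[, 1], m[m > 0], mean))
    cy <- round(tapply(idx[, 2], m[m > 0], mean))
    want <- table(factor(roi[cbind(cx, cy)], levels = 1:2))
    expect_equal(d$count, as.integer(want))
  }
})

test_that("slice medians flag incomplete series", {
  expect_equal(region_median(c(10, 20, 400))$median, 20)
  one <- region_median(7)
  expect_equal(one$median, 7)
  expect_true(one$flagged)
  expect_false(region_median(c(1, 2, 3))$flagged)
  expect_error(region_median(numeric(0)), "no slice")
  set.seed(71)
  for (i in 1:50) {
    x <- runif(3, 0, 500)
    expect_equal(region_median(x)$median, sort(x)[2])
  }
})

test_that("activation scores use control median/p75/max cuts and combine
           paired regions to 0-6", {
  set.seed(73)
  regions <- c("BA", "LA", "CeL", "CeM",
               "dPAG_ant", "dPAG_post", "vPAG_ant", "vPAG_post")
  ids <- sprintf("a%02d", 1:16)
  dens <- expand.grid(animal_id = ids, region = regions,
                      stringsAsFactors = FALSE)
  dens$density <- runif(nrow(dens), 50, 400)
  ctrl_ids <- ids[1:8]
  res <- activation_scores(dens, ctrl_ids)
  # per-region scores replay through an independent one-sided bin scan
  for (rg in regions) {
    d <- dens[dens$region == rg, ]
    ctrl <- d$density[d$animal_id %in% ctrl_ids]
    cuts <- c(oracle_pctl(ctrl, 50), oracle_pctl(ctrl, 75), max(ctrl))
    want <- vapply(d$density, function(v) {
      for (s in 0:2) if (v <= cuts[s + 1]) return(s)
      3L
    }, numeric(1))
    got <- res$scores$score[res$scores$region == rg]
    expect_equal(got, as.integer(want))
  }
  # a density exactly at the control median scores 0
  d1 <- dens[dens$region == "BA", ]
  med <- median(d1$density[d1$animal_id %in% ctrl_ids])
  probe <- rbind(d1, data.frame(animal_id = "probe", region = "BA",
                                density = med))
  pr <- activation_scores(probe, ctrl_ids)
  expect_equal(pr$scores$score[pr$scores$animal_id == "probe"], 0L)
  # combined scores are the stated sums
  wide <- reshape(res$scores, idvar = "animal_id", timevar = "region",
                  direction = "wide")
  expect_equal(res$combined$BLA,
               wide$score.BA + wide$score.LA)
  expect_equal(res$combined$vPAG,
               wide$score.vPAG_ant + wide$score.vPAG_post)
  expect_true(all(res$combined$CeA >= 0 & res$combined$CeA <= 6))
  expect_error(activation_scores(dens[dens$animal_id %in% ids[1:3], ],
                                 ids[1:3]), "undersampled")
})

test_that("density is invariant to imaging the same scene at double
           resolution", {
  sp <- simulate_spot_field(40, 256, 256, radius = 4, min_distance = 16,
                            seed = 81)
  lo <- simulate_cfos_image(256, 256, sp, noise_sd = 0)
  sp2 <- data.frame(x = 2 * sp$x, y = 2 * sp$y, radius = 2 * sp$radius,
                    cfos = sp$cfos)
  hi <- simulate_cfos_image(512, 512, sp2, noise_sd = 0)
  m_lo <- detect_nuclei(lo$image[, , 1])
  m_hi <- detect_nuclei(hi$image[, , 1],
                        spot_params(smoothing_sigma = 4,
                                    maxima_min_distance = 10,
                                    min_object_area = 36))
  d_lo <- count_in_roi(m_lo, matrix(1L, 256, 256), pixel_size_um = 2)
  d_hi <- count_in_roi(m_hi, matrix(1L, 512, 512), pixel_size_um = 1)
  expect_lt(abs(d_hi$density - d_lo$density) / d_lo$density, 0.02)
})

test_that("two-channel TIFF round-trips through disk", {
  sp <- simulate_spot_field(8, 96, 96, radius = 3, seed = 91,
                            cfos_fraction = 0.5)
  sim <- simulate_cfos_image(96, 96, sp, noise_sd = 0)
  p <- tempfile(fileext = ".tif")
  write_cfos_tiff(sim$image, p)
  back <- read_cfos_tiff(p)
  expect_equal(dim(back), dim(sim$image))
  clipped <- pmin(pmax(sim$image, 0), 1)   # storage clips to [0, 1]
  expect_equal(back, clipped, tolerance = 1e-6)
  unlink(p)
})
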