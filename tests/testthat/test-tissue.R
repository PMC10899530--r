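test_that("blank channels give empty tissue and tumor masks", {
  blank <- matrix(100, 64, 64)
  mask <- segment_tissue(blank)
  expect_false(any(mask))
  expect_equal(max(segment_tumor(blank, mask)), 0)
})

test_that("the rendered lung is segmented within 1% of its true area", {
  sim <- simulate_tissue_section(tissue_sim_params(n_tumors = 0), seed = 6)
  mask <- segment_tissue(sim$dapi)
  expect_lt(abs(sum(mask) - sim$truth$lung_area_px) / sim$truth$lung_area_px,
            0.01)
})

test_that("interior holes in the tissue are filled", {
  sim <- simulate_tissue_section(
    tissue_sim_params(n_tumors = 0, image_shape = c(200, 200), pixel_noise = 0),
    seed = 7)
  dapi <- sim$dapi
  # punch a vessel-like hole into the lung interior
  dapi <- ktrq:::add_disk(dapi, 100, 100, 10, sim$params$background)
  mask <- segment_tissue(dapi)
  expect_equal(sum(mask), sim$truth$lung_area_px)
})

test_that("manual correction masks are applied by union and subtraction", {
  sim <- simulate_tissue_section(
    tissue_sim_params(n_tumors = 0, image_shape = c(120, 120)), seed = 8)
  add <- matrix(FALSE, 120, 120); add[1:5, 1:5] <- TRUE
  rm_ <- matrix(FALSE, 120, 120); rm_[60, 60] <- TRUE
  mask <- segment_tissue(sim$dapi, manual_add = add, manual_remove = rm_)
  expect_true(all(mask[1:5, 1:5]))
  expect_false(mask[60, 60])
})

test_that("tumor segmentation counts blobs and honors the min-area filter", {
  p <- tissue_sim_params(n_tumors = 5, tumor_radius_range = c(8, 10),
                         min_tumor_separation = 20, image_shape = c(300, 300))
  sim <- simulate_tissue_section(p, seed = 9)
  mask <- segment_tissue(sim$dapi)
  lab <- segment_tumor(sim$vimentin, mask)
  expect_equal(max(lab), 5)
  # raising the min area above the blob size excludes all of them
  big <- tissue_opts(min_tumor_area = 1000)
  expect_equal(max(segment_tumor(sim$vimentin, mask, big)), 0)
})

test_that("vimentin signal outside the tissue mask is ignored", {
  p <- tissue_sim_params(n_tumors = 3, image_shape = c(250, 250),
                         lung_fill_fraction = 0.4, pixel_noise = 0)
  sim <- simulate_tissue_section(p, seed = 10)
  mask <- segment_tissue(sim$dapi)
  vim <- sim$vimentin
  vim[1:20, 1:20] <- 60000   # bright blob far outside the lung
  lab <- segment_tumor(vim, mask)
  expect_equal(max(lab), 3)
  expect_true(all(lab[1:20, 1:20] == 0))
})

test_that("metastatic burden follows tumor/lung x 100", {
  lung <- matrix(FALSE, 50, 50); lung[1:40, 1:25] <- TRUE  # 1000 px
  expect_error(metastatic_burden(matrix(FALSE, 50, 50), matrix(0L, 50, 50)),
               "zero")
  none <- matrix(0L, 50, 50)
  expect_equal(metastatic_burden(lung, none)$burden_percent, 0)
  tum <- matrix(0L, 50, 50); tum[1:10, 1:25] <- 1L  # 250 px
  rep <- metastatic_burden(lung, tum)
  expect_equal(rep$burden_percent, 25)
  expect_equal(rep$tumor_count, 1)
  full <- matrix(0L, 50, 50); full[lung] <- 1L
  expect_equal(metastatic_burden(lung, full)$burden_percent, 100)
})

test_that("marker p90 uses interpolated percentiles and ignores out-of-mask pixels", {
  m <- matrix(0, 5, 5)
  lab <- matrix(0L, 5, 5)
  m[1:10] <- 1:10
  lab[1:10] <- 1L
  expect_equal(marker_p90(m, lab), 9.1)
  expect_equal(marker_p90(m, lab), p90_oracle(1:10))
  m2 <- m; m2[lab == 0] <- 65535
  expect_equal(marker_p90(m2, lab), 9.1)
  # uniform intensity returns the constant; empty mask returns NA
  expect_equal(marker_p90(matrix(7, 4, 4),
                          matrix(1L, 4, 4)), 7)
  expect_true(is.na(marker_p90(m, matrix(0L, 5, 5))))
  per <- marker_p90(m, lab, scope = "per_tumor")
  expect_equal(per$p90, 9.1)
})

test_that("marker p90 matches the percentile oracle on random masked images", {
  set.seed(123)
  for (i in 1:20) {
    img <- matrix(stats::runif(400, 0, 65535), 20, 20)
    lab <- matrix(as.integer(stats::runif(400) < 0.4), 20, 20)
    if (!any(lab > 0)) next
    expect_equal(marker_p90(img, lab), p90_oracle(img[lab > 0]),
                 tolerance = 1e-10)
  }
})

test_that("compartment signals report raw means and scale with normalization", {
  nuc <- matrix(0L, 40, 40); nuc <- ktrq:::add_disk(nuc, 20, 20, 5, 1L)
  storage.mode(nuc) <- "integer"
  ring <- make_cyto_rings(nuc, 3)
  img <- matrix(0, 40, 40)
  img[nuc == 1] <- 50
  img[ring == 1] <- 150
  out_n <- icc_compartment_signal(img, nuc, ring, "nuclear")
  expect_equal(out_n$raw_mean, 50)
  out_c <- icc_compartment_signal(img, nuc, ring, "cytoplasmic",
                                  control_mean = 150)
  expect_equal(out_c$normalized, 1)
  out2 <- icc_compartment_signal(2 * img, nuc, ring, "cytoplasmic",
                                 control_mean = 150)
  expect_equal(out2$normalized, 2 * out_c$normalized)
  expect_error(icc_compartment_signal(img, nuc, ring, control_mean = 0), "> 0")
})

test_that("Bland-Altman matches closed forms", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  d <- c(1, -1, 1, -1)
  ba <- bland_altman(rep(0, 4), d)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  off <- bland_altman(c(5, 6, 7), c(7, 8, 9))
  expect_equal(off$bias, 2)
  expect_equal(c(off$loa_low, off$loa_high), c(2, 2))
  expect_error(bland_altman(1, 1:2), "equal length")
  expect_error(bland_altman(1, 1), "n >= 2")
  expect_s3_class(autoplot(ba), "ggplot")
  expect_equal(tidy(ba)$estimate[1], 0)
})

test_that("Bland-Altman agrees with direct computation on random pairs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    manual <- stats::rnorm(n, 20, 5)
    auto <- manual + stats::rnorm(n, 1, 2)
    ba <- bland_altman(manual, auto)
    d <- auto - manual
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(ba$loa_low, mean(d) - 1.96 * stats::sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  }
})
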