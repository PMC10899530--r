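render_disks <- function(size, centers, radius, level = 3000, bg = 100) {
  m <- matrix(bg, size[1], size[2])
  for (i in seq_len(nrow(centers))) {
    m <- ktrq:::add_disk(m, centers[i, 1], centers[i, 2], radius, bg + level)
  }
  m
}

test_that("a blank frame segments to zero objects", {
  expect_equal(max(segment_nuclei(matrix(100, 64, 64))), 0)
})

test_that("well-separated disks are recovered with centroids within 1 px", {
  centers <- cbind(c(30, 30, 70, 70, 100), c(30, 90, 30, 90, 60))
  img <- render_disks(c(128, 128), centers, radius = 8)
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 5)
  got <- label_centroids_test(lab)
  for (i in seq_len(5)) {
    d <- sqrt((got$y - centers[i, 1])^2 + (got$x - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("watershed splits two overlapping disks", {
  centers <- cbind(c(50, 50), c(50, 63))   # radius 8, centers 13 apart: 3 px overlap
  img <- render_disks(c(100, 100), centers, radius = 8)
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2)
})

test_that("cytoplasmic rings exclude nuclei and scale with perimeter", {
  nuc <- matrix(0L, 80, 80)
  nuc <- ktrq:::add_disk(nuc, 40, 40, 8, 1L)
  storage.mode(nuc) <- "integer"
  ring <- make_cyto_rings(nuc, ring_width = 3)
  expect_equal(sum(ring > 0 & nuc > 0), 0)
  # annulus area approx perimeter * width = 2*pi*(r + w/2)*w
  expected <- 2 * pi * (8 + 1.5) * 3
  expect_lt(abs(sum(ring == 1) - expected) / expected, 0.25)
})

test_that("rings of adjacent nuclei are disjoint and split by distance", {
  nuc <- matrix(0L, 60, 120)
  nuc <- ktrq:::add_disk(nuc, 30, 40, 6, 1L)
  nuc <- ktrq:::add_disk(nuc, 30, 56, 6, 2L)
  storage.mode(nuc) <- "integer"
  ring <- make_cyto_rings(nuc, ring_width = 4)
  expect_true(all(ring[nuc > 0] == 0))
  # the midline (x = 48) splits claims: ring-1 pixels lie left of ring-2 pixels
  r1 <- which(ring == 1, arr.ind = TRUE)
  r2 <- which(ring == 2, arr.ind = TRUE)
  expect_true(max(r1[, 2]) <= 49)
  expect_true(min(r2[, 2]) >= 48)
})

test_that("rings at the image border are clipped without error", {
  nuc <- matrix(0L, 40, 40)
  nuc <- ktrq:::add_disk(nuc, 3, 3, 5, 1L)
  storage.mode(nuc) <- "integer"
  expect_silent(ring <- make_cyto_rings(nuc, ring_width = 3))
  expect_gt(sum(ring == 1), 0)
  expect_error(make_cyto_rings(nuc, ring_width = 0), "ring_width")
})

test_that("a stationary cell yields a single full-length track", {
  m <- matrix(0L, 50, 50)
  m <- ktrq:::add_disk(m, 25, 25, 6, 1L)
  storage.mode(m) <- "integer"
  masks <- replicate(10, m, simplify = FALSE)
  tr <- link_tracks(masks)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(nrow(tr), 10)
  expect_error(link_tracks(list()), "frame")
})

test_that("a disappearing cell ends its track without re-linking", {
  mk <- function(with_a) {
    m <- matrix(0L, 60, 90)
    if (with_a) m <- ktrq:::add_disk(m, 30, 25, 5, 1L)
    m <- ktrq:::add_disk(m, 30, 65, 5, 2L)
    storage.mode(m) <- "integer"
    m
  }
  masks <- c(replicate(5, mk(TRUE), simplify = FALSE),
             replicate(4, mk(FALSE), simplify = FALSE))
  tr <- link_tracks(masks, max_disp = 10)
  lens <- table(tr$cell_id)
  expect_setequal(as.integer(lens), c(5L, 9L))
  # the long track never jumps to the removed cell's position
  long_id <- names(lens)[lens == 9]
  long_tr <- tr[tr$cell_id == as.integer(long_id), ]
  expect_true(all(abs(long_tr$x - 65) < 1))
})

test_that("simulated drifting cells are tracked with full identity agreement", {
  sched <- acquisition_schedule(frame_interval = 6, baseline_duration = 30,
                                post_duration = 60, meki_window = 24)
  p <- sim_params(n_cells = 20, noise_sigma = 0)
  ro <- render_opts(image_size = c(300, 300), drift_step = 2)
  mv <- simulate_timelapse(p, sched, ro, seed = 11)
  nuclei <- lapply(seq_len(sched$n_frames),
                   function(f) segment_nuclei(mv$h2b[, , f]))
  tr <- link_tracks(nuclei, max_disp = 12)
  expect_equal(length(unique(tr$cell_id)), 20)
  map <- match_tracks_to_truth(tr, mv$truth$tracks)
  truth <- mv$truth$tracks
  for (i in seq_len(nrow(tr))) {
    tt <- truth[truth$cell_id == map[[as.character(tr$cell_id[i])]] &
                  truth$frame == tr$frame[i], ]
    expect_lt(sqrt((tt$y - tr$y[i])^2 + (tt$x - tr$x[i])^2), 2)
  }
})

test_that("extraction recovers the rendered compartment ratio exactly", {
  sched <- acquisition_schedule(frame_interval = 6, baseline_duration = 12,
                                post_duration = 24, meki_window = 12)
  p <- sim_params(response_class = 0, noise_sigma = 0, baseline_level = 2,
                  meki_floor = 0.5, n_cells = 1)
  ro <- render_opts(image_size = c(96, 96), drift_step = 0, photon_noise = 0)
  mv <- simulate_timelapse(p, sched, ro, seed = 1)
  ex <- ktr_extract(mv$h2b, mv$erktr, sched)
  pre <- ex$traces[ex$traces$time_min <= sched$meki_time, ]
  expect_true(all(pre$valid))
  expect_equal(pre$activity, rep(2, nrow(pre)), tolerance = 1e-9)
})

test_that("nuc-over-cyt orientation is the reciprocal of cyt-over-nuc", {
  sched <- acquisition_schedule(frame_interval = 6, baseline_duration = 12,
                                post_duration = 24, meki_window = 12)
  p <- sim_params(n_cells = 4, noise_sigma = 0)
  ro <- render_opts(image_size = c(200, 200), photon_noise = 10)
  mv <- simulate_timelapse(p, sched, ro, seed = 8)
  ex <- ktr_extract(mv$h2b, mv$erktr, sched)
  ex2 <- extract_activity_traces(mv$erktr, ex$tracks, ex$nuclei_masks,
                                 ex$ring_masks, sched,
                                 orientation = "nuc_over_cyt")
  both <- merge(ex$traces, ex2, by = c("cell_id", "frame"))
  ok <- both$valid.x & both$valid.y
  expect_true(any(ok))
  expect_equal(both$activity.y[ok], 1 / both$activity.x[ok], tolerance = 1e-12)
})
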