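# Shared fixtures and independent oracles for the test suite.

# A short schedule for unit tests: 5 pre frames (times 6..30), treatment at
# 30 min, MEKi at 90 min, 12 min floor tail.
tiny_schedule <- function() {
  acquisition_schedule(frame_interval = 6, baseline_duration = 30,
                       post_duration = 60, meki_window = 12)
}

# Single-cell trace tibble on an explicit grid.
make_trace <- function(times, activity, valid = TRUE, cell_id = 1L) {
  tibble::tibble(
    cell_id = cell_id,
    frame = seq_along(times),
    time_min = times,
    activity = activity,
    valid = rep_len(valid, length(times)),
    condition = "test",
    dose_ng_ml = 1
  )
}

# Map extracted track ids to ground-truth cell ids by nearest centroid in
# the first frame each track appears.
match_tracks_to_truth <- function(tracks, truth_tracks) {
  first <- tracks[!duplicated(tracks$cell_id), , drop = FALSE]
  vapply(seq_len(nrow(first)), function(i) {
    tt <- truth_tracks[truth_tracks$frame == first$frame[i], , drop = FALSE]
    d2 <- (tt$y - first$y[i])^2 + (tt$x - first$x[i])^2
    tt$cell_id[which.min(d2)]
  }, numeric(1)) |>
    stats::setNames(first$cell_id)
}

# Plain centroid computation from a label matrix (independent of the
# package's internals).
label_centroids_test <- function(labels) {
  labs <- setdiff(sort(unique(as.vector(labels))), 0L)
  out <- data.frame(label = labs, y = NA_real_, x = NA_real_)
  for (i in seq_along(labs)) {
    idx <- which(labels == labs[i], arr.ind = TRUE)
    out$y[i] <- mean(idx[, 1])
    out$x[i] <- mean(idx[, 2])
  }
  out
}

# Brute-force Benjamini-Hochberg step-up oracle: for the i-th smallest
# p-value, q = min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Interpolated-percentile oracle (the classic h = (n-1)q + 1 convention).
p90_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * 0.9 + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}
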