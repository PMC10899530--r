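# Nuclear segmentation, cytoplasmic rings, tracking and trace extraction.

#' Options for nuclear segmentation
#'
#' @param min_area Minimum object area in px^2 (default 30, matched to the
#'   default rendered nucleus of radius 6 px).
#' @param bg_subtract Subtract the per-frame median intensity before
#'   thresholding.
#' @param watershed_tolerance Minimum depth between watershed basins used
#'   when splitting touching nuclei.
#' @return A list of class `ktrq_segment_opts`.
#' @export
segment_opts <- function(min_area = 30, bg_subtract = TRUE,
                         watershed_tolerance = 1) {
  structure(list(min_area = min_area, bg_subtract = bg_subtract,
                 watershed_tolerance = watershed_tolerance),
            class = "ktrq_segment_opts")
}

#' Segment nuclei from an H2B frame
#'
#' Pipeline: per-frame median background subtraction, Otsu threshold, hole
#' filling, distance-transform watershed to split touching nuclei, and a
#' minimum-area filter. An all-constant frame yields an empty mask.
#'
#' @param frame Single-channel intensity matrix.
#' @param opts A [segment_opts()] object.
#' @return Integer label matrix, 0 = background, labels 1..K contiguous.
#' @export
segment_nuclei <- function(frame, opts = segment_opts()) {
  stopifnot(is.matrix(frame))
  x <- frame
  if (opts$bg_subtract) x <- pmax(x - stats::median(x), 0)
  thr <- otsu_threshold(x)
  if (!is.finite(thr)) return(matrix(0L, nrow(frame), ncol(frame)))
  bin <- x > thr
  if (!any(bin)) return(matrix(0L, nrow(frame), ncol(frame)))
  bin <- EBImage::imageData(EBImage::fillHull(bin * 1)) > 0
  dm <- EBImage::distmap(bin * 1)
  lab <- EBImage::imageData(
    EBImage::watershed(dm, tolerance = opts$watershed_tolerance)
  )
  storage.mode(lab) <- "integer"
  filter_min_area(lab, opts$min_area)
}

#' Build cytoplasmic ring masks around segmented nuclei
#'
#' Each nucleus receives an annulus: pixels within `ring_width` (Euclidean)
#' of that nucleus, excluding every nuclear pixel. A pixel reachable from
#' several nuclei is assigned to the nearest one; exact ties go to the
#' lower label. Rings are clipped at image borders.
#'
#' @param nuclei Integer nuclear label matrix from [segment_nuclei()].
#' @param ring_width Ring width in pixels (>= 1).
#' @return Integer label matrix of rings; labels match `nuclei`.
#' @export
make_cyto_rings <- function(nuclei, ring_width = 3) {
  stopifnot(is.matrix(nuclei))
  if (ring_width < 1) stop("`ring_width` must be >= 1", call. = FALSE)
  k <- max(nuclei)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (k == 0) return(out)
  any_nuc <- nuclei > 0
  best_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  for (lab in seq_len(k)) {
    if (!any(nuclei == lab)) next
    # distance from every pixel to nucleus `lab`
    d <- EBImage::imageData(EBImage::distmap((nuclei != lab) * 1))
    claim <- !any_nuc & d > 0 & d <= ring_width & d < best_d
    out[claim] <- lab
    best_d[claim] <- d[claim]
  }
  out
}

#' Link segmented nuclei into tracks across frames
#'
#' Greedy nearest-neighbor centroid linking: candidate links between
#' consecutive frames are taken closest-first, links longer than
#' `max_disp` are refused, unmatched objects start new tracks, and no gap
#' closing is performed.
#'
#' @param masks List of integer label matrices in temporal order.
#' @param max_disp Maximum allowed centroid displacement per frame, pixels.
#' @return A tibble (`cell_id`, `frame`, `label`, `y`, `x`) ordered by
#'   `cell_id` then `frame`.
#' @export
link_tracks <- function(masks, max_disp = 15) {
  if (length(masks) == 0) stop("`masks` must contain at least one frame", call. = FALSE)
  cents <- lapply(masks, label_centroids)
  rows <- list()
  next_id <- 1L
  prev <- NULL   # tibble with cell_id, y, x for previous frame
  for (f in seq_along(cents)) {
    cur <- cents[[f]]
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev) > 0 && nrow(cur) > 0) {
      d <- outer(prev$y, cur$y, `-`)^2 + outer(prev$x, cur$x, `-`)^2
      d <- sqrt(d)
      cand <- which(d <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_prev <- logical(nrow(prev)); used_cur <- logical(nrow(cur))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!used_prev[i] && !used_cur[j]) {
            assigned[j] <- prev$cell_id[i]
            used_prev[i] <- TRUE; used_cur[j] <- TRUE
          }
        }
      }
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      assigned[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    if (nrow(cur)) {
      rows[[f]] <- tibble::tibble(
        cell_id = assigned, frame = f,
        label = cur$label, y = cur$y, x = cur$x
      )
      prev <- tibble::tibble(cell_id = assigned, y = cur$y, x = cur$x)
    } else {
      prev <- NULL
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$cell_id, .data$frame)
}

#' Extract per-cell ERK activity traces from an ERKTR stack
#'
#' For every tracked cell and frame, computes the mean ERKTR intensity over
#' the nuclear mask and over the cytoplasmic ring, subtracts a per-frame
#' background (median over pixels outside all nuclei and rings), and forms
#' the activity ratio. The default orientation `cyt_over_nuc` rises with
#' ERK activity (the reporter exits the nucleus when phosphorylated);
#' `nuc_over_cyt` gives the reciprocal. Frames where either compartment
#' has fewer than `min_pixels` pixels, or a non-positive
#' background-corrected denominator, are flagged invalid (activity `NA`)
#' rather than propagating NaNs.
#'
#' @param erktr Numeric array `[rows, cols, frames]` (or list of matrices).
#' @param tracks Tibble from [link_tracks()].
#' @param nuclei_masks,ring_masks Lists of label matrices per frame, labels
#'   matching the `label` column of `tracks`.
#' @param schedule Optional [acquisition_schedule()] used to fill
#'   `time_min`; without it, `time_min` is `(frame - 1)` in frame units.
#' @param orientation `"cyt_over_nuc"` (default) or `"nuc_over_cyt"`.
#' @param min_pixels Minimum compartment size per frame.
#' @param condition,dose_ng_ml Metadata carried into the output.
#' @return A trace tibble with columns `cell_id`, `frame`, `time_min`,
#'   `activity`, `valid`, `condition`, `dose_ng_ml`, `nuc_mean`,
#'   `cyt_mean`, `background`.
#' @export
extract_activity_traces <- function(erktr, tracks, nuclei_masks, ring_masks,
                                    schedule = NULL,
                                    orientation = c("cyt_over_nuc", "nuc_over_cyt"),
                                    min_pixels = 5,
                                    condition = NA_character_,
                                    dose_ng_ml = NA_real_) {
  orientation <- match.arg(orientation)
  get_frame <- if (is.list(erktr)) function(f) erktr[[f]] else function(f) erktr[, , f]
  n_frames <- if (is.list(erktr)) length(erktr) else dim(erktr)[3]
  stopifnot(length(nuclei_masks) == n_frames, length(ring_masks) == n_frames)
  require_columns(tracks, c("cell_id", "frame", "label"), "`tracks`")

  per_frame <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    tf <- tracks[tracks$frame == f, , drop = FALSE]
    if (!nrow(tf)) next
    img <- get_frame(f)
    nuc <- nuclei_masks[[f]]
    ring <- ring_masks[[f]]
    bg <- stats::median(img[nuc == 0 & ring == 0])
    nuc_n <- tabulate(nuc[nuc > 0], nbins = max(nuc, 1L))
    ring_n <- tabulate(ring[ring > 0], nbins = max(ring, 1L))
    nuc_sum <- rep(0, max(nuc, 1L)); ring_sum <- rep(0, max(ring, 1L))
    idx <- nuc > 0
    if (any(idx)) {
      s <- tapply(img[idx], nuc[idx], sum)
      nuc_sum[as.integer(names(s))] <- s
    }
    idx <- ring > 0
    if (any(idx)) {
      s <- tapply(img[idx], ring[idx], sum)
      ring_sum[as.integer(names(s))] <- s
    }
    lab <- tf$label
    nn <- ifelse(lab <= length(nuc_n), nuc_n[lab], 0L)
    rn <- ifelse(lab <= length(ring_n), ring_n[lab], 0L)
    nmean <- ifelse(nn > 0, nuc_sum[lab] / nn, NA_real_)
    cmean <- ifelse(rn > 0, ring_sum[lab] / rn, NA_real_)
    num <- cmean - bg; den <- nmean - bg
    if (orientation == "nuc_over_cyt") { tmp <- num; num <- den; den <- tmp }
    valid <- nn >= min_pixels & rn >= min_pixels &
      is.finite(num) & is.finite(den) & den > 0
    per_frame[[f]] <- tibble::tibble(
      cell_id = tf$cell_id, frame = f,
      activity = ifelse(valid, num / den, NA_real_),
      valid = valid, nuc_mean = nmean, cyt_mean = cmean, background = bg
    )
  }
  out <- dplyr::bind_rows(per_frame)
  times <- if (!is.null(schedule)) schedule$times else (seq_len(n_frames) - 1)
  out$time_min <- times[out$frame]
  out$condition <- condition
  out$dose_ng_ml <- dose_ng_ml
  out <- out[, c("cell_id", "frame", "time_min", "activity", "valid",
                 "condition", "dose_ng_ml", "nuc_mean", "cyt_mean", "background")]
  dplyr::arrange(out, .data$cell_id, .data$frame)
}

#' Run the full live-cell extraction pipeline on a two-channel movie
#'
#' Convenience wrapper: segments nuclei on every H2B frame, builds
#' cytoplasmic rings, links tracks, and extracts activity traces from the
#' ERKTR channel.
#'
#' @param h2b,erktr Numeric arrays `[rows, cols, frames]`.
#' @param schedule Optional [acquisition_schedule()].
#' @param opts A [segment_opts()] object.
#' @param ring_width Ring width, pixels.
#' @param max_disp Maximum tracking displacement per frame, pixels.
#' @inheritParams extract_activity_traces
#' @return A list with `traces` (trace tibble), `tracks`, `nuclei_masks`
#'   and `ring_masks`.
#' @export
ktr_extract <- function(h2b, erktr, schedule = NULL, opts = segment_opts(),
                        ring_width = 3, max_disp = 15,
                        orientation = "cyt_over_nuc", min_pixels = 5,
                        condition = NA_character_, dose_ng_ml = NA_real_) {
  n_frames <- dim(h2b)[3]
  nuclei <- lapply(seq_len(n_frames), function(f) segment_nuclei(h2b[, , f], opts))
  rings <- lapply(nuclei, make_cyto_rings, ring_width = ring_width)
  tracks <- link_tracks(nuclei, max_disp = max_disp)
  traces <- extract_activity_traces(
    erktr, tracks, nuclei, rings, schedule = schedule,
    orientation = orientation, min_pixels = min_pixels,
    condition = condition, dose_ng_ml = dose_ng_ml
  )
  list(traces = traces, tracks = tracks, nuclei_masks = nuclei,
       ring_masks = rings)
}
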