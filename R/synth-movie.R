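# Two-channel synthetic time-lapse rendering with exact ground truth.

# Rejection-sample n cell centers with pairwise distance >= min_spacing and
# enough margin that the whole cell plus its drift box stays in frame.
place_cells <- function(n, image_size, margin, min_spacing, max_tries = 5000L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("y", "x"))))
  lo <- margin + 1
  hi_y <- image_size[1] - margin
  hi_x <- image_size[2] - margin
  if (hi_y <= lo || hi_x <= lo) {
    stop("field too small for the requested cell geometry", call. = FALSE)
  }
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("y", "x")))
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries * n) {
      stop(sprintf("could not place %d cells at spacing %g px", n, min_spacing),
           call. = FALSE)
    }
    cand <- c(stats::runif(1, lo, hi_y), stats::runif(1, lo, hi_x))
    if (placed == 0L ||
        min(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2))) >= min_spacing) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  pos
}

# Reflected random walk inside [center - bound, center + bound] per axis.
bounded_walk <- function(start, n_steps, step, bound) {
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  y <- numeric(n_steps); x <- numeric(n_steps)
  y[1] <- start[1]; x[1] <- start[2]
  if (n_steps > 1) {
    dy <- stats::runif(n_steps - 1, -step, step)
    dx <- stats::runif(n_steps - 1, -step, step)
    y[-1] <- reflect(start[1] + cumsum(dy), start[1] - bound, start[1] + bound)
    x[-1] <- reflect(start[2] + cumsum(dx), start[2] - bound, start[2] + bound)
  }
  cbind(y = y, x = x)
}

#' Simulate a two-channel KTR time-lapse movie with ground truth
#'
#' Renders an H2B (nuclear) and an ERKTR channel for an ensemble of cells
#' whose true activities come from [simulate_trace_ensemble()]. Each cell is
#' drawn as a nuclear disk inside a cytoplasmic disk; the ERKTR cytoplasm is
#' rendered at `erktr_nuclear * activity` so that the background-corrected
#' cytoplasm/nucleus mean-intensity ratio equals the cell's true (noiseless)
#' activity at every frame. Nuclei perform reflected random walks bounded
#' around their initial positions, which keeps ground-truth tracks
#' unambiguous; there are no divisions or deaths.
#'
#' @param params A [sim_params()] object (its `noise_sigma` does not affect
#'   the rendering; image noise is controlled by `render$photon_noise`).
#' @param schedule An [acquisition_schedule()].
#' @param render A [render_opts()] object.
#' @param seed Optional integer seed.
#' @return A list of class `ktrq_movie`:
#' \describe{
#'   \item{h2b, erktr}{numeric arrays `[rows, cols, frames]`, 16-bit scale.}
#'   \item{truth}{list with `tracks` (tibble `cell_id`, `frame`, `y`, `x`),
#'     `activity` (noiseless per-cell traces), `cells` (responder flags),
#'     and `masks` (per-frame integer nuclear label images, label ==
#'     cell_id).}
#' }
#' @export
simulate_timelapse <- function(params, schedule, render = render_opts(),
                               seed = NULL) {
  stopifnot(inherits(params, "ktrq_sim_params"),
            inherits(schedule, "ktrq_schedule"),
            inherits(render, "ktrq_render_opts"))
  if (!is.null(seed)) set.seed(seed)
  ro <- render
  n <- params$n_cells
  nf <- schedule$n_frames
  nr <- ro$image_size[1]; nc <- ro$image_size[2]

  sim <- simulate_trace_ensemble(params, schedule)
  act <- matrix(sim$truth$traces$activity, nrow = nf)   # frame x cell

  margin <- ro$cell_radius + ro$drift_bound + 1
  starts <- place_cells(n, ro$image_size, margin, ro$min_spacing)
  walks <- lapply(seq_len(n), function(i) {
    bounded_walk(starts[i, ], nf, ro$drift_step, ro$drift_bound)
  })

  h2b <- array(ro$background, dim = c(nr, nc, nf))
  erk <- array(ro$background, dim = c(nr, nc, nf))
  masks <- vector("list", nf)
  cap <- 2^ro$bit_depth - 1

  for (f in seq_len(nf)) {
    h <- matrix(ro$background, nr, nc)
    e <- matrix(ro$background, nr, nc)
    m <- matrix(0L, nr, nc)
    for (i in seq_len(n)) {
      cy <- walks[[i]][f, 1]; cx <- walks[[i]][f, 2]
      # cytoplasm first, nucleus over-writes its interior
      e <- add_disk(e, cy, cx, ro$cell_radius,
                    ro$background + ro$erktr_nuclear * act[f, i])
      e <- add_disk(e, cy, cx, ro$nucleus_radius,
                    ro$background + ro$erktr_nuclear)
      h <- add_disk(h, cy, cx, ro$nucleus_radius,
                    ro$background + ro$h2b_intensity)
      m <- add_disk(m, cy, cx, ro$nucleus_radius, i)
    }
    if (ro$photon_noise > 0) {
      h <- h + matrix(stats::rnorm(nr * nc, sd = ro$photon_noise), nr, nc)
      e <- e + matrix(stats::rnorm(nr * nc, sd = ro$photon_noise), nr, nc)
    }
    h2b[, , f] <- pmin(pmax(h, 0), cap)
    erk[, , f] <- pmin(pmax(e, 0), cap)
    storage.mode(m) <- "integer"
    masks[[f]] <- m
  }

  tracks <- tibble::tibble(
    cell_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf), times = n),
    y = unlist(lapply(walks, function(w) w[, 1])),
    x = unlist(lapply(walks, function(w) w[, 2]))
  )
  structure(
    list(
      h2b = h2b, erktr = erk,
      truth = list(tracks = tracks, activity = sim$truth$traces,
                   cells = sim$truth$cells, masks = masks),
      schedule = schedule, params = params, render = ro
    ),
    class = "ktrq_movie"
  )
}

#' @export
print.ktrq_movie <- function(x, ...) {
  d <- dim(x$h2b)
  cat(sprintf("<ktrq_movie> %d x %d px, %d frames, %d cells (H2B + ERKTR)\n",
              d[1], d[2], d[3], x$params$n_cells))
  invisible(x)
}
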