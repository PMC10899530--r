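# Three-channel synthetic tissue sections with exact ground truth.

# Binary lung mask: centered ellipse occupying `fill` of the field, or the
# full field when fill == 1. The recorded lung area is always the pixel
# count of the rendered mask, so discretization never breaks ground truth.
render_lung_mask <- function(image_shape, fill) {
  nr <- image_shape[1]; nc <- image_shape[2]
  if (fill >= 0.999) {
    return(matrix(TRUE, nr, nc))
  }
  scale <- sqrt(4 * fill / pi)
  if (scale > 1) scale <- 1   # ellipse capped at the field; area recorded from pixels
  a <- scale * nr / 2; b <- scale * nc / 2
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  outer(((seq_len(nr) - cy) / a)^2, ((seq_len(nc) - cx) / b)^2, `+`) <= 1
}

#' Simulate a three-channel fluorescent lung section with ground truth
#'
#' Renders DAPI (tissue), vimentin (tumor) and marker channels at 16-bit
#' scale. The lung is a DAPI-positive region occupying
#' `lung_fill_fraction` of the field; tumors are vimentin-positive disks
#' placed fully inside the lung with a minimum edge-to-edge separation;
#' the marker channel carries one intensity level per tumor drawn from
#' `N(marker_mean, marker_sd)`. Ground truth records the pixel-exact lung
#' area, tumor count, per-tumor areas and 90th-percentile marker intensity,
#' plus the implied metastatic burden.
#'
#' @param params A [tissue_sim_params()] object.
#' @param seed Optional integer seed.
#' @return A list of class `ktrq_tissue_sim`:
#' \describe{
#'   \item{dapi, vimentin, marker}{numeric intensity matrices.}
#'   \item{truth}{list with `lung_mask`, `tumor_labels` (integer label
#'     image), `lung_area_px`, `tumor_count`, `burden_percent`, and a
#'     per-tumor tibble `tumors` (`tumor_id`, `y`, `x`, `radius`,
#'     `area_px`, `marker_level`, `marker_p90`).}
#' }
#' @export
simulate_tissue_section <- function(params, seed = NULL) {
  stopifnot(inherits(params, "ktrq_tissue_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  cap <- 2^p$bit_depth - 1

  lung <- render_lung_mask(p$image_shape, p$lung_fill_fraction)
  lung_area <- sum(lung)

  # distance from each lung pixel to the lung boundary: a tumor of radius r
  # fits entirely inside the lung iff the boundary distance at its center
  # is >= r (with a 1 px guard for disk discretization).
  inner_dist <- EBImage::imageData(EBImage::distmap(lung * 1))

  n <- p$n_tumors
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  tries <- 0L
  while (length(radii) < n) {
    tries <- tries + 1L
    if (tries > 5000L * max(n, 1L)) {
      stop(sprintf("could not place %d tumors at separation %g px",
                   n, p$min_tumor_separation), call. = FALSE)
    }
    r <- stats::runif(1, p$tumor_radius_range[1], p$tumor_radius_range[2])
    cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
    iy <- round(cy); ix <- round(cx)
    if (iy < 1 || iy > nr || ix < 1 || ix > nc) next
    if (inner_dist[iy, ix] < r + 1) next
    if (length(radii)) {
      gap <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) -
        (radii + r)
      if (min(gap) < p$min_tumor_separation) next
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
  }

  dapi <- matrix(p$background, nr, nc)
  dapi[lung] <- p$background + p$dapi_level
  vim <- matrix(p$background, nr, nc)
  marker <- matrix(p$background, nr, nc)
  labels <- matrix(0L, nr, nc)
  marker_levels <- numeric(n)

  for (i in seq_len(n)) {
    lvl <- min(max(stats::rnorm(1, p$marker_mean, p$marker_sd), 0), cap)
    marker_levels[i] <- lvl
    vim <- add_disk(vim, centers[i, 1], centers[i, 2], radii[i],
                    p$background + p$vimentin_level)
    marker <- add_disk(marker, centers[i, 1], centers[i, 2], radii[i],
                       p$background + lvl)
    labels <- add_disk(labels, centers[i, 1], centers[i, 2], radii[i], i)
  }
  storage.mode(labels) <- "integer"

  if (p$pixel_noise > 0) {
    dapi <- dapi + matrix(stats::rnorm(nr * nc, sd = p$pixel_noise), nr, nc)
    vim <- vim + matrix(stats::rnorm(nr * nc, sd = p$pixel_noise), nr, nc)
    marker <- marker + matrix(stats::rnorm(nr * nc, sd = p$pixel_noise), nr, nc)
  }
  clampf <- function(m) pmin(pmax(m, 0), cap)
  dapi <- clampf(dapi); vim <- clampf(vim); marker <- clampf(marker)

  areas <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  p90 <- vapply(seq_len(n), function(i) {
    stats::quantile(marker[labels == i], 0.9, type = 7, names = FALSE)
  }, numeric(1))

  tumors <- tibble::tibble(
    tumor_id = seq_len(n),
    y = if (n > 0) centers[, 1] else numeric(0),
    x = if (n > 0) centers[, 2] else numeric(0),
    radius = radii,
    area_px = as.integer(areas),
    marker_level = marker_levels,
    marker_p90 = p90
  )
  structure(
    list(
      dapi = dapi, vimentin = vim, marker = marker,
      truth = list(
        lung_mask = lung,
        tumor_labels = labels,
        lung_area_px = lung_area,
        tumor_count = n,
        burden_percent = 100 * sum(areas) / lung_area,
        tumors = tumors
      ),
      params = p
    ),
    class = "ktrq_tissue_sim"
  )
}

#' @export
print.ktrq_tissue_sim <- function(x, ...) {
  cat(sprintf("<ktrq_tissue_sim> %d x %d px, %d tumors, burden %.2f%%\n",
              nrow(x$dapi), ncol(x$dapi), x$truth$tumor_count,
              x$truth$burden_percent))
  invisible(x)
}
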