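# Histology quantification: tissue/tumor segmentation, burden, marker p90,
# fixed-cell compartment signals, Bland-Altman agreement.

#' Options for tissue and tumor segmentation
#'
#' @param min_tissue_area Minimum connected tissue component kept, px^2.
#' @param min_tumor_area Minimum tumor component kept, px^2 (default 50 at
#'   working resolution).
#' @param closing_size Diameter of the disc used for morphological closing
#'   of the tissue mask, pixels (0 disables closing).
#' @return A list of class `ktrq_tissue_opts`.
#' @export
tissue_opts <- function(min_tissue_area = 500, min_tumor_area = 50,
                        closing_size = 5) {
  structure(list(min_tissue_area = min_tissue_area,
                 min_tumor_area = min_tumor_area,
                 closing_size = closing_size),
            class = "ktrq_tissue_opts")
}

#' Segment tissue from the DAPI channel
#'
#' Auto-threshold (Otsu) on the DAPI signal, morphological closing, hole
#' filling, and removal of components below the minimum tissue area.
#' Optional manual correction masks are applied afterwards, mirroring
#' operator curation: `manual_add` pixels are unioned in, `manual_remove`
#' pixels are subtracted.
#'
#' @param dapi Single-channel intensity matrix.
#' @param opts A [tissue_opts()] object.
#' @param manual_add,manual_remove Optional logical matrices of the same
#'   shape.
#' @return Logical tissue mask.
#' @export
segment_tissue <- function(dapi, opts = tissue_opts(),
                           manual_add = NULL, manual_remove = NULL) {
  stopifnot(is.matrix(dapi))
  thr <- otsu_threshold(dapi)
  if (!is.finite(thr)) {
    mask <- matrix(FALSE, nrow(dapi), ncol(dapi))
  } else {
    mask <- dapi > thr
    if (opts$closing_size > 0) {
      brush <- EBImage::makeBrush(
        max(3L, 2L * (opts$closing_size %/% 2L) + 1L), shape = "disc")
      mask <- EBImage::imageData(EBImage::closing(mask * 1, brush)) > 0
    }
    mask <- EBImage::imageData(EBImage::fillHull(mask * 1)) > 0
    lab <- label_8connected(mask)
    lab <- filter_min_area(lab, opts$min_tissue_area)
    mask <- lab > 0
  }
  if (!is.null(manual_add)) mask <- mask | manual_add
  if (!is.null(manual_remove)) mask <- mask & !manual_remove
  mask
}

#' Segment tumors from the vimentin channel within the tissue mask
#'
#' Otsu threshold computed over vimentin intensities inside the tissue
#' mask; signal outside the mask is ignored. Components are labeled with
#' 8-connectivity and those below the minimum tumor area are removed.
#'
#' @param vimentin Single-channel intensity matrix.
#' @param tissue_mask Logical mask from [segment_tissue()].
#' @param opts A [tissue_opts()] object.
#' @return Integer tumor label matrix (0 = background).
#' @export
segment_tumor <- function(vimentin, tissue_mask, opts = tissue_opts()) {
  stopifnot(is.matrix(vimentin), identical(dim(vimentin), dim(tissue_mask)))
  empty <- matrix(0L, nrow(vimentin), ncol(vimentin))
  if (!any(tissue_mask)) return(empty)
  thr <- otsu_threshold(vimentin[tissue_mask])
  if (!is.finite(thr)) return(empty)
  bin <- vimentin > thr & tissue_mask
  if (!any(bin)) return(empty)
  lab <- label_8connected(bin)
  filter_min_area(lab, opts$min_tumor_area)
}

#' Metastatic burden report from tissue and tumor masks
#'
#' Burden is the percentage of lung section area occupied by tumor:
#' `100 * tumor_area / lung_area`. The count is the number of labeled
#' tumor components.
#'
#' @param tissue_mask Logical lung mask.
#' @param tumor_labels Integer tumor label matrix.
#' @param pixel_size Microns per pixel (for the µm² columns).
#' @return One-row tibble of class `ktrq_burden`: `lung_area_px`,
#'   `lung_area_um2`, `tumor_area_px`, `tumor_area_um2`, `tumor_count`,
#'   `burden_percent`.
#' @export
metastatic_burden <- function(tissue_mask, tumor_labels, pixel_size = 0.32) {
  stopifnot(identical(dim(tissue_mask), dim(tumor_labels)))
  lung <- sum(tissue_mask)
  if (lung == 0) stop("lung area is zero; cannot compute burden", call. = FALSE)
  tum <- sum(tumor_labels > 0)
  out <- tibble::tibble(
    lung_area_px = as.integer(lung),
    lung_area_um2 = lung * pixel_size^2,
    tumor_area_px = as.integer(tum),
    tumor_area_um2 = tum * pixel_size^2,
    tumor_count = length(setdiff(unique(as.vector(tumor_labels)), 0L)),
    burden_percent = 100 * tum / lung
  )
  class(out) <- c("ktrq_burden", class(out))
  out
}

#' 90th-percentile marker intensity within the tumor mask
#'
#' The 90th percentile (linear interpolation between order statistics,
#' `quantile(type = 7)`) of marker pixels inside the tumor mask. Intensity
#' outside the mask never affects the result.
#'
#' @param marker Single-channel intensity matrix.
#' @param tumor_labels Integer tumor label matrix.
#' @param scope `"whole_mask"` (one value over the pooled mask, default)
#'   or `"per_tumor"` (a tibble with one value per label).
#' @return A single numeric (`whole_mask`) or a tibble `tumor_id`, `p90`
#'   (`per_tumor`). An empty mask yields `NA` / an empty tibble.
#' @export
marker_p90 <- function(marker, tumor_labels,
                       scope = c("whole_mask", "per_tumor")) {
  scope <- match.arg(scope)
  stopifnot(identical(dim(marker), dim(tumor_labels)))
  if (scope == "whole_mask") {
    px <- marker[tumor_labels > 0]
    if (!length(px)) return(NA_real_)
    return(stats::quantile(px, 0.9, type = 7, names = FALSE))
  }
  labs <- setdiff(sort(unique(as.vector(tumor_labels))), 0L)
  tibble::tibble(
    tumor_id = labs,
    p90 = vapply(labs, function(l) {
      stats::quantile(marker[tumor_labels == l], 0.9, type = 7, names = FALSE)
    }, numeric(1))
  )
}

#' Per-cell compartment signal for fixed-cell immunostains
#'
#' Measures each cell's mean marker intensity in the named compartment
#' (nuclear mask or cytoplasmic ring, e.g. nuclear for Fra-1, cytoplasmic
#' for MCL1 given its localization pattern) and normalizes to the
#' control-condition mean when supplied.
#'
#' @param image Marker intensity matrix.
#' @param nuclei,rings Label matrices from [segment_nuclei()] /
#'   [make_cyto_rings()].
#' @param compartment `"nuclear"` or `"cytoplasmic"`.
#' @param control_mean Optional positive control-condition mean used for
#'   normalization; `NULL` returns raw means with `normalized = NA`.
#' @return Tibble `cell_id`, `raw_mean`, `normalized`.
#' @export
icc_compartment_signal <- function(image, nuclei, rings,
                                   compartment = c("nuclear", "cytoplasmic"),
                                   control_mean = NULL) {
  compartment <- match.arg(compartment)
  mask <- if (compartment == "nuclear") nuclei else rings
  stopifnot(identical(dim(image), dim(mask)))
  if (!is.null(control_mean) && control_mean <= 0) {
    stop("`control_mean` must be > 0", call. = FALSE)
  }
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  raw <- vapply(labs, function(l) mean(image[mask == l]), numeric(1))
  tibble::tibble(
    cell_id = labs,
    raw_mean = raw,
    normalized = if (is.null(control_mean)) NA_real_ else raw / control_mean
  )
}

#' Bland-Altman agreement between manual and automated measurements
#'
#' Differences are `automated - manual`; the bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 * SD` (SD with `n - 1`
#' denominator).
#'
#' @param manual,automated Equal-length paired numeric vectors, `n >= 2`.
#' @return One-row tibble of class `ktrq_ba`: `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`. Supports [generics::tidy()] and
#'   [ggplot2::autoplot()].
#' @export
bland_altman <- function(manual, automated) {
  if (length(manual) != length(automated)) {
    stop("`manual` and `automated` must have equal length", call. = FALSE)
  }
  if (length(manual) < 2) stop("Bland-Altman needs n >= 2 pairs", call. = FALSE)
  d <- automated - manual
  bias <- mean(d)
  s <- stats::sd(d)
  out <- tibble::tibble(
    n = length(d), bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s
  )
  attr(out, "pairs") <- tibble::tibble(
    mean = (manual + automated) / 2, difference = d)
  class(out) <- c("ktrq_ba", class(out))
  out
}

#' @method tidy ktrq_ba
#' @export
tidy.ktrq_ba <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_low", "loa_high"),
    estimate = c(x$bias, x$loa_low, x$loa_high)
  )
}

#' Bland-Altman plot
#' @param object A `ktrq_ba` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ktrq_ba
#' @export
autoplot.ktrq_ba <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "mean of methods", y = "automated - manual",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
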