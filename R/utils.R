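# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_num <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s]", name, min, max), call. = FALSE)
  }
  invisible(x)
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Otsu threshold on an arbitrary-scale numeric matrix. Returns the threshold
# on the original intensity scale; a constant image yields +Inf (no
# foreground) rather than an error.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) return(Inf)
  xn <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

# Paint a filled disk into a matrix (in place semantics via return value).
# Pixel (i, j) belongs to the disk when its center is within `radius` of
# (cy, cx); centers are continuous, pixels are 1-based integer coordinates.
add_disk <- function(mat, cy, cx, radius, value, mode = c("set", "add")) {
  mode <- match.arg(mode)
  nr <- nrow(mat); nc <- ncol(mat)
  i0 <- max(1L, floor(cy - radius)); i1 <- min(nr, ceiling(cy + radius))
  j0 <- max(1L, floor(cx - radius)); j1 <- min(nc, ceiling(cx + radius))
  if (i0 > i1 || j0 > j1) return(mat)
  ii <- i0:i1; jj <- j0:j1
  inside <- outer((ii - cy)^2, (jj - cx)^2, `+`) <= radius^2
  block <- mat[ii, jj, drop = FALSE]
  if (mode == "set") block[inside] <- value else block[inside] <- block[inside] + value
  mat[ii, jj] <- block
  mat
}

disk_pixels <- function(nr, nc, cy, cx, radius) {
  i0 <- max(1L, floor(cy - radius)); i1 <- min(nr, ceiling(cy + radius))
  j0 <- max(1L, floor(cx - radius)); j1 <- min(nc, ceiling(cx + radius))
  ii <- rep(i0:i1, times = j1 - j0 + 1L)
  jj <- rep(j0:j1, each = i1 - i0 + 1L)
  keep <- (ii - cy)^2 + (jj - cx)^2 <= radius^2
  cbind(row = ii[keep], col = jj[keep])
}

# 8-connected labeling built on EBImage's 4-connected bwlabel: label with
# 4-connectivity, then merge any pair of distinct labels that touch
# diagonally (union-find over the diagonal adjacencies).
label_8connected <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(binary * 1))
  k <- max(lab)
  if (k < 2) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

# Drop labeled objects below a pixel-area cutoff and relabel 1..K.
filter_min_area <- function(labels, min_area) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- relab[labels[labels > 0]]
  storage.mode(out) <- "integer"
  out
}

# Centroids of a label image as a tibble (label, y, x, area).
label_centroids <- function(labels) {
  k <- max(labels)
  if (k == 0) {
    return(tibble::tibble(label = integer(), y = double(), x = double(),
                          area = integer()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  tibble::tibble(
    label = sort(unique(lab)),
    y = as.numeric(tapply(rr, lab, mean)),
    x = as.numeric(tapply(cc, lab, mean)),
    area = as.integer(tapply(lab, lab, length))
  )
}

# Trapezoidal integral of y over x (x sorted ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Wilson 95% score interval for a binomial proportion.
wilson_ci <- function(successes, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}
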