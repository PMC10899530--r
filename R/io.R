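# Reading and writing the package's standard on-disk formats.

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Frames are written in acquisition order, one page per frame, as
#' unsigned 16-bit samples.
#'
#' @param stack Numeric array `[rows, cols, frames]` (or a single matrix)
#'   on the 16-bit intensity scale.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  cap <- 2^16 - 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    pmin(pmax(stack[, , f], 0), cap) / cap
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @return Numeric array `[rows, cols, frames]` on the 16-bit scale.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  cap <- 2^16 - 1
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * cap
  arr
}

#' Write an integer label mask as a 16-bit TIFF
#'
#' @param mask Integer label matrix (labels up to 65535).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(mask, path) {
  write_stack_tiff(array(as.numeric(mask), dim = c(dim(mask), 1)), path)
}

#' Write or read a trace table as tidy CSV
#'
#' The trace table is the package's interchange format: one row per cell
#' per frame with columns `cell_id`, `frame`, `time_min`, `activity`,
#' `valid`, `condition`, `dose_ng_ml`.
#'
#' @param traces Trace tibble.
#' @param path CSV file path.
#' @return `path` (write) or the trace tibble (read).
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$valid <- as.logical(df$valid)
  tibble::as_tibble(df)
}

#' Read or write a pipeline configuration as YAML
#'
#' Configurations are plain named lists of scalars and lists; they
#' round-trip through the YAML file losslessly.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return The configuration list (read) or `path` (write).
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
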