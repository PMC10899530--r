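# Reporting statistics: group summaries, fold changes, organoid survival,
# Benjamini-Hochberg adjustment.

#' Summarize a measurement by group (mean and SEM)
#'
#' @param data A data frame.
#' @param values Column of measurements (tidy-eval).
#' @param by Grouping column (tidy-eval).
#' @return Tibble `group`, `n`, `mean`, `sem` with `sem = sd / sqrt(n)`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4), y = c(1:4, 3:6))
#' group_summary(df, y, g)
#' @export
group_summary <- function(data, values, by) {
  data |>
    dplyr::group_by(group = {{ by }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ values }}),
      sem = stats::sd({{ values }}) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Fold change between experimental and control means
#'
#' Fold increase divides the experimental mean by the control mean; fold
#' decrease divides the control mean by the experimental mean, so for the
#' same pair of groups `fold increase x fold decrease = 1`.
#'
#' @param experimental,control Positive scalar means, or one-row
#'   [group_summary()] tibbles (their `mean` column is used).
#' @param direction `"increase"` or `"decrease"`.
#' @return Scalar fold change.
#' @export
fold_change <- function(experimental, control,
                        direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  pick <- function(x) if (is.data.frame(x)) x$mean[1] else x
  e <- pick(experimental); c0 <- pick(control)
  if (!is.finite(e) || !is.finite(c0) || e <= 0 || c0 <= 0) {
    stop("group means must be positive", call. = FALSE)
  }
  if (direction == "increase") e / c0 else c0 / e
}

#' Percent survival of metastatic organoids
#'
#' The post-treatment organoid count divided by the pre-treatment count,
#' times 100.
#'
#' @param pre_count Pre-treatment count (>= 1).
#' @param post_count Post-treatment count (>= 0).
#' @return Percent survival.
#' @export
percent_survival <- function(pre_count, post_count) {
  if (any(pre_count < 1)) stop("`pre_count` must be >= 1", call. = FALSE)
  if (any(post_count < 0)) stop("`post_count` must be >= 0", call. = FALSE)
  100 * post_count / pre_count
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The original step-up FDR procedure: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1 and returned in
#' the input order. Adjusting already-adjusted values leaves them
#' unchanged.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
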