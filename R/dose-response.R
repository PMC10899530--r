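# Logistic (Hill) dose-response fit to per-dose responder fractions.

#' Fit a Hill dose-response curve to responder fractions
#'
#' Least-squares fit of \eqn{p(dose) = p_{max} / (1 + (EC_{50}/dose)^h)}
#' to observed responder fractions at three or more doses, via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with box constraints
#' (`0 <= pmax <= 1`, `ec50 > 0`, `0.1 <= hill <= 10`). Non-monotone data
#' are fitted anyway but flagged; if the optimizer cannot make progress
#' (e.g. identical fractions at all doses) a degenerate fit is returned
#' with `pmax` set to the mean fraction and `ec50` unidentifiable (`NA`),
#' flagged accordingly.
#'
#' @param data Tibble with columns `dose` (> 0, ng/mL) and `fraction`
#'   (in \[0, 1\]); an optional `n` column (cells per dose) adds Wilson
#'   CIs to the stored data.
#' @return An object of class `ktrq_drc` with elements `coef` (named
#'   vector `pmax`, `ec50`, `hill`), `data` (with fitted values and
#'   residuals), `flags` (`non_monotone`, `degenerate`), and `rss`.
#'   Supports [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(dose = c(1, 3, 10, 30, 100),
#'                     fraction = 0.8 / (1 + 10 / dose))
#' fit <- fit_dose_response(d)
#' generics::tidy(fit)
#' @export
fit_dose_response <- function(data) {
  require_columns(data, c("dose", "fraction"), "`data`")
  if (any(data$dose <= 0)) stop("all doses must be > 0", call. = FALSE)
  if (any(data$fraction < 0 | data$fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(data$dose)) < 3) {
    stop("at least 3 distinct doses are required", call. = FALSE)
  }
  d <- dplyr::arrange(tibble::as_tibble(data), .data$dose)
  non_monotone <- is.unsorted(cummax(d$fraction) - 1e-9) ||
    suppressWarnings(stats::cor(d$dose, d$fraction, method = "spearman")) < 0
  non_monotone <- isTRUE(non_monotone)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction ~ pmax / (1 + (ec50 / dose)^hill),
      data = d,
      start = list(pmax = min(max(d$fraction), 1), ec50 = stats::median(d$dose), hill = 1),
      lower = c(pmax = 0, ec50 = 1e-9, hill = 0.1),
      upper = c(pmax = 1, ec50 = 1e9, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  degenerate <- is.null(fit) || stats::sd(d$fraction) < 1e-12
  if (degenerate) {
    cf <- c(pmax = mean(d$fraction), ec50 = NA_real_, hill = NA_real_)
    d$fitted <- mean(d$fraction)
  } else {
    cf <- stats::coef(fit)[c("pmax", "ec50", "hill")]
    d$fitted <- as.numeric(stats::predict(fit))
  }
  d$residual <- d$fraction - d$fitted
  if ("n" %in% names(d)) {
    ci <- t(vapply(seq_len(nrow(d)),
                   function(i) wilson_ci(round(d$fraction[i] * d$n[i]), d$n[i]),
                   numeric(2)))
    d$ci_low <- ci[, 1]; d$ci_high <- ci[, 2]
  }
  structure(
    list(coef = cf, data = d, rss = sum(d$residual^2),
         flags = list(non_monotone = non_monotone, degenerate = degenerate)),
    class = "ktrq_drc"
  )
}

#' @export
print.ktrq_drc <- function(x, ...) {
  cat("<ktrq_drc> Hill dose-response fit\n")
  cat(sprintf("  pmax = %.3f, EC50 = %.3g ng/mL, hill = %.3g (RSS %.3g)\n",
              x$coef["pmax"], x$coef["ec50"], x$coef["hill"], x$rss))
  if (x$flags$degenerate) cat("  [degenerate: EC50 unidentifiable]\n")
  if (x$flags$non_monotone) cat("  [warning: non-monotone fractions]\n")
  invisible(x)
}

#' @export
predict.ktrq_drc <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  cf <- object$coef
  if (object$flags$degenerate) return(rep(cf[["pmax"]], length(dose)))
  cf[["pmax"]] / (1 + (cf[["ec50"]] / dose)^cf[["hill"]])
}

#' Tidy a dose-response fit
#' @param x A `ktrq_drc` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy ktrq_drc
#' @export
tidy.ktrq_drc <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = as.numeric(x$coef))
}

#' One-row model summary of a dose-response fit
#' @param x A `ktrq_drc` object.
#' @param ... Unused.
#' @return One-row tibble: `n_doses`, `rss`, `degenerate`, `non_monotone`.
#' @method glance ktrq_drc
#' @export
glance.ktrq_drc <- function(x, ...) {
  tibble::tibble(n_doses = nrow(x$data), rss = x$rss,
                 degenerate = x$flags$degenerate,
                 non_monotone = x$flags$non_monotone)
}

#' Plot a dose-response fit
#' @param object A `ktrq_drc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ktrq_drc
#' @export
autoplot.ktrq_drc <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(dose = exp(seq(log(min(d$dose)), log(max(d$dose)),
                                        length.out = 100)))
  grid$fraction <- predict(object, grid)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (ng/mL)", y = "responder fraction",
                  title = "Hill dose-response fit") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(d))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.05)
  }
  p
}
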