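#' Unit-peak response shape for a ligand class
#'
#' Evaluates the noiseless response kinetics used by the trace simulator.
#' Time is minutes since treatment; the shape is 0 for `t < 0`. Class 1 is a
#' transient pulse peaking at `tau_rise` with unit height, class 2 rises
#' with `tau_rise` and wanes with `tau_decay`, class 3 saturates at 1, and
#' class 0 is identically 0.
#'
#' @param t Minutes since treatment (vectorized).
#' @param response_class 0, 1, 2 or 3.
#' @param tau_rise,tau_decay Time constants, minutes.
#' @return Numeric vector, same length as `t`.
#' @export
response_shape <- function(t, response_class, tau_rise, tau_decay) {
  f <- switch(as.character(response_class),
    "0" = rep(0, length(t)),
    "1" = (t / tau_rise) * exp(1 - t / tau_rise),
    "2" = exp(-t / tau_decay) * (1 - exp(-t / tau_rise)),
    "3" = 1 - exp(-t / tau_rise),
    stop("`response_class` must be 0, 1, 2 or 3", call. = FALSE)
  )
  f[t < 0] <- 0
  f
}

# Noiseless activity trace for one cell on the schedule grid.
noiseless_trace <- function(times, is_responder, amplitude, params, schedule) {
  p <- params
  act <- rep(p$baseline_level, length(times))
  if (is_responder && p$response_class != 0L) {
    post <- times >= schedule$treatment_time
    act[post] <- p$baseline_level + amplitude *
      response_shape(times[post] - schedule$treatment_time,
                     p$response_class, p$tau_rise, p$tau_decay)
  }
  meki <- times > schedule$meki_time
  if (any(meki)) {
    v_at_meki <- act[max(which(times <= schedule$meki_time))]
    act[meki] <- p$meki_floor +
      (v_at_meki - p$meki_floor) * exp(-(times[meki] - schedule$meki_time) / p$meki_tau)
  }
  act
}

# Responder probability implied by the simulator's dose-response model.
responder_probability <- function(params) {
  if (params$response_class == 0L) return(0)
  params$responder_pmax /
    (1 + (params$responder_ec50 / params$dose)^params$responder_hill)
}

#' Simulate an ensemble of single-cell ERK activity traces
#'
#' Draws `n_cells` cells on the schedule's frame grid. Each cell is a
#' responder with probability \eqn{p_{max}/(1+(EC_{50}/dose)^h)} (0 for a
#' class-0 non-inducer); responders follow
#' `baseline + A * f_class(t - treatment)` with a per-cell gamma amplitude,
#' all cells relax exponentially to the MEKi floor after inhibitor
#' addition, and additive Gaussian noise is applied per frame (iid, or
#' AR(1) when `noise_ar1 > 0`).
#'
#' @param params A [sim_params()] object.
#' @param schedule An [acquisition_schedule()].
#' @param seed Optional integer seed; with a fixed seed the output is
#'   bit-reproducible.
#' @return A list of class `ktrq_trace_sim` with elements
#' \describe{
#'   \item{traces}{tibble with columns `cell_id`, `frame`, `time_min`,
#'     `activity`, `valid`, `condition`, `dose_ng_ml` (the observed,
#'     noisy ensemble).}
#'   \item{truth}{a list: `cells` (per-cell `is_responder`, `amplitude`,
#'     `response_class`, `p_respond`) and `traces` (the noiseless
#'     activities on the same grid).}
#' }
#' @examples
#' sched <- acquisition_schedule()
#' sim <- simulate_trace_ensemble(sim_params(n_cells = 5), sched, seed = 1)
#' head(sim$traces)
#' @export
simulate_trace_ensemble <- function(params, schedule, seed = NULL) {
  stopifnot(inherits(params, "ktrq_sim_params"), inherits(schedule, "ktrq_schedule"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- p$n_cells
  times <- schedule$times
  nf <- length(times)

  p_resp <- responder_probability(p)
  is_resp <- stats::runif(n) < p_resp
  if (p$amplitude_cv > 0) {
    shape <- 1 / p$amplitude_cv^2
    amp <- stats::rgamma(n, shape = shape, scale = p$amplitude_mean / shape)
  } else {
    amp <- rep(p$amplitude_mean, n)
  }
  amp[!is_resp] <- 0

  clean <- vapply(seq_len(n), function(i) {
    noiseless_trace(times, is_resp[i], amp[i], p, schedule)
  }, numeric(nf))                      # nf x n

  if (p$noise_sigma > 0) {
    if (p$noise_ar1 > 0) {
      phi <- p$noise_ar1
      innov <- matrix(stats::rnorm(nf * n, sd = p$noise_sigma), nf, n)
      eps <- innov
      eps[1, ] <- innov[1, ]
      scl <- sqrt(1 - phi^2)
      for (f in 2:nf) eps[f, ] <- phi * eps[f - 1, ] + scl * innov[f, ]
    } else {
      eps <- matrix(stats::rnorm(nf * n, sd = p$noise_sigma), nf, n)
    }
    noisy <- clean + eps
  } else {
    noisy <- clean
  }

  traces <- tibble::tibble(
    cell_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf), times = n),
    time_min = rep(times, times = n),
    activity = as.vector(noisy),
    valid = TRUE,
    condition = p$condition,
    dose_ng_ml = p$dose
  )
  truth <- list(
    cells = tibble::tibble(
      cell_id = seq_len(n),
      is_responder = is_resp,
      amplitude = amp,
      response_class = p$response_class,
      p_respond = p_resp
    ),
    traces = tibble::tibble(
      cell_id = rep(seq_len(n), each = nf),
      frame = rep(seq_len(nf), times = n),
      time_min = rep(times, times = n),
      activity = as.vector(clean)
    )
  )
  structure(list(traces = traces, truth = truth, params = p, schedule = schedule),
            class = "ktrq_trace_sim")
}

#' @export
print.ktrq_trace_sim <- function(x, ...) {
  cat(sprintf("<ktrq_trace_sim> %d cells x %d frames (class %d, dose %g ng/mL)\n",
              x$params$n_cells, x$schedule$n_frames,
              x$params$response_class, x$params$dose))
  cat(sprintf("  true responders: %d/%d\n",
              sum(x$truth$cells$is_responder), x$params$n_cells))
  invisible(x)
}
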