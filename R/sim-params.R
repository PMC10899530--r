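#' Parameters for the single-cell ERK trace simulator
#'
#' Defines the generative model for an ensemble of single-cell ERK activity
#' traces in KTR ratio units. Each cell is a responder with probability
#' \eqn{p(dose) = p_{max} / (1 + (EC_{50}/dose)^{h})}. A responder's
#' noiseless activity is `baseline_level + A * f_class(t - treatment)`,
#' where `A` is a per-cell gamma-distributed amplitude and `f_class` is one
#' of three unit-peak response shapes:
#' \itemize{
#'   \item class 1 (transient): \eqn{f_1(t) = (t/\tau_r) e^{1 - t/\tau_r}}
#'   \item class 2 (waning): \eqn{f_2(t) = e^{-t/\tau_d} (1 - e^{-t/\tau_r})}
#'   \item class 3 (sustained): \eqn{f_3(t) = 1 - e^{-t/\tau_r}}
#'   \item class 0 (non-inducer): no response; responder probability forced to 0.
#' }
#' After MEKi addition every trace relaxes exponentially (time constant
#' `meki_tau`) to `meki_floor`. Per-frame noise is additive Gaussian, iid by
#' default or AR(1) when `noise_ar1 > 0`.
#'
#' @param response_class 0 (non-inducer), 1 (transient), 2 (waning) or
#'   3 (sustained).
#' @param baseline_level Pre-treatment activity in ratio units (default 1).
#' @param amplitude_mean,amplitude_cv Mean and coefficient of variation of
#'   the per-cell response amplitude (gamma distributed; `amplitude_cv = 0`
#'   gives a fixed amplitude).
#' @param tau_rise,tau_decay Rise and decay time constants, minutes.
#'   `tau_decay` is ignored by the class-3 plateau.
#' @param responder_pmax,responder_ec50,responder_hill Maximal responder
#'   probability, half-maximal dose (ng/mL) and Hill coefficient of the
#'   dose-response curve.
#' @param noise_sigma Per-frame additive Gaussian noise SD (ratio units).
#' @param noise_ar1 AR(1) coefficient in \[0, 1); 0 means iid noise.
#' @param meki_floor ERK activity floor under MEKi, must be below
#'   `baseline_level`.
#' @param meki_tau Relaxation time constant after MEKi addition, minutes.
#' @param n_cells Number of cells in the ensemble.
#' @param dose Ligand concentration in ng/mL (must be > 0).
#' @param condition Optional condition label carried into the trace table.
#' @return A list of class `ktrq_sim_params`.
#' @seealso [simulate_trace_ensemble()], [simulate_timelapse()]
#' @export
sim_params <- function(response_class = 3,
                       baseline_level = 1,
                       amplitude_mean = 1.5,
                       amplitude_cv = 0.2,
                       tau_rise = 12,
                       tau_decay = 300,
                       responder_pmax = 0.8,
                       responder_ec50 = 10,
                       responder_hill = 1,
                       noise_sigma = 0.05,
                       noise_ar1 = 0,
                       meki_floor = 0.6,
                       meki_tau = 12,
                       n_cells = 100,
                       dose = 100,
                       condition = NULL) {
  if (!response_class %in% 0:3) {
    stop("`response_class` must be 0, 1, 2 or 3", call. = FALSE)
  }
  assert_scalar_num(baseline_level, "baseline_level", positive = TRUE)
  assert_scalar_num(amplitude_mean, "amplitude_mean", positive = TRUE)
  assert_scalar_num(amplitude_cv, "amplitude_cv", min = 0)
  assert_scalar_num(tau_rise, "tau_rise", positive = TRUE)
  assert_scalar_num(tau_decay, "tau_decay", positive = TRUE)
  assert_scalar_num(responder_pmax, "responder_pmax", min = 0, max = 1)
  assert_scalar_num(responder_ec50, "responder_ec50", positive = TRUE)
  assert_scalar_num(responder_hill, "responder_hill", positive = TRUE)
  assert_scalar_num(noise_sigma, "noise_sigma", min = 0)
  assert_scalar_num(noise_ar1, "noise_ar1", min = 0, max = 0.999)
  assert_scalar_num(meki_floor, "meki_floor", positive = TRUE)
  assert_scalar_num(meki_tau, "meki_tau", positive = TRUE)
  assert_scalar_num(dose, "dose", positive = TRUE)
  if (meki_floor >= baseline_level) {
    stop("`meki_floor` must be below `baseline_level`", call. = FALSE)
  }
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  structure(
    list(
      response_class = as.integer(response_class),
      baseline_level = baseline_level,
      amplitude_mean = amplitude_mean,
      amplitude_cv = amplitude_cv,
      tau_rise = tau_rise,
      tau_decay = tau_decay,
      responder_pmax = responder_pmax,
      responder_ec50 = responder_ec50,
      responder_hill = responder_hill,
      noise_sigma = noise_sigma,
      noise_ar1 = noise_ar1,
      meki_floor = meki_floor,
      meki_tau = meki_tau,
      n_cells = as.integer(n_cells),
      dose = dose,
      condition = condition %||% paste0("class", response_class)
    ),
    class = "ktrq_sim_params"
  )
}

#' Parameters for the synthetic tissue-section generator
#'
#' Describes a three-channel fluorescent lung section: a DAPI-positive lung
#' region (an ellipse occupying `lung_fill_fraction` of the field, or the
#' whole field when the fraction is 1), vimentin-positive circular tumor
#' blobs placed inside the lung at a minimum separation, and a marker
#' channel (e.g. Fra-1 or MCL1) whose intensity is drawn per tumor.
#'
#' @param image_shape Image height and width in pixels.
#' @param pixel_size Microns per pixel (default 0.32, a 20x whole-section
#'   scan at 16-bit depth).
#' @param n_tumors Number of tumor blobs (>= 0).
#' @param tumor_radius_range Min and max tumor radius, pixels.
#' @param min_tumor_separation Minimum edge-to-edge gap between tumors,
#'   pixels.
#' @param lung_fill_fraction Fraction of the field occupied by lung, in
#'   (0, 1].
#' @param marker_mean,marker_sd Per-tumor marker intensity distribution
#'   (normal, truncated at 0 and the bit-depth ceiling).
#' @param dapi_level,vimentin_level,background Channel intensity levels
#'   (16-bit scale).
#' @param pixel_noise Additive Gaussian pixel noise SD.
#' @return A list of class `ktrq_tissue_params`.
#' @seealso [simulate_tissue_section()]
#' @export
tissue_sim_params <- function(image_shape = c(400, 400),
                              pixel_size = 0.32,
                              n_tumors = 10,
                              tumor_radius_range = c(6, 14),
                              min_tumor_separation = 8,
                              lung_fill_fraction = 0.6,
                              marker_mean = 5000,
                              marker_sd = 1500,
                              dapi_level = 8000,
                              vimentin_level = 12000,
                              background = 200,
                              pixel_noise = 50) {
  if (length(image_shape) != 2 || any(image_shape < 32)) {
    stop("`image_shape` must be two dimensions >= 32 px", call. = FALSE)
  }
  assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (n_tumors < 0) stop("`n_tumors` must be >= 0", call. = FALSE)
  if (length(tumor_radius_range) != 2 || any(tumor_radius_range <= 0) ||
      diff(tumor_radius_range) < 0) {
    stop("`tumor_radius_range` must be an increasing positive pair", call. = FALSE)
  }
  assert_scalar_num(min_tumor_separation, "min_tumor_separation", min = 0)
  assert_scalar_num(lung_fill_fraction, "lung_fill_fraction", min = 1e-6, max = 1)
  structure(
    list(
      image_shape = as.integer(image_shape),
      pixel_size = pixel_size,
      n_tumors = as.integer(n_tumors),
      tumor_radius_range = tumor_radius_range,
      min_tumor_separation = min_tumor_separation,
      lung_fill_fraction = lung_fill_fraction,
      marker_mean = marker_mean,
      marker_sd = marker_sd,
      dapi_level = dapi_level,
      vimentin_level = vimentin_level,
      background = background,
      pixel_noise = pixel_noise,
      bit_depth = 16L
    ),
    class = "ktrq_tissue_params"
  )
}

#' Rendering options for the synthetic time-lapse generator
#'
#' @param image_size Field height and width, pixels.
#' @param nucleus_radius,cell_radius Nucleus and whole-cell radius, pixels.
#' @param min_spacing Minimum center-to-center distance between cells at
#'   placement, pixels. Must exceed `2 * cell_radius`.
#' @param drift_step Maximum per-frame displacement per axis, pixels.
#' @param drift_bound Half-width of the reflecting box each nucleus walks
#'   in, centred on its initial position. The default,
#'   `min((min_spacing - 2 * cell_radius) / 2 - 1, min_spacing / 3)`,
#'   guarantees that cells placed at `min_spacing` can never overlap and
#'   that ground-truth tracks stay unambiguous.
#' @param background Camera background level.
#' @param h2b_intensity Nuclear H2B fluorescence above background.
#' @param erktr_nuclear ERKTR nuclear fluorescence above background; the
#'   cytoplasm is rendered at `erktr_nuclear * activity` so that the
#'   background-corrected cytoplasm/nucleus ratio equals the cell's true
#'   activity.
#' @param photon_noise Additive Gaussian pixel noise SD (0 = noiseless).
#' @return A list of class `ktrq_render_opts`.
#' @export
render_opts <- function(image_size = c(220, 220),
                        nucleus_radius = 6,
                        cell_radius = 11,
                        min_spacing = 36,
                        drift_step = 2,
                        drift_bound = NULL,
                        background = 100,
                        h2b_intensity = 3000,
                        erktr_nuclear = 1200,
                        photon_noise = 0) {
  if (length(image_size) != 2 || any(image_size < 32)) {
    stop("`image_size` must be two dimensions >= 32 px", call. = FALSE)
  }
  assert_scalar_num(nucleus_radius, "nucleus_radius", positive = TRUE)
  assert_scalar_num(cell_radius, "cell_radius", positive = TRUE)
  if (cell_radius <= nucleus_radius) {
    stop("`cell_radius` must exceed `nucleus_radius`", call. = FALSE)
  }
  if (min_spacing <= 2 * cell_radius) {
    stop("`min_spacing` must exceed the cell diameter", call. = FALSE)
  }
  structure(
    list(
      image_size = as.integer(image_size),
      nucleus_radius = nucleus_radius,
      cell_radius = cell_radius,
      min_spacing = min_spacing,
      drift_step = drift_step,
      drift_bound = drift_bound %||%
        max(1, min((min_spacing - 2 * cell_radius) / 2 - 1, min_spacing / 3)),
      background = background,
      h2b_intensity = h2b_intensity,
      erktr_nuclear = erktr_nuclear,
      photon_noise = photon_noise,
      bit_depth = 16L
    ),
    class = "ktrq_render_opts"
  )
}
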