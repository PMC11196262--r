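#' Protocol stage labels
#'
#' The five measurement stages, in protocol order: 60-degree upper-body
#' elevation (`UBE1`), supine (`SUP1`), upper-body elevation again
#' (`UBE2`), supine again (`SUP2`), and supine after the 500-700 mL saline
#' fluid challenge (`SUP_FLUID`). The repeated UBE/supine pair supports
#' the repeat-consistency check; position, not time, drives the underlying
#' physiology, so the noiseless truth is identical for `UBE1`/`UBE2` and
#' for `SUP1`/`SUP2`.
#'
#' @return Character vector of the five ordered stage labels.
#' @export
stage_labels <- function() c("UBE1", "SUP1", "UBE2", "SUP2", "SUP_FLUID")

stage_position <- function(stage) {
  switch(stage,
         UBE1 = "ube", UBE2 = "ube",
         SUP1 = "supine", SUP2 = "supine",
         SUP_FLUID = "supine_fluid",
         stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
}

#' Beat-level measurement noise parameters
#'
#' The noise model has three components, mirroring how spontaneous
#' breathing and probe handling corrupt Doppler VTI tracings:
#' a smooth respiratory modulation that dips the VTI by
#' `resp_modulation_frac` at peak inspiration and vanishes at
#' end-expiration; sporadic probe-misalignment events that multiply a beat
#' by a factor drawn from `misalignment_frac_range` — strictly downward,
#' since a drifted Doppler gate can only under-read the true envelope; and
#' multiplicative Gaussian beat-to-beat jitter with coefficient of
#' variation `jitter_cv`.
#'
#' @param resp_modulation_frac Fractional VTI dip at peak inspiration
#'   (default 0.15).
#' @param misalignment_prob Per-beat probability of a misalignment
#'   deflation (default 0.04).
#' @param misalignment_frac_range Multiplicative deflation interval,
#'   both endpoints in (0, 1) (default 0.78-0.95).
#' @param jitter_cv Coefficient of variation of the per-beat
#'   multiplicative Gaussian jitter (default 0.012).
#' @return Named list of class `noise_params`.
#' @export
noise_params <- function(resp_modulation_frac = 0.15,
                         misalignment_prob = 0.04,
                         misalignment_frac_range = c(0.78, 0.95),
                         jitter_cv = 0.012) {
  bad <- character(0)
  if (resp_modulation_frac < 0 || resp_modulation_frac >= 1)
    bad <- c(bad, "resp_modulation_frac")
  if (misalignment_prob < 0 || misalignment_prob >= 1)
    bad <- c(bad, "misalignment_prob")
  if (length(misalignment_frac_range) != 2 ||
      any(misalignment_frac_range <= 0) || any(misalignment_frac_range >= 1) ||
      misalignment_frac_range[1] > misalignment_frac_range[2])
    bad <- c(bad, "misalignment_frac_range")
  if (jitter_cv < 0 || jitter_cv >= 1) bad <- c(bad, "jitter_cv")
  if (length(bad))
    stop("invalid noise parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(resp_modulation_frac = resp_modulation_frac,
                 misalignment_prob = misalignment_prob,
                 misalignment_frac_range = misalignment_frac_range,
                 jitter_cv = jitter_cv),
            class = "noise_params")
}

#' Saturating Frank-Starling preload-to-VTI curve
#'
#' The generator's ground-truth physiology: stroke volume (proxied by the
#' LVOT VTI) rises with preload along a strictly increasing, concave,
#' saturating curve
#' \deqn{VTI(p) = plateau \cdot (1 - e^{-p / scale}).}
#' A hypovolemic subject sits on the steep limb, so a given preload shift
#' (posture change or fluid bolus) produces a large VTI change; a replete
#' subject sits on the flat limb and barely responds. Exponential
#' saturation is the simplest two-parameter curve with these properties.
#'
#' @param preload Preload, in arbitrary preload units (> 0).
#' @param fs List with `vti_plateau_cm` (asymptotic VTI, cm) and
#'   `preload_scale` (saturation constant, preload units).
#' @return VTI in cm. Vectorised over `preload`.
#' @export
frank_starling_vti <- function(preload, fs) {
  check_positive(preload, "preload")
  fs$vti_plateau_cm * (1 - exp(-preload / fs$preload_scale))
}

#' Preload at a protocol stage
#'
#' Maps the protocol to the preload axis: supine preload is the euvolemic
#' baseline minus the subject's true volume deficit; 60-degree upper-body
#' elevation subtracts a positional shift `delta_position` (venous pooling
#' away from the thorax); the fluid stage adds `bolus_ml * preload_per_ml`
#' to the supine preload. The two UBE stages and the two supine stages map
#' to identical preloads.
#'
#' @param stage One of [stage_labels()].
#' @param true_deficit True hypovolemic deficit, preload units (>= 0).
#' @param fs Frank-Starling parameter list with `baseline_preload`.
#' @param bolus_ml Fluid bolus volume, mL (used only for `SUP_FLUID`).
#' @param delta_position Preload shift induced by 60-degree elevation
#'   (default 0.31 preload units).
#' @param preload_per_ml Preload gained per mL of saline
#'   (default 5.1e-4).
#' @param floor Positive lower bound below which the subject is flagged
#'   degenerate (default 0.05).
#' @return Preload in preload units.
#' @export
stage_preload <- function(stage, true_deficit, fs, bolus_ml = 600,
                          delta_position = 0.31, preload_per_ml = 5.1e-4,
                          floor = 0.05) {
  stage <- match.arg(stage, stage_labels())
  supine <- fs$baseline_preload - true_deficit
  p <- switch(stage_position(stage),
              ube = supine - delta_position,
              supine = supine,
              supine_fluid = supine + bolus_ml * preload_per_ml)
  if (!is.finite(p) || p <= floor)
    stop(sprintf(
      "degenerate subject: preload %.3f at stage %s is at or below the floor %.3f",
      p, stage, floor), call. = FALSE)
  p
}

#' Simulate a beat-level Doppler recording
#'
#' Generates one cardiac beat per heart period over `duration_s` seconds.
#' Each beat's VTI is
#' `true_vti * (1 - m * s(phase)) * d * (1 + eps)`, where `s` is a smooth
#' bump (`sin^2(pi * phase)`) peaking mid-inspiration and vanishing at
#' end-expiration, `d = 1` except for misalignment events where `d` is
#' drawn from the deflation interval, and `eps` is Gaussian jitter. Peak
#' velocity is generated by the same recipe with the misalignment factor
#' `d` shared beat-wise (a drifted gate deflates both quantities together)
#' and independent jitter.
#'
#' @param true_vti True (noiseless) VTI at this stage, cm.
#' @param true_pv True peak velocity, cm/s.
#' @param duration_s Recording length, seconds; must span at least 9
#'   respiratory cycles.
#' @param noise A [noise_params()] list.
#' @param resp_rate_per_min Respiratory rate (default 15/min).
#' @param heart_rate_per_min Heart rate (default 70/min, inside the
#'   normal-sinus-rhythm stability window).
#' @param phase_offset Respiratory phase at time zero (default random).
#' @return Data frame with columns `t_s`, `vti_cm`, `pv_cm_s`,
#'   `resp_phase`.
#' @export
sample_beats <- function(true_vti, true_pv, duration_s,
                         noise = noise_params(),
                         resp_rate_per_min = 15, heart_rate_per_min = 70,
                         phase_offset = stats::runif(1)) {
  check_positive(true_vti, "true_vti")
  check_positive(true_pv, "true_pv")
  resp_period <- 60 / resp_rate_per_min
  if (duration_s < 9 * resp_period)
    stop(sprintf(
      "insufficient data: duration %.1f s spans fewer than 9 respiratory cycles",
      duration_s), call. = FALSE)
  beat_dt <- 60 / heart_rate_per_min
  t <- seq(0, duration_s, by = beat_dt)
  nb <- length(t)
  phase <- (t / resp_period + phase_offset) %% 1

  s <- sin(pi * phase)^2
  deflate <- stats::runif(nb) < noise$misalignment_prob
  d <- ifelse(deflate,
              stats::runif(nb, noise$misalignment_frac_range[1],
                           noise$misalignment_frac_range[2]),
              1)
  eps_v <- stats::rnorm(nb, 0, noise$jitter_cv)
  eps_p <- stats::rnorm(nb, 0, noise$jitter_cv)
  mod <- 1 - noise$resp_modulation_frac * s
  data.frame(
    t_s = t,
    vti_cm = pmax(true_vti * mod * d * (1 + eps_v), 1e-6),
    pv_cm_s = pmax(true_pv * mod * d * (1 + eps_p), 1e-6),
    resp_phase = phase
  )
}

# One protocol stage's accepted readings: simulate beats until the
# end-expiratory selection yields at least 9 readings, then keep the most
# recent n_readings of them.
simulate_reading_set <- function(true_vti, true_pv, n_readings, noise,
                                 window = 0.10, resp_rate_per_min = 15,
                                 heart_rate_per_min = 70, stage = NA) {
  resp_period <- 60 / resp_rate_per_min
  extra <- 2
  for (attempt in 1:6) {
    beats <- sample_beats(true_vti, true_pv,
                          duration_s = (n_readings + extra) * resp_period,
                          noise = noise,
                          resp_rate_per_min = resp_rate_per_min,
                          heart_rate_per_min = heart_rate_per_min)
    rs <- tryCatch(
      select_end_expiratory_maxima(beats, window = window, stage = stage),
      error = function(e) NULL)
    if (!is.null(rs)) {
      if (rs$n > n_readings) {
        keep <- (rs$n - n_readings + 1L):rs$n
        rs <- reading_set(rs$vti_cm[keep], rs$pv_cm_s[keep], stage = stage)
      }
      return(rs)
    }
    extra <- extra + 3
  }
  stop("failed to obtain 9 end-expiratory readings for a stage",
       call. = FALSE)
}

# Subject-level latent state for the jugular-vein and pressure channels.
ijv_latent <- function(true_deficit) {
  list(
    d_sup_mm = stats::rlnorm(1, log(8.4) - 0.12 * true_deficit, 0.27),
    ube_factor = exp(stats::rnorm(1, min(log(2.6 / 8.4) +
                                           0.10 * true_deficit, log(0.8)),
                                  0.28)),
    area_k = exp(stats::rnorm(1, log(1.2), 0.20)),
    map_sup_mmHg = stats::rnorm(1, 98, 6)
  )
}

#' Simulate jugular-vein dimensions and arterial pressure at one stage
#'
#' Generates the right internal jugular vein's maximal/minimal vertical
#' diameter (mm) and cross-sectional area (mm^2), measured at the level of
#' the cricoid cartilage, plus the mean arterial pressure (mmHg), for one
#' protocol stage. The vein is larger supine than elevated and distends
#' further after fluid; its respiratory collapsibility increases only
#' weakly with the true deficit and carries a large lognormal measurement
#' scatter — in spontaneously breathing subjects thoracic and abdominal
#' pressure swings dominate the respiratory swing of the vein, which is
#' why collapsibility is a poor responder discriminator. MAP declines
#' mildly with deficit in the elevated position.
#'
#' @param stage One of [stage_labels()].
#' @param true_deficit True hypovolemic deficit, preload units.
#' @param latent Optional subject-level latent list (from an internal
#'   draw); omitted, a fresh subject is drawn.
#' @return List with `ijvd_max_mm`, `ijvd_min_mm`, `ijva_max_mm2`,
#'   `ijva_min_mm2`, `map_mmHg`.
#' @export
sample_ijv_and_map <- function(stage, true_deficit, latent = NULL) {
  stage <- match.arg(stage, stage_labels())
  if (is.null(latent)) latent <- ijv_latent(true_deficit)
  pos <- stage_position(stage)
  pos_factor <- switch(pos, ube = latent$ube_factor, supine = 1,
                       supine_fluid = 1.2)
  dmax <- latent$d_sup_mm * pos_factor * exp(stats::rnorm(1, 0, 0.06))
  c_d <- min(stats::rlnorm(1, log(13 + 3 * true_deficit), 0.45), 190)
  dmin <- dmax * (200 - c_d) / (200 + c_d)
  amax <- latent$area_k * dmax^2 * exp(stats::rnorm(1, 0, 0.12))
  c_a <- min(stats::rlnorm(1, log(26 + 5 * true_deficit), 0.45), 190)
  amin <- amax * (200 - c_a) / (200 + c_a)
  map <- switch(pos,
                ube = latent$map_sup_mmHg - 7 * true_deficit +
                  stats::rnorm(1, 0, 5),
                supine = latent$map_sup_mmHg + stats::rnorm(1, 0, 2),
                supine_fluid = latent$map_sup_mmHg + 2 +
                  stats::rnorm(1, 0, 2))
  list(ijvd_max_mm = dmax, ijvd_min_mm = dmin,
       ijva_max_mm2 = amax, ijva_min_mm2 = amin,
       map_mmHg = map)
}

#' Cohort generator configuration
#'
#' Bundles and validates everything the cohort generator needs. The
#' defaults reproduce the study conditions: 45 euvolemic healthy
#' volunteers and 215 screened ICU patients with exponentially distributed
#' volume deficits, 9-17 accepted readings per stage, a 500-700 mL bolus,
#' and the beat-level noise model of [noise_params()]. Physiological
#' calibration constants (`delta_position_mean`, `preload_per_ml`,
#' `deficit_rate`) are generator choices pinned so that a euvolemic
#' subject's noiseless positional change sits near 4%, well under the 7%
#' screening threshold, and deficits span the observed patient range.
#'
#' @param n_healthy Number of healthy euvolemic volunteers (default 45).
#' @param n_patients Number of screened ICU patients (default 215).
#' @param deficit_rate Rate of the exponential true-deficit distribution
#'   for patients (default 2.6; mean deficit 0.38 preload units).
#' @param deficit_max Truncation of the deficit distribution (default
#'   1.8 preload units): the cohort is hemodynamically stable with at
#'   most mild hypovolemia, so deficits that would collapse preload are
#'   outside the study population.
#' @param noise A [noise_params()] list.
#' @param window End-expiratory phase half-width (default 0.10).
#' @param resp_rate_per_min,heart_rate_per_min Breathing and heart rates.
#' @param fluid_bolus_range_ml Uniform bolus interval, mL
#'   (default c(500, 700)).
#' @param delta_position_mean,delta_position_sd Mean and between-subject
#'   SD of the positional preload shift (default 0.31, 0.03).
#' @param baseline_preload_mean,baseline_preload_sd Euvolemic supine
#'   preload (default 2.30, 0.05).
#' @param preload_per_ml Preload per mL of saline (default 5.1e-4).
#' @param fluid_effect_sd Log-scale SD of the per-subject bolus
#'   effectiveness factor for ICU patients (default 0.35): how much of
#'   the infused volume reaches the central circulation varies between
#'   ill subjects (venous capacitance, capillary leak), which partially
#'   decouples the fluid-induced response from the positional one.
#' @param fluid_effect_sd_healthy As `fluid_effect_sd`, for healthy
#'   well-hydrated volunteers (default 0.12): volunteers handle a bolus
#'   far more homogeneously than ICU patients.
#' @param unclear_window_prob Probability that a patient's ultrasound
#'   window is unusable (default 19/215).
#' @param repeat_tol_pct Repeat-consistency tolerance, percent (default 5).
#' @param ijv_sign_convention `"table"` or `"formula"`, see
#'   [ijv_positional_change_pct()].
#' @param screen_healthy Should healthy volunteers pass the 7% screening
#'   gate before their fluid challenge? Default `FALSE`: all volunteers
#'   are challenged regardless, the patients-only gate being an ethical
#'   constraint on fluid administration, not part of the volunteer
#'   protocol.
#' @param thresholds Threshold list, see [default_thresholds()].
#' @param seed Optional integer seed; fixed seed gives an identical
#'   cohort.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy = 45L, n_patients = 215L,
                          deficit_rate = 2.6, deficit_max = 1.8,
                          noise = noise_params(),
                          window = 0.10,
                          resp_rate_per_min = 15, heart_rate_per_min = 70,
                          fluid_bolus_range_ml = c(500, 700),
                          delta_position_mean = 0.31,
                          delta_position_sd = 0.03,
                          baseline_preload_mean = 2.30,
                          baseline_preload_sd = 0.05,
                          preload_per_ml = 5.1e-4,
                          fluid_effect_sd = 0.35,
                          fluid_effect_sd_healthy = 0.12,
                          unclear_window_prob = 19 / 215,
                          repeat_tol_pct = 5.0,
                          ijv_sign_convention = c("table", "formula"),
                          screen_healthy = FALSE,
                          thresholds = default_thresholds(),
                          seed = NULL) {
  ijv_sign_convention <- match.arg(ijv_sign_convention)
  bad <- character(0)
  if (n_healthy < 0) bad <- c(bad, "n_healthy")
  if (n_patients < 0) bad <- c(bad, "n_patients")
  if (deficit_rate <= 0) bad <- c(bad, "deficit_rate")
  if (deficit_max <= 0 || deficit_max >= baseline_preload_mean -
        delta_position_mean)
    bad <- c(bad, "deficit_max")
  if (window <= 0 || window > 0.25) bad <- c(bad, "window")
  if (length(fluid_bolus_range_ml) != 2 ||
      any(fluid_bolus_range_ml <= 0) ||
      fluid_bolus_range_ml[1] > fluid_bolus_range_ml[2])
    bad <- c(bad, "fluid_bolus_range_ml")
  if (delta_position_mean <= 0) bad <- c(bad, "delta_position_mean")
  if (baseline_preload_mean <= delta_position_mean)
    bad <- c(bad, "baseline_preload_mean")
  if (preload_per_ml <= 0) bad <- c(bad, "preload_per_ml")
  if (fluid_effect_sd < 0) bad <- c(bad, "fluid_effect_sd")
  if (fluid_effect_sd_healthy < 0) bad <- c(bad, "fluid_effect_sd_healthy")
  if (unclear_window_prob < 0 || unclear_window_prob >= 1)
    bad <- c(bad, "unclear_window_prob")
  if (repeat_tol_pct <= 0) bad <- c(bad, "repeat_tol_pct")
  if (length(bad))
    stop("invalid cohort config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    n_healthy = as.integer(n_healthy), n_patients = as.integer(n_patients),
    deficit_rate = deficit_rate, deficit_max = deficit_max,
    noise = noise, window = window,
    resp_rate_per_min = resp_rate_per_min,
    heart_rate_per_min = heart_rate_per_min,
    fluid_bolus_range_ml = fluid_bolus_range_ml,
    delta_position_mean = delta_position_mean,
    delta_position_sd = delta_position_sd,
    baseline_preload_mean = baseline_preload_mean,
    baseline_preload_sd = baseline_preload_sd,
    preload_per_ml = preload_per_ml, fluid_effect_sd = fluid_effect_sd,
    fluid_effect_sd_healthy = fluid_effect_sd_healthy,
    unclear_window_prob = unclear_window_prob,
    repeat_tol_pct = repeat_tol_pct,
    ijv_sign_convention = ijv_sign_convention,
    screen_healthy = screen_healthy,
    thresholds = thresholds, seed = seed), class = "cohort_config")
}

# One synthetic subject: ground truth plus full five-stage measurements.
simulate_subject <- function(id, group, config) {
  # truncated exponential deficit: stable patients, mild hypovolemia only
  deficit <- if (group == "healthy") 0
             else stats::qexp(stats::runif(1) *
                                stats::pexp(config$deficit_max,
                                            config$deficit_rate),
                              config$deficit_rate)
  baseline <- stats::rnorm(1, config$baseline_preload_mean,
                           config$baseline_preload_sd)
  delta_pos <- max(stats::rnorm(1, config$delta_position_mean,
                                config$delta_position_sd), 0.15)
  # patients run somewhat larger plateau VTI/PV than volunteers
  if (group == "healthy") {
    plateau <- stats::rlnorm(1, log(20), 0.12)
    pv_plateau <- stats::rlnorm(1, log(95), 0.10)
  } else {
    plateau <- stats::rlnorm(1, log(24), 0.15)
    pv_plateau <- stats::rlnorm(1, log(110), 0.10)
  }
  fs <- list(vti_plateau_cm = plateau, preload_scale = 1,
             baseline_preload = baseline,
             pv_plateau_cm_s = pv_plateau, pv_preload_scale = 0.55)
  bolus <- stats::runif(1, config$fluid_bolus_range_ml[1],
                        config$fluid_bolus_range_ml[2])
  # per-subject bolus effectiveness (median 1): decouples the fluid
  # response from the positional one the way real physiology does
  fluid_eff <- exp(stats::rnorm(1, 0, if (group == "healthy")
    config$fluid_effect_sd_healthy else config$fluid_effect_sd))
  age <- round(min(max(stats::rnorm(1, 50 + 20 * min(deficit, 2), 13),
                       18), 95))

  stages <- stage_labels()
  preload <- vapply(stages, stage_preload, 0, true_deficit = deficit,
                    fs = fs, bolus_ml = bolus, delta_position = delta_pos,
                    preload_per_ml = config$preload_per_ml * fluid_eff)
  true_vti <- frank_starling_vti(preload, fs)
  true_pv <- fs$pv_plateau_cm_s *
    (1 - exp(-preload / fs$pv_preload_scale))
  names(true_vti) <- names(true_pv) <- stages

  true_fluid_change <- symmetric_change_pct(true_vti["SUP2"],
                                            true_vti["SUP_FLUID"])
  true_ube_change <- symmetric_change_pct(true_vti["UBE1"],
                                          true_vti["SUP1"])

  reading_sets <- lapply(stages, function(st)
    simulate_reading_set(true_vti[[st]], true_pv[[st]],
                         n_readings = sample(9:17, 1),
                         noise = config$noise, window = config$window,
                         resp_rate_per_min = config$resp_rate_per_min,
                         heart_rate_per_min = config$heart_rate_per_min,
                         stage = st))
  names(reading_sets) <- stages

  latent <- ijv_latent(deficit)
  ijv <- lapply(stages, sample_ijv_and_map, true_deficit = deficit,
                latent = latent)
  names(ijv) <- stages
  map <- vapply(ijv, `[[`, 0, "map_mmHg")

  structure(list(
    subject_id = id, group = group, age_y = age,
    true_deficit = deficit, fs = fs, bolus_ml = bolus,
    fluid_effect = fluid_eff, delta_position = delta_pos,
    true_vti_by_stage = true_vti, true_pv_by_stage = true_pv,
    true_ube_change_pct = unname(true_ube_change),
    true_fluid_change_pct = unname(true_fluid_change),
    true_responder = unname(true_fluid_change >=
                              config$thresholds$responder_pct),
    reading_sets = reading_sets,
    ijv_by_stage = ijv, map_by_stage = map,
    unclear_window = (group == "icu_patient" &&
                        stats::runif(1) < config$unclear_window_prob)
  ), class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' Draws `n_healthy` euvolemic volunteers and `n_patients` ICU patients
#' with exponentially distributed true volume deficits, and attaches to
#' each subject the noiseless stage truths, the ground-truth responder
#' label (noiseless fluid-induced change at or above the responder
#' threshold), full five-stage beat-derived reading sets, jugular-vein
#' dimensions, and mean arterial pressures. With `config$seed` set the
#' cohort is identical across runs.
#'
#' @param config A [cohort_config()].
#' @return List of `synthetic_subject` objects, class `synthetic_cohort`,
#'   with the configuration attached as an attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("config must be built with cohort_config()", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_healthy + config$n_patients
  subjects <- vector("list", n)
  i <- 0L
  for (j in seq_len(config$n_healthy)) {
    i <- i + 1L
    subjects[[i]] <- simulate_subject(sprintf("H%03d", j), "healthy", config)
  }
  for (j in seq_len(config$n_patients)) {
    i <- i + 1L
    subjects[[i]] <- simulate_subject(sprintf("P%03d", j), "icu_patient",
                                      config)
  }
  structure(subjects, class = "synthetic_cohort", config = config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat(sprintf("synthetic_cohort: %d subjects (%d healthy, %d ICU patients)\n",
              length(x), sum(grp == "healthy"), sum(grp == "icu_patient")))
  invisible(x)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with one row per subject: id, group, age, true
#'   deficit, noiseless stage VTIs, noiseless positional and fluid-induced
#'   changes, and the ground-truth responder label.
#' @export
cohort_truth <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    tv <- s$true_vti_by_stage
    data.frame(subject_id = s$subject_id, group = s$group, age_y = s$age_y,
               true_deficit = s$true_deficit, bolus_ml = s$bolus_ml,
               true_vti_ube = unname(tv["UBE1"]),
               true_vti_supine = unname(tv["SUP1"]),
               true_vti_fluid = unname(tv["SUP_FLUID"]),
               true_ube_change_pct = s$true_ube_change_pct,
               true_fluid_change_pct = s$true_fluid_change_pct,
               true_responder = s$true_responder,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split-normal sampler matched to a printed median and quartiles
#'
#' Draws values whose median and quartiles match a published
#' "median (q25, q75)" summary exactly, via a two-piece (split) normal:
#' with `u ~ Uniform(0,1)` and `z` its standard-normal quantile, the draw
#' is `m + z * sigma_L` for `u < 0.5` and `m + z * sigma_U` otherwise,
#' where `sigma_L = (m - q25)/0.67449` and `sigma_U = (q75 - m)/0.67449`.
#' On the log scale the recipe is applied to the logged targets and the
#' result exponentiated, which suits strictly positive, right-skewed
#' summaries. Symmetric targets reduce to a plain normal.
#'
#' @param n Number of draws.
#' @param median,q25,q75 Target quantiles, `q25 < median < q75`.
#' @param scale `"linear"` or `"log"` (log requires `q25 > 0`).
#' @return Numeric vector of length `n`.
#' @export
quantile_split_sampler <- function(n, median, q25, q75,
                                   scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!(q25 < median && median < q75))
    stop("quantile targets must satisfy q25 < median < q75", call. = FALSE)
  if (scale == "log" && q25 <= 0)
    stop("log scale requires q25 > 0", call. = FALSE)
  z75 <- stats::qnorm(0.75)  # 0.67449
  if (scale == "log") {
    m <- log(median); sL <- (m - log(q25)) / z75; sU <- (log(q75) - m) / z75
  } else {
    m <- median; sL <- (median - q25) / z75; sU <- (q75 - median) / z75
  }
  u <- stats::runif(n)
  z <- stats::qnorm(u)
  out <- ifelse(u < 0.5, m + z * sL, m + z * sU)
  if (scale == "log") exp(out) else out
}
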