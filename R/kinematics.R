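#' Chest-compression scenario
#'
#' Describes one simulated CPR recording: the target compression depth and
#' rate the rescuer aims for, the radar aspect angle, a per-subject kinematic
#' profile, and the noise level. The defaults mirror a guideline-style
#' mannequin session (5 cm at 100 compressions per minute, radar above the
#' chest, 30 s).
#'
#' @param target_depth_cm Target compression depth in cm (> 0).
#' @param rate_cpm Compression rate in compressions per minute (> 0).
#' @param duration_s Recording duration in seconds.
#' @param aspect_angle_deg Angle between the radar line of sight and the
#'   chest's motion direction, in degrees; 0 means the radar looks straight
#'   along the compression axis. Must satisfy `0 <= angle < 90`.
#' @param subject_profile List with `depth_bias_cm` (systematic per-subject
#'   offset from the target depth), `depth_jitter_sd_cm` (per-cycle depth
#'   variation) and `rate_jitter_sd_cpm` (per-cycle rate variation).
#' @param noise_snr_db Signal-to-noise ratio of the synthesized radar signal
#'   in dB (`Inf` = noise-free).
#' @param rng_seed Integer seed making the scenario reproducible.
#'
#' @return An object of class `compression_scenario`.
#' @examples
#' sc <- compression_scenario(target_depth_cm = 5, rate_cpm = 100)
#' @export
compression_scenario <- function(target_depth_cm = 5,
                                 rate_cpm = 100,
                                 duration_s = 30,
                                 aspect_angle_deg = 0,
                                 subject_profile = NULL,
                                 noise_snr_db = Inf,
                                 rng_seed = 1L) {
  stopifnot_scalar(target_depth_cm, "target_depth_cm")
  stopifnot_scalar(rate_cpm, "rate_cpm")
  stopifnot_scalar(duration_s, "duration_s")
  if (!is.numeric(aspect_angle_deg) || aspect_angle_deg < 0 || aspect_angle_deg >= 90)
    stop("`aspect_angle_deg` must lie in [0, 90)", call. = FALSE)
  if (is.null(subject_profile)) subject_profile <- mdcpr::subject_profile()
  sc <- list(target_depth_cm = target_depth_cm,
             rate_cpm = rate_cpm,
             duration_s = duration_s,
             aspect_angle_deg = aspect_angle_deg,
             subject_profile = subject_profile,
             noise_snr_db = noise_snr_db,
             rng_seed = as.integer(rng_seed))
  class(sc) <- "compression_scenario"
  sc
}

#' @param depth_bias_cm,depth_jitter_sd_cm,rate_jitter_sd_cpm See
#'   [compression_scenario()].
#' @rdname compression_scenario
#' @export
subject_profile <- function(depth_bias_cm = 0,
                            depth_jitter_sd_cm = 0,
                            rate_jitter_sd_cpm = 0) {
  list(depth_bias_cm = depth_bias_cm,
       depth_jitter_sd_cm = depth_jitter_sd_cm,
       rate_jitter_sd_cpm = rate_jitter_sd_cpm)
}

#' Simulate chest-compression kinematics
#'
#' Generates the chest displacement trace for a scenario on the radar's
#' slow-time grid. Each compression cycle is a raised sine,
#' \eqn{d(t) = D_k \sin^2(\pi t'/T_c)}, which starts and ends at rest with
#' zero velocity (consistent with the lobed micro-Doppler signatures of real
#' compressions). The achieved depth \eqn{D_k} of cycle \eqn{k} is the target
#' depth plus the subject's systematic bias plus per-cycle jitter; the cycle
#' period is jittered analogously. Displacement is measured from rest along
#' the compression axis: 0 = released, positive = compressed.
#'
#' @param scenario A [compression_scenario()].
#' @param config A [radar_config()]; supplies the slow-time sampling rate.
#'
#' @return An object of class `kinematics_trace`: list with `time_s`,
#'   `displacement_m`, `velocity_m_s` (central differences),
#'   `per_cycle_truth` (data frame: `cycle`, `start_idx`, `end_idx`,
#'   `depth_m`, `period_s`), `prf_hz` and `aspect_angle_deg` (0 until
#'   [project_radial()] is applied).
#' @examples
#' tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 5))
#' max(tr$displacement_m)  # ~0.05 m
#' @export
simulate_kinematics <- function(scenario, config = radar_config()) {
  stopifnot(inherits(scenario, "compression_scenario"))
  prf <- config$prf_hz
  n <- floor(scenario$duration_s * prf)
  tgt <- scenario$target_depth_cm / 100
  prof <- scenario$subject_profile

  # reject sampling rates that would alias the compression micro-Doppler
  tc_nom <- 60 / scenario$rate_cpm
  if (tgt > 0) {
    f_max <- 2 * (pi * tgt / tc_nom) / config$wavelength_m
    if (prf < 4 * f_max)
      stop(sprintf(
        "PRF %.0f Hz is below 4x the expected peak Doppler (%.0f Hz); raise the frame rate",
        prf, f_max), call. = FALSE)
  }

  d <- numeric(n)
  truth <- list()
  with_seed(scenario$rng_seed, {
    bias <- prof$depth_bias_cm / 100
    # cumulative (not per-cycle-rounded) boundaries, so that e.g. 30 s at
    # 110 CPM holds exactly floor(30*110/60) = 55 complete cycles
    s_exact <- 0
    k <- 0L
    while (TRUE) {
      k <- k + 1L
      Dk <- tgt + bias + stats::rnorm(1, 0, prof$depth_jitter_sd_cm / 100)
      Dk <- max(Dk, 0)
      rate_k <- scenario$rate_cpm + stats::rnorm(1, 0, prof$rate_jitter_sd_cpm)
      if (rate_k <= 0) rate_k <- scenario$rate_cpm
      tc <- 60 / rate_k
      e_exact <- s_exact + tc
      i0 <- floor(s_exact * prf + 1e-9) + 1L
      i1 <- round(e_exact * prf)
      if (i1 > n) break
      tt <- (i0:i1 - 1L) / prf - s_exact
      d[i0:i1] <- Dk * sin(pi * tt / tc)^2
      truth[[k]] <- data.frame(cycle = k, start_idx = i0, end_idx = i1,
                               depth_m = Dk, period_s = tc)
      s_exact <- e_exact
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cycle = integer(), start_idx = integer(), end_idx = integer(),
               depth_m = numeric(), period_s = numeric())

  t_s <- (seq_len(n) - 1L) / prf
  v <- c(0, diff(d)) * prf
  out <- list(time_s = t_s, displacement_m = d, velocity_m_s = v,
              per_cycle_truth = truth, prf_hz = prf, aspect_angle_deg = 0)
  class(out) <- "kinematics_trace"
  out
}

#' Project kinematics onto the radar line of sight
#'
#' The radar measures only the radial component of chest motion. For an
#' aspect angle \eqn{\theta} between the line of sight and the compression
#' axis, the observed radial displacement is
#' \eqn{r(t) = d(t)\cos\theta}. Inverted later by [compensate_angle()].
#'
#' @param trace A `kinematics_trace`.
#' @param aspect_angle_deg Aspect angle in degrees, `0 <= angle < 90`.
#' @return A `kinematics_trace` whose displacement and velocity are scaled by
#'   \eqn{\cos\theta}; `aspect_angle_deg` records the projection.
#' @examples
#' tr <- simulate_kinematics(compression_scenario(4, 100, duration_s = 2))
#' r <- project_radial(tr, 60)
#' max(r$displacement_m) / max(tr$displacement_m)  # 0.5
#' @export
project_radial <- function(trace, aspect_angle_deg) {
  stopifnot(inherits(trace, "kinematics_trace"))
  if (!is.numeric(aspect_angle_deg) || aspect_angle_deg < 0 || aspect_angle_deg >= 90)
    stop("`aspect_angle_deg` must lie in [0, 90): beyond that the radial component vanishes",
         call. = FALSE)
  ct <- cos(aspect_angle_deg * pi / 180)
  trace$displacement_m <- trace$displacement_m * ct
  trace$velocity_m_s <- trace$velocity_m_s * ct
  trace$aspect_angle_deg <- aspect_angle_deg
  trace
}
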