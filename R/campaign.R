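#' Generate a synthetic measurement campaign
#'
#' Emulates a multi-subject mannequin study: the cross-product of radar
#' placements (cases), target depths and rates is simulated for every
#' subject. Each subject receives a kinematic profile drawn once (systematic
#' depth bias, per-cycle depth jitter, per-cycle rate jitter), so that the
#' between-subject error spread of downstream estimators resembles a real
#' cohort. Case geometry is expressed through the aspect angle: case 1 looks
#' straight down the compression axis (0 degrees), cases 2 and 3 observe the
#' chest obliquely.
#'
#' @param config A [radar_config()].
#' @param subjects Number of subjects.
#' @param cases Named numeric vector of aspect angles in degrees, one per
#'   radar placement, e.g. `c(case1 = 0, case2 = 30, case3 = 45)`.
#' @param depths_cm,rates_cpm Condition grids.
#' @param duration_s Recording length per condition.
#' @param noise_snr_db SNR of the synthesized signals.
#' @param seed Master seed; subject profiles and per-record noise streams are
#'   derived from it deterministically.
#' @param profile_sd List with the population spread of the subject profiles:
#'   `depth_bias_cm` (sd of the systematic bias), `depth_jitter_cm`,
#'   `rate_jitter_cpm` (per-cycle sds, identical across subjects).
#' @param keep_signals If `TRUE` (default) the synthesized signals and truth
#'   tables are kept in memory in `$records`; set to `FALSE` to produce only
#'   the manifest.
#' @param out_dir Optional directory: writes `manifest.csv`, one
#'   `signal_<id>.csv` (columns `re`, `im`) and one `truth_<id>.csv` per
#'   record.
#'
#' @return List of class `campaign` with `manifest` (data frame: `record`,
#'   `subject`, `case`, `angle_deg`, `depth_cm`, `rate_cpm`, `duration_s`,
#'   `snr_db`, `seed`), `profiles` (per-subject), and optionally `records`,
#'   a list of `list(signal, truth)`.
#' @examples
#' cp <- generate_campaign(subjects = 2, depths_cm = 5, rates_cpm = 100,
#'                         duration_s = 5, keep_signals = FALSE)
#' nrow(cp$manifest)  # 2 subjects x 3 cases
#' @export
generate_campaign <- function(config = radar_config(),
                              subjects = 8,
                              cases = c(case1 = 0, case2 = 30, case3 = 45),
                              depths_cm = c(3, 4, 5, 6),
                              rates_cpm = c(90, 100, 110),
                              duration_s = 30,
                              noise_snr_db = 20,
                              seed = 1L,
                              profile_sd = list(depth_bias_cm = 0.2,
                                                depth_jitter_cm = 0.15,
                                                rate_jitter_cpm = 2),
                              keep_signals = TRUE,
                              out_dir = NULL) {
  if (length(cases) == 0 || length(depths_cm) == 0 || length(rates_cpm) == 0)
    stop("condition lists must be non-empty", call. = FALSE)
  if (is.null(names(cases))) names(cases) <- paste0("case", seq_along(cases))
  subjects <- as.integer(subjects)

  prof_seed <- fan_out_seeds(seed, 1)
  biases <- with_seed(prof_seed, stats::rnorm(subjects, 0, profile_sd$depth_bias_cm))
  profiles <- lapply(seq_len(subjects), function(s)
    subject_profile(depth_bias_cm = biases[s],
                    depth_jitter_sd_cm = profile_sd$depth_jitter_cm,
                    rate_jitter_sd_cpm = profile_sd$rate_jitter_cpm))

  grid <- expand.grid(rate_cpm = rates_cpm, depth_cm = depths_cm,
                      case = names(cases), subject = seq_len(subjects),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "case", "depth_cm", "rate_cpm")]
  grid$angle_deg <- unname(cases[grid$case])
  n_rec <- nrow(grid)
  rec_seeds <- fan_out_seeds(seed + 1L, n_rec)
  manifest <- data.frame(record = seq_len(n_rec), grid,
                         duration_s = duration_s, snr_db = noise_snr_db,
                         seed = rec_seeds)

  records <- NULL
  if (keep_signals || !is.null(out_dir)) {
    records <- vector("list", n_rec)
    for (i in seq_len(n_rec)) {
      sc <- compression_scenario(
        target_depth_cm = manifest$depth_cm[i],
        rate_cpm = manifest$rate_cpm[i],
        duration_s = duration_s,
        aspect_angle_deg = manifest$angle_deg[i],
        subject_profile = profiles[[manifest$subject[i]]],
        noise_snr_db = noise_snr_db,
        rng_seed = manifest$seed[i])
      tr <- simulate_kinematics(sc, config)
      tr_r <- project_radial(tr, manifest$angle_deg[i])
      sig <- phase_synthesize(tr_r, config, noise_snr_db, seed = manifest$seed[i])
      records[[i]] <- list(signal = sig, truth = tr$per_cycle_truth)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mf <- manifest
    mf$path <- sprintf("signal_%03d.csv", mf$record)
    utils::write.csv(mf, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    for (i in seq_len(n_rec)) {
      s <- records[[i]]$signal$samples
      utils::write.csv(data.frame(re = Re(s), im = Im(s)),
                       file.path(out_dir, sprintf("signal_%03d.csv", i)),
                       row.names = FALSE)
      utils::write.csv(records[[i]]$truth,
                       file.path(out_dir, sprintf("truth_%03d.csv", i)),
                       row.names = FALSE)
    }
  }

  out <- list(manifest = manifest, profiles = profiles, config = config,
              records = if (keep_signals) records else NULL)
  class(out) <- "campaign"
  out
}
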