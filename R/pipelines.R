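#' Per-cycle analysis table of a synthetic campaign
#'
#' Runs the Doppler-integration front end (spectrogram, envelope, cycle
#' segmentation, integration, angle compensation) on every record of a
#' campaign and matches each detected cycle to the simulator's ground-truth
#' cycle by maximal time overlap. The result is the tidy per-cycle table
#' that the regression and CNN estimators train on.
#'
#' @param campaign A [generate_campaign()] result with `records` kept.
#' @param ... Passed to [estimate_depths()].
#' @return Data frame: `record`, `subject`, `case`, `angle_deg`,
#'   `rate_cpm`, `target_depth_cm`, `cycle`, `t_start`, `t_end`,
#'   `peak_doppler_hz` (as observed), `peak_doppler_comp_hz`
#'   (angle-compensated, comparable across cases), `depth_cm` (reference =
#'   achieved per-cycle depth) and `depth_est_cm` (Doppler-integration
#'   estimate).
#' @export
campaign_cycles <- function(campaign, ...) {
  stopifnot(inherits(campaign, "campaign"), !is.null(campaign$records))
  mf <- campaign$manifest
  prf <- campaign$config$prf_hz
  out <- lapply(seq_len(nrow(mf)), function(i) {
    rec <- campaign$records[[i]]
    est <- estimate_depths(rec$signal, campaign$config,
                           aspect_angle_deg = mf$angle_deg[i], ...)
    if (nrow(est) == 0) return(NULL)
    truth <- rec$truth
    ref <- vapply(seq_len(nrow(est)), function(k) {
      ov <- pmin(est$t_end[k], (truth$end_idx - 1) / prf) -
        pmax(est$t_start[k], (truth$start_idx - 1) / prf)
      j <- which.max(ov)
      if (ov[j] <= 0) NA_real_ else truth$depth_m[j] * 100
    }, numeric(1))
    keep <- !is.na(ref)
    if (!any(keep)) return(NULL)
    data.frame(record = mf$record[i], subject = mf$subject[i],
               case = mf$case[i], angle_deg = mf$angle_deg[i],
               rate_cpm = mf$rate_cpm[i], target_depth_cm = mf$depth_cm[i],
               cycle = est$cycle[keep], t_start = est$t_start[keep],
               t_end = est$t_end[keep],
               peak_doppler_hz = est$peak_doppler_hz[keep],
               peak_doppler_comp_hz = est$peak_doppler_hz[keep] /
                 cos(mf$angle_deg[i] * pi / 180),
               depth_cm = ref[keep], depth_est_cm = est$depth_cm[keep])
  })
  do.call(rbind, out)
}

#' Doppler-integration evaluation of a campaign
#'
#' Per-(subject, case) RMSE of the Doppler-integration estimator against
#' the simulated reference depths, in the familiar subjects-by-placements
#' table layout.
#'
#' @param campaign A [generate_campaign()] result.
#' @param cycles Optionally a precomputed [campaign_cycles()] table.
#' @return An `eval_table` (see [loso_evaluate()]).
#' @export
run_integration_pipeline <- function(campaign, cycles = NULL) {
  cyc <- if (is.null(cycles)) campaign_cycles(campaign) else cycles
  subjects <- sort(unique(cyc$subject))
  cases <- sort(unique(cyc$case))
  rows <- lapply(subjects, function(s) {
    r <- vapply(cases, function(cs) {
      d <- cyc[cyc$subject == s & cyc$case == cs, ]
      if (nrow(d) == 0) return(NA_real_)
      rmse(d$depth_est_cm, d$depth_cm)
    }, numeric(1))
    c(subject = s, r)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("subject", cases)
  summ <- lapply(cases, function(cs) summarize_rmse(out[[cs]][!is.na(out[[cs]])]))
  names(summ) <- cases
  attr(out, "summary") <- summ
  class(out) <- c("eval_table", "data.frame")
  out
}

#' Polynomial-regression evaluation of a campaign
#'
#' Leave-one-subject-out evaluation of the second-order polynomial
#' regression of reference depth on the per-cycle maximum Doppler
#' frequency. The angle-compensated peak frequency is used so that data
#' from all radar placements can be pooled.
#'
#' @inheritParams run_integration_pipeline
#' @param order Polynomial order.
#' @return An `eval_table`.
#' @export
run_regression_pipeline <- function(campaign, cycles = NULL, order = 2L) {
  cyc <- if (is.null(cycles)) campaign_cycles(campaign) else cycles
  loso_evaluate(cyc,
                fit = function(tr) fit_polyreg(tr$peak_doppler_comp_hz,
                                               tr$depth_cm, order = order),
                predict_fun = function(m, te) predict(m, te$peak_doppler_comp_hz))
}

#' Per-cycle spectrogram images for the CNN
#'
#' Crops the time-frequency map of each record around every detected
#' compression cycle (fixed time span, fixed frequency span) and converts
#' the crops to normalized grayscale images.
#'
#' @param campaign A [generate_campaign()] result.
#' @param cycles A [campaign_cycles()] table (computed if `NULL`).
#' @param method `"stft"` or `"spwvd"` map for the crops.
#' @param crop_span_s Time span of each crop; cycles are padded/truncated to
#'   this duration starting at the cycle onset.
#' @param freq_span_hz Frequency half-span of the crop: only
#'   `[-freq_span_hz, +freq_span_hz]` is kept, concentrating image
#'   resolution on the micro-Doppler band.
#' @param out_size Image size, see [tf_to_image()].
#' @param window_length,overlap,fft_length STFT parameters for
#'   `method = "stft"`.
#' @return List with `images` (list of matrices) and `meta` (the matching
#'   rows of `cycles`).
#' @export
cycle_images <- function(campaign, cycles = NULL, method = c("stft", "spwvd"),
                         crop_span_s = 1.0, freq_span_hz = 400,
                         out_size = c(64L, 64L),
                         window_length = 64L, overlap = 48L,
                         fft_length = 256L) {
  method <- match.arg(method)
  cyc <- if (is.null(cycles)) campaign_cycles(campaign) else cycles
  prf <- campaign$config$prf_hz
  images <- vector("list", nrow(cyc))
  pos <- 1L
  for (rec_id in unique(cyc$record)) {
    sig <- campaign$records[[rec_id]]$signal
    tf <- if (method == "stft")
      stft_spectrogram(sig, window_length = window_length, overlap = overlap,
                       fft_length = fft_length)
    else spwvd(sig, hop = 16L, fft_length = 512L)
    frows <- which(abs(tf$freq_axis_hz) <= freq_span_hz)
    rows_k <- which(cyc$record == rec_id)
    for (k in rows_k) {
      jj <- which(tf$time_axis_s >= cyc$t_start[k] &
                    tf$time_axis_s < cyc$t_start[k] + crop_span_s)
      sub <- new_tf_map(tf$power[frows, jj, drop = FALSE],
                        tf$freq_axis_hz[frows], tf$time_axis_s[jj],
                        tf$method, tf$window, tf$prf_hz)
      images[[k]] <- tf_to_image(sub, out_size = out_size)
    }
    pos <- pos + length(rows_k)
  }
  list(images = images, meta = cyc)
}

#' CNN evaluation with a subject-exclusive split
#'
#' Trains the spectrogram-image CNN on all subjects except the held-out
#' one, using a validation split (also subject-disjoint from the test
#' subject) for early stopping, and reports the held-out RMSE. Run it once
#' per subject for a full leave-one-subject-out table.
#'
#' @param imgset A [cycle_images()] result.
#' @param holdout_subject Subject id to hold out entirely.
#' @param val_fraction Fraction of the remaining cycles used for
#'   validation.
#' @param seed Master seed (split, initialization, shuffling).
#' @param ... Passed to [train_cnn()].
#' @return List with `rmse_cm`, `model`, `n_train`, `n_val`, `n_test`.
#' @export
run_cnn_holdout <- function(imgset, holdout_subject, val_fraction = 1 / 7,
                            seed = 1L, ...) {
  meta <- imgset$meta
  is_test <- meta$subject == holdout_subject
  if (!any(is_test)) stop("holdout subject has no cycles", call. = FALSE)
  rest <- which(!is_test)
  seeds <- fan_out_seeds(seed, 3)
  val_idx <- with_seed(seeds[1],
                       sample(rest, max(1L, round(length(rest) * val_fraction))))
  train_idx <- setdiff(rest, val_idx)
  model <- build_cnn(cnn_spec(dim(imgset$images[[1]])), seed = seeds[2])
  model <- train_cnn(model,
                     images = imgset$images[train_idx],
                     labels = meta$depth_cm[train_idx],
                     val_images = imgset$images[val_idx],
                     val_labels = meta$depth_cm[val_idx],
                     seed = seeds[3], ...)
  list(rmse_cm = evaluate_cnn(model, imgset$images[is_test],
                              meta$depth_cm[is_test]),
       model = model, n_train = length(train_idx), n_val = length(val_idx),
       n_test = sum(is_test))
}
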