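#' Leave-one-subject-out evaluation
#'
#' Subject-exclusive cross-validation: for every subject, an estimator is
#' fitted on the data of all other subjects and evaluated (RMSE, cm) on the
#' held-out subject. No observation of the held-out subject enters fitting
#' or validation. When the data carry a `case` column the RMSE is reported
#' per case, mirroring the per-placement layout of campaign result tables.
#'
#' @param data Data frame with at least `subject`, `depth_cm` (reference)
#'   and whatever columns `fit` and `predict_fun` use; optionally `case`.
#' @param fit `function(train_df)` returning a fitted estimator.
#' @param predict_fun `function(model, test_df)` returning predicted depths
#'   (cm) for the rows of `test_df`.
#' @return An `eval_table`: data frame with one row per subject and one
#'   RMSE column per case (or `rmse` if no case column), with a `summary`
#'   attribute (per column: mean, sd, 95% CI half-width from
#'   [summarize_rmse()]).
#' @examples
#' d <- data.frame(subject = rep(1:2, each = 4),
#'                 x = rep(c(100, 150, 200, 250), 2),
#'                 depth_cm = rep(c(3, 4, 5, 6), 2))
#' et <- loso_evaluate(d, fit = function(tr) fit_polyreg(tr$x, tr$depth_cm),
#'                     predict_fun = function(m, te) predict(m, te$x))
#' @export
loso_evaluate <- function(data, fit, predict_fun) {
  stopifnot(is.data.frame(data), "subject" %in% names(data),
            "depth_cm" %in% names(data))
  subjects <- sort(unique(data$subject))
  if (length(subjects) < 2)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  has_case <- "case" %in% names(data)
  cases <- if (has_case) sort(unique(data$case)) else "rmse"

  rows <- lapply(subjects, function(s) {
    test <- data[data$subject == s, , drop = FALSE]
    train <- data[data$subject != s, , drop = FALSE]
    if (nrow(test) == 0) stop("subject ", s, " has no cycles", call. = FALSE)
    model <- fit(train)
    r <- vapply(cases, function(cs) {
      te <- if (has_case) test[test$case == cs, , drop = FALSE] else test
      if (nrow(te) == 0) return(NA_real_)
      rmse(predict_fun(model, te), te$depth_cm)
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

#' @export
print.eval_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  summ <- attr(x, "summary")
  for (cs in names(summ)) {
    s <- summ[[cs]]
    cat(sprintf("%s: mean %.3f +/- %.3f (sd %.3f, n = %d)\n",
                cs, s$mean, s$ci95_halfwidth, s$sd, s$n))
  }
  invisible(x)
}
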