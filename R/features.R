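## Feature extraction: drift series -> (mean, max, oscillation) and the
## labeled limb-instance table that feeds the graders.

#' Analysis window for the drift test
#'
#' Analysis starts `t_start` seconds into the test to exclude the initial
#' dip after limb placement and ends at `t_test`, the duration of the hold.
#'
#' @param t_start seconds (default 10).
#' @param t_test seconds (default 20).
#' @export
analysis_window <- function(t_start = 10, t_test = 20) {
  if (!(t_start >= 0 && t_start < t_test))
    stop_dg("need 0 <= t_start < t_test", class = "dg_invalid_input")
  structure(list(t_start = t_start, t_test = t_test),
            class = "analysis_window")
}

#' Kinematic weakness features of a drift series
#'
#' Over frames with `t_start <= t <= t_test`:
#' * `mean_drift` — arithmetic mean of the drift angle;
#' * `max_drift`  — the signed drift value of largest magnitude;
#' * `oscillation` — peak-to-peak range `max - min` (default), or the sum of
#'   absolute successive differences when `oscillation = "abs_diff"`.
#'
#' @param series a `drift_series`.
#' @param window an [analysis_window()].
#' @param oscillation `"range"` (default) or `"abs_diff"`.
#' @return named list `mean_drift`, `max_drift`, `oscillation` (degrees).
#' @export
extract_features <- function(series, window = analysis_window(),
                             oscillation = c("range", "abs_diff")) {
  oscillation <- match.arg(oscillation)
  ord <- order(series$t)
  t <- series$t[ord]
  theta <- series$theta_drift[ord]
  sel <- t >= window$t_start & t <= window$t_test
  if (sum(sel) < 2L || max(t) < window$t_test || min(t) > window$t_start)
    stop_dg("drift series does not cover the analysis window [%g, %g]",
            window$t_start, window$t_test, class = "dg_insufficient_data")
  th <- theta[sel]
  osc <- if (oscillation == "range") max(th) - min(th) else sum(abs(diff(th)))
  list(mean_drift = mean(th),
       max_drift = th[which.max(abs(th))],
       oscillation = osc)
}

#' Assemble one labeled limb instance
#'
#' @param features list as returned by [extract_features()].
#' @param subject_id,limb_id identifiers; `limb_id` must be one of
#'   ULL/URL/LLL/LRL and determines `limb_level` (upper vs lower).
#' @param age,sex optional demographics (`sex` in `{"M","F"}`).
#' @param nihss optional NIHSS motor grade, 0 or 1.
#' @param mrc optional subdivided MRC grade, 7, 8 or 9.
#' @return one-row data frame with columns
#'   `subject_id, limb_id, mean, max, osc, nihss, mrc, age, sex`.
#'   A label pair outside the clinically observed co-occurrence
#'   (NIHSS 0 with MRC 8/9; NIHSS 1 with MRC 7/8) triggers a warning,
#'   not an error.
#' @export
build_instance <- function(features, subject_id, limb_id,
                           age = NA_real_, sex = NA_character_,
                           nihss = NA_integer_, mrc = NA_integer_) {
  if (!limb_id %in% LIMB_IDS)
    stop_dg("unknown limb_id '%s'", limb_id, class = "dg_invalid_input")
  if (!is.na(nihss) && !nihss %in% c(0L, 1L))
    stop_dg("nihss must be 0 or 1", class = "dg_invalid_input")
  if (!is.na(mrc) && !mrc %in% c(7L, 8L, 9L))
    stop_dg("mrc must be 7, 8 or 9", class = "dg_invalid_input")
  if (!is.na(nihss) && !is.na(mrc)) {
    ok <- (nihss == 0L && mrc %in% c(8L, 9L)) ||
          (nihss == 1L && mrc %in% c(7L, 8L))
    if (!ok)
      warn_dg("label pair NIHSS %d / MRC %d outside observed co-occurrence",
              nihss, mrc, class = "dg_label_consistency")
  }
  data.frame(subject_id = subject_id, limb_id = limb_id,
             mean = features$mean_drift, max = features$max_drift,
             osc = features$oscillation,
             nihss = as.integer(nihss), mrc = as.integer(mrc),
             age = age, sex = sex)
}

#' Construct an instance table
#'
#' @param df data frame with at least `subject_id, limb_id, mean, max, osc`;
#'   optional `nihss, mrc, age, sex, diagnosis`.
#' @return object of class `instance_table` (a data frame).
#' @export
instance_table <- function(df) {
  need <- c("subject_id", "limb_id", "mean", "max", "osc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_dg("instance table missing column(s): %s",
            paste(missing_cols, collapse = ", "), class = "dg_schema_error")
  for (col in c("nihss", "mrc"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  key <- paste(df$subject_id, df$limb_id)
  real <- !is.na(df$limb_id)
  if (anyDuplicated(key[real]))
    stop_dg("duplicate (subject_id, limb_id) pairs", class = "dg_invalid_input")
  if (any(!is.finite(df$mean)) || any(!is.finite(df$max)) ||
      any(!is.finite(df$osc)))
    stop_dg("non-finite feature values", class = "dg_invalid_input")
  structure(as.data.frame(df), class = c("instance_table", "data.frame"))
}

#' @export
print.instance_table <- function(x, ...) {
  cat(sprintf("<instance_table> %d limb instances (%d labeled NIHSS, %d MRC)\n",
              nrow(x), sum(!is.na(x$nihss)), sum(!is.na(x$mrc))))
  NextMethod()
}

limb_level <- function(limb_id) {
  ifelse(is.na(limb_id), NA_character_,
         ifelse(limb_id %in% c("ULL", "URL"), "upper", "lower"))
}

#' Build the numeric feature matrix for model training
#'
#' Columns are emitted in a fixed order: `mean, max, osc`, then `age` and a
#' male indicator if `include_demographics`, then an upper-limb indicator if
#' `include_limb_level`. Standardization is the z-score with the population
#' standard deviation; when a fitted `scaler` is supplied (the training-set
#' statistics), it is applied instead of refitting, so test data is
#' transformed identically to the training data.
#'
#' @param table an [instance_table()].
#' @param labels `"none"`, `"nihss"` or `"mrc"`; when not `"none"` the label
#'   column must be complete and is returned as a factor.
#' @param include_demographics,include_limb_level logical flags (default
#'   `FALSE`, the reproduction configuration).
#' @param standardize logical (default `TRUE`).
#' @param scaler optional scaler from a previous call (`$scaler`).
#' @return list `x` (numeric matrix), `y` (factor or `NULL`), `scaler`.
#' @export
to_feature_matrix <- function(table, labels = c("none", "nihss", "mrc"),
                              include_demographics = FALSE,
                              include_limb_level = FALSE,
                              standardize = TRUE, scaler = NULL) {
  labels <- match.arg(labels)
  x <- cbind(mean = table$mean, max = table$max, osc = table$osc)
  if (include_demographics) {
    # SMOTE-synthesized tables carry an interpolated sex_m indicator instead
    # of a categorical sex column
    sex_m <- if ("sex_m" %in% names(table)) table$sex_m
             else as.numeric(table$sex == "M")
    if (any(is.na(table$age)) || any(is.na(sex_m)))
      stop_dg("demographics requested but age/sex incomplete",
              class = "dg_schema_error")
    x <- cbind(x, age = table$age, sex_m = sex_m)
  }
  if (include_limb_level)
    x <- cbind(x, limb_upper = as.numeric(limb_level(table$limb_id) == "upper"))
  y <- NULL
  if (labels != "none") {
    lab <- table[[labels]]
    if (any(is.na(lab)))
      stop_dg("label '%s' missing for %d instance(s)", labels,
              sum(is.na(lab)), class = "dg_labeled_data_required")
    lev <- if (labels == "nihss") c("0", "1") else c("7", "8", "9")
    y <- factor(as.character(lab), levels = lev)
  }
  if (standardize) {
    if (is.null(scaler)) scaler <- scaler_fit(x)
    x <- scaler_apply(x, scaler)
  } else {
    scaler <- NULL
  }
  list(x = x, y = y, scaler = scaler)
}
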