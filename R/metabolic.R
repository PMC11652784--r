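#' HOMA-IR insulin-resistance index
#'
#' Homeostasis Model Assessment of Insulin Resistance:
#' fasting glucose (mM) x fasting insulin (U/mL) / 22.5. The function is
#' vectorized and bilinear in its arguments. Unit conversion (e.g. from
#' pmol/L insulin) is the caller's responsibility.
#'
#' @param glucose_mM Fasting blood glucose in mM (>= 0).
#' @param insulin_UmL Fasting insulin in U/mL (>= 0).
#' @return HOMA-IR score(s).
#' @examples
#' homa_ir(5.0, 4.5)  # 1.0
#' @export
homa_ir <- function(glucose_mM, insulin_UmL) {
  if (any(glucose_mM < 0) || any(insulin_UmL < 0))
    stop("glucose and insulin must be nonnegative")
  glucose_mM * insulin_UmL / 22.5
}

#' Area under an oral glucose tolerance curve
#'
#' Trapezoidal integral of blood glucose over the full sampled window, in
#' mM x min. With `incremental = TRUE` the baseline (first) glucose value is
#' subtracted before integration (incremental AUC); the default is total
#' AUC.
#'
#' @param time_min Sampling times in minutes, strictly increasing, length
#'   >= 2.
#' @param glucose_mM Glucose values at those times.
#' @param incremental Subtract the baseline value first (default FALSE).
#' @return AUC in mM x min.
#' @examples
#' ogtt_auc(c(0, 30, 60, 90, 120), rep(10, 5))  # 1200
#' @export
ogtt_auc <- function(time_min, glucose_mM, incremental = FALSE) {
  if (length(time_min) < 2) stop("need at least 2 timepoints")
  if (length(time_min) != length(glucose_mM))
    stop("time and glucose lengths differ")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  y <- if (incremental) glucose_mM - glucose_mM[1] else glucose_mM
  pracma::trapz(time_min, y)
}

#' Summarise a metabolic cohort table
#'
#' Computes per-animal HOMA-IR and OGTT AUC and per-group means with SEM.
#'
#' @param cohort Data frame with columns `animal_id`, `group`,
#'   `fasting_glucose_mM`, `fasting_insulin_UmL`, and OGTT columns named
#'   `ogtt_<time>` (glucose in mM at `<time>` minutes).
#' @param incremental Passed to [ogtt_auc()].
#' @return List with `animals` (per-animal table incl. `homa_ir` and
#'   `ogtt_auc`) and `groups` (per-group mean/SEM of glucose, insulin,
#'   HOMA-IR and AUC).
#' @export
summarize_metabolic <- function(cohort, incremental = FALSE) {
  need <- c("animal_id", "group", "fasting_glucose_mM", "fasting_insulin_UmL")
  stopifnot(all(need %in% names(cohort)))
  ogtt_cols <- grep("^ogtt_", names(cohort), value = TRUE)
  times <- as.numeric(sub("^ogtt_", "", ogtt_cols))
  ord <- order(times)
  cohort$homa_ir <- homa_ir(cohort$fasting_glucose_mM,
                            cohort$fasting_insulin_UmL)
  cohort$ogtt_auc <- if (length(ogtt_cols) >= 2) {
    apply(as.matrix(cohort[, ogtt_cols[ord]]), 1, function(g)
      ogtt_auc(times[ord], g, incremental = incremental))
  } else NA_real_
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  groups <- do.call(rbind, lapply(split(cohort, cohort$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               glucose_mean = mean(d$fasting_glucose_mM),
               glucose_sem = sem(d$fasting_glucose_mM),
               insulin_mean = mean(d$fasting_insulin_UmL),
               insulin_sem = sem(d$fasting_insulin_UmL),
               homa_ir_mean = mean(d$homa_ir), homa_ir_sem = sem(d$homa_ir),
               auc_mean = mean(d$ogtt_auc), auc_sem = sem(d$ogtt_auc),
               row.names = NULL)))
  rownames(groups) <- NULL
  list(animals = cohort, groups = groups)
}
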