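#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function; deaths precede
#' censorings at tied times (standard life-table convention).
#'
#' @param surv data.frame with `time` (> 0) and `event` (0/1), optionally
#'   `sample_id`.
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (one row per observed time); `S(0) = 1` implicitly, `surv`
#'   non-increasing.
#' @export
km_estimate <- function(surv) {
  check_survival(surv)
  fit <- survival::survfit(
    survival::Surv(surv$time, surv$event) ~ 1, conf.type = "none"
  )
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
}

#' Median survival time from a KM curve
#'
#' @param km A [km_estimate()] result.
#' @return Smallest time with `S(t) <= 0.5`, or `NA` if the curve never
#'   reaches 0.5.
#' @export
km_median <- function(km) {
  hit <- which(km$surv <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  km$time[min(hit)]
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected log-rank chi-square across 2 or more groups.
#'
#' @param surv data.frame with `time` and `event`.
#' @param group_labels One group label per row of `surv`.
#' @return List with `chi2`, `df` (= groups - 1), `p`.
#' @export
logrank_test <- function(surv, group_labels) {
  check_survival(surv)
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop_arg("need at least 2 groups")
  if (sum(surv$event) < 1) stop_arg("need at least one event")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- nlevels(g) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Stratified Kaplan-Meier analysis over two factors
#'
#' Crosses two per-sample factors (e.g. TMB group x score group), drops
#' empty combinations with a warning, and returns the KM curve per stratum
#' plus the overall log-rank test across strata.
#'
#' @param surv data.frame with `time` and `event`.
#' @param factor_a,factor_b Per-sample factors.
#' @return List with `curves` (named list of KM data.frames), `medians`,
#'   and `logrank` (as in [logrank_test()]).
#' @export
stratified_km <- function(surv, factor_a, factor_b) {
  check_survival(surv)
  strata <- interaction(factor_a, factor_b, sep = "/", drop = FALSE)
  empty <- setdiff(levels(strata), unique(as.character(strata)))
  if (length(empty) > 0) {
    warning("empty stratum(a) dropped: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  strata <- droplevels(strata)
  curves <- lapply(levels(strata), function(s) {
    km_estimate(surv[strata == s, , drop = FALSE])
  })
  names(curves) <- levels(strata)
  list(
    curves = curves,
    medians = vapply(curves, km_median, numeric(1)),
    logrank = logrank_test(surv, strata)
  )
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each evaluation time: cases are
#' samples with an observed event by time t, controls those still at risk
#' beyond t; case/control pairs are weighted by the inverse probability of
#' censoring estimated from the censoring Kaplan-Meier curve.
#'
#' @param marker Numeric risk marker, higher = higher risk.
#' @param surv data.frame with `time` and `event`, same order as `marker`.
#' @param eval_times Times at which to evaluate the AUC.
#' @return Named numeric vector `AUC(t)`; `NaN` with a warning where a time
#'   has no cases or no controls.
#' @export
time_dependent_auc <- function(marker, surv, eval_times) {
  check_survival(surv)
  if (length(marker) != nrow(surv)) {
    stop_arg("marker must have one value per sample")
  }
  time <- surv$time
  event <- surv$event
  # censoring KM: G(t) = P(censoring time > t)
  gfit <- survival::survfit(
    survival::Surv(time, 1 - event) ~ 1, conf.type = "none"
  )
  g_at <- function(t) {
    # left-continuous survival of censoring at t- (and G(t) for controls)
    s <- c(1, gfit$surv)
    tt <- c(0, gfit$time)
    s[max(which(tt <= t))]
  }
  g_before <- function(t) {
    s <- c(1, gfit$surv)
    tt <- c(0, gfit$time)
    s[max(which(tt < t))]
  }
  auc <- vapply(eval_times, function(t) {
    cases <- which(time <= t & event == 1)
    controls <- which(time > t)
    if (length(cases) == 0 || length(controls) == 0) {
      warning("no cases or no controls at t = ", t, call. = FALSE)
      return(NaN)
    }
    w_case <- vapply(time[cases], function(ti) 1 / max(g_before(ti), 1e-12),
                     numeric(1))
    w_ctrl <- rep(1 / max(g_at(t), 1e-12), length(controls))
    mc <- marker[cases]
    mn <- marker[controls]
    conc <- outer(mc, mn, function(a, b) (a > b) + 0.5 * (a == b))
    sum(outer(w_case, w_ctrl) * conc) / (sum(w_case) * sum(w_ctrl))
  }, numeric(1))
  stats::setNames(auc, eval_times)
}

check_survival <- function(surv) {
  if (!is.data.frame(surv) || !all(c("time", "event") %in% names(surv))) {
    stop_arg("survival table needs `time` and `event` columns")
  }
  if (nrow(surv) == 0) stop_arg("empty survival table")
  if (any(surv$time <= 0)) stop_arg("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop_arg("event must be 0/1")
  invisible(surv)
}

#' Read a survival table from TSV
#' @param path File with columns `sample_id`, `time`, `event`.
#' @return Validated data.frame.
#' @export
read_survival_tsv <- function(path) {
  surv <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_survival(surv)
  surv
}
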