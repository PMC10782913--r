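#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of overall survival, optionally per group.
#'
#' @param clinical Clinical tibble (columns `time_months`, `event`).
#' @param group Optional vector of group labels (same length as rows
#'   of `clinical`); one curve per label.
#' @return Tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, starting at 1 at time 0).
#' @export
km_curve <- function(clinical, group = NULL) {
  stopifnot(nrow(clinical) >= 1)
  if (is.null(group)) group <- rep("all", nrow(clinical))
  df <- data.frame(time = clinical$time_months, event = clinical$event,
                   group = as.character(group))
  purrr::map_dfr(split(df, df$group), function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    tibble::tibble(group = d$group[1],
                   time = c(0, fit$time),
                   n_risk = c(nrow(d), fit$n.risk),
                   n_event = c(0, fit$n.event),
                   survival = c(1, fit$surv))
  })
}

#' Log-rank test between survival groups
#'
#' @param clinical Clinical tibble.
#' @param group Group label per row (>=2 non-empty groups).
#' @return List with `statistic` (chi-square), `df` (k-1) and `p`.
#' @export
logrank <- function(clinical, group) {
  group <- as.character(group)
  k <- length(unique(group))
  if (k < 2) stop("log-rank needs >=2 groups")
  df <- data.frame(time = clinical$time_months, event = clinical$event,
                   group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = unname(sd$chisq), df = k - 1,
       p = stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE))
}

# KM estimate of the censoring distribution G(t) = P(C > t),
# evaluated just before each requested time (left limit).
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    idx <- findInterval(t - 1e-9, fit$time)
    ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
  }
}

#' Time-dependent ROC/AUC at fixed horizons
#'
#' Cumulative-case / dynamic-control estimator with inverse
#' probability of censoring weights (IPCW) from the Kaplan-Meier
#' estimate of the censoring distribution. Cases at horizon t are
#' samples with an observed event at or before t; controls are
#' samples still under observation beyond t. Higher score = higher
#' risk. With no censoring all weights are 1 and the estimator
#' reduces to the empirical AUC of cases versus controls.
#'
#' @param scores Tibble with `sample_id` and `score` (e.g. from
#'   [risk_score()]).
#' @param clinical Clinical tibble.
#' @param horizons Evaluation times in months (default 12, 36, 60).
#' @return Tibble with columns `horizon`, `auc`, `n_cases`,
#'   `n_controls`. A horizon with no cases or no controls gets
#'   `auc = NA` rather than an error.
#' @export
time_dependent_auc <- function(scores, clinical, horizons = c(12, 36, 60)) {
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  if (anyNA(cl$sample_id)) stop("scores contain samples absent from clinical")
  time <- cl$time_months; event <- cl$event; s <- scores$score
  G <- censoring_km(time, event)
  purrr::map_dfr(horizons, function(h) {
    case <- which(time <= h & event == 1)
    ctrl <- which(time > h)
    if (length(case) == 0 || length(ctrl) == 0)
      return(tibble::tibble(horizon = h, auc = NA_real_,
                            n_cases = length(case), n_controls = length(ctrl)))
    # IPCW: cases weighted by 1/G(T_i-), controls by 1/G(h)
    w_case <- 1 / G(time[case])
    w_ctrl <- rep(1 / G(h), length(ctrl))
    # weighted probability that a case outscores a control (ties = 1/2)
    ord <- outer(s[case], s[ctrl], function(a, b) (a > b) + 0.5 * (a == b))
    w <- outer(w_case, w_ctrl)
    tibble::tibble(horizon = h, auc = sum(ord * w) / sum(w),
                   n_cases = length(case), n_controls = length(ctrl))
  })
}

#' ROC curve at one horizon
#'
#' Sensitivity/specificity grid over score thresholds for the
#' cumulative/dynamic case-control split at `horizon`, IPCW-weighted.
#'
#' @inheritParams time_dependent_auc
#' @param horizon Single evaluation time in months.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`;
#'   endpoints reach (0,0) and (1,1) in ROC space.
#' @export
time_roc_curve <- function(scores, clinical, horizon) {
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  time <- cl$time_months; event <- cl$event; s <- scores$score
  G <- censoring_km(time, event)
  case <- which(time <= horizon & event == 1)
  ctrl <- which(time > horizon)
  if (length(case) == 0 || length(ctrl) == 0)
    stop("no cases or no controls at horizon ", horizon)
  w_case <- 1 / G(time[case]); w_ctrl <- rep(1 / G(horizon), length(ctrl))
  thr <- c(-Inf, sort(unique(s)), Inf)
  purrr::map_dfr(thr, function(t0) tibble::tibble(
    threshold = t0,
    sensitivity = sum(w_case[s[case] >= t0]) / sum(w_case),
    specificity = sum(w_ctrl[s[ctrl] < t0]) / sum(w_ctrl)
  ))
}

#' Harrell's concordance index
#'
#' Over usable pairs (the shorter observed time ends in an event;
#' time ties excluded), the fraction where the higher risk score
#' belongs to the shorter survival; score ties count 0.5. C = 1 means
#' perfect risk ranking, 0.5 is chance.
#'
#' @param scores Tibble with `sample_id`, `score`.
#' @param clinical Clinical tibble.
#' @return C in [0, 1].
#' @export
concordance_index <- function(scores, clinical) {
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  time <- cl$time_months; event <- cl$event; s <- scores$score
  # usable pair (i, j): t_i < t_j and subject i had the event
  usable <- outer(time, time, "<") & (event == 1)
  n_usable <- sum(usable)
  if (n_usable == 0) stop("no usable pairs for concordance")
  better <- outer(s, s, ">")   # shorter-lived sample has the higher score
  tied <- outer(s, s, "==")
  (sum(better & usable) + 0.5 * sum(tied & usable)) / n_usable
}

#' Calibration of predicted versus observed survival
#'
#' Samples are binned by quantiles of model-predicted survival at the
#' horizon; each bin's mean predicted S(horizon) is compared with the
#' Kaplan-Meier estimate within the bin. Predictions come from the
#' Cox fit's Breslow baseline hazard.
#'
#' @param signature A fitted `pair_signature` (needs `$fit`), or a
#'   `coxph` object.
#' @param indicators Indicator tibble (used when `signature` is a
#'   `pair_signature`).
#' @param clinical Clinical tibble.
#' @param horizon Evaluation time in months.
#' @param n_bins Number of quantile bins (default 3).
#' @return Tibble with `bin`, `n`, `predicted`, `observed`; bins
#'   partition the cohort. A bin with no at-risk samples at the
#'   horizon gets `observed = NA`.
#' @export
calibration <- function(signature, indicators, clinical, horizon, n_bins = 3) {
  if (inherits(signature, "pair_signature")) {
    if (is.null(signature$fit))
      stop("calibration needs a fitted signature (with a Cox model)")
    fit <- signature$fit
    keys <- paste(signature$entries$regulator, signature$entries$target, sep = "|")
    al <- align_surv(indicators[match(keys, indicators$pair), , drop = FALSE],
                     clinical)
    lp <- as.vector(al$x %*% signature$entries$coefficient)
    time <- al$time; event <- al$event
  } else if (inherits(signature, "coxph")) {
    fit <- signature
    lp <- unname(fit$linear.predictors)
    y <- fit$y
    time <- y[, 1]; event <- y[, 2]
  } else stop("signature must be a fitted pair_signature or a coxph model")

  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- function(t) {
    idx <- findInterval(t, bh$time)
    ifelse(idx == 0, 0, bh$hazard[pmax(idx, 1)])
  }
  pred <- exp(-H0(horizon) * exp(lp))
  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(pred, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  purrr::map_dfr(sort(unique(bin)), function(b) {
    in_b <- bin == b
    obs <- if (max(time[in_b]) < horizon) NA_real_ else {
      # KM estimate within the bin, evaluated at the horizon
      km <- survival::survfit(survival::Surv(time[in_b], event[in_b]) ~ 1)
      idx <- findInterval(horizon, km$time)
      if (idx == 0) 1 else km$surv[idx]
    }
    tibble::tibble(bin = b, n = sum(in_b),
                   predicted = mean(pred[in_b]), observed = obs)
  })
}

#' Full survival-evaluation report for a risk score
#'
#' Bundles the validation suite: median-split Kaplan-Meier with
#' log-rank p, time-dependent AUC at the requested horizons, and
#' Harrell's C-index.
#'
#' @param scores Tibble from [risk_score()] (needs `group`).
#' @param clinical Clinical tibble.
#' @param horizons Months (default 12, 36, 60).
#' @return List with `km` (curve tibble), `logrank`, `auc` (tibble),
#'   `c_index`.
#' @export
evaluate_scores <- function(scores, clinical, horizons = c(12, 36, 60)) {
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  list(
    km = km_curve(cl, scores$group),
    logrank = logrank(cl, scores$group),
    auc = time_dependent_auc(scores, cl, horizons),
    c_index = concordance_index(scores, cl)
  )
}
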