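#' Nomogram points table from a fitted hazard model
#'
#' Renders a proportional-hazards model as a points table: each covariate
#' value maps to 0-100 points via
#' \code{points(x) = 100 * |coef * (x - ref)| / max_j |coef_j * range_j|},
#' where ref is the end of the covariate's range with the lowest risk, so the
#' covariate with the largest |coef| x range spans exactly 0-100 points.
#' Total points map back to the linear predictor and hence to predicted
#' survival \code{S0(t)^exp(lp)} at each horizon.
#'
#' @param model a \code{\link{fit_hazard_model}} result.
#' @param covariate_ranges named list of length-2 numeric ranges (on the
#'   model-matrix scale; binary covariates use c(0, 1)). Defaults to the
#'   observed range of each model term.
#' @param horizons numeric vector of prediction times (warned and
#'   extrapolated flat beyond the last observed time).
#' @param n_grid number of points per covariate scale and of total-point
#'   rows.
#' @return A list of class \code{tsp_nomogram}: \code{scales} (per-covariate
#'   data.frame value -> points), \code{risk_table} (total_points, lp, and
#'   one predicted-survival column per horizon), \code{max_span}.
#' @export
build_nomogram <- function(model, covariate_ranges = NULL, horizons,
                           n_grid = 11) {
  stopifnot(inherits(model, "tsp_hazard_model"))
  beta <- stats::coef(model$fit)
  if (is.null(covariate_ranges)) {
    mm <- stats::model.matrix(model$fit)
    covariate_ranges <- lapply(colnames(mm), function(j) range(mm[, j]))
    names(covariate_ranges) <- colnames(mm)
  }
  covariate_ranges <- covariate_ranges[names(beta)]
  if (anyNA(names(covariate_ranges)))
    stop("covariate_ranges must cover every model coefficient")
  spans <- abs(beta) * vapply(covariate_ranges, function(r) diff(range(r)), 0)
  max_span <- max(spans)
  if (max_span == 0) stop("all covariates have zero effect span")

  scales <- lapply(names(beta), function(cv) {
    r <- range(covariate_ranges[[cv]])
    ref <- if (beta[cv] >= 0) r[1] else r[2]    # lowest-risk end scores 0
    vals <- seq(r[1], r[2], length.out = n_grid)
    data.frame(value = vals,
               points = 100 * abs(beta[cv] * (vals - ref)) / max_span)
  })
  names(scales) <- names(beta)

  # total points <-> linear predictor (centered at the baseline's covariate
  # means): lp(x) = lp_ref + (max_span/100) * total_points
  lp_ref <- sum(vapply(names(beta), function(cv) {
    r <- range(covariate_ranges[[cv]])
    ref <- if (beta[cv] >= 0) r[1] else r[2]
    beta[cv] * (ref - model$covariate_means[cv])
  }, 0))
  total_max <- sum(vapply(scales, function(s) max(s$points), 0))
  totals <- seq(0, total_max, length.out = n_grid)
  lp <- lp_ref + (max_span / 100) * totals
  risk <- data.frame(total_points = totals, lp = lp)
  for (h in horizons) {
    idx <- findInterval(h, model$baseline$time)
    s0 <- if (idx == 0) 1 else model$baseline$surv[idx]
    if (h > max(model$baseline$time))
      warning(sprintf("horizon %g beyond the last observed time; extrapolated flat", h))
    risk[[sprintf("surv_%g", h)]] <- s0^exp(lp)
  }
  structure(list(scales = scales, risk_table = risk, max_span = max_span,
                 horizons = horizons),
            class = "tsp_nomogram")
}

#' Points awarded to a covariate value
#'
#' @param nomogram a \code{\link{build_nomogram}} result.
#' @param covariate model term name.
#' @param value covariate value (model-matrix scale).
#' @return Points on the 0-100 scale (linear interpolation).
#' @export
nomogram_points <- function(nomogram, covariate, value) {
  s <- nomogram$scales[[covariate]]
  if (is.null(s)) stop("unknown covariate: ", covariate)
  stats::approx(s$value, s$points, xout = value, rule = 2)$y
}

#' Calibration of predicted versus observed survival
#'
#' Bins samples by model-predicted survival probability at the horizon and
#' contrasts the mean prediction in each bin with the Kaplan-Meier estimate
#' (and its 95% CI) of the bin at the same horizon. Bins with fewer than
#' \code{min_per_bin} samples are merged with their neighbour.
#'
#' @param model a \code{\link{fit_hazard_model}} result.
#' @param cohort data.frame with time, event and covariate columns.
#' @param horizon time point.
#' @param n_bins number of quantile bins (>= 1).
#' @param min_per_bin minimum samples per bin before merging.
#' @return data.frame: \code{bin}, \code{n}, \code{predicted} (mean),
#'   \code{observed} (KM), \code{lower}, \code{upper}.
#' @export
calibration_curve <- function(model, cohort, horizon, n_bins = 4,
                              min_per_bin = 10) {
  pred <- predict_survival(model, cohort, horizon)
  n <- length(pred)
  n_bins <- max(1, min(n_bins, floor(n / min_per_bin)))
  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(pred, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (anyNA(bin)) bin[is.na(bin)] <- 1
  # merge undersized bins into the neighbour below
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_per_bin]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.integer(small[1])
    tgt <- if (b > min(bin)) max(bin[bin < b]) else min(bin[bin > b])
    bin[bin == b] <- tgt
  }
  levels_sorted <- sort(unique(bin))
  out <- lapply(seq_along(levels_sorted), function(i) {
    sel <- bin == levels_sorted[i]
    tt <- cohort[[model$time_col]][sel]
    ee <- cohort[[model$event_col]][sel]
    fit <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    sf <- summary(fit, times = horizon, extend = TRUE)
    data.frame(bin = i, n = sum(sel), predicted = mean(pred[sel]),
               observed = sf$surv, lower = sf$lower, upper = sf$upper)
  })
  do.call(rbind, out)
}

#' Time-dependent cumulative/dynamic AUC
#'
#' Discrimination of a risk score for events by a horizon t: cases are
#' subjects with an observed event at or before t, controls those still at
#' risk after t. Pairs are weighted by inverse-probability-of-censoring
#' weights from the Kaplan-Meier estimate of the censoring distribution, so
#' the estimate is consistent under independent censoring. With no censoring
#' it reduces to the Wilcoxon AUC of (event by t) versus (survived past t).
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param time positive times.
#' @param event 0/1 event indicators.
#' @param horizon time point t.
#' @return AUC in [0, 1].
#' @export
time_dependent_auc <- function(scores, time, event, horizon) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case) || !any(is_ctrl))
    stop("need at least one event before the horizon and one subject at risk after it")
  # censoring survivor function G from the flipped-indicator KM
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    idx <- findInterval(t, cfit$time)
    ifelse(idx == 0, 1, cfit$surv[pmax(idx, 1)])
  }
  Gminus <- function(t) G(t - 1e-10)     # left limit G(t-)
  w_case <- 1 / Gminus(time[is_case])
  w_ctrl <- rep(1 / G(horizon), sum(is_ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl)))
    stop("censoring weights undefined at the horizon")
  sc <- scores[is_case]; sn <- scores[is_ctrl]
  cmp <- outer(sc, sn, ">") + 0.5 * outer(sc, sn, "==")
  num <- as.numeric(w_case %*% cmp %*% w_ctrl)
  num / (sum(w_case) * sum(w_ctrl))
}

#' Risk-group stratification of a validation cohort
#'
#' The end-to-end survival validation step for one subtype signature: score
#' every sample, find the optimal cutpoint, dichotomize into high/low risk
#' and test the split by log-rank.
#'
#' @param expr numeric matrix, samples x genes.
#' @param sig_entry one subtype's signature data.frame.
#' @param time,event survival outcome vectors aligned with \code{expr} rows.
#' @param minprop minimum group proportion for the cutpoint search.
#' @param mode score aggregation mode (see \code{\link{signature_score}}).
#' @return A list: \code{scores}, \code{cutpoint}
#'   (\code{\link{optimal_cutpoint}} result), \code{risk_group} factor
#'   (high/low), \code{logrank} (\code{\link{logrank_test}} result), and
#'   \code{km} (per-group Kaplan-Meier curves).
#' @export
stratify_cohort <- function(expr, sig_entry, time, event, minprop = 0.1,
                            mode = "signed_mean") {
  scores <- signature_score(expr, sig_entry, mode = mode)
  cp <- optimal_cutpoint(scores, time, event, minprop = minprop)
  grp <- factor(ifelse(scores > cp$threshold, "high", "low"),
                levels = c("high", "low"))
  list(scores = scores, cutpoint = cp, risk_group = grp,
       logrank = logrank_test(time, event, grp),
       km = km_estimate(time, event, grp))
}
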