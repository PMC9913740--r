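#' Per-sample signature risk score
#'
#' Collapses a multi-gene signature into one per-sample score. Default mode
#' \code{"signed_mean"}: each signature gene is z-scored across samples and
#' the per-sample mean is taken with down-regulated genes entering with
#' negative sign. \code{"unsigned_mean"} ignores directions; \code{"pc1"}
#' returns the first principal component of the z-scored signature genes,
#' sign-aligned with the signed mean. Signature genes absent from the matrix
#' are dropped with a warning; genes constant across samples contribute 0.
#'
#' @param expr numeric matrix, samples x genes.
#' @param sig_entry one subtype's signature data.frame (columns
#'   \code{gene_id}, \code{direction}).
#' @param mode aggregation mode.
#' @return Named numeric vector of risk scores, one per sample, with
#'   attribute \code{mode}.
#' @export
signature_score <- function(expr, sig_entry,
                            mode = c("signed_mean", "unsigned_mean", "pc1")) {
  mode <- match.arg(mode)
  genes <- sig_entry$gene_id
  present <- genes %in% colnames(expr)
  if (!any(present)) stop("no signature genes present in the expression matrix")
  if (!all(present))
    warning("dropping signature gene(s) absent from the cohort: ",
            paste(genes[!present], collapse = ", "))
  genes <- genes[present]
  dirs <- ifelse(sig_entry$direction[present] == "down", -1, 1)
  sub <- expr[, genes, drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, stats::sd)
  z <- sweep(sub, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")   # constant gene -> all 0
  signed <- as.numeric(z %*% dirs) / length(genes)
  score <- switch(mode,
    signed_mean = signed,
    unsigned_mean = rowMeans(z),
    pc1 = {
      if (all(sdv == 0)) signed
      else {
        pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
        if (stats::sd(signed) > 0 && stats::cor(pc, signed) < 0) pc <- -pc
        pc
      }
    })
  names(score) <- rownames(expr)
  attr(score, "mode") <- mode
  score
}

# standardized two-group log-rank; grp is logical (TRUE = group 1).
# Returns z = (O1 - E1)/sqrt(V), chisq = z^2.
.logrank_z <- function(time, event, grp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; grp <- grp[ord]
  n <- length(time)
  # at-risk counts just before each position (ties share the risk set)
  ut <- unique(time[event == 1])
  O1 <- E1 <- V <- 0
  # vectorized over distinct event times
  n_at <- n - findInterval(ut, time, left.open = TRUE)  # at risk (time >= t)
  csg <- cumsum(grp)
  n1_at <- sum(grp) - c(0, csg)[findInterval(ut, time, left.open = TRUE) + 1]
  ev_idx <- which(event == 1)
  d_tab <- table(factor(time[ev_idx], levels = ut))
  d1_tab <- table(factor(time[ev_idx][grp[ev_idx]], levels = ut))
  d <- as.numeric(d_tab); d1 <- as.numeric(d1_tab)
  O1 <- sum(d1)
  E1 <- sum(d * n1_at / n_at)
  ok <- n_at > 1
  V <- sum((d * (n1_at / n_at) * (1 - n1_at / n_at) *
              (n_at - d) / (n_at - 1))[ok])
  z <- if (V > 0) (O1 - E1) / sqrt(V) else 0
  list(z = z, chisq = z^2, O1 = O1, E1 = E1, V = V)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Evaluates every admissible threshold on a continuous score by the
#' standardized two-group log-rank statistic and returns the threshold
#' maximizing its absolute value. A threshold is admissible when both
#' resulting groups (high = score > threshold) hold at least a
#' \code{minprop} fraction of the samples. The reported \code{p_naive} is the
#' log-rank p-value of the selected dichotomy, which is anti-conservative
#' because the split was optimized on the same data; it matches what
#' Kaplan-Meier panels conventionally display and must not be read as a
#' calibrated test of association.
#'
#' @param scores numeric vector of risk scores.
#' @param time positive survival/censoring times.
#' @param event 0/1 event indicators.
#' @param minprop minimum group proportion, in (0, 0.5).
#' @return A list: \code{threshold}, \code{max_statistic} (|z|),
#'   \code{p_naive}, \code{n_high}, \code{n_low}.
#' @export
optimal_cutpoint <- function(scores, time, event, minprop = 0.1) {
  n <- length(scores)
  stopifnot(n >= 10, length(time) == n, length(event) == n,
            minprop > 0, minprop < 0.5)
  if (sum(event) < 1) stop("need at least one event")
  if (length(unique(scores)) == 1) stop("all scores identical")
  cand <- sort(unique(scores))
  cand <- cand[-length(cand)]            # threshold = score value, high = >
  n_high <- vapply(cand, function(c) sum(scores > c), 0L)
  adm <- n_high >= ceiling(minprop * n) & (n - n_high) >= ceiling(minprop * n)
  if (!any(adm)) stop("no threshold satisfies the minprop constraint")
  cand <- cand[adm]
  zs <- vapply(cand, function(c)
    .logrank_z(time, event, scores > c)$z, 0)
  best <- which.max(abs(zs))
  thr <- cand[best]
  chisq <- zs[best]^2
  list(threshold = thr, max_statistic = abs(zs[best]),
       p_naive = stats::pchisq(chisq, 1, lower.tail = FALSE),
       n_high = sum(scores > thr), n_low = sum(scores <= thr))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator via \code{survival::survfit}.
#'
#' @param time positive times.
#' @param event 0/1 event indicators.
#' @param group group labels (single group when omitted).
#' @return A data.frame with columns \code{group}, \code{time}, \code{surv},
#'   \code{lower}, \code{upper}, \code{n_risk}, \code{n_event}; S(0) = 1 is
#'   implicit.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ grp,
                           data = data.frame(time = time, event = event,
                                             grp = factor(group)))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(factor(group)), length(sm$time))
         else sub("^grp=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, surv = sm$surv,
             lower = sm$lower, upper = sm$upper,
             n_risk = sm$n.risk, n_event = sm$n.event,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance, two-sided p from a
#' chi-square(1) reference. Identical groups give statistic 0 and p = 1.
#'
#' @param time positive times.
#' @param event 0/1 event indicators.
#' @param group a vector with exactly 2 distinct values.
#' @return A list: \code{chisq}, \code{p}, \code{z} (signed, first group
#'   level as group 1), \code{observed}, \code{expected}.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("need exactly 2 groups")
  if (sum(event) < 1) stop("need at least one event")
  lr <- .logrank_z(time, event, g == levels(g)[1])
  list(chisq = lr$chisq,
       p = if (lr$V > 0) stats::pchisq(lr$chisq, 1, lower.tail = FALSE) else 1,
       z = lr$z, observed = lr$O1, expected = lr$E1)
}

#' Fit a proportional-hazards model
#'
#' Cox partial-likelihood fit (Efron tie handling) of
#' \code{Surv(time, event)} on the named covariates, via
#' \code{survival::coxph}. Returns per-covariate hazard ratios with Wald 95%
#' confidence intervals and p-values, the coefficient covariance and the
#' Breslow baseline cumulative hazard (at the mean of the covariates).
#' Monotone-likelihood non-convergence (e.g. complete separation on a
#' covariate) is reported as an error naming the offending covariate.
#'
#' @param cohort data.frame containing \code{time}, \code{event} and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col names of the time and event columns, so OS/RFS/
#'   DFI/MFS endpoints share one engine via column mapping.
#' @return An object of class \code{tsp_hazard_model}: list with
#'   \code{fit} (the coxph object), \code{summary} (data.frame: covariate,
#'   coef, HR, lower95, upper95, p), \code{covariance}, \code{baseline}
#'   (data.frame time, cumhaz, surv) and \code{covariate_means}.
#' @export
fit_hazard_model <- function(cohort, covariates, time_col = "time",
                             event_col = "event") {
  stopifnot(all(covariates %in% names(cohort)))
  n <- nrow(cohort)
  if (n <= length(covariates)) stop("need more samples than covariates")
  if (sum(cohort[[event_col]]) < 1) stop("need at least one event")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "efron",
                    control = survival::coxph.control(eps = 1e-11,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("proportional-hazards fit did not converge (monotone likelihood); ",
             "check covariate(s): ",
             paste(covariates, collapse = ", "), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  smry <- data.frame(covariate = rownames(co), coef = co[, "coef"],
                     HR = co[, "exp(coef)"],
                     lower95 = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                     upper95 = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                     p = co[, "Pr(>|z|)"], row.names = NULL,
                     stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = TRUE)
  baseline <- data.frame(time = bh$time, cumhaz = bh$hazard,
                         surv = exp(-bh$hazard))
  structure(list(fit = fit, summary = smry, covariance = stats::vcov(fit),
                 baseline = baseline,
                 covariate_means = fit$means,
                 time_col = time_col, event_col = event_col),
            class = "tsp_hazard_model")
}

#' @export
print.tsp_hazard_model <- function(x, ...) {
  cat("Proportional-hazards model (Efron ties)\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Univariate and multivariate hazard-model table
#'
#' Fits one univariate proportional-hazards model per covariate and one
#' multivariate model with all covariates jointly, and lays the results out
#' side by side (HR, 95% CI, p for each analysis).
#'
#' @inheritParams fit_hazard_model
#' @return A data.frame with univariate and multivariate HR/CI/p columns and
#'   the multivariate model in \code{attr(, "multivariate_model")}.
#' @export
hazard_table <- function(cohort, covariates, time_col = "time",
                         event_col = "event") {
  uni <- lapply(covariates, function(cv)
    fit_hazard_model(cohort, cv, time_col, event_col)$summary)
  uni <- do.call(rbind, uni)
  multi_fit <- fit_hazard_model(cohort, covariates, time_col, event_col)
  multi <- multi_fit$summary
  out <- data.frame(covariate = uni$covariate,
                    HR_uni = uni$HR, lower95_uni = uni$lower95,
                    upper95_uni = uni$upper95, p_uni = uni$p,
                    HR_multi = multi$HR, lower95_multi = multi$lower95,
                    upper95_multi = multi$upper95, p_multi = multi$p,
                    stringsAsFactors = FALSE)
  attr(out, "multivariate_model") <- multi_fit
  out
}

# linear predictor centered at the covariate means used for the baseline
.centered_lp <- function(model, cohort) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(model$fit)),
                            data = cohort)
  mm <- mm[, names(stats::coef(model$fit)), drop = FALSE]
  as.numeric(sweep(mm, 2, model$covariate_means, "-") %*%
               stats::coef(model$fit))
}

#' Predicted survival probability at a horizon
#'
#' S(t | x) = S0(t)^exp(lp(x)), with S0 the Breslow baseline survival at the
#' covariate means and lp the mean-centered linear predictor.
#'
#' @param model a \code{\link{fit_hazard_model}} result.
#' @param cohort data.frame of covariate values.
#' @param horizon time point.
#' @return Numeric vector of survival probabilities.
#' @export
predict_survival <- function(model, cohort, horizon) {
  lp <- .centered_lp(model, cohort)
  idx <- findInterval(horizon, model$baseline$time)
  s0 <- if (idx == 0) 1 else model$baseline$surv[idx]
  if (horizon > max(model$baseline$time))
    warning("horizon beyond the last observed time; baseline extrapolated flat")
  s0^exp(lp)
}
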