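sim_cohort <- function(n, beta = 1, seed = 1, censor = 0.3) {
  simulate_survival(n, betas = c(score = beta), censoring_target = censor,
                    seed = seed)$cohort
}

test_that("signature score: single gene, constant genes, signed-mean oracle", {
  set.seed(73)
  expr <- matrix(rnorm(40 * 5, 5), 40, 5,
                 dimnames = list(sprintf("s%02d", 1:40), paste0("g", 1:5)))
  one <- data.frame(gene_id = "g2", direction = "up")
  sc <- signature_score(expr, one)
  expect_equal(as.numeric(sc), as.numeric(scale(expr[, "g2"])), tolerance = 1e-12)

  flat <- matrix(3, 40, 2, dimnames = list(rownames(expr), c("g1", "g2")))
  sc0 <- signature_score(flat, data.frame(gene_id = c("g1", "g2"),
                                          direction = c("up", "down")))
  expect_equal(as.numeric(sc0), rep(0, 40))

  sig <- data.frame(gene_id = c("g1", "g3", "g5"),
                    direction = c("up", "down", "up"))
  sc2 <- signature_score(expr, sig)
  oracle <- sapply(seq_len(40), function(i) {
    z <- sapply(c("g1", "g3", "g5"), function(g)
      (expr[i, g] - mean(expr[, g])) / sd(expr[, g]))
    mean(z * c(1, -1, 1))
  })
  expect_equal(as.numeric(sc2), oracle, tolerance = 1e-12)
})

test_that("missing signature genes are dropped with warning; none is an error", {
  expr <- matrix(rnorm(20), 10, 2,
                 dimnames = list(sprintf("s%02d", 1:10), c("g1", "g2")))
  sig <- data.frame(gene_id = c("g1", "gX"), direction = c("up", "up"))
  expect_warning(sc <- signature_score(expr, sig), "absent")
  expect_equal(as.numeric(sc), as.numeric(scale(expr[, "g1"])), tolerance = 1e-12)
  expect_error(signature_score(expr, data.frame(gene_id = "gZ",
                                                direction = "up")),
               "no signature genes")
})

test_that("binary scores admit only one split and recover it", {
  set.seed(79)
  score <- rep(c(0, 1), each = 150)
  time <- rexp(300, rate = ifelse(score == 1, 3, 1) / 20)
  cp <- optimal_cutpoint(score, time, rep(1, 300), minprop = 0.1)
  expect_gte(cp$threshold, 0)
  expect_lt(cp$threshold, 1)
  expect_equal(cp$n_high, 150)
  expect_lt(cp$p_naive, 1e-6)
})

test_that("cutpoint search enforces its preconditions", {
  expect_error(optimal_cutpoint(rep(1, 50), rexp(50), rep(1, 50)),
               "identical")
  expect_error(optimal_cutpoint(rnorm(50), rexp(50), rep(0, 50)), "event")
  expect_error(optimal_cutpoint(rnorm(5), rexp(5), rep(1, 5)))
})

test_that("cutpoint at the median is recovered within the 40-60 pct band", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 300
    score <- rnorm(n)
    hr <- ifelse(score > median(score), 3, 1)
    time <- rexp(n, rate = hr / 40)
    cens <- runif(n, 0, 120)
    cp <- optimal_cutpoint(score, pmin(time, cens),
                           as.integer(time <= cens), minprop = 0.1)
    q <- mean(score <= cp$threshold)
    if (q >= 0.40 && q <= 0.60) hits <- hits + 1
  }
  expect_gte(hits, 16)    # >= 80% of runs
})

test_that("KM matches hand computation with and without censoring", {
  km <- km_estimate(c(2, 5, 7, 9), c(1, 0, 0, 0))
  expect_equal(km$surv[km$time == 2], 0.75)
  # no events: survival stays 1
  km0 <- km_estimate(1:5, rep(0, 5))
  expect_true(all(km0$surv == 1))
  # mixed censoring, n = 10, against the explicit product-limit loop
  time <- c(1, 2, 2, 3, 4, 5, 5, 6, 8, 9)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km2 <- km_estimate(time, event)
  hand <- km_by_hand(time, event)
  got <- km2[match(hand$time, km2$time), "surv"]
  expect_equal(got, hand$surv, tolerance = 1e-12)
})

test_that("KM without censoring equals the empirical survivor function", {
  set.seed(83)
  t <- sort(rexp(40, 0.1))
  km <- km_estimate(t, rep(1, 40))
  emp <- sapply(km$time, function(x) mean(t > x))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank: identity, hand oracle, label invariance, power", {
  time <- c(1, 2, 3, 1, 2, 3)
  event <- rep(1, 6)
  grp <- rep(c("a", "b"), each = 3)
  same <- logrank_test(time, event, grp)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # tiny 3v3 with distinct times: observed-minus-expected by hand
  t2 <- c(1, 3, 5, 2, 4, 6)
  e2 <- c(1, 1, 0, 1, 1, 1)
  lt <- logrank_test(t2, e2, grp)
  hand <- logrank_by_hand(t2, e2, grp == "a")
  expect_equal(lt$observed, hand$O1)
  expect_equal(lt$expected, hand$E1, tolerance = 1e-12)
  expect_equal(lt$chisq, hand$chisq, tolerance = 1e-12)
  # agreement with the survival package's test
  sd_ <- survival::survdiff(survival::Surv(t2, e2) ~ grp)
  expect_equal(lt$chisq, sd_$chisq, tolerance = 1e-10)

  # relabeling leaves the statistic unchanged
  lt2 <- logrank_test(t2, e2, rev(grp))
  expect_equal(lt2$chisq, lt$chisq, tolerance = 1e-12)

  set.seed(89)
  power <- mean(replicate(60, {
    ta <- rexp(200, 3 / 30); tb <- rexp(200, 1 / 30)
    logrank_test(c(ta, tb), rep(1, 400), rep(c("a", "b"), each = 200))$p < 0.001
  }))
  expect_gte(power, 0.95)
})

test_that("null covariate gives HR ~ 1; grid scan confirms the optimum", {
  set.seed(97)
  n <- 400
  cohort <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1, 0.8),
                       arm = rep(0:1, each = n / 2))
  m <- fit_hazard_model(cohort, "arm")
  expect_lt(abs(m$summary$coef), 0.25)
  expect_gt(m$summary$p, 0.001)

  # 1-covariate fit on 20 samples: Efron partial log-likelihood at the
  # optimum dominates a dense grid (independent loop oracle)
  set.seed(101)
  sm <- data.frame(time = rexp(20, 0.1), event = rbinom(20, 1, 0.8),
                   x = rnorm(20))
  sm$time <- sm$time * exp(-0.5 * sm$x)
  fit <- fit_hazard_model(sm, "x")
  b_hat <- fit$summary$coef
  ll_hat <- efron_loglik(b_hat, sm$time, sm$event, sm$x)
  grid <- seq(b_hat - 2, b_hat + 2, length.out = 161)
  lls <- sapply(grid, efron_loglik, time = sm$time, event = sm$event,
                x = sm$x)
  expect_true(all(ll_hat >= lls - 1e-8))
})

test_that("hazard model recovers a planted log-HR with nominal CI coverage", {
  n_rep <- 100
  est <- cover <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- sim_cohort(500, beta = 0.7, seed = 1000 + i)
    m <- fit_hazard_model(d, "score")
    est[i] <- m$summary$coef
    cover[i] <- m$summary$lower95 <= exp(0.7) && exp(0.7) <= m$summary$upper95
  }
  expect_lt(abs(mean(est) - 0.7), 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})

test_that("monotone likelihood is reported with the offending covariate", {
  d <- data.frame(time = c(1:10, 21:30), event = 1,
                  sep = rep(c(1, 0), each = 10))
  expect_error(fit_hazard_model(d, "sep"), "converge|monotone")
})

test_that("uni/multivariate table mirrors per-covariate fits", {
  d <- sim_cohort(300, beta = 0.8, seed = 7)
  tab <- hazard_table(d, c("score", "age", "stage"))
  expect_equal(nrow(tab), 3)
  uni_score <- fit_hazard_model(d, "score")$summary
  expect_equal(tab$HR_uni[tab$covariate == "score"], uni_score$HR)
  multi <- fit_hazard_model(d, c("score", "age", "stage"))$summary
  expect_equal(tab$HR_multi, multi$HR)
  expect_true(all(tab$lower95_uni <= tab$HR_uni &
                    tab$HR_uni <= tab$upper95_uni))
})

test_that("nomogram endpoints: reference 0, dominant covariate 100, baseline", {
  d <- sim_cohort(400, beta = 1, seed = 11)
  m <- fit_hazard_model(d, c("score", "stage"))
  nom <- build_nomogram(m, horizons = c(36))
  spans <- sapply(nom$scales, function(s) max(s$points))
  expect_equal(max(spans), 100)
  for (s in nom$scales) expect_equal(min(s$points), 0)
  # linear predictor 0 (mean covariates) reproduces baseline survival
  pred <- predict_survival(m, d[1, , drop = FALSE], 36)
  lp1 <- sum(coef(m$fit) * (c(d$score[1], d$stage[1]) - m$covariate_means))
  idx <- findInterval(36, m$baseline$time)
  expect_equal(pred, m$baseline$surv[idx]^exp(lp1), tolerance = 1e-10)
  # monotone: survival nonincreasing in total points at every horizon
  expect_true(all(diff(nom$risk_table$surv_36) <= 1e-12))
})

test_that("nomogram points interpolate and unknown covariates error", {
  d <- sim_cohort(200, beta = 1, seed = 13)
  m <- fit_hazard_model(d, "score")
  nom <- build_nomogram(m, horizons = 24)
  r <- range(d$score)
  expect_equal(nomogram_points(nom, "score", r[1]), 0)
  expect_equal(nomogram_points(nom, "score", r[2]), 100)
  expect_error(nomogram_points(nom, "nope", 1), "unknown")
})

test_that("calibration: single bin equals overall mean prediction and KM", {
  d <- sim_cohort(120, beta = 0.8, seed = 17)
  m <- fit_hazard_model(d, "score")
  cal1 <- calibration_curve(m, d, horizon = 24, n_bins = 1)
  expect_equal(nrow(cal1), 1)
  expect_equal(cal1$predicted, mean(predict_survival(m, d, 24)),
               tolerance = 1e-10)
  km <- km_estimate(d$time, d$event)
  km_at <- km$surv[max(which(km$time <= 24))]
  expect_equal(cal1$observed, km_at, tolerance = 1e-10)
  # n_bins larger than n reduces to merged bins without error
  cal_big <- calibration_curve(m, d, horizon = 24, n_bins = 500)
  expect_true(all(cal_big$n >= 10))
})

test_that("calibration is close to the diagonal under self-consistency", {
  ok_bins <- all_bins <- 0
  for (s in 1:10) {
    d <- sim_cohort(400, beta = 1, seed = 300 + s)
    m <- fit_hazard_model(d, "score")
    cal <- calibration_curve(m, d, horizon = 36, n_bins = 4)
    inside <- cal$lower - 0.01 <= cal$predicted &
      cal$predicted <= cal$upper + 0.01
    ok_bins <- ok_bins + sum(inside)
    all_bins <- all_bins + nrow(cal)
  }
  expect_gte(ok_bins / all_bins, 0.9)
})

test_that("time-dependent AUC: perfect, null and no-censoring reduction", {
  set.seed(103)
  n <- 200
  t <- sort(rexp(n, 0.05))
  sc_perfect <- -t                # higher score = earlier event
  expect_equal(time_dependent_auc(sc_perfect, t, rep(1, n), median(t)), 1)

  aucs <- replicate(50, {
    tt <- rexp(500, 0.05)
    time_dependent_auc(rnorm(500), tt, rep(1, 500), quantile(tt, 0.4))
  })
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)

  # no censoring: equals binary Wilcoxon AUC for (event by t) vs (after t)
  set.seed(107)
  tt <- rexp(150, 0.04)
  sc <- -tt + rnorm(150, 0, 10)
  h <- quantile(tt, 0.5)
  auc <- time_dependent_auc(sc, tt, rep(1, 150), h)
  cases <- sc[tt <= h]; ctrls <- sc[tt > h]
  wilcox_auc <- mean(outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "=="))
  expect_equal(auc, wilcox_auc, tolerance = 1e-12)
})

test_that("stratification pipeline detects a planted signature effect", {
  sig <- data.frame(gene_id = paste0("SG", 1:6),
                    direction = rep(c("up", "down"), 3))
  hits <- 0
  for (s in 1:25) {
    sv <- simulate_survival(150, betas = c(score = 1.1),
                            censoring_target = 0.3, sig_entry = sig,
                            seed = 500 + s)
    st <- stratify_cohort(sv$expr, sig, sv$cohort$time, sv$cohort$event)
    if (st$logrank$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)
})
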