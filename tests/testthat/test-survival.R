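test_that("KM estimate matches the hand-computed product-limit oracle", {
  # {(1,event),(2,censor),(3,event)}: S(1) = 2/3; at t=3 one at risk,
  # one event -> S(3) = 0; median = 3
  rec <- data.frame(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE))
  km <- km_estimate(rec)
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  expect_equal(km$median, 3)

  # no censoring: KM equals the empirical survival function
  set.seed(16)
  t2 <- rexp(40, 0.1)
  km2 <- km_estimate(data.frame(time = t2, event = TRUE))
  emp <- sapply(km2$time, function(tt) mean(t2 > tt))
  expect_equal(km2$surv, emp)

  # random censored data agrees with the loop oracle everywhere
  t3 <- rexp(60, 0.05); ev3 <- runif(60) < 0.7
  km3 <- km_estimate(data.frame(time = t3, event = ev3))
  o <- oracle_km(t3, ev3)
  expect_equal(km3$surv[match(o$time, km3$time)], o$surv)

  # all censored: flat at 1, median not reached
  km4 <- km_estimate(data.frame(time = 1:5, event = FALSE))
  expect_true(all(km4$surv == 1))
  expect_true(is.na(km4$median))

  expect_error(km_estimate(data.frame(time = -1, event = TRUE)),
               "negative")
})

test_that("KM curve is invariant to record order and ordered in time", {
  set.seed(17)
  rec <- data.frame(time = rexp(50, 0.1), event = runif(50) < 0.6)
  k1 <- km_estimate(rec)
  k2 <- km_estimate(rec[sample(50), ])
  expect_equal(k1$surv, k2$surv)
  expect_true(!is.unsorted(k1$time))
  expect_true(all(diff(k1$surv) <= 1e-12))
})

test_that("log-rank matches the hand oracle and is label-symmetric", {
  rec <- data.frame(time = c(1, 3, 2, 4), event = TRUE,
                    stratum = c("a", "a", "b", "b"))
  lr <- logrank_test(rec)
  expect_equal(lr$chisq,
               oracle_logrank(rec$time, rec$event, rec$stratum))

  # identical groups: statistic 0, p = 1
  same <- data.frame(time = rep(c(2, 5, 9), 2), event = TRUE,
                     stratum = rep(c("x", "y"), each = 3))
  lr0 <- logrank_test(same)
  expect_lt(lr0$chisq, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)

  # swapping labels leaves the statistic unchanged
  rec2 <- rec; rec2$stratum <- c("b", "b", "a", "a")
  expect_equal(logrank_test(rec2)$chisq, lr$chisq)

  # zero events: undefined, reported not crashed
  none <- data.frame(time = 1:4, event = FALSE,
                     stratum = c("a", "a", "b", "b"))
  expect_warning(lrn <- logrank_test(none), "undefined|no events")
  expect_true(is.na(lrn$chisq))
})

test_that("log-rank power and calibration on exponential groups", {
  # medians 22 vs 42 months, n = 100/group: rejection well above 5%
  set.seed(18)
  rej_alt <- replicate(40, {
    rec <- data.frame(time = c(rexp(100, log(2) / 22), rexp(100, log(2) / 42)),
                      event = TRUE, stratum = rep(c("low", "high"), each = 100))
    logrank_test(rec)$p < 0.05
  })
  expect_gte(mean(rej_alt), 0.8)
  # equal medians: rejection near the nominal 5%
  rej_null <- replicate(100, {
    rec <- data.frame(time = rexp(200, log(2) / 30), event = TRUE,
                      stratum = rep(c("low", "high"), each = 100))
    logrank_test(rec)$p < 0.05
  })
  expect_lte(mean(rej_null), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("median dichotomization applies the tie rule and recovers effects", {
  scores <- data.frame(patient = 1:4, score = c(1, 2, 3, 4))
  rec <- data.frame(patient = 1:4, time = c(10, 12, 30, 40), event = TRUE)
  r <- dichotomize_at_median(scores, rec)
  expect_equal(r$cutoff, 2.5)
  expect_setequal(r$strata$patient[r$strata$stratum == "low"], 1:2)

  # odd n with a score exactly at the median: that patient goes low
  s5 <- data.frame(patient = 1:5, score = c(1, 2, 3, 4, 5))
  r5 <- dichotomize_at_median(s5, data.frame(patient = 1:5,
                                             time = 10 * (1:5), event = TRUE))
  expect_true("3" %in% as.character(r5$strata$patient[r5$strata$stratum == "low"]) ||
                3 %in% r5$strata$patient[r5$strata$stratum == "low"])
  expect_equal(sum(r5$strata$stratum == "low"), 3L)

  expect_error(dichotomize_at_median(
    data.frame(patient = 1:3, score = 2),
    data.frame(patient = 1:3, time = 1:3, event = TRUE)), "identical")

  # planted band-survival association is recovered with the right sign
  set.seed(19)
  n <- 120
  sc <- data.frame(patient = 1:n, score = runif(n, 0, 3))
  med <- median(sc$score)
  rate <- ifelse(sc$score > med, log(2) / 42, log(2) / 22)
  rc <- data.frame(patient = 1:n, time = rexp(n, rate), event = TRUE)
  rr <- dichotomize_at_median(sc, rc)
  expect_lt(rr$logrank$p, 0.05)
  expect_gt(rr$medians[["high"]], rr$medians[["low"]])
})
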