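test_that("Kaplan-Meier estimates match the product-limit arithmetic", {
  # no events: survival stays at 1
  k0 <- kmEstimate(c(5, 8, 9), c(0, 0, 0))
  expect_true(all(k0$curve$surv == 1))
  expect_true(is.na(k0$median))

  # hand computation: death at 1 (3 at risk), censor at 2, death at 3
  k <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k$curve$surv[k$curve$time == 1], 2 / 3)
  expect_equal(k$curve$surv[k$curve$time == 3], 0)
  expect_true(all(diff(k$curve$surv) <= 0))

  # duplicating every subject leaves the curve unchanged
  k2 <- kmEstimate(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  expect_equal(unique(k2$curve$surv), unique(k$curve$surv))

  # no censoring: KM equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  ke <- kmEstimate(tt, rep(1, 5))
  expect_equal(ke$curve$surv,
               sapply(sort(unique(tt)), function(s) mean(tt > s)))
})

test_that("log-rank matches a brute-force risk-table computation", {
  g <- rep(c("a", "b"), each = 3)
  t1 <- c(1, 2, 3, 1, 2, 3); e1 <- c(1, 0, 1, 1, 0, 1)
  same <- logrankTest(g, t1, e1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  set.seed(17)
  t2 <- c(rexp(20, 1), rexp(20, 3))
  e2 <- rbinom(40, 1, 0.8)
  g2 <- rep(c("a", "b"), each = 20)
  res <- logrankTest(g2, t2, e2)
  expect_equal(res$chi2, logrankOracle(g2, t2, e2), tolerance = 1e-8)
  expect_equal(res$df, 1L)
  expect_error(logrankTest(rep("a", 6), t1, e1), ">= 2")
})

test_that("log-rank equals the Cox score test on the group indicator", {
  set.seed(23)
  tt <- round(rexp(60, c(rep(1, 30), rep(2, 30))), 6)  # tie-free
  ee <- rbinom(60, 1, 0.8)
  gg <- rep(0:1, each = 30)
  lr <- logrankTest(gg, tt, ee)
  sc <- summary(survival::coxph(survival::Surv(tt, ee) ~ gg))$sctest
  expect_equal(lr$chi2, unname(sc["test"]), tolerance = 1e-8)
})

test_that("the spline basis reconstructs x exactly", {
  expect_equal(splineBasis(1.0, 2.5)[1, ], c(below = 1.0, above = 0))
  expect_equal(splineBasis(4.0, 2.5)[1, ], c(below = 2.5, above = 1.5))
  expect_equal(splineBasis(2.5, 2.5)[1, ], c(below = 2.5, above = 0))
  x <- runif(500, 0, 10)
  b <- splineBasis(x, 2.5)
  expect_identical(b[, "below"] + b[, "above"], x)
})

test_that("the Cox fit matches an algebraic partial-likelihood solution", {
  # 3 subjects, events at t=1,2,3 with x = (1, 0, 1); solving
  # d/db log PL = 0 gives exp(b) = 1/sqrt(2)
  cohort <- data.frame(time = c(1, 2, 3), event = 1, x = c(1, 0, 1))
  fit <- survival::coxph(survival::Surv(time, event) ~ x, cohort)
  expect_equal(unname(coef(fit)), -log(2) / 2, tolerance = 1e-6)

  # the spline wrapper reproduces a hand-built basis fit coefficient
  # for coefficient
  sv0 <- simulateSurvival(n = 150, seed = 77)
  fw <- coxSplineFit(sv0$cohort, 2.5)
  b <- splineBasis(sv0$cohort$expression, 2.5)
  dd <- data.frame(time = sv0$cohort$time, event = sv0$cohort$event,
                   below = b[, 1], above = b[, 2])
  ref <- survival::coxph(survival::Surv(time, event) ~ below + above, dd)
  expect_equal(fw@beta, coef(ref), tolerance = 1e-8)
  expect_equal(fw@loglik, ref$loglik[2], tolerance = 1e-8)

  # Efron and Breslow agree on tie-free data
  set.seed(41)
  sv <- simulateSurvival(n = 80, seed = 41)
  fe <- coxSplineFit(sv$cohort, 2.5, ties = "efron")
  fb <- coxSplineFit(sv$cohort, 2.5, ties = "breslow")
  expect_equal(fe@beta, fb@beta, tolerance = 1e-10)
  expect_equal(fe@aic, -2 * fe@loglik + 4)
  expect_error(coxSplineFit(sv$cohort, knot = 1e6), "outside")
  none <- data.frame(time = 1:4, event = 0, expression = 1:4)
  expect_error(coxSplineFit(none, 2.5), ">= 1 event")
})

test_that("knot search returns the AIC argmin with full profile", {
  sv <- simulateSurvival(n = 300, seed = 13)
  one <- knotSearch(sv$cohort, gridLo = 2.5, gridHi = 2.5, step = 0.1)
  expect_equal(one$best_knot, 2.5)
  ks <- suppressWarnings(knotSearch(sv$cohort))
  expect_lte(nrow(ks$profile), 11L)
  expect_equal(ks$profile$aic[ks$profile$knot == ks$best_knot],
               min(ks$profile$aic))
  expect_s4_class(ks$best_fit, "SplineCoxFit")
  expect_error(knotSearch(sv$cohort, gridLo = 3, gridHi = 2), "grid")
})

test_that("martingale residuals behave like the estimator identities", {
  sv <- simulateSurvival(n = 200, seed = 19)
  f <- coxSplineFit(sv$cohort, 2.5)
  r <- martingaleResiduals(f)
  expect_lt(abs(sum(r)), 1e-6 * 200)
  # a subject censored before the first event accrues no hazard
  cohort <- data.frame(time = c(0.5, 2, 3, 4, 5), event = c(0, 1, 1, 1, 0),
                       expression = c(1, 2, 3, 1, 2))
  fc <- coxSplineFit(cohort, 2)
  expect_equal(martingaleResiduals(fc)[1], 0)
})

test_that("risk grouping is strict above the cutoff", {
  expect_identical(as.character(riskGroupSplit(c(2.5, 2.51, 0))),
                   c("low", "high", "low"))
  expect_equal(length(riskGroupSplit(numeric(0))), 0L)
})

test_that("a 3x-hazard two-arm cohort is detected decisively", {
  hits <- 0L
  for (i in 1:20) {
    set.seed(600 + i)
    n <- 200
    arm <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.002 * 3^arm)
    cc <- rexp(n, 0.001)
    lr <- logrankTest(arm, pmin(tt, cc), as.integer(tt <= cc))
    hits <- hits + (lr$p < 0.001)
  }
  expect_gte(hits, 19L)
})
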