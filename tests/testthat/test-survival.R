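simulatePH <- function(n, beta, x = rnorm(n), lambda0 = 0.01,
                       censorRate = 0.005) {
  h <- lambda0 * exp(beta * x)
  t <- rexp(n, h); c <- rexp(n, censorRate)
  list(x = x, time = pmin(t, c), event = as.integer(t <= c))
}

test_that("Cox fit recovers a known log-hazard and is null-calibrated", {
  set.seed(41)
  d <- simulatePH(400, log(2))
  fit <- coxUnivariate(d$x, d$time, d$event)
  expect_lt(abs(fit$beta - log(2)), 0.2)
  expect_true(fit$ci95[1] <= fit$hazardRatio &&
              fit$hazardRatio <= fit$ci95[2])

  d0 <- simulatePH(400, 0)
  fit0 <- coxUnivariate(d0$x, d0$time, d0$event)
  expect_gt(fit0$hazardRatio, 0.8)
  expect_lt(fit0$hazardRatio, 1.25)
})

test_that("Cox fit rejects inestimable inputs and drops missing rows with a warning", {
  expect_error(coxUnivariate(rnorm(20), rexp(20), rep(0, 20)), "inestimable")
  expect_error(coxUnivariate(rep(1, 20), rexp(20), rep(1, 20)), "inestimable")
  set.seed(42)
  d <- simulatePH(50, 0.5)
  xna <- d$x; xna[1:3] <- NA
  expect_warning(fit <- coxUnivariate(xna, d$time, d$event), "dropped")
  expect_identical(fit$n, 47L)
})

test_that("duplicating every subject leaves the Cox estimate essentially unchanged", {
  set.seed(43)
  d <- simulatePH(120, 0.8)
  f1 <- coxUnivariate(d$x, d$time, d$event)
  f2 <- coxUnivariate(rep(d$x, 2), rep(d$time, 2), rep(d$event, 2))
  expect_lt(abs(f1$beta - f2$beta), 0.02)
})

test_that("Holm adjustment matches the hand-worked step-down and its invariants", {
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(0.2), 0.2)
  expect_equal(holmAdjust(rep(1, 5)), rep(1, 5))
  expect_error(holmAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(44)
  p <- runif(20)
  adj <- holmAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("the threshold scan reproduces survdiff's log-rank statistic", {
  set.seed(45)
  d <- simulatePH(60, 1)
  scan <- DeltaRadiomics:::logrankScan(d$x, d$time, d$event, 5)
  for (k in c(1, length(scan$thresholds) %/% 2, length(scan$thresholds))) {
    grp <- d$x <= scan$thresholds[k]
    sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ grp)
    expect_equal(scan$stat[k], sd$chisq, tolerance = 1e-8)
  }
})

test_that("bestSplit recovers a known group boundary and respects preconditions", {
  # fully separable outcomes: every early event sits in the high-covariate
  # half, so the maximum log-rank split must land at the group boundary
  x <- c(seq(0, 0.9, length.out = 10), seq(3, 3.9, length.out = 10))
  t <- c(seq(100, 145, length.out = 10), seq(1, 10, length.out = 10))
  rs <- bestSplit(x, t, rep(1L, 20), nPerm = 199, seed = 9)
  expect_true(rs$splitFound)
  expect_gt(rs$threshold, 0.9)
  expect_lt(rs$threshold, 3)
  expect_identical(unname(table(rs$group)["high"]), 10L)
  expect_output(print(rs), "threshold")

  # stochastic recovery: 4-fold hazard separation, threshold in the gap
  # in nearly all replicates
  set.seed(46)
  inGap <- replicate(15, {
    xx <- c(rnorm(30, 0, 0.5), rnorm(30, 4, 0.5))
    tt <- rexp(60, ifelse(xx > 2, 0.04, 0.01))
    r <- bestSplit(xx, tt, rep(1L, 60), nPerm = 49, seed = 2)
    r$threshold > max(xx[xx < 2]) && r$threshold < min(xx[xx > 2])
  })
  expect_gte(mean(inGap), 0.9)

  few <- bestSplit(x[1:8], t[1:8], rep(1L, 8), nPerm = 99, seed = 1)
  expect_false(few$splitFound)
  expect_match(few$reason, "fewer than 10")
  noev <- bestSplit(x, t, rep(0L, 20), nPerm = 99, seed = 1)
  expect_match(noev$reason, "fewer than 2 events")
})

test_that("the split is invariant to monotone transformation of the covariate", {
  set.seed(47)
  x <- c(rnorm(20, 0), rnorm(20, 3))
  t <- rexp(40, ifelse(x > 1.5, 0.05, 0.01))
  e <- rep(1L, 40)
  r1 <- bestSplit(x, t, e, nPerm = 99, seed = 3)
  r2 <- bestSplit(exp(x), t, e, nPerm = 99, seed = 3)
  expect_identical(r1$group, r2$group)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
})

test_that("Kaplan-Meier and log-rank match closed-form cases", {
  fit <- kmCurve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(summary(fit, times = 2.5)$surv, 0.5)

  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1),
                    c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrankTest(numeric(0), numeric(0), 1, 1), "empty")
  expect_error(kmCurve(numeric(0), numeric(0)), "empty")

  # KM median of exponential data approaches log(2)/lambda
  set.seed(48)
  t <- rexp(1000, 0.02)
  fit2 <- kmCurve(t, rep(1L, 1000))
  med <- summary(fit2)$table["median"]
  expect_lt(abs(med - log(2) / 0.02), 4)
})

test_that("RECIST thresholds are inclusive at +20% and -30%", {
  expect_identical(recistClassify(50, 60), "PD")
  expect_identical(recistClassify(50, 35), "PR")
  expect_identical(recistClassify(50, 52), "SD")
  expect_identical(recistClassify(50, c(59.9, 60.1, 35.1, 34.9)),
                   c("SD", "PD", "SD", "PR"))
  expect_error(recistClassify(0, 10), "> 0")
})

test_that("the family-wise Cox screen adjusts within histogram and texture separately", {
  set.seed(49)
  cohort <- generateCohort(syntheticConfig(nPatients = 12,
                                           dims = c(32, 32, 12), seed = 50))
  dt <- buildDeltaTable(cohort$studies)
  sv <- do.call(rbind, lapply(cohort$studies, survivalRecord))
  sc <- coxScreen(dt, sv)
  expect_identical(nrow(sc), 73L)
  ok <- !is.na(sc$p_adjusted)
  expect_true(all(sc$p_adjusted[ok] >= sc$p_raw[ok]))
  # Holm multipliers never exceed the family size
  histOk <- ok & sc$family == "histogram"
  expect_true(all(sc$p_adjusted[histOk] <=
                  pmin(1, sc$p_raw[histOk] * sum(histOk)) + 1e-12))
})
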