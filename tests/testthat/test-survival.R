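sim_surv <- function(n, beta = 0.7, rate = 0.1, censor = 15) {
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate * exp(beta * x))
  cens <- pmin(rexp(n, 1 / censor), censor)
  data.frame(time = pmin(t, cens), event = as.integer(t <= cens), x = x)
}

test_that("product-limit estimates match hand computation", {
  none <- km_fit(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(none$surv == 1))

  all_d <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_d$surv, c(2 / 3, 1 / 3, 0))

  # deaths at 2 and 4, censor at 3: risk sets 5 then 3
  mixed <- km_fit(c(2, 3, 4, 6, 7), c(1, 0, 1, 0, 0))
  expect_equal(km_surv_at(mixed, 2), 0.8)
  expect_equal(km_surv_at(mixed, 4), 0.8 * (1 - 1 / 3))
  expect_equal(km_surv_at(mixed, 1), 1)

  expect_error(km_fit(c(0, 1), c(1, 1)), "positive")
  expect_error(km_fit(numeric(0), numeric(0)), "one record")
})

test_that("KM equals the empirical survival function without censoring, and survfit with", {
  skip_if_not_installed("survival")
  set.seed(2)
  t_all <- sample(1:40, 60, replace = TRUE)
  fit <- km_fit(t_all, rep(1, 60))
  for (tt in c(5, 17, 33))
    expect_equal(km_surv_at(fit, tt), mean(t_all > tt))

  d <- sim_surv(150)
  fit2 <- km_fit(d$time, d$event)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  expect_equal(km_surv_at(fit2, summary(ref)$time), summary(ref)$surv,
               tolerance = 1e-10)
  # monotone, starts at 1
  expect_true(all(diff(fit2$surv) <= 1e-12))
  expect_true(all(fit2$surv <= 1))
})

test_that("log-rank matches a manual O-E/V accumulation and survdiff", {
  skip_if_not_installed("survival")
  # identical groups: statistic exactly 0
  t0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e0 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g0 <- rep(1:2, each = 4)
  expect_equal(log_rank(t0, e0, g0)$statistic, 0, tolerance = 1e-12)

  # small worked two-group example, accumulated by hand:
  # group A: 1+ (censored), 2, 4 ; group B: 2, 3+, 5
  tA <- c(1, 2, 4); eA <- c(0, 1, 1)
  tB <- c(2, 3, 5); eB <- c(1, 0, 1)
  # event times 2 (n=5, nA=2, d=2), 4 (n=2, nA=1, d=1), 5 (n=1, nA=0, d=1)
  O_A <- 1 + 1 + 0
  E_A <- 2 * 2 / 5 + 1 * 1 / 2 + 0
  V <- (2 * 3 * 2 * 3) / (25 * 4) + (1 * 1 * 1 * 1) / (4 * 1)
  res <- log_rank(c(tA, tB), c(eA, eB), rep(c("A", "B"), each = 3))
  expect_equal(unname(res$observed["A"]), O_A)
  expect_equal(unname(res$expected["A"]), E_A)
  expect_equal(res$statistic, (O_A - E_A)^2 / V, tolerance = 1e-10)

  set.seed(4)
  for (rep in 1:5) {
    d <- sim_surv(120)
    d$g <- sample(1:3, 120, replace = TRUE)
    res <- log_rank(d$time, d$event, d$g)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    expect_equal(res$statistic, ref$chisq, tolerance = 1e-8)
    expect_identical(res$df, 2L)
  }
  expect_error(log_rank(c(1, 2), c(0, 0), c(1, 2)), "no events")
})

test_that("pairwise log-rank covers every pair and equals two-group runs", {
  set.seed(6)
  d <- sim_surv(90)
  d$g <- sample(c("a", "b", "c"), 90, replace = TRUE)
  res <- log_rank(d$time, d$event, d$g, pairwise = TRUE)
  expect_identical(nrow(res$pairwise), 3L)
  sel <- d$g != "c"
  solo <- log_rank(d$time[sel], d$event[sel], d$g[sel])
  row <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "b", ]
  expect_equal(row$statistic, solo$statistic)
})

test_that("Cox gradient matches central finite differences", {
  set.seed(8)
  d <- sim_surv(80)
  X <- cbind(x = d$x, z = rnorm(80))
  for (ties in c("breslow", "efron")) {
    for (rep in 1:3) {
      beta <- rnorm(2, sd = 0.5)
      pl <- cox_partial_loglik(beta, d$time, d$event, X, ties)
      num <- vapply(1:2, function(j) {
        h <- 1e-5
        bp <- beta; bp[j] <- bp[j] + h
        bm <- beta; bm[j] <- bm[j] - h
        (cox_partial_loglik(bp, d$time, d$event, X, ties)$loglik -
           cox_partial_loglik(bm, d$time, d$event, X, ties)$loglik) / (2 * h)
      }, numeric(1))
      expect_equal(pl$gradient, num, tolerance = 1e-5)
    }
  }
})

test_that("Cox estimates agree with survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(10)
  d <- sim_surv(250)
  d$z <- rnorm(250)
  X <- cbind(x = d$x, z = d$z)
  for (ties in c("breslow", "efron")) {
    fit <- cox_fit(d$time, d$event, X, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x + z, data = d,
                           ties = ties)
    expect_equal(fit$coefficients$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  }
})

test_that("Cox edge cases: null effect, errors, divergence", {
  # same event pattern in both arms: coefficient ~ 0
  t2 <- rep(c(1, 2, 3, 4, 5), 2)
  e2 <- rep(c(1, 1, 0, 1, 0), 2)
  x2 <- rep(0:1, each = 5)
  fit <- cox_fit(t2, e2, cbind(x = x2))
  expect_lt(abs(fit$coefficients$coef), 1e-6)

  expect_error(cox_fit(c(-1, 2, 3), c(1, 1, 0), cbind(x = c(0, 1, 1))),
               "positive")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), cbind(x = c(1, 1, 1))),
               "constant")
  expect_error(cox_fit(c(1, 2), c(1, 0), cbind(a = c(0, 1), b = c(1, 0))),
               "fewer events")
  # perfect separation: all early deaths in one arm
  ts <- c(1:10, 101:110)
  es <- c(rep(1, 10), rep(0, 10))
  xs <- rep(1:0, each = 10)
  expect_error(cox_fit(ts, es, cbind(x = xs)), "separation|convergence")
})

test_that("survival_records assembles the analysis table", {
  co <- shared_cohort()
  rec <- survival_records(co$covariates, co$truth$archetype)
  expect_identical(nrow(rec), nrow(co$covariates))
  expect_true(is.factor(rec$charlson))
  expect_true(all(rec$time > 0))
  expect_identical(levels(rec$cluster), as.character(1:4))
})
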