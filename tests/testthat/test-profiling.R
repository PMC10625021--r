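test_that("chi-square matches hand computation and stats::chisq.test", {
  prop <- rbind(c(10, 20), c(20, 40))
  res <- chi_square(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res2 <- chi_square(rbind(c(10, 20), c(20, 10)))  # expecteds all 15
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(res2$df, 1L)

  set.seed(3)
  for (rep in 1:25) {
    tab <- matrix(sample(1:100, 4), 2)
    res <- chi_square(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
  r3 <- chi_square(matrix(sample(1:30, 12), 3))
  expect_identical(r3$df, (3L - 1L) * (4L - 1L))
  expect_error(chi_square(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("undernutrition-by-cluster contingency is overwhelmingly significant", {
  # printed stratified counts: 7840/2527/4341/432 undernourished out of
  # cluster sizes 35975/6543/11375/652
  yes <- c(7840, 2527, 4341, 432)
  size <- c(35975, 6543, 11375, 652)
  res <- chi_square(rbind(yes, size - yes))
  expect_identical(res$df, 3L)
  expect_lt(res$p_value, 0.001)
})

test_that("one-way ANOVA matches hand sums of squares and stats::aov", {
  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(res$F, 13.5)       # SSB = 13.5, SSW = 4, MSW = 1
  expect_identical(c(res$df1, res$df2), c(1L, 4L))

  set.seed(5)
  for (rep in 1:10) {
    g <- factor(sample(1:3, 30, replace = TRUE))
    y <- rnorm(30) + as.integer(g) * 0.5
    res <- one_way_anova(y, g)
    ref <- summary(aov(y ~ g))[[1]]
    expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # size-one group absorbed by pooled residual
  r1 <- one_way_anova(c(1, 2, 3, 10), c(1, 1, 1, 2))
  expect_true(is.finite(r1$F))
  expect_error(one_way_anova(1:5, rep(1, 5)), "2 groups")
})

test_that("ANOVA power at a 1-SD shift, n = 50 per group, exceeds 80%", {
  set.seed(11)
  rej <- mean(replicate(1000, {
    y <- c(rnorm(50), rnorm(50, mean = 1))
    one_way_anova(y, rep(1:2, each = 50))$p_value < 0.05
  }))
  expect_gte(rej, 0.8)
})

test_that("Charlson categories bin the weighted flag sum", {
  w <- c(mi = 1, chf = 2, tumor = 2)
  expect_identical(as.character(charlson_category(
    c(mi = 0, chf = 0, tumor = 0), w)), "0")
  expect_identical(as.character(charlson_category(
    c(mi = 0, chf = 1, tumor = 0), w)), "1-2")
  expect_identical(as.character(charlson_category(
    c(mi = 1, chf = 1, tumor = 1), w)), ">=5")
  expect_identical(as.character(charlson_category(
    c(mi = 1, chf = 1, tumor = 0), w)), "3-4")
  expect_error(charlson_category(c(mi = 1, unknown = 1), w), "unknown")
})

test_that("cluster profile counts, percentages and tests are coherent", {
  co <- shared_cohort()
  seqs <- co$sequences
  labels <- co$truth$archetype
  specs <- list(
    profile_spec("age", "continuous"),
    profile_spec("sex", "categorical"),
    profile_spec("undernutrition", "categorical"),
    profile_spec("exacerbations", "categorical",
                 source = "event:copd_exacerbation_stay",
                 breaks = c(-1, 0, 2, 4, Inf),
                 labels = c("0", "1-2", "3-4", ">=5")))
  prof <- profile_clusters(co$covariates, co$events, labels, specs)

  sex <- prof[prof$variable == "sex" & prof$cluster != "all", ]
  sizes <- table(labels)
  for (cc in names(sizes))
    expect_identical(sum(sex$n[sex$cluster == cc]), as.integer(sizes[[cc]]))
  expect_equal(prof$pct_display,
               ifelse(is.na(prof$pct), NA_real_, floor(prof$pct + 0.5)))

  age <- prof[prof$variable == "age" & prof$cluster == "all", ]
  expect_equal(age$median, median(co$covariates$age))

  # more exacerbation stays in higher archetypes: chi-square must flag it
  ex <- prof[prof$variable == "exacerbations", ]
  expect_lt(ex$p_value[1], 1e-10)

  expect_error(profile_clusters(co$covariates, co$events, labels,
                                list(profile_spec("nope", "continuous"))),
               "nope")
  expect_error(profile_clusters(co$covariates, co$events, labels[-1], specs),
               "cover")
})

test_that("one-patient clusters yield degenerate medians", {
  cov1 <- data.frame(patient_id = c("a", "b", "c"), age = c(50, 60, 70))
  prof <- profile_clusters(cov1, ev("a", "niv", 0),
                           c(1, 1, 2), list(profile_spec("age", "continuous")))
  c2 <- prof[prof$cluster == "2", ]
  expect_equal(c2$median, 70)
  expect_equal(c2$q1, 70)
  expect_equal(c2$q3, 70)
})

test_that("Benjamini-Hochberg option adds adjusted p-values", {
  co <- shared_cohort()
  specs <- list(profile_spec("age", "continuous"),
                profile_spec("sex", "categorical"))
  prof <- profile_clusters(co$covariates, co$events, co$truth$archetype,
                           specs, p_adjust = "BH")
  expect_true("p_adjusted" %in% colnames(prof))
  expect_true(all(prof$p_adjusted >= prof$p_value - 1e-12))
})
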