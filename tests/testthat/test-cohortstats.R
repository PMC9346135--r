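test_that("coefficient of variation follows the sd/mean definition", {
  expect_equal(coefficient_of_variation(c(90, 110), digits = 1), 14.1)
  expect_equal(coefficient_of_variation(rep(5, 4)), 0)
  x <- c(148.2, 180.3, 269.1, 200)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "n >= 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "mean must be > 0")
})

test_that("subgroup summaries reduce to order statistics", {
  d <- data.frame(sex = "male", origin = "Mauritius", side = "OD",
                  T5 = 193.4)
  s <- summarize_cohort(d, measures = "T5")
  expect_equal(s$mean, 193.4)
  expect_equal(s$min, s$max)
  expect_equal(s$std, 0)  # a lone observation has no dispersion
  d2 <- data.frame(sex = rep("male", 2), origin = rep("Asia", 2),
                   T5 = c(148.20, 269.10))
  s2 <- summarize_cohort(d2, measures = "T5")
  expect_equal(s2$min, 148.20)
  expect_equal(s2$max, 269.10)
})

test_that("group summary means recover configured population truth", {
  mdl <- population_model(374, preset = "paper_cohort", seed = 33)
  tt <- generate_cohort(mdl, small_geometry(3L), rasterize = FALSE)$truth_table
  s <- summarize_cohort(tt, group_by = "sex", measures = "T5", cv = TRUE)
  for (i in seq_len(nrow(s))) {
    se <- 15.04 / sqrt(s$n[i])
    expect_lt(abs(s$mean[i] - 192.83), 3 * se)
  }
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
})

test_that("covariate frequencies reproduce printed cohort percentages", {
  f <- covariate_frequencies(c(female = 147, male = 227))
  expect_equal(f$pct[f$level == "female"], 39.30)
  expect_equal(sum(f$count), 374)
})

test_that("Pearson panel matches the direct covariance-formula oracle", {
  set.seed(5)
  tbl <- as.data.frame(matrix(rnorm(50 * 4), 50, 4,
                              dimnames = list(NULL, c("T1", "T2", "A1", "A2"))))
  tbl$T2 <- tbl$T1 * 0.6 + tbl$T2 * 0.4
  r <- pearson_matrix(tbl, c("T1", "T2"), c("T1", "T2", "A1", "A2"))
  for (a in c("T1", "T2")) for (b in c("T1", "T2", "A1", "A2")) {
    x <- tbl[[a]]; y <- tbl[[b]]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r[a, b], oracle, tolerance = 1e-12)
  }
  expect_equal(r["T1", "T1"], 1)
  tbl$neg <- -2 * tbl$T1 + 3
  expect_equal(pearson_matrix(tbl, "T1", "neg")[1, 1], -1)
  tbl$flat <- 7
  expect_warning(rz <- pearson_matrix(tbl, "T1", "flat"), "zero variance")
  expect_true(is.na(rz[1, 1]))
})

test_that("type-II ANOVA matches the nested least-squares oracle and is order-invariant", {
  set.seed(8)
  d <- null_effect_table(150)
  d$origin[1:10] <- "Asia"  # force imbalance
  a <- anova_two_way_type2(d, "T5")
  or <- type2_oracle(d, "T5")
  expect_equal(a$sumsq[a$term == "sex"], or$sumsq[1], tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "origin"], or$sumsq[2], tolerance = 1e-8)
  expect_equal(a$statistic[1:2], or$statistic, tolerance = 1e-8)
  expect_equal(a$p.value[1:2], or$p.value, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "Residuals"], or$rss, tolerance = 1e-8)
  # residual df for the additive model
  expect_equal(a$df[a$term == "Residuals"],
               nrow(d) - 1 - a$df[1] - a$df[2])
  # factor order does not change type-II sums of squares
  a_rev <- anova_two_way_type2(d, "T5", factors = c("origin", "sex"))
  expect_equal(a_rev$sumsq[a_rev$term == "sex"], a$sumsq[a$term == "sex"])
  expect_equal(a_rev$sumsq[a_rev$term == "origin"], a$sumsq[a$term == "origin"])
})

test_that("balanced designs make type-II equal sequential sums of squares", {
  set.seed(9)
  d <- expand.grid(sex = c("male", "female"), origin = c("Mauritius", "Asia"),
                   rep = 1:10, stringsAsFactors = FALSE)
  d$T5 <- rnorm(nrow(d), 193, 12)
  a <- anova_two_way_type2(d, "T5")
  seq_ss <- stats::anova(stats::lm(T5 ~ sex + origin, d))
  expect_equal(a$sumsq[a$term == "sex"], seq_ss["sex", "Sum Sq"])
  expect_equal(a$sumsq[a$term == "origin"], seq_ss["origin", "Sum Sq"])
})

test_that("unknown-origin rows are excluded and degenerate designs rejected", {
  set.seed(10)
  d <- null_effect_table(60)
  d$origin[1:5] <- "unknown"
  expect_message(a <- anova_two_way_type2(d, "T5"), "excluding 5 rows")
  expect_equal(attr(a, "n"), 55)
  d_one <- null_effect_table(30)
  d_one$sex <- "male"
  expect_error(suppressMessages(anova_two_way_type2(d_one, "T5")),
               "fewer than 2")
})

test_that("Bonferroni banding divides significance levels by the test count", {
  b <- bonferroni_band(0.00126, m = 9)
  expect_equal(as.character(b$band), "weakly significant")
  expect_equal(attr(b, "threshold_weak"), 0.05 / 9)
  expect_equal(attr(b, "threshold_significant"), 0.01 / 9)
  expect_equal(as.character(bonferroni_band(0.5, 9)$band), "not significant")
  expect_equal(as.character(bonferroni_band(0.0001, 9)$band), "significant")
  expect_error(bonferroni_band(0), "p-values")
  expect_error(bonferroni_band(0.5, 0), "m must be")
})

test_that("no-effect cohorts rarely cross the Bonferroni thresholds", {
  set.seed(12)
  bands <- character(0)
  for (rep in 1:20) {
    mdl <- population_model(120, seed = 4000 + rep)
    tt <- generate_cohort(mdl, small_geometry(3L), rasterize = FALSE)$truth_table
    tt <- tt[tt$origin != "unknown", ]
    for (resp in paste0("T", c(1, 5, 9))) {
      a <- suppressMessages(anova_two_way_type2(tt, resp))
      bands <- c(bands, as.character(bonferroni_band(a$p.value[1:2], 9)$band))
    }
  }
  expect_gte(mean(bands == "not significant"), 0.95)
})
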