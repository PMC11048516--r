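test_that("Kendall matrix equals the pair-enumeration oracle, with Bonferroni calls", {
  set.seed(1)
  n <- 50
  df <- data.frame(a = round(rnorm(n), 1), b = round(rnorm(n), 1),
                   c = round(rnorm(n), 1))
  df$b <- df$b + 0.5 * df$a   # real association, with ties from rounding
  km <- kendall_matrix(df, variables = c("a", "b", "c"))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(km$tau[pair[1], pair[2]],
                 taub_oracle(df[[pair[1]]], df[[pair[2]]]), tolerance = 1e-12)
  }
  expect_identical(km$tau, t(km$tau))
  expect_true(all(abs(km$tau) <= 1))
  expect_equal(unname(diag(km$tau)), rep(1, 3))
  # self-copy: tau 1, p ~ 0; negated copy: tau -1
  df2 <- data.frame(x = rnorm(20), y = NA, z = NA)
  df2$y <- df2$x; df2$z <- -df2$x
  km2 <- kendall_matrix(df2, variables = c("x", "y", "z"))
  expect_equal(km2$tau["x", "y"], 1)
  expect_equal(km2$tau["x", "z"], -1)
  expect_lt(km2$p_raw["x", "y"], 1e-8)
  expect_true(km2$significant["x", "y"])
  # constant column flagged undefined
  df3 <- cbind(df, k = 1)
  expect_warning(km3 <- kendall_matrix(df3, variables = c("a", "b", "k")),
                 "constant")
  expect_true(all(is.na(km3$tau["k", c("a", "b")])))
})

test_that("correlation clustering recovers block structure and the cut size", {
  tau <- diag(6)
  tau[1:3, 1:3] <- 0.9; tau[4:6, 4:6] <- 0.9
  tau[1:3, 4:6] <- -0.2; tau[4:6, 1:3] <- -0.2
  diag(tau) <- 1
  rownames(tau) <- colnames(tau) <- letters[1:6]
  corr <- structure(list(tau = tau), class = "correlation_matrix")
  cl <- cluster_crmbs(corr, 2)
  expect_length(unique(cl$labels[1:3]), 1)
  expect_length(unique(cl$labels[4:6]), 1)
  expect_false(cl$labels[1] == cl$labels[4])
  # as many subtrees as variables -> singletons
  cl6 <- cluster_crmbs(corr, 6)
  expect_length(unique(cl6$labels), 6)
  expect_error(cluster_crmbs(corr, 7), class = "octacrmb_config_error")
  # engineered three-cluster cohort recovered near-perfectly
  set.seed(9)
  n <- 120
  z <- matrix(rnorm(n * 3), n, 3)
  x <- as.data.frame(z[, rep(1:3, each = 3)] + 0.25 * matrix(rnorm(n * 9), n, 9))
  names(x) <- paste0("v", 1:9)
  cl3 <- cluster_crmbs(kendall_matrix(x, variables = names(x)), 3)
  truth <- rep(1:3, each = 3)
  agree <- outer(cl3$labels, cl3$labels, `==`) == outer(truth, truth, `==`)
  expect_gte(mean(agree[upper.tri(agree)]), 0.95)
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(bh_adjust(p), c(0.004, 0.02, 0.08 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:5) {
    pr <- runif(12)
    expect_equal(bh_adjust(pr), bh_oracle(pr), tolerance = 1e-12)
    # monotone non-decreasing along the sorted raw order
    expect_true(all(diff(bh_adjust(pr)[order(pr)]) >= -1e-12))
  }
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.04, 8)), rep(0.04, 8))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("two-proportion chi-square is symmetric and matches known values", {
  expect_equal(two_proportion_chisq(10, 10, 10, 10)$p_value, 1)
  a <- two_proportion_chisq(19, 24, 17, 13)
  # swapping the groups and transposing the table leave p unchanged
  expect_equal(two_proportion_chisq(17, 13, 19, 24)$p_value, a$p_value)
  expect_equal(two_proportion_chisq(19, 17, 24, 13)$p_value, a$p_value)
  expect_error(two_proportion_chisq(0, 0, 5, 5))
})

test_that("Welch test from summaries matches t.test on raw data", {
  set.seed(3)
  x <- rnorm(25, 1, 2); y <- rnorm(35, 0.4, 1.2)
  ref <- t.test(x, y)
  got <- welch_t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 35)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # equal means -> t = 0, p = 1
  eq <- welch_t_from_summary(1, 1, 10, 1, 2, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10))
})

test_that("group difference tests: identical groups yield no discoveries", {
  set.seed(4)
  tab <- data.frame(group = rep(c("normal", "rvo"), each = 15),
                    PDCS = rnorm(30, 0.2, 0.02), FDS = rnorm(30, 1.7, 0.05))
  gt <- group_difference_tests(tab, c("PDCS", "FDS"))
  expect_false(any(gt$significant))
  # planted difference detected
  tab$PDCS[tab$group == "rvo"] <- tab$PDCS[tab$group == "rvo"] - 0.1
  gt2 <- group_difference_tests(tab, c("PDCS", "FDS"))
  expect_true(gt2$significant[gt2$variable == "PDCS"])
  expect_equal(gt2$p_adjusted, bh_oracle(gt2$p_raw), tolerance = 1e-12)
})

test_that("LASSO recovers planted supports, shrinks to zero, and tolerates collinearity", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 15), n, 15); colnames(X) <- paste0("V", 1:15)
  y <- 1.5 * X[, 1] - 1.2 * X[, 2] + 0.9 * X[, 3] + rnorm(n)
  tab <- data.frame(X, bcva_initial = y)
  lr <- lasso_model(tab, "bcva_initial", predictors = paste0("V", 1:15),
                    seed = 1)
  expect_true(all(c("V1", "V2", "V3") %in% lr$nonzero))
  expect_gt(lr$lambda_selected, 0)
  expect_length(lr$coefficients, 15)
  # seeded fold assignment makes the selection reproducible
  lr2 <- lasso_model(tab, "bcva_initial", predictors = paste0("V", 1:15),
                     seed = 1)
  expect_identical(lr$nonzero, lr2$nonzero)
  expect_equal(lr$lambda_selected, lr2$lambda_selected)
  # coefficient path shrinks to the all-zero limit as lambda grows
  f <- glmnet::glmnet(scale(X), y, lambda = c(100, 1, 0.01))
  expect_true(all(abs(as.matrix(f$beta)[, 1]) < 1e-12))
  # pure-noise outcome: the 1-SE rule keeps the model empty or near-empty
  nz_1se <- vapply(1:6, function(s) {
    set.seed(400 + s)
    tabn <- data.frame(matrix(rnorm(200 * 15), 200, 15),
                       bcva_initial = rnorm(200))
    length(lasso_model(tabn, "bcva_initial", predictors = paste0("X", 1:15),
                       seed = s, lambda_rule = "1se")$nonzero)
  }, numeric(1))
  expect_gte(mean(nz_1se <= 1), 0.8)
  # duplicated predictor leaves the achievable fit deviance unchanged
  X2 <- cbind(X, V1dup = X[, 1])
  d1 <- min(deviance(glmnet::glmnet(scale(X), y)))
  d2 <- min(deviance(glmnet::glmnet(scale(X2), y)))
  expect_equal(d1, d2, tolerance = 1e-4)
  # binomial outcome runs on the synthetic cohort
  coh <- cached_cohort()
  lb <- lasso_model(rbind(coh, coh), "rvo_status", seed = 2)
  expect_equal(lb$family, "binomial")
})

test_that("demographics tables reproduce published-style statistics columns", {
  path <- system.file("extdata", "rvo_cohort_summary.csv", package = "octacrmb")
  tests <- crmb_table1(path)
  expect_equal(nrow(tests), 8)
  # raw p-values for the binary rows (chi-square, no continuity correction)
  p <- setNames(tests$p_value, tests$variable)
  expect_lt(abs(p[["sex_men_women"]] - 0.2940), 1e-4)
  expect_lt(abs(p[["eye_right_left"]] - 0.9221), 1e-4)
  expect_lt(abs(p[["hypertension_yes_no"]] - 0.0003), 1e-4)
  expect_lt(abs(p[["age_years"]] - 0.0029), 1e-4)
  expect_lt(p[["bcva_initial"]], 0.001)
  # adjusted column equals BH over the computed raw p-values
  expect_equal(tests$p_adjusted, bh_oracle(tests$p_value), tolerance = 1e-12)
  # identical groups: all p ~ 1
  same <- data.frame(variable = c("b1", "c1"), type = c("binary", "continuous"),
                     g1_a = c(10, 1.0), g1_b = c(20, 0.5), g1_n = c(30, 30),
                     g2_a = c(10, 1.0), g2_b = c(20, 0.5), g2_n = c(30, 30))
  expect_true(all(demographics_from_summary(same)$p_value == 1))
  # raw-cohort route: BH family = the testable rows only
  coh <- cached_cohort()
  dt <- demographics_table(coh)
  ok <- !is.na(dt$tests$p_value)
  expect_gt(sum(ok), 1)
  expect_equal(dt$tests$p_adjusted[ok], bh_oracle(dt$tests$p_value[ok]),
               tolerance = 1e-12)
  expect_error(demographics_from_summary(data.frame(x = 1)),
               class = "octacrmb_schema_error")
})
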