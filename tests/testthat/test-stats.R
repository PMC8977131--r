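# Robust regression, effect-size conversion, dependent-correlation
# comparison, paired tests and the mixed ANOVA.

test_that("robust regression equals OLS on clean data and resists outliers", {
  set.seed(1)
  x1 <- rnorm(20); x2 <- rnorm(20)
  y <- 1 + 2 * x1 - x2
  f <- robust_fit(y, cbind(x1, x2))
  expect_lt(max(abs(f$coefficients - c(1, 2, -1))), 1e-8)
  expect_true(all(f$weights == 1))
  expect_true(f$converged)
  # gross outlier: downweighted below 0.5, slope within 5% of clean OLS
  y2 <- y + rnorm(20, 0, 0.3)
  ols <- coef(lm(y2 ~ x1 + x2))
  y2[7] <- y2[7] + 8
  f2 <- robust_fit(y2, cbind(x1, x2))
  expect_lt(f2$weights[7], 0.5)
  expect_lt(abs(f2$coefficients[2] - ols[2]) / abs(ols[2]), 0.05)
  expect_true(all(f2$weights >= 0 & f2$weights <= 1))
  # independent cross-check against the reference IRLS implementation
  fr <- MASS::rlm(y2 ~ x1 + x2, psi = MASS::psi.bisquare, c = 4.685)
  expect_lt(max(abs(f2$coefficients - coef(fr))), 0.05)
})

test_that("collinear predictors are refused", {
  set.seed(2)
  x1 <- rnorm(30); x2 <- x1 + rnorm(30, 0, 1e-4)
  expect_gt(cor(x1, x2), 0.999)
  expect_error(robust_fit(rnorm(30), cbind(x1, x2)), "collinear")
  expect_error(robust_fit(rnorm(3), cbind(x1[1:3], rnorm(3))), "observations")
})

test_that("the t-to-r conversion matches its definition and limits", {
  expect_equal(round(t_to_r(-2.83, 19), 2), -0.54)
  expect_equal(round(t_to_r(-2.94, 15), 2), -0.60)
  expect_equal(round(t_to_r(2.18, 15), 2), 0.49)
  expect_equal(round(t_to_r(-4.75, 20), 2), -0.73)
  expect_equal(t_to_r(0, 10), 0)
  ts <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(t_to_r(ts, 12)) > 0))
  expect_gt(t_to_r(1e6, 10), 1 - 1e-6)
  expect_lt(t_to_r(2, 1e8), 1e-3)
  expect_error(t_to_r(1, 0), "df")
})

test_that("fitted lines hold the other predictor at its mean", {
  expect_equal(fitted_line(1, c(2, 3), 1, 0, 1), 4)
  x <- seq(-1, 1, by = 0.5)
  yl <- fitted_line(0.5, c(1.2, -0.7), 1, x, 2)
  expect_equal(unname(diff(yl) / diff(x)), rep(1.2, 4))
  yl2 <- fitted_line(0.5, c(1.2, -0.7), 2, x, 0.3)
  expect_equal(unname(diff(yl2) / diff(x)), rep(-0.7, 4))
})

test_that("the dependent-correlation z is zero at equality, antisymmetric, and matches the worked value", {
  expect_equal(compare_dependent_corrs(0.4, 0.4, 0.1, 30)$z, 0)
  a <- compare_dependent_corrs(-0.59, 0.09, -0.36, 22)
  expect_equal(a$z, -2.0112, tolerance = 1e-4)
  expect_match(a$method, "Steiger")
  b <- compare_dependent_corrs(0.09, -0.59, -0.36, 22)
  expect_equal(a$z, -b$z)
  expect_error(compare_dependent_corrs(1, 0.5, 0.2, 22), "correlations")
  expect_error(compare_dependent_corrs(0.5, 0.2, 0.1, 3), "n must")
})

test_that("paired t handles identity, degeneracy, and has the predicted power", {
  x <- rnorm(10)
  expect_equal(paired_t(x, x)$t, 0)
  expect_error(paired_t(x, x - 1), "zero variance")
  set.seed(3)
  rej <- mean(replicate(2000, {
    y <- rnorm(22)
    paired_t(y + rnorm(22, 1, 1), y)$p < 0.05
  }))
  pw <- power.t.test(n = 22, delta = 1, sd = 1, sig.level = 0.05,
                     type = "one.sample")$power
  expect_lt(abs(rej - pw), 3 * sqrt(pw * (1 - pw) / 2000))
})

test_that("the mixed ANOVA interaction equals the squared two-sample t on deltas", {
  set.seed(4)
  g <- rep(c("anodal", "sham"), c(18, 14))
  pre <- rnorm(32, 0.6, 0.08)
  post <- pre + ifelse(g == "sham", 0.12, 0.02) + rnorm(32, 0, 0.06)
  an <- rm_anova_2x2(g, pre, post)
  tt <- t.test((post - pre) ~ g, var.equal = TRUE)
  expect_equal(an$F[an$effect == "Group:Block"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(an$df2, rep(30, 3))
  # identical group means and deltas: zero interaction
  g2 <- rep(c("a", "b"), each = 4)
  pre2 <- rep(c(1, 2, 3, 4), 2)
  post2 <- pre2 + 1
  an2 <- rm_anova_2x2(g2, pre2, post2)
  expect_equal(an2$F[an2$effect == "Group:Block"], 0)
  expect_error(rm_anova_2x2(rep("a", 6), rnorm(6), rnorm(6)), "2 groups")
})

test_that("the mixed ANOVA agrees with the reference decomposition on balanced data", {
  set.seed(5)
  g <- rep(c("a", "b"), each = 10)
  pre <- rnorm(20); post <- pre + ifelse(g == "a", 0, 0.5) + rnorm(20, 0, 0.3)
  an <- rm_anova_2x2(g, pre, post)
  dd <- data.frame(y = c(pre, post), blk = rep(c("pre", "post"), each = 20),
                   g = rep(g, 2), id = factor(rep(1:20, 2)))
  av <- summary(aov(y ~ g * blk + Error(id / blk), data = dd))
  within <- av[["Error: id:blk"]][[1]]
  between <- av[["Error: id"]][[1]]
  expect_equal(an$F[an$effect == "Block"], within["blk", "F value"],
               tolerance = 1e-10)
  expect_equal(an$F[an$effect == "Group:Block"], within["g:blk", "F value"],
               tolerance = 1e-10)
  expect_equal(an$F[an$effect == "Group"], between["g", "F value"],
               tolerance = 1e-10)
})

test_that("interaction p values are uniform under label permutation", {
  set.seed(6)
  g <- rep(c("a", "b"), c(18, 14))
  pre <- rnorm(32); post <- pre + rnorm(32, 0.5, 0.4)
  ps <- replicate(1000, {
    gp <- sample(g)
    an <- rm_anova_2x2(gp, pre, post)
    an$p[an$effect == "Group:Block"]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the association battery reports one tidy row per outcome-predictor pair", {
  set.seed(7)
  d <- data.frame(d_dr = rnorm(22), d_th = rnorm(22))
  d$glu <- -0.8 * scale(d$d_dr)[, 1] + 0.6 * rnorm(22)
  d$gaba <- rnorm(22)
  out <- association_battery(d, c("glu", "gaba"))
  expect_equal(nrow(out), 4)
  expect_equal(out$df, rep(19, 4))
  expect_true(out$p[out$outcome == "glu" & out$predictor == "d_dr"] < 0.05)
  expect_equal(out$r, sign(out$t) * sqrt(out$t^2 / (out$t^2 + out$df)))
})
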