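test_that("design matrix has the stacked interaction structure", {
  pr <- timepoint_pair(c(1, 2), c(5, 6), c(3, 4), c(7, 8))
  # n = 4 < 5: df would be 0
  expect_error(build_design(pr), "insufficient animals")
  pr5 <- timepoint_pair(c(1, 2, 9), c(5, 6, 7), c(3, 4), c(7, 8))
  d <- build_design(pr5)
  expect_equal(dim(d$X), c(5L, 4L))
  expect_equal(unname(d$X),
               cbind(c(1, 1, 1, 1, 1), c(0, 0, 0, 1, 1),
                     c(1, 2, 9, 3, 4), c(0, 0, 0, 3, 4)))
  expect_equal(d$y, c(5, 6, 7, 7, 8))
  # interaction column is zero on all group-0 rows
  expect_true(all(d$X[d$X[, 2] == 0, 4] == 0))
})

test_that("OLS reproduces an exactly-interpolating coefficient vector", {
  set.seed(11)
  pr <- random_pair(4, 4)
  d <- build_design(pr)
  y <- drop(d$X %*% c(1, 2, 3, 4))
  fit <- fit_ols(y, d$X)
  expect_equal(fit$beta_hat, c(1, 2, 3, 4), tolerance = 1e-10)
  expect_equal(fit$sse, 0, tolerance = 1e-8)
  expect_equal(fit$df, 4L)
})

test_that("OLS matches the normal-equations solution on a hand dataset", {
  # independent oracle: solve X'X b = X'y directly
  pr <- timepoint_pair(c(1, 2, 4), c(3, 5, 8), c(2, 3, 5), c(6, 9, 13))
  d <- build_design(pr)
  fit <- fit_ols(d$y, d$X, n0 = 3, n1 = 3)
  oracle <- solve(crossprod(d$X), crossprod(d$X, d$y))
  expect_equal(fit$beta_hat, drop(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$xtx_inv, solve(crossprod(d$X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # and against lm()
  lmfit <- lm(d$y ~ d$X[, 2] + d$X[, 3] + d$X[, 4])
  expect_equal(fit$beta_hat, unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(fit$sse, sum(resid(lmfit)^2), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with a named column", {
  pr <- timepoint_pair(c(2, 2, 2), c(1, 2, 3), c(5, 5, 5), c(4, 5, 6))
  d <- build_design(pr)
  expect_error(fit_ols(d$y, d$X), "singular design")
})

test_that("contrast vector substitutes the covariate group means", {
  pr <- timepoint_pair(c(1, 3), c(0, 0), c(4, 6), c(0, 0))
  z <- contrast_vector(pr)
  expect_equal(z$z, c(0, 1, 3, 5))
  # equal covariate means
  pr2 <- timepoint_pair(c(1, 3), c(0, 0), c(0, 4), c(0, 0))
  expect_equal(contrast_vector(pr2)$z, c(0, 1, 0, 2))
  # centered covariates in both groups: contrast picks out the group effect
  pr3 <- timepoint_pair(c(-1, 1), c(0, 0), c(-2, 2), c(0, 0))
  expect_equal(contrast_vector(pr3)$z, c(0, 1, 0, 0))
})

test_that("D-hat equals the raw difference of group means (identity)", {
  for (s in 1:50) {
    pr <- random_pair(n0 = sample(3:8, 1), n1 = sample(3:8, 1), seed = s)
    ht <- homologous_test(pr, group_estimates = FALSE)
    expect_equal(ht$d_hat, mean(pr$y_curr1) - mean(pr$y_curr0),
                 tolerance = 1e-10)
  }
})

test_that("contrast leverage equals 1/n0 + 1/n1 for arbitrary data", {
  for (s in 1:50) {
    n0 <- sample(3:9, 1); n1 <- sample(3:9, 1)
    pr <- random_pair(n0, n1, seed = 100 + s)
    d <- build_design(pr)
    fit <- fit_ols(d$y, d$X)
    z <- contrast_vector(pr)$z
    expect_equal(drop(z %*% fit$xtx_inv %*% z), 1 / n0 + 1 / n1,
                 tolerance = 1e-10)
  }
})

test_that("joint interaction fit decouples into per-group simple regressions", {
  for (s in 1:20) {
    pr <- random_pair(6, 5, seed = 200 + s)
    d <- build_design(pr)
    b <- fit_ols(d$y, d$X)$beta_hat
    f0 <- lm(pr$y_curr0 ~ pr$y_prev0)
    f1 <- lm(pr$y_curr1 ~ pr$y_prev1)
    expect_equal(b[1], unname(coef(f0)[1]), tolerance = 1e-8)
    expect_equal(b[3], unname(coef(f0)[2]), tolerance = 1e-8)
    expect_equal(b[1] + b[2], unname(coef(f1)[1]), tolerance = 1e-8)
    expect_equal(b[3] + b[4], unname(coef(f1)[2]), tolerance = 1e-8)
  }
})

test_that("identical outcome groups give zero difference and p = 1", {
  set.seed(5)
  yc <- rnorm(5)
  pr <- timepoint_pair(rnorm(5), yc, rnorm(5), yc)
  ht <- homologous_test(pr)
  expect_equal(ht$d_hat, 0, tolerance = 1e-12)
  expect_equal(ht$p_value, 1, tolerance = 1e-12)
})

test_that("regression path and conditional path agree on a hand dataset", {
  pr <- random_pair(4, 4, seed = 42)
  ht <- homologous_test(pr)
  ge <- conditional_group_estimates(pr)
  # conditional point estimates are the group means (identity), and match
  # the regression-path decoupled coefficients evaluated at the means
  expect_equal(ge$group0$estimate, mean(pr$y_curr0), tolerance = 1e-12)
  expect_equal(ge$group1$estimate, mean(pr$y_curr1), tolerance = 1e-12)
  b <- ht$fit$beta_hat
  expect_equal(b[1] + b[3] * mean(pr$y_prev0), ge$group0$estimate,
               tolerance = 1e-8)
  expect_equal(b[1] + b[2] + (b[3] + b[4]) * mean(pr$y_prev1),
               ge$group1$estimate, tolerance = 1e-8)
  # pooled SSE equals the sum of the two within-group SSEs
  sse0 <- ge$group0$mse * (pr$n0 - 2)
  sse1 <- ge$group1$mse * (pr$n1 - 2)
  expect_equal(ht$fit$sse, sse0 + sse1, tolerance = 1e-8)
  # from-scratch t and p via the normal equations
  d <- build_design(pr)
  xtx_inv <- solve(crossprod(d$X))
  beta <- drop(xtx_inv %*% crossprod(d$X, d$y))
  z <- c(0, 1, mean(pr$y_prev1) - mean(pr$y_prev0), mean(pr$y_prev1))
  dd <- sum(z * beta)
  mse <- sum((d$y - drop(d$X %*% beta))^2) / 4
  tt <- dd / sqrt(mse * drop(z %*% xtx_inv %*% z))
  expect_equal(ht$t_stat, tt, tolerance = 1e-8)
  expect_equal(ht$p_value, 2 * pt(-abs(tt), 4), tolerance = 1e-10)
})

test_that("conditional estimates handle perfect fits and degenerate covariates", {
  # data on an exact line: zero MSE, |rho| = 1
  pr <- timepoint_pair(c(1, 2, 3), 2 * c(1, 2, 3) + 1,
                       c(1, 2, 4), -c(1, 2, 4) + 10)
  ge <- conditional_group_estimates(pr)
  expect_equal(ge$group0$mse, 0, tolerance = 1e-12)
  expect_equal(ge$group0$se, 0, tolerance = 1e-12)
  expect_equal(abs(ge$group0$rho), 1, tolerance = 1e-12)
  expect_equal(ge$group1$rho, -1, tolerance = 1e-12)
  # constant covariate: rho missing, flagged
  pr2 <- timepoint_pair(c(2, 2, 2), c(1, 2, 3), c(1, 2, 3), c(4, 5, 7))
  ge2 <- conditional_group_estimates(pr2)
  expect_true(is.na(ge2$group0$rho))
  expect_true(ge2$group0$degenerate)
  expect_false(ge2$group1$degenerate)
  # n_g < 3 refused
  expect_error(conditional_group_estimates(
    timepoint_pair(c(1, 2), c(1, 2), c(1, 2, 3), c(1, 2, 3))),
    "n_g >= 3")
  # cross-check against lm on a generic group
  pr3 <- random_pair(6, 6, seed = 8)
  ge3 <- conditional_group_estimates(pr3)
  f <- lm(pr3$y_curr0 ~ pr3$y_prev0)
  expect_equal(ge3$group0$mse, sum(resid(f)^2) / 4, tolerance = 1e-10)
  expect_equal(ge3$group0$slope, unname(coef(f)[2]), tolerance = 1e-10)
  expect_equal(ge3$group0$rho, cor(pr3$y_prev0, pr3$y_curr0),
               tolerance = 1e-12)
})

test_that("one-sided alternatives orient to group 1 minus group 0", {
  pr <- random_pair(5, 5, seed = 77)
  two <- homologous_test(pr, "two.sided", group_estimates = FALSE)
  gt <- homologous_test(pr, "greater", group_estimates = FALSE)
  lt <- homologous_test(pr, "less", group_estimates = FALSE)
  expect_equal(gt$p_value + lt$p_value, 1, tolerance = 1e-12)
  expect_equal(min(gt$p_value, lt$p_value) * 2, two$p_value,
               tolerance = 1e-12)
  # hyphenated spelling accepted
  expect_equal(homologous_test(pr, "two-sided",
                               group_estimates = FALSE)$p_value,
               two$p_value)
})

test_that("strong serial correlation shrinks the homologous SE below s/sqrt(n)", {
  # high-correlation regime: conditional SE beats the conventional SE in
  # nearly all replicates
  set.seed(314)
  wins <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    n <- 12
    yp <- rnorm(n)
    yc <- 2 + 3 * yp + rnorm(n, sd = sqrt(1 - 0.95^2) * 3) # rho ~ 0.95
    pr <- timepoint_pair(yp, yc, rnorm(n), rnorm(n))
    ge <- conditional_group_estimates(pr)
    conv <- sd(yc) / sqrt(n)
    if (ge$group0$se < conv) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95)
})

test_that("test results flatten to the documented record", {
  ht <- homologous_test(random_pair(4, 5, seed = 3))
  rec <- as.data.frame(ht)
  expect_named(rec, c("time_prev", "time_curr", "n0", "n1", "d_hat", "se",
                      "t", "df", "p", "rho0", "rho1", "method"))
  expect_equal(rec$df, 4 + 5 - 4)
  expect_equal(rec$method, "homologous")
})
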