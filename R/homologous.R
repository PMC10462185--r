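#' Build the interaction-model design matrix
#'
#' Stacks the two groups (group 0 first) and builds the n x 4 design of the
#' conditional regression at one time point: columns are intercept, treatment
#' indicator, previous-time volume, and their interaction. The interaction
#' column is identically zero on group-0 rows, so the joint fit decouples into
#' the two within-group simple regressions.
#'
#' @param pair a `timepoint_pair`.
#' @return A list with `y` (response vector, volumes at the current time) and
#'   `X` (the n x 4 design matrix).
#' @export
build_design <- function(pair) {
  n <- pair$n0 + pair$n1
  if (n < 5L) {
    stop(sprintf(
      "insufficient animals for df = n-4 >= 1 (n = %d, need >= 5)", n),
      call. = FALSE)
  }
  x <- rep(c(0, 1), c(pair$n0, pair$n1))
  yprev <- c(pair$y_prev0, pair$y_prev1)
  X <- cbind(1, x, yprev, x * yprev)
  colnames(X) <- c("(Intercept)", "group", "y_prev", "group:y_prev")
  list(y = c(pair$y_curr0, pair$y_curr1), X = X)
}

#' Ordinary least squares with the sum-of-squares bookkeeping the test needs
#'
#' Fits the four-parameter interaction model by QR factorization and returns
#' the pieces the contrast variance requires: coefficients, the inverse
#' cross-product matrix, the residual sum of squares SSE = Y'Y - b'X'Y, and
#' MSE = SSE/(n-4).
#'
#' @param y response vector.
#' @param X design matrix from [build_design()].
#' @param n0,n1 per-group counts (carried through for downstream df/report).
#' @return A list of class `hom_regfit` with `beta_hat`, `xtx_inv`, `sse`,
#'   `mse`, `df`, `n0`, `n1`.
#' @export
fit_ols <- function(y, X, n0 = NULL, n1 = NULL) {
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- qrx$pivot[(qrx$rank + 1L):p]
    stop(sprintf(
      "singular design: column(s) %s collinear (within-group-constant covariate?)",
      paste(colnames(X)[bad], collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  # invert X'X = R'R, undoing any pivoting of the factorization
  R <- qr.R(qrx)
  inv_perm <- chol2inv(R)
  piv <- qrx$pivot
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- inv_perm
  df <- length(y) - p
  sse <- max(sum(y * y) - sum(beta * crossprod(X, y)), 0)
  structure(list(
    beta_hat = unname(beta), xtx_inv = xtx_inv,
    sse = sse, mse = sse / df, df = df,
    n0 = n0, n1 = n1
  ), class = "hom_regfit")
}

#' Contrast vector for the group-mean difference
#'
#' The difference in conditional group means, each evaluated at its own
#' group's observed covariate mean, is the linear combination
#' z = (0, 1, m1 - m0, m1) of the interaction-model coefficients, where m_g is
#' group g's sample mean volume at the previous time point.
#'
#' @param pair a `timepoint_pair`.
#' @return A list of class `hom_contrast` with the 1 x 4 vector `z` and the
#'   covariate means `ybar_prev_0`, `ybar_prev_1`.
#' @export
contrast_vector <- function(pair) {
  m0 <- mean(pair$y_prev0)
  m1 <- mean(pair$y_prev1)
  structure(list(z = c(0, 1, m1 - m0, m1),
                 ybar_prev_0 = m0, ybar_prev_1 = m1),
            class = "hom_contrast")
}

#' Homologous hypothesis test at one time point
#'
#' Tests equality of the two groups' mean tumor volumes at the current time
#' point, each conditioned on its group's observed mean at the preceding time
#' point. The estimate D-hat is numerically identical to the raw difference
#' of group sample means; its standard error comes from the interaction
#' regression (pooled MSE, n-4 df), which shrinks with the serial correlation
#' and is what gives the test its power advantage over the plain t-test.
#'
#' @param pair a `timepoint_pair`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   directions refer to group 1 minus group 0. `"two-sided"` is accepted as
#'   an alias.
#' @param group_estimates if `TRUE` (default), attach the per-group
#'   conditional estimates, homologous SEs and serial correlations from
#'   [conditional_group_estimates()].
#' @return A list of class `homologous_test` with `d_hat`, `se`, `t_stat`,
#'   `df`, `p_value`, `alternative`, the regression fit, the contrast, and
#'   (optionally) `group_estimates` and `correlations`.
#' @export
homologous_test <- function(pair,
                            alternative = c("two.sided", "greater", "less"),
                            group_estimates = TRUE) {
  if (identical(alternative, "two-sided")) alternative <- "two.sided"
  alternative <- match.arg(alternative)
  d <- build_design(pair)
  fit <- fit_ols(d$y, d$X, n0 = pair$n0, n1 = pair$n1)
  ctr <- contrast_vector(pair)
  z <- ctr$z
  d_hat <- sum(z * fit$beta_hat)
  se <- sqrt(fit$mse * drop(z %*% fit$xtx_inv %*% z))
  t_stat <- if (se > 0) d_hat / se else if (d_hat == 0) 0 else sign(d_hat) * Inf
  p_value <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t_stat), fit$df),
    greater = stats::pt(t_stat, fit$df, lower.tail = FALSE),
    less = stats::pt(t_stat, fit$df)
  )
  res <- list(
    d_hat = d_hat, se = se, t_stat = t_stat, df = fit$df,
    p_value = p_value, alternative = alternative,
    n0 = pair$n0, n1 = pair$n1,
    time_prev = pair$time_prev, time_curr = pair$time_curr,
    fit = fit, contrast = ctr,
    group_labels = pair$group_labels,
    method = "homologous"
  )
  if (group_estimates) {
    ge <- conditional_group_estimates(pair)
    res$group_estimates <- ge
    res$correlations <- c(rho0 = ge$group0$rho, rho1 = ge$group1$rho)
  }
  class(res) <- "homologous_test"
  res
}

#' Per-group conditional estimates (the descriptive path)
#'
#' For each group separately, regresses the current-time volumes on the
#' previous-time volumes. Evaluated at the group's own covariate mean the
#' fitted value is exactly the group sample mean at the current time; its
#' estimated variance is MSE_g / n_g with MSE_g on n_g - 2 degrees of
#' freedom. These are the "homologous" point estimates and SEs reported per
#' group in scan tables; the test's p-value itself comes from the pooled
#' regression path in [homologous_test()].
#'
#' @param pair a `timepoint_pair`; each group needs at least 3 animals.
#' @return A list of class `hom_group_estimates` with components `group0` and
#'   `group1`, each holding `estimate` (= group mean at the current time),
#'   `se` (sqrt(MSE_g/n_g)), `rho` (Pearson correlation with the previous
#'   time point, `NA` if a variance is zero), `mse`, `slope`, `intercept`,
#'   `n`, and a `degenerate` flag set when the covariate has zero
#'   within-group variance.
#' @export
conditional_group_estimates <- function(pair) {
  one_group <- function(yp, yc) {
    n <- length(yp)
    if (n < 3L) {
      stop(sprintf("conditional estimates need n_g >= 3 (got %d)", n),
           call. = FALSE)
    }
    sxx <- sum((yp - mean(yp))^2)
    syy <- sum((yc - mean(yc))^2)
    sxy <- sum((yp - mean(yp)) * (yc - mean(yc)))
    degenerate <- sxx <= 0
    if (degenerate) {
      slope <- NA_real_
      intercept <- NA_real_
      mse <- NA_real_
      se <- NA_real_
    } else {
      slope <- sxy / sxx
      intercept <- mean(yc) - slope * mean(yp)
      resid <- yc - (intercept + slope * yp)
      mse <- sum(resid^2) / (n - 2)
      se <- sqrt(mse / n)
    }
    rho <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
    list(estimate = mean(yc), se = se, rho = rho, mse = mse,
         slope = slope, intercept = intercept, n = n,
         degenerate = degenerate)
  }
  structure(list(group0 = one_group(pair$y_prev0, pair$y_curr0),
                 group1 = one_group(pair$y_prev1, pair$y_curr1)),
            class = "hom_group_estimates")
}

#' Flatten a test result to a single record
#'
#' @param x a `homologous_test`.
#' @return A one-row data frame with fields `time_prev`, `time_curr`, `n0`,
#'   `n1`, `d_hat`, `se`, `t`, `df`, `p`, `rho0`, `rho1`, `method`.
#' @export
as.data.frame.homologous_test <- function(x, ...) {
  data.frame(
    time_prev = x$time_prev, time_curr = x$time_curr,
    n0 = x$n0, n1 = x$n1,
    d_hat = x$d_hat, se = x$se, t = x$t_stat, df = x$df, p = x$p_value,
    rho0 = if (!is.null(x$correlations)) x$correlations[["rho0"]] else NA_real_,
    rho1 = if (!is.null(x$correlations)) x$correlations[["rho1"]] else NA_real_,
    method = x$method,
    stringsAsFactors = FALSE
  )
}

#' @export
print.homologous_test <- function(x, ...) {
  labs <- x$group_labels
  cat("Homologous hypothesis test (conditional on previous time point)\n")
  cat(sprintf("  time %s | %s;  n0 = %d, n1 = %d\n",
              format(x$time_curr), format(x$time_prev), x$n0, x$n1))
  cat(sprintf("  D-hat (%s - %s) = %.6g,  SE = %.6g\n",
              labs[["1"]], labs[["0"]], x$d_hat, x$se))
  cat(sprintf("  t = %.4f on %d df,  p = %.4g (%s)\n",
              x$t_stat, x$df, x$p_value, x$alternative))
  if (!is.null(x$correlations)) {
    cat(sprintf("  serial correlation: rho0 = %.3f, rho1 = %.3f\n",
                x$correlations[["rho0"]], x$correlations[["rho1"]]))
  }
  invisible(x)
}
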