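#' Parameters of the synthetic tumor-growth generator
#'
#' The generator emulates the structure of a two-arm xenograft study:
#' per-animal log-volume trajectories that are linear in time with a random
#' intercept and a stationary AR(1) residual across successive measurement
#' occasions, then exponentiated to the raw mm^3 scale. High `ar1_phi` gives
#' the strong adjacent-time-point correlation (typically 0.7-0.99) that the
#' homologous test exploits.
#'
#' Defaults describe a small study of 4 animals per arm measured on days
#' 3-24, starting near 4 mm^3 and growing to a few hundred mm^3 by day 24
#' (log-scale growth ~0.2/day in the control arm), with a modest
#' growth-slowing treatment effect.
#'
#' @param n_per_group animals per arm.
#' @param times strictly increasing measurement days.
#' @param log_intercept_mean,log_intercept_sd mean and between-animal SD of
#'   the log-volume intercept (at time 0).
#' @param growth_rate group-0 log-volume slope per day.
#' @param treatment_effect additive change in slope for group 1
#'   (group 1 minus group 0; negative = growth delay).
#' @param ar1_phi lag-1 autocorrelation of the residual process, |phi| < 1.
#' @param noise_sd marginal SD of the residual process on the log scale,
#'   >= 0.
#' @param seed integer RNG seed.
#' @param group_labels length-2 character vector, labels for groups 0 and 1.
#' @return A list of class `growth_sim_params`.
#' @export
growth_sim_params <- function(n_per_group = 4L,
                              times = c(3, 5, 7, 12, 14, 17, 19, 21, 24),
                              log_intercept_mean = log(4),
                              log_intercept_sd = 0.1,
                              growth_rate = 0.2,
                              treatment_effect = -0.03,
                              ar1_phi = 0.95,
                              noise_sd = 0.3,
                              seed = 1L,
                              group_labels = c("control", "treated")) {
  stopifnot(n_per_group >= 1L,
            length(times) >= 2L, all(diff(times) > 0),
            noise_sd >= 0, abs(ar1_phi) < 1,
            length(group_labels) == 2L)
  structure(list(
    n_per_group = as.integer(n_per_group), times = as.numeric(times),
    log_intercept_mean = log_intercept_mean,
    log_intercept_sd = log_intercept_sd,
    growth_rate = growth_rate, treatment_effect = treatment_effect,
    ar1_phi = ar1_phi, noise_sd = noise_sd, seed = as.integer(seed),
    group_labels = group_labels
  ), class = "growth_sim_params")
}

#' Generate a synthetic two-group longitudinal study
#'
#' Per animal i in group g, over the measurement grid:
#' `log V_i(t) = a_i + s_g * t + e_i(t)` with `a_i ~ N(mu, tau^2)`,
#' `s_1 = s_0 + treatment effect`, and `e_i` a stationary AR(1) process over
#' successive occasions (marginal SD `noise_sd`, lag-1 correlation
#' `ar1_phi`). Volumes are returned on the raw scale. Deterministic under
#' the seed.
#'
#' @param params a `growth_sim_params`.
#' @return A `study_table`.
#' @export
generate_growth_study <- function(params) {
  set.seed(params$seed)
  m <- length(params$times)
  rows_id <- character(0)
  rows_g <- integer(0)
  rows_t <- numeric(0)
  rows_v <- numeric(0)
  for (g in 0:1) {
    slope <- params$growth_rate + g * params$treatment_effect
    for (i in seq_len(params$n_per_group)) {
      a <- stats::rnorm(1, params$log_intercept_mean,
                        params$log_intercept_sd)
      e <- numeric(m)
      if (params$noise_sd > 0) {
        e[1] <- stats::rnorm(1, sd = params$noise_sd)
        if (m > 1) {
          innov_sd <- params$noise_sd * sqrt(1 - params$ar1_phi^2)
          for (k in 2:m) {
            e[k] <- params$ar1_phi * e[k - 1] +
              stats::rnorm(1, sd = innov_sd)
          }
        }
      }
      id <- sprintf("%s_%02d", c("c", "t")[g + 1], i)
      rows_id <- c(rows_id, rep(id, m))
      rows_g <- c(rows_g, rep(g, m))
      rows_t <- c(rows_t, params$times)
      rows_v <- c(rows_v, exp(a + slope * params$times + e))
    }
  }
  study_table(rows_id, rows_g, rows_t, rows_v,
              group_labels = stats::setNames(params$group_labels,
                                             c("0", "1")),
              volume_scale = "raw")
}
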