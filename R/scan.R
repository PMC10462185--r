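#' Scan every time point of a study
#'
#' Applies the homologous test and the classical two-sample t-test at each
#' observed time point and assembles a report table: per-group means,
#' conventional SEs (s_g/sqrt(n_g)), homologous SEs (sqrt(MSE_g/n_g)), serial
#' correlation with the previous time point, and both p-values. The earliest
#' time point has no predecessor and carries only the t-test; a degenerate
#' homologous fit (e.g. a within-group-constant covariate) falls back to
#' missing homologous fields with a warning, never to a silently substituted
#' p-value.
#'
#' @param study a `study_table`.
#' @param alternative passed to both tests; default `"two.sided"`.
#' @param t_variant `"pooled"` (default) or `"welch"`.
#' @param log_transform if `TRUE`, volumes are natural-log transformed before
#'   testing (only for raw-scale studies).
#' @param adjust `"none"` (default) or `"holm"`: optional multiplicity
#'   adjustment of each p-value column across time points.
#' @return A data frame of class `scan_table`, one row per time point sorted
#'   ascending, columns `time, n0, n1, mean0, se0_conv, se0_hom, rho0, mean1,
#'   se1_conv, se1_hom, rho1, d_hat, p_hom, p_ttest`. Options used are kept
#'   in the `"options"` attribute.
#' @export
scan_study <- function(study, alternative = "two.sided",
                       t_variant = c("pooled", "welch"),
                       log_transform = FALSE,
                       adjust = c("none", "holm")) {
  t_variant <- match.arg(t_variant)
  adjust <- match.arg(adjust)
  times <- sort(unique(study$time))
  if (length(times) < 2L) {
    stop("study has fewer than 2 time points; nothing to scan", call. = FALSE)
  }
  if (log_transform) {
    if (identical(attr(study, "volume_scale"), "log")) {
      stop("study is already on the log scale", call. = FALSE)
    }
    study$volume <- log(study$volume)
  }
  rows <- vector("list", length(times))
  for (k in seq_along(times)) {
    tk <- times[k]
    y0 <- study$volume[study$group == 0 & study$time == tk]
    y1 <- study$volume[study$group == 1 & study$time == tk]
    row <- data.frame(
      time = tk, n0 = length(y0), n1 = length(y1),
      mean0 = mean(y0), se0_conv = stats::sd(y0) / sqrt(length(y0)),
      se0_hom = NA_real_, rho0 = NA_real_,
      mean1 = mean(y1), se1_conv = stats::sd(y1) / sqrt(length(y1)),
      se1_hom = NA_real_, rho1 = NA_real_,
      d_hat = mean(y1) - mean(y0),
      p_hom = NA_real_, p_ttest = NA_real_
    )
    row$p_ttest <- two_sample_t(y0, y1, variant = t_variant,
                                alternative = alternative)$p_value
    if (k > 1L) {
      ht <- tryCatch(
        homologous_test(suppressWarnings(extract_pair(study, tk)),
                        alternative = alternative),
        error = function(e) {
          warning(sprintf(
            "time %s: homologous fit unavailable (%s); classical test only",
            format(tk), conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(ht)) {
        row$p_hom <- ht$p_value
        row$se0_hom <- ht$group_estimates$group0$se
        row$se1_hom <- ht$group_estimates$group1$se
        row$rho0 <- ht$group_estimates$group0$rho
        row$rho1 <- ht$group_estimates$group1$rho
      }
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    ok <- !is.na(out$p_hom)
    out$p_hom[ok] <- stats::p.adjust(out$p_hom[ok], method = "holm")
    out$p_ttest <- stats::p.adjust(out$p_ttest, method = "holm")
  }
  rownames(out) <- NULL
  attr(out, "options") <- list(alternative = alternative,
                               t_variant = t_variant,
                               log_transform = log_transform,
                               adjust = adjust)
  attr(out, "group_labels") <- attr(study, "group_labels")
  class(out) <- c("scan_table", "data.frame")
  out
}

#' Write a scan table to CSV
#'
#' Stable column order; missing homologous fields are written as empty
#' fields.
#'
#' @param scan a `scan_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  cols <- c("time", "n0", "n1", "mean0", "se0_conv", "se0_hom", "rho0",
            "mean1", "se1_conv", "se1_hom", "rho1", "d_hat", "p_hom",
            "p_ttest")
  utils::write.csv(as.data.frame(scan)[, cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read a scan table written by [write_scan_csv()]
#'
#' @param path CSV file path.
#' @return A `scan_table` data frame (options attribute not restored).
#' @export
read_scan_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("scan_table", "data.frame")
  out
}

#' @export
print.scan_table <- function(x, digits = 4, ...) {
  cat(sprintf("scan_table: %d time points\n", nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
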