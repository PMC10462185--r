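#' Construct a study table
#'
#' A `study_table` holds a two-group longitudinal tumor-volume study in long
#' format: one row per animal per measurement time. Group membership is coded
#' 0/1 internally; display labels are kept in the `group_labels` attribute so
#' that the direction of every reported difference (group 1 minus group 0) is
#' unambiguous.
#'
#' @param animal_id character vector of animal identifiers.
#' @param group integer vector of 0/1 treatment codes.
#' @param time numeric vector of measurement times (study units, e.g. days).
#' @param volume numeric vector of nonnegative tumor volumes.
#' @param group_labels named character vector mapping `c("0", "1")` to display
#'   labels.
#' @param volume_scale `"raw"` (mm^3) or `"log"` (natural-log mm^3).
#'
#' @return A data frame of class `study_table` with columns `animal_id`,
#'   `group`, `time`, `volume`.
#' @export
study_table <- function(animal_id, group, time, volume,
                        group_labels = c("0" = "group0", "1" = "group1"),
                        volume_scale = c("raw", "log")) {
  volume_scale <- match.arg(volume_scale)
  df <- data.frame(
    animal_id = as.character(animal_id),
    group = as.integer(group),
    time = as.numeric(time),
    volume = as.numeric(volume),
    stringsAsFactors = FALSE
  )
  attr(df, "group_labels") <- group_labels
  attr(df, "volume_scale") <- volume_scale
  class(df) <- c("study_table", "data.frame")
  rep_ <- validate_study(df)
  if (length(rep_$errors) > 0L) {
    stop("invalid study table: ", paste(rep_$errors, collapse = "; "),
         call. = FALSE)
  }
  df
}

#' Validate a study table
#'
#' Checks the structural invariants a usable study must satisfy: unique
#' (animal, time) measurements, one group per animal, both groups present,
#' and at least two distinct time points.
#'
#' @param study a `study_table` (or plain data frame with the same columns).
#' @return A list of class `validation_report` with character vectors
#'   `errors` and `warnings`. The study is usable iff `errors` is empty.
#' @export
validate_study <- function(study) {
  errors <- character()
  warnings <- attr(study, "validation_warnings") %||% character()
  if (anyDuplicated(study[, c("animal_id", "time")])) {
    dup <- study[duplicated(study[, c("animal_id", "time")]), , drop = FALSE]
    errors <- c(errors, sprintf(
      "duplicate (animal_id, time) measurement(s): %s",
      paste(unique(paste0(dup$animal_id, "@", dup$time)), collapse = ", ")))
  }
  gr_per_animal <- tapply(study$group, study$animal_id,
                          function(g) length(unique(g)))
  if (any(gr_per_animal > 1L)) {
    errors <- c(errors, sprintf(
      "animal(s) assigned to more than one group: %s",
      paste(names(gr_per_animal)[gr_per_animal > 1L], collapse = ", ")))
  }
  if (length(unique(study$time)) < 2L) {
    errors <- c(errors, "fewer than 2 distinct time points")
  }
  for (g in 0:1) {
    if (!any(study$group == g)) {
      errors <- c(errors, sprintf("group %d is empty", g))
    }
  }
  if (any(!is.finite(study$volume))) {
    errors <- c(errors, "non-finite volumes present")
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format tumor-volume CSV
#'
#' Expects a header row and columns resolvable to animal id, group, time and
#' volume. Group values may be 0/1 or exactly two arbitrary labels; labels are
#' mapped to 0/1 in first-seen order unless `group_map` says otherwise. Rows
#' with missing volume or time are dropped with a warning recorded in the
#' attached validation report.
#'
#' @param source path to a CSV file, or a character vector of CSV text lines.
#' @param column_map optional named character vector mapping the canonical
#'   names `animal_id`, `group`, `time`, `volume` to the file's column names.
#' @param group_map optional named integer vector mapping group labels to 0/1,
#'   e.g. `c(control = 0, treated = 1)`.
#' @param log_transform if `TRUE`, volumes are natural-log transformed on
#'   read and the table is marked `volume_scale = "log"`.
#'
#' @return A validated `study_table`; the per-read `validation_report` is
#'   attached as attribute `"validation"`.
#' @export
read_long_table <- function(source, column_map = NULL, group_map = NULL,
                            log_transform = FALSE) {
  if (length(source) == 1L && file.exists(source)) {
    raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                           check.names = FALSE)
  } else {
    raw <- utils::read.csv(text = paste(source, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  }
  defaults <- c(animal_id = "animal_id", group = "group",
                time = "time", volume = "volume")
  cmap <- defaults
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!cmap %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in input: ",
         paste(sprintf("'%s'", missing_cols), collapse = ", "), call. = FALSE)
  }
  warnings <- character()

  time_num <- suppressWarnings(as.numeric(raw[[cmap["time"]]]))
  vol_num <- suppressWarnings(as.numeric(raw[[cmap["volume"]]]))
  time_raw <- raw[[cmap["time"]]]
  vol_raw <- raw[[cmap["volume"]]]
  bad_time <- which(is.na(time_num) & !is.na(time_raw) &
                      !toupper(trimws(as.character(time_raw))) %in% c("NA", ""))
  bad_vol <- which(is.na(vol_num) & !is.na(vol_raw) &
                     !toupper(trimws(as.character(vol_raw))) %in% c("NA", ""))
  if (length(bad_time) > 0L) {
    stop(sprintf("non-numeric time value at data row %d: '%s'",
                 bad_time[1L], time_raw[bad_time[1L]]), call. = FALSE)
  }
  if (length(bad_vol) > 0L) {
    stop(sprintf("non-numeric volume value at data row %d: '%s'",
                 bad_vol[1L], vol_raw[bad_vol[1L]]), call. = FALSE)
  }
  keep <- !is.na(time_num) & !is.na(vol_num)
  if (any(!keep)) {
    warnings <- c(warnings, sprintf(
      "%d record(s) dropped for missing time or volume (rows %s)",
      sum(!keep), paste(which(!keep), collapse = ", ")))
  }

  grp_raw <- as.character(raw[[cmap["group"]]])[keep]
  labels <- unique(grp_raw)
  if (length(labels) > 2L) {
    stop("more than 2 group labels found: ",
         paste(sprintf("'%s'", labels), collapse = ", "), call. = FALSE)
  }
  if (is.null(group_map)) {
    if (all(labels %in% c("0", "1"))) {
      group_map <- stats::setNames(as.integer(labels), labels)
    } else {
      group_map <- stats::setNames(seq_along(labels) - 1L, labels)
    }
  }
  grp <- unname(group_map[grp_raw])
  vol <- vol_num[keep]
  if (log_transform) vol <- log(vol)

  out <- study_table(
    animal_id = as.character(raw[[cmap["animal_id"]]])[keep],
    group = grp,
    time = time_num[keep],
    volume = vol,
    group_labels = stats::setNames(names(sort(group_map)),
                                   as.character(sort(group_map))),
    volume_scale = if (log_transform) "log" else "raw"
  )
  attr(out, "validation_warnings") <- warnings
  attr(out, "validation") <- validate_study(out)
  out
}

#' Write a study table to long-format CSV
#'
#' Inverse of [read_long_table()]: writes columns `animal_id`, `group`,
#' `time`, `volume` with the display labels restored in `group`.
#'
#' @param study a `study_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(study, path) {
  labs <- attr(study, "group_labels")
  out <- data.frame(
    animal_id = study$animal_id,
    group = unname(labs[as.character(study$group)]),
    time = study$time,
    volume = study$volume,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract adjacent-time-point pairs
#'
#' For a chosen time point, pairs each animal's volume with its volume at the
#' immediately preceding observed time point (sorted numeric order). Pairing
#' is complete-case per pair: an animal enters the time-`time_curr` test only
#' if it was measured at both times. Vector order within a group is stable by
#' animal id.
#'
#' @param study a `study_table`.
#' @param time_curr an observed time point other than the earliest one.
#' @return A list of class `timepoint_pair` with elements `time_prev`,
#'   `time_curr`, per-group paired vectors `y_prev0`, `y_curr0`, `y_prev1`,
#'   `y_curr1`, pair counts `n0`, `n1`, the per-group number of animals
#'   dropped for missing one of the two measurements (`dropped0`, `dropped1`)
#'   and the study's `group_labels`.
#' @export
extract_pair <- function(study, time_curr) {
  times <- sort(unique(study$time))
  idx <- match(time_curr, times)
  if (is.na(idx)) {
    stop(sprintf("time %s is not an observed time point", time_curr),
         call. = FALSE)
  }
  if (idx == 1L) {
    stop(sprintf("time %s has no preceding time point", time_curr),
         call. = FALSE)
  }
  time_prev <- times[idx - 1L]
  out <- list(time_prev = time_prev, time_curr = time_curr)
  for (g in 0:1) {
    sub <- study[study$group == g, , drop = FALSE]
    prev <- sub[sub$time == time_prev, , drop = FALSE]
    curr <- sub[sub$time == time_curr, , drop = FALSE]
    ids <- sort(intersect(prev$animal_id, curr$animal_id))
    n_group <- length(unique(sub$animal_id))
    if (length(ids) == 0L) {
      stop(sprintf(
        "group %d has no animal measured at both times %s and %s",
        g, time_prev, time_curr), call. = FALSE)
    }
    out[[paste0("y_prev", g)]] <- prev$volume[match(ids, prev$animal_id)]
    out[[paste0("y_curr", g)]] <- curr$volume[match(ids, curr$animal_id)]
    out[[paste0("n", g)]] <- length(ids)
    out[[paste0("dropped", g)]] <- n_group - length(ids)
    if (n_group > length(ids)) {
      warning(sprintf(
        "group %d: %d animal(s) dropped at times (%s, %s) for missing one measurement",
        g, n_group - length(ids), time_prev, time_curr), call. = FALSE)
    }
  }
  out$group_labels <- attr(study, "group_labels")
  class(out) <- "timepoint_pair"
  out
}

#' Construct a timepoint pair directly from vectors
#'
#' Convenience constructor used by the simulation engine and by tests; bypasses
#' the long-table representation.
#'
#' @param y_prev0,y_curr0 paired volumes for group 0.
#' @param y_prev1,y_curr1 paired volumes for group 1.
#' @param time_prev,time_curr nominal time values.
#' @return A `timepoint_pair`.
#' @export
timepoint_pair <- function(y_prev0, y_curr0, y_prev1, y_curr1,
                           time_prev = 0, time_curr = 1) {
  stopifnot(length(y_prev0) == length(y_curr0),
            length(y_prev1) == length(y_curr1),
            length(y_prev0) >= 1L, length(y_prev1) >= 1L)
  structure(list(
    time_prev = time_prev, time_curr = time_curr,
    y_prev0 = as.numeric(y_prev0), y_curr0 = as.numeric(y_curr0),
    y_prev1 = as.numeric(y_prev1), y_curr1 = as.numeric(y_curr1),
    n0 = length(y_prev0), n1 = length(y_prev1),
    dropped0 = 0L, dropped1 = 0L,
    group_labels = c("0" = "group0", "1" = "group1")
  ), class = "timepoint_pair")
}

#' @export
print.study_table <- function(x, ...) {
  labs <- attr(x, "group_labels")
  cat(sprintf(
    "study_table: %d records, %d animals, %d time points (%s scale)\n",
    nrow(x), length(unique(x$animal_id)), length(unique(x$time)),
    attr(x, "volume_scale")))
  cat(sprintf("  groups: 0 = %s (n=%d), 1 = %s (n=%d)\n",
              labs[["0"]], length(unique(x$animal_id[x$group == 0])),
              labs[["1"]], length(unique(x$animal_id[x$group == 1]))))
  NextMethod()
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:",
      if (length(x$errors) == 0L) "OK" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
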