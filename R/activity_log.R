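#' Construct a single activity trial
#'
#' A trial is one subject's ordered list of (activity, duration) events
#' observed inside a fixed window of `window_min` minutes. It is the unit that
#' is later encoded as one behavioral spectrum.
#'
#' @param subject_id,trial_id identifier strings.
#' @param events data frame with columns `seq_index` (1..K, contiguous),
#'   `activity` (name), `activity_id` (integer ID from the vocabulary),
#'   `duration_min` (positive minutes) and optionally `start_time`
#'   (ISO-8601-style clock time `HH:MM[:SS]`, or `NA`).
#' @param window_min observation-window length W in minutes; the event
#'   durations must sum to at most W.
#' @param period optional day-period tag, one of `"morning"`, `"afternoon"`,
#'   `"night"`.
#' @param d_min minimum legal event duration in minutes (default 1).
#' @param k_max maximum number of events per trial (default 90, below the
#'   Nyquist limit of the 200-point spectrum).
#' @return A validated `habit_trial` object.
#' @export
trial <- function(subject_id, trial_id, events, window_min, period = NA_character_,
                  d_min = 1, k_max = 90) {
  if (!"start_time" %in% names(events)) events$start_time <- NA_character_
  events <- events[order(events$seq_index),
                   c("seq_index", "activity", "activity_id", "duration_min", "start_time")]
  rownames(events) <- NULL
  x <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         period = as.character(period),
         window_min = as.numeric(window_min),
         events = events),
    class = "habit_trial"
  )
  validate_trial(x, d_min = d_min, k_max = k_max)
  x
}

PERIODS <- c("morning", "afternoon", "night")

#' Validate a trial against the data-model invariants
#'
#' Checks contiguous sequence indices 1..K, positive durations at least
#' `d_min`, total duration at most the window length, K at most `k_max`, and a
#' legal period tag when present.
#'
#' @inheritParams trial
#' @param x a `habit_trial`.
#' @return `x`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_trial <- function(x, d_min = 1, k_max = 90) {
  ev <- x$events
  lab <- paste0(x$subject_id, "/", x$trial_id)
  abort_if(nrow(ev) < 1L, "trial ", lab, ": needs at least one event")
  abort_if(!identical(as.integer(ev$seq_index), seq_len(nrow(ev))),
           "trial ", lab, ": seq_index must be contiguous 1..K with no gaps")
  abort_if(nrow(ev) > k_max, "trial ", lab, ": K = ", nrow(ev),
           " exceeds k_max = ", k_max)
  abort_if(anyNA(ev$duration_min) || any(ev$duration_min < d_min),
           "trial ", lab, ": durations must be >= d_min (", d_min, " min)")
  abort_if(sum(ev$duration_min) > x$window_min + 1e-9,
           "trial ", lab, ": durations sum to ", sum(ev$duration_min),
           " min, exceeding the ", x$window_min, " min window")
  abort_if(anyNA(ev$activity_id) || any(ev$activity_id < 1L),
           "trial ", lab, ": activity ids must be positive integers")
  abort_if(!is.na(x$period) && !x$period %in% PERIODS,
           "trial ", lab, ": period must be one of ", paste(PERIODS, collapse = ", "))
  invisible(x)
}

#' @export
print.habit_trial <- function(x, ...) {
  cat(sprintf("Trial %s/%s (%s): %d events in %g min window\n",
              x$subject_id, x$trial_id,
              if (is.na(x$period)) "untagged" else x$period,
              nrow(x$events), x$window_min))
  print.data.frame(x$events, row.names = FALSE)
  invisible(x)
}

LOG_COLUMNS <- c("subject_id", "trial_id", "period", "seq_index", "activity",
                 "start_time", "duration_min")

#' Load an activity log CSV into validated trials
#'
#' The canonical dialect is comma-separated UTF-8 with a header row and columns
#' `subject_id, trial_id, seq_index, activity, duration_min` (plus optional
#' `period` and `start_time`). Rows are grouped by (subject, trial) and sorted
#' by `seq_index`; activity names are resolved against `vocab`.
#'
#' @param path CSV file path.
#' @param vocab an [activity_vocab()].
#' @param window_min observation-window length in minutes applied to every
#'   trial.
#' @inheritParams trial
#' @return A list of `habit_trial` objects (empty for a header-only file),
#'   ordered by first appearance in the file.
#' @export
load_activity_log <- function(path, vocab, window_min, d_min = 1, k_max = 90) {
  abort_if(!file.exists(path), "activity log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "trial_id", "seq_index", "activity", "duration_min")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0L,
           "activity log is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  if (!"period" %in% names(df)) df$period <- NA_character_
  if (!"start_time" %in% names(df)) df$start_time <- NA_character_
  df$period[!nzchar(df$period) | is.na(df$period)] <- NA_character_
  df$start_time[!nzchar(df$start_time) | is.na(df$start_time)] <- NA_character_

  ids <- vocab_id(vocab, df$activity)
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop("unknown activity '", df$activity[bad], "' at data row ", bad,
         " (subject ", df$subject_id[bad], ", trial ", df$trial_id[bad], ")",
         call. = FALSE)
  }
  df$activity_id <- ids
  df$seq_index <- as.integer(df$seq_index)
  df$duration_min <- as.numeric(df$duration_min)
  abort_if(anyNA(df$seq_index), "non-integer seq_index in activity log")
  abort_if(anyNA(df$duration_min), "non-numeric duration_min in activity log")

  key <- paste(df$subject_id, df$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    abort_if(anyDuplicated(g$seq_index) > 0L,
             "duplicate seq_index in trial ", g$subject_id[1], "/", g$trial_id[1])
    period <- unique(g$period)
    abort_if(length(period) > 1L,
             "conflicting period tags in trial ", g$subject_id[1], "/", g$trial_id[1])
    trial(g$subject_id[1], g$trial_id[1],
          events = g[c("seq_index", "activity", "activity_id", "duration_min",
                       "start_time")],
          window_min = window_min, period = period,
          d_min = d_min, k_max = k_max)
  }) |> unname()
}

#' Write trials back to the canonical activity-log CSV
#'
#' Inverse of [load_activity_log()]: `load_activity_log(write_activity_log(x))`
#' reproduces `x` exactly (durations are written with full double precision).
#'
#' @param trials list of `habit_trial` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_log <- function(trials, path) {
  header <- paste(LOG_COLUMNS, collapse = ",")
  rows <- unlist(lapply(trials, function(tr) {
    ev <- tr$events
    paste(tr$subject_id, tr$trial_id,
          ifelse(is.na(tr$period), "", tr$period),
          ev$seq_index, ev$activity,
          ifelse(is.na(ev$start_time), "", ev$start_time),
          format_num(ev$duration_min),
          sep = ",")
  }))
  writeLines(c(header, rows), con = path, useBytes = TRUE)
  invisible(path)
}

#' Assign a day period to a trial from its start time
#'
#' Partitions the day into morning `[00:00, 12:00)`, afternoon
#' `[12:00, 18:00)` (the window after lunch and before 6 pm) and night
#' `[18:00, 24:00)`, half-open. An explicit period tag always wins; otherwise
#' the first event's start time decides. Idempotent.
#'
#' @param x a `habit_trial`.
#' @param boundaries clock times (noon, evening) separating the three periods.
#' @return The trial with its `period` field set.
#' @export
assign_period <- function(x, boundaries = c("12:00", "18:00")) {
  stopifnot(inherits(x, "habit_trial"), length(boundaries) == 2L)
  if (!is.na(x$period)) return(x)
  st <- x$events$start_time[1]
  abort_if(is.na(st), "trial ", x$subject_id, "/", x$trial_id,
           ": no start_time on first event and no period tag")
  h <- parse_clock(st)
  noon <- parse_clock(boundaries[1])
  evening <- parse_clock(boundaries[2])
  abort_if(noon >= evening, "period boundaries must be increasing")
  x$period <- if (h < noon) "morning" else if (h < evening) "afternoon" else "night"
  x
}
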