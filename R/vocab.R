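#' Activity vocabulary
#'
#' An ordered mapping from activity names to contiguous integer IDs starting
#' at 1. The ID of an activity sets the phase of the harmonic carrying that
#' activity in a behavioral spectrum, so the vocabulary must be fixed before
#' encoding and shared by every trial in an analysis.
#'
#' @param activities character vector of unique, non-empty activity names; IDs
#'   are assigned 1..M in the order given.
#' @return An `activity_vocab` object: a data frame with columns `activity`
#'   and `id`.
#' @examples
#' activity_vocab(c("cooking", "eating"))
#' @export
activity_vocab <- function(activities) {
  abort_if(length(activities) < 1L, "vocabulary must contain at least one activity")
  activities <- as.character(activities)
  abort_if(anyNA(activities) || any(!nzchar(activities)),
           "activity names must be non-empty")
  abort_if(anyDuplicated(activities) > 0L, "activity names must be unique")
  structure(
    data.frame(activity = activities, id = seq_along(activities),
               stringsAsFactors = FALSE),
    class = c("activity_vocab", "data.frame")
  )
}

#' Default six-activity vocabulary
#'
#' The small daily-living vocabulary used throughout the examples and by the
#' synthetic cohort generator: cooking, eating, drinking, studying, sleeping,
#' watching TV.
#'
#' @return An [activity_vocab()] with six entries.
#' @export
default_activity_vocab <- function() {
  activity_vocab(c("cooking", "eating", "drinking", "studying",
                   "sleeping", "watching_tv"))
}

#' @export
print.activity_vocab <- function(x, ...) {
  cat("Activity vocabulary (", nrow(x), " activities)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

vocab_size <- function(vocab) nrow(vocab)

# name -> id lookup; returns NA for unknown names.
vocab_id <- function(vocab, activity) {
  vocab$id[match(activity, vocab$activity)]
}

vocab_name <- function(vocab, id) {
  vocab$activity[match(id, vocab$id)]
}

#' Read an activity vocabulary from CSV or YAML
#'
#' CSV files need an `activity` column (an optional `id` column must be
#' contiguous 1..M in row order); YAML files are a plain list of names, with
#' IDs assigned in listed order.
#'
#' @param path file path ending in `.csv`, `.yml`, or `.yaml`.
#' @return An [activity_vocab()].
#' @export
read_activity_vocab <- function(path) {
  abort_if(!file.exists(path), "vocabulary file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    return(activity_vocab(unlist(entries, use.names = FALSE)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!"activity" %in% names(df), "vocabulary CSV needs an 'activity' column")
  v <- activity_vocab(df$activity)
  if ("id" %in% names(df)) {
    abort_if(!identical(as.integer(df$id), v$id),
             "vocabulary CSV ids must be contiguous 1..M in row order")
  }
  v
}

#' Write an activity vocabulary to CSV
#'
#' @param vocab an [activity_vocab()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_activity_vocab <- function(vocab, path) {
  utils::write.csv(as.data.frame(vocab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
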