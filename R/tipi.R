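# Published TIPI keying: two items per trait, reverse-keyed items are 2, 4, 6,
# 8, 10. Emotional stability is reported as neuroticism = 8 - stability.
TIPI_DIRECT <- c(extraversion = 1L, agreeableness = 7L, conscientiousness = 3L,
                 stability = 9L, openness = 5L)
TIPI_REVERSE <- c(extraversion = 6L, agreeableness = 2L, conscientiousness = 8L,
                  stability = 4L, openness = 10L)
TRAITS <- c("E", "A", "C", "N", "O")
PERSONALITY_MODES <- c("ALL5", "EN", "N")

#' Score a ten-item personality inventory (TIPI)
#'
#' Each big-five trait is the mean of its direct item and the reversal
#' `8 - item` of its reverse-keyed item, staying on the 1-7 scale in steps of
#' 0.5. Emotional stability is converted to neuroticism (`N = 8 - stability`)
#' so that higher values mean less stable.
#'
#' @param items integer vector of 10 responses, each in 1..7 (item order as in
#'   the published TIPI).
#' @return Named numeric vector with elements `E`, `A`, `C`, `N`, `O`
#'   (extraversion, agreeableness, conscientiousness, neuroticism, openness).
#' @examples
#' score_tipi(rep(4, 10))  # keying-neutral midpoint: all 4.0
#' @export
score_tipi <- function(items) {
  abort_if(length(items) != 10L, "TIPI responses must have exactly 10 items")
  items <- as.numeric(items)
  abort_if(anyNA(items) || any(items < 1 | items > 7 | items != round(items)),
           "TIPI items must be integers in 1..7")
  raw <- stats::setNames((items[TIPI_DIRECT] + (8 - items[TIPI_REVERSE])) / 2,
                         names(TIPI_DIRECT))
  out <- c(raw["extraversion"], raw["agreeableness"], raw["conscientiousness"],
           8 - raw["stability"], raw["openness"])
  names(out) <- TRAITS
  out
}

#' Score a table of TIPI responses
#'
#' @param responses data frame with `subject_id` and `item_1` .. `item_10`.
#' @return Data frame `subject_id`, `E`, `A`, `C`, `N`, `O`.
#' @export
score_tipi_table <- function(responses) {
  item_cols <- paste0("item_", 1:10)
  missing <- setdiff(c("subject_id", item_cols), names(responses))
  abort_if(length(missing) > 0L,
           "TIPI table is missing column(s): ", paste(missing, collapse = ", "))
  scores <- t(apply(as.matrix(responses[item_cols]), 1, score_tipi))
  out <- data.frame(subject_id = as.character(responses$subject_id),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Slice personality scores into a feature mode
#'
#' The three feature modes compared in the analysis: all five traits
#' (`"ALL5"` -> E, A, C, N, O), extraversion plus neuroticism (`"EN"`), and
#' neuroticism alone (`"N"`). Scores are used raw on the 1-7 scale, without
#' standardization.
#'
#' @param scores named numeric vector from [score_tipi()], or a data frame
#'   from [score_tipi_table()].
#' @param mode one of `"ALL5"`, `"EN"`, `"N"`.
#' @return Numeric vector of length 5, 2 or 1 (or a matrix with those columns
#'   when `scores` is a data frame).
#' @export
select_features <- function(scores, mode) {
  abort_if(!is.character(mode) || length(mode) != 1L ||
             !mode %in% PERSONALITY_MODES,
           "mode must be one of ", paste(PERSONALITY_MODES, collapse = ", "))
  cols <- switch(mode, ALL5 = TRAITS, EN = c("E", "N"), N = "N")
  if (is.data.frame(scores)) {
    m <- as.matrix(scores[cols])
    rownames(m) <- NULL
    return(m)
  }
  scores[cols]
}

#' Load TIPI responses from CSV
#'
#' @param path CSV with columns `subject_id`, `item_1` .. `item_10`.
#' @return Data frame of validated responses.
#' @export
load_tipi <- function(path) {
  abort_if(!file.exists(path), "TIPI file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- paste0("item_", 1:10)
  missing <- setdiff(c("subject_id", item_cols), names(df))
  abort_if(length(missing) > 0L,
           "TIPI file is missing column(s): ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  apply(as.matrix(df[item_cols]), 1, score_tipi)  # validation side effect
  df[c("subject_id", item_cols)]
}

#' Write TIPI responses or scores to CSV
#'
#' @param x data frame (responses or scores).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tipi <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  out <- x
  out[num] <- lapply(out[num], format_num)
  writeLines(
    c(paste(names(out), collapse = ","),
      do.call(paste, c(unname(as.list(out)), sep = ","))),
    con = path, useBytes = TRUE)
  invisible(path)
}
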