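#' Variability features of a behavioral spectrum
#'
#' Reduces a spectrum to five summary values that characterise how spread a
#' trial's time budget is over its activities without fixing their order:
#'
#' * `mean` — sample mean, equal to the occupancy fraction `a0`;
#' * `std` — population standard deviation of the samples, which by Parseval
#'   equals `sqrt(sum(A_k^2) / 2)`;
#' * `variation` — the variance `std^2`;
#' * `autocorr_lag1` — circular lag-1 autocorrelation of the mean-centered
#'   samples, `sum(A_k^2 cos(2 pi k / N)) / sum(A_k^2)`;
#' * `entropy` — Shannon entropy (nats) of the normalised harmonic power
#'   distribution `p_k = A_k^2 / sum(A_j^2)`; 0 for a single activity, `log(K)`
#'   for K equal durations.
#'
#' `mean`, `std`, `variation` and `entropy` depend only on the multiset of
#' durations; `autocorr_lag1` additionally depends on their order; none depend
#' on the activity IDs (the phases cancel).
#'
#' @param x a `behavioral_spectrum`.
#' @return Named numeric vector of the five features.
#' @export
compute_variability <- function(x) {
  stopifnot(inherits(x, "behavioral_spectrum"))
  s <- x$samples
  N <- length(s)
  m <- mean(s)
  centered <- s - m
  ss <- sum(centered^2)
  abort_if(ss <= 0, "degenerate constant signal: lag-1 autocorrelation undefined")
  std <- sqrt(ss / N)                                  # population sd
  ac1 <- sum(centered * centered[c(2:N, 1)]) / ss      # circular lag 1
  p <- x$harmonics$amplitude^2
  p <- p / sum(p)
  entropy <- -sum(p * log(p))
  c(mean = m, std = std, variation = std^2, autocorr_lag1 = ac1,
    entropy = entropy)
}

#' Variability feature table for a spectrum set
#'
#' @param x a `spectrum_set` from [encode_trials()].
#' @return Data frame: `subject_id`, `trial_id`, `period`, `mean`, `std`,
#'   `variation`, `autocorr_lag1`, `entropy` — one row per trial.
#' @export
variability_table <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  feats <- do.call(rbind, lapply(x$spectra, compute_variability))
  cbind(x$meta, as.data.frame(feats))
}

#' Write a variability feature table to CSV
#'
#' @param features data frame from [variability_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_variability <- function(features, path) {
  num <- vapply(features, is.numeric, logical(1))
  out <- features
  out[num] <- lapply(out[num], format_num)
  out$period[is.na(out$period)] <- ""
  writeLines(
    c(paste(names(out), collapse = ","),
      do.call(paste, c(unname(as.list(out)), sep = ","))),
    con = path, useBytes = TRUE)
  invisible(path)
}
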