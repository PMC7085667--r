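#' Encoding configuration for behavioral spectra
#'
#' Fixes the sampling and mapping constants shared by an analysis: the number
#' of samples per period `n_samples` (200), the observation window `window_min`
#' (W, minutes), the vocabulary size `vocab_size` (M), the minimum legal event
#' duration `d_min`, the decoder's amplitude floor (default half the amplitude
#' of the smallest legal activity, `0.5 * d_min / W`) and the maximum sequence
#' length `k_max` (must stay below the Nyquist limit `n_samples / 2`).
#'
#' @param window_min observation-window length W in minutes.
#' @param vocab_size number of activities M in the vocabulary.
#' @param n_samples samples per period of the synthesized signal.
#' @param d_min minimum event duration (minutes).
#' @param amplitude_floor decoder threshold separating harmonics from noise.
#' @param k_max maximum number of events (harmonics) per trial.
#' @return An `encoding_config` object (a list).
#' @export
encoding_config <- function(window_min, vocab_size, n_samples = 200, d_min = 1,
                            amplitude_floor = 0.5 * d_min / window_min,
                            k_max = 90) {
  abort_if(window_min <= 0, "window_min must be positive")
  abort_if(vocab_size < 1, "vocab_size must be at least 1")
  abort_if(k_max >= n_samples / 2,
           "k_max must be below the Nyquist limit n_samples / 2")
  structure(list(window_min = window_min, vocab_size = as.integer(vocab_size),
                 n_samples = as.integer(n_samples), d_min = d_min,
                 amplitude_floor = amplitude_floor, k_max = as.integer(k_max)),
            class = "encoding_config")
}

#' Encode a trial as a behavioral spectrum
#'
#' Synthesizes the periodic signal
#' \deqn{s_n = a_0 + \sum_{k=1}^{K} \frac{d_k}{W}
#'       \cos\!\left(\frac{2\pi k n}{N} + \frac{2\pi\,\mathrm{id}_k}{M+1}\right),
#'       \quad n = 0,\dots,N-1,}
#' where the k-th activity in the sequence drives frequency k (the "(k+1)-th
#' harmonic", the first harmonic being the DC average), its duration sets the
#' amplitude `d_k / W`, its vocabulary ID sets the phase on an `M+1`-step grid
#' (never 0, so an activity is distinguishable from an absent harmonic), and
#' the DC term `a_0` is the occupancy fraction `sum(d) / W`.
#'
#' @param x a `habit_trial`.
#' @param cfg an [encoding_config()].
#' @return A `behavioral_spectrum`: list with `samples` (length N), `a0`,
#'   `harmonics` (data frame `k`, `amplitude`, `phase`), `subject_id`,
#'   `trial_id`, `period`, and `config`.
#' @examples
#' v <- activity_vocab(c("eating_breakfast", "watching_tv"))
#' tr <- trial("s1", "t1",
#'   data.frame(seq_index = 1:2, activity = v$activity, activity_id = v$id,
#'              duration_min = c(30, 60)), window_min = 120)
#' sp <- encode_trial(tr, encoding_config(window_min = 120, vocab_size = 6))
#' sp$harmonics
#' @export
encode_trial <- function(x, cfg) {
  stopifnot(inherits(x, "habit_trial"), inherits(cfg, "encoding_config"))
  validate_trial(x, d_min = cfg$d_min, k_max = cfg$k_max)
  ev <- x$events
  abort_if(any(ev$activity_id > cfg$vocab_size),
           "trial ", x$subject_id, "/", x$trial_id,
           ": activity id exceeds vocab_size = ", cfg$vocab_size)
  abort_if(abs(x$window_min - cfg$window_min) > 1e-9,
           "trial window (", x$window_min, ") differs from config window (",
           cfg$window_min, ")")
  K <- nrow(ev)
  N <- cfg$n_samples
  W <- cfg$window_min
  M <- cfg$vocab_size
  amp <- ev$duration_min / W
  phase <- 2 * pi * ev$activity_id / (M + 1)
  a0 <- sum(ev$duration_min) / W
  n <- 0:(N - 1)
  # angles: K x N matrix, row k = 2*pi*k*n/N + phase_k
  ang <- outer(seq_len(K), n, function(k, nn) 2 * pi * k * nn / N) + phase
  samples <- a0 + as.numeric(crossprod(matrix(amp, ncol = 1), cos(ang)))
  structure(list(samples = samples, a0 = a0,
                 harmonics = data.frame(k = seq_len(K), amplitude = amp,
                                        phase = phase),
                 subject_id = x$subject_id, trial_id = x$trial_id,
                 period = x$period, config = cfg),
            class = "behavioral_spectrum")
}

#' @export
print.behavioral_spectrum <- function(x, ...) {
  cat(sprintf("Behavioral spectrum %s/%s: %d harmonics, a0 = %.4g, N = %d\n",
              x$subject_id, x$trial_id, nrow(x$harmonics), x$a0,
              x$config$n_samples))
  invisible(x)
}

#' Decode a behavioral spectrum back to (activity ID, duration) events
#'
#' Inverts [encode_trial()] through the discrete Fourier transform of the
#' sample vector: the coefficient at frequency k gives the amplitude
#' `2 |S_k| / N` and phase `Arg(S_k)`; the sequence length K is the largest k
#' whose amplitude exceeds the floor; IDs are read off the phase grid and
#' durations rescaled by W. Used for round-trip validation of the encoding.
#'
#' @param x a `behavioral_spectrum` or a numeric sample vector.
#' @param cfg an [encoding_config()] (taken from `x` when absent).
#' @param phase_tol maximum allowed distance of a recovered phase from its
#'   nearest grid point, in radians (default a tenth of the grid step).
#' @return Data frame with columns `seq_index`, `activity_id`, `duration_min`.
#' @export
decode_spectrum <- function(x, cfg = NULL,
                            phase_tol = 0.1 * 2 * pi / (cfg$vocab_size + 1)) {
  if (inherits(x, "behavioral_spectrum")) {
    if (is.null(cfg)) cfg <- x$config
    samples <- x$samples
  } else {
    abort_if(is.null(cfg), "decoding a bare sample vector requires `cfg`")
    samples <- as.numeric(x)
  }
  N <- cfg$n_samples
  abort_if(length(samples) != N, "sample vector has length ", length(samples),
           ", expected ", N)
  S <- stats::fft(samples)
  ks <- seq_len(cfg$k_max)
  amp <- 2 * Mod(S[ks + 1]) / N
  present <- amp > cfg$amplitude_floor
  abort_if(!any(present), "no activities: spectrum has no harmonic above the ",
           "amplitude floor")
  K <- max(which(present))
  abort_if(!all(present[seq_len(K)]),
           "gap in harmonic sequence: position(s) ",
           paste(which(!present[seq_len(K)]), collapse = ", "),
           " fall below the amplitude floor")
  phase <- Arg(S[seq_len(K) + 1]) %% (2 * pi)
  grid_step <- 2 * pi / (cfg$vocab_size + 1)
  id <- round(phase / grid_step)
  # distance to nearest grid point, circular
  dev <- abs(phase - id * grid_step)
  dev <- pmin(dev, 2 * pi - dev)
  abort_if(any(dev > phase_tol),
           "recovered phase off-grid at position(s) ",
           paste(which(dev > phase_tol), collapse = ", "))
  id[id == 0L] <- cfg$vocab_size + 1L  # phase wrapped past 2*pi
  abort_if(any(id > cfg$vocab_size),
           "recovered phase maps outside the vocabulary")
  data.frame(seq_index = seq_len(K), activity_id = as.integer(id),
             duration_min = amp[seq_len(K)] * cfg$window_min)
}

#' Mean absolute error between two spectra
#'
#' The dissimilarity used to assign a spectrum to its nearest habit centroid:
#' the mean over sample points of the absolute difference. Symmetric, zero only
#' for identical sample vectors.
#'
#' @param a,b `behavioral_spectrum` objects or numeric sample vectors of equal
#'   length.
#' @return A non-negative scalar.
#' @export
spectrum_mae <- function(a, b) {
  sa <- if (inherits(a, "behavioral_spectrum")) a$samples else as.numeric(a)
  sb <- if (inherits(b, "behavioral_spectrum")) b$samples else as.numeric(b)
  abort_if(length(sa) != length(sb),
           "spectra have different lengths (", length(sa), " vs ", length(sb), ")")
  mean(abs(sa - sb))
}

#' Encode a list of trials into a spectrum set
#'
#' @param trials list of `habit_trial` objects.
#' @param cfg an [encoding_config()].
#' @return A `spectrum_set`: list with `samples` (n x N matrix), `meta`
#'   (data frame `subject_id`, `trial_id`, `period`), `spectra` (the individual
#'   `behavioral_spectrum` objects) and `config`.
#' @export
encode_trials <- function(trials, cfg) {
  specs <- lapply(trials, encode_trial, cfg = cfg)
  samples <- do.call(rbind, lapply(specs, `[[`, "samples"))
  meta <- data.frame(
    subject_id = vapply(trials, `[[`, character(1), "subject_id"),
    trial_id = vapply(trials, `[[`, character(1), "trial_id"),
    period = vapply(trials, `[[`, character(1), "period"),
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, meta = meta, spectra = specs, config = cfg),
            class = "spectrum_set")
}

#' Write a spectrum set to CSV
#'
#' One row per trial: `subject_id`, `trial_id`, `period`, then samples
#' `s0..s<N-1>`.
#'
#' @param x a `spectrum_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  N <- x$config$n_samples
  header <- paste(c("subject_id", "trial_id", "period",
                    paste0("s", 0:(N - 1))), collapse = ",")
  rows <- vapply(seq_len(nrow(x$meta)), function(i) {
    paste(c(x$meta$subject_id[i], x$meta$trial_id[i],
            ifelse(is.na(x$meta$period[i]), "", x$meta$period[i]),
            format_num(x$samples[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), con = path, useBytes = TRUE)
  invisible(path)
}
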