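#' Synthetic cohort configuration
#'
#' Describes a simulated study: cohort size, trial layout, observation window,
#' activity vocabulary, and the generative parameters. Latent big-five traits
#' are drawn per subject on the 1-7 scale; each trial's activity count follows
#' `K = 1 + Poisson(max(0, base_rate + coupling * (neuroticism - 4)))`, so
#' `coupling` plants a monotone link between neuroticism and how often the
#' subject switches activities, while `coupling = 0` is the null. Durations
#' split `occupancy * window_min` by a symmetric Dirichlet; questionnaire items
#' add Gaussian noise `item_noise` before rounding to the 1..7 grid.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials per subject (cycled over `periods` when
#'   those are set).
#' @param n_trials optional total trial count overriding
#'   `n_subjects * trials_per_subject`; extra trials go to the first subjects
#'   (e.g. 29 trials over 24 subjects).
#' @param periods `NULL`, or a subset of `c("morning", "afternoon", "night")`
#'   tagged cyclically onto each subject's trials.
#' @param vocab an [activity_vocab()] (default the six-activity vocabulary).
#' @param window_min observation window W in minutes (20 for a short
#'   free-choice session; 360 for a day-period log).
#' @param occupancy fraction of the window covered by activities, in (0, 1].
#' @param base_rate baseline Poisson rate for the activity count.
#' @param coupling slope of the neuroticism effect on the activity count
#'   (>= 0; 0 = no planted structure).
#' @param item_noise standard deviation of questionnaire item noise.
#' @param d_min minimum event duration (minutes).
#' @param k_max maximum events per trial.
#' @param with_start_times attach clock start times to events (default: only
#'   when `periods` are set).
#' @param seed integer seed; the whole cohort is reproducible from the config.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects, trials_per_subject = 1, n_trials = NULL,
                          periods = NULL, vocab = default_activity_vocab(),
                          window_min = 20, occupancy = 0.9, base_rate = 3,
                          coupling = 0, item_noise = 0.8, d_min = 1,
                          k_max = 90, with_start_times = !is.null(periods),
                          seed = 1) {
  abort_if(n_subjects < 1, "n_subjects must be at least 1")
  abort_if(occupancy <= 0 || occupancy > 1, "occupancy must be in (0, 1]")
  abort_if(base_rate <= 0, "base_rate must be positive")
  abort_if(coupling < 0, "coupling must be non-negative")
  abort_if(item_noise < 0, "item_noise must be non-negative")
  abort_if(!is.null(periods) && !all(periods %in% PERIODS),
           "periods must be a subset of ", paste(PERIODS, collapse = ", "))
  abort_if(window_min * occupancy < d_min,
           "window too short for even one activity of d_min minutes")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 n_trials = if (is.null(n_trials)) NULL else as.integer(n_trials),
                 periods = periods, vocab = vocab, window_min = window_min,
                 occupancy = occupancy, base_rate = base_rate,
                 coupling = coupling, item_noise = item_noise, d_min = d_min,
                 k_max = as.integer(k_max),
                 with_start_times = isTRUE(with_start_times),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Preset: short free-choice sessions (young cohort)
#'
#' 24 subjects contributing 29 trials in a 20-minute observation window with
#' the six-activity vocabulary.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_aal <- function(seed = 1, ...) {
  args <- list(n_subjects = 24, trials_per_subject = 1, n_trials = 29,
               window_min = 20, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

#' Preset: day-period logs (elderly cohort)
#'
#' 12 subjects, one trial in each of the morning, afternoon and night periods,
#' 360-minute windows.
#'
#' @inheritParams cohort_config_aal
#' @return A `cohort_config`.
#' @export
cohort_config_hs <- function(seed = 1, ...) {
  args <- list(n_subjects = 12, trials_per_subject = 3,
               periods = c("morning", "afternoon", "night"),
               window_min = 360, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

# Truncated normal on [lo, hi] via inverse-CDF sampling (exact, no rejection).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Draw latent personality traits for a cohort
#'
#' Five traits per subject (E, A, C, N, O), each from a normal law with mean 4
#' and standard deviation 1.2 truncated to the 1-7 questionnaire scale.
#'
#' @param cfg a [cohort_config()].
#' @return Data frame `subject_id`, `E`, `A`, `C`, `N`, `O`.
#' @export
generate_subjects <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  traits <- with_seed(cfg$seed, {
    matrix(rtruncnorm(cfg$n_subjects * 5L, 4, 1.2, 1, 7), ncol = 5L)
  })
  colnames(traits) <- TRAITS
  cbind(data.frame(subject_id = sprintf("s%02d", seq_len(cfg$n_subjects)),
                   stringsAsFactors = FALSE),
        as.data.frame(traits))
}

# Split `total` minutes over K events: symmetric Dirichlet(2) shares, then
# entries below d_min are pinned there and the remainder rescaled.
split_durations <- function(K, total, d_min) {
  stopifnot(K * d_min <= total + 1e-9)
  g <- stats::rgamma(K, shape = 2)
  d <- g / sum(g) * total
  repeat {
    low <- d < d_min
    if (!any(low)) break
    if (all(low)) {
      d <- rep(total / K, K)
      break
    }
    d[!low] <- d[!low] / sum(d[!low]) * (total - sum(low) * d_min)
    d[low] <- d_min
  }
  d
}

period_start_hour <- c(morning = 8, afternoon = 13, night = 19)

#' Generate activity trials for a cohort
#'
#' Per trial: the activity count K is drawn from the coupled Poisson law and
#' clamped to the feasible range, activity IDs are drawn without immediate
#' repeats, and durations split `occupancy * window_min` by a clipped
#' Dirichlet. Every generated trial passes [validate_trial()].
#'
#' @param subjects data frame from [generate_subjects()].
#' @param cfg a [cohort_config()].
#' @return List of `habit_trial` objects.
#' @export
generate_trials <- function(subjects, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  M <- vocab_size(cfg$vocab)
  total <- cfg$occupancy * cfg$window_min
  k_cap <- min(cfg$k_max, floor(total / cfg$d_min))
  n_per <- rep(cfg$trials_per_subject, cfg$n_subjects)
  if (!is.null(cfg$n_trials)) {
    base <- cfg$n_trials %/% cfg$n_subjects
    extra <- cfg$n_trials %% cfg$n_subjects
    n_per <- rep(base, cfg$n_subjects) + (seq_len(cfg$n_subjects) <= extra)
  }
  with_seed(cfg$seed + 1L, {
    trials <- list()
    for (i in seq_len(cfg$n_subjects)) {
      neuro <- subjects$N[i]
      lambda <- max(0, cfg$base_rate + cfg$coupling * (neuro - 4))
      for (j in seq_len(n_per[i])) {
        K <- 1L + stats::rpois(1L, lambda)
        K <- max(1L, min(K, k_cap))
        ids <- integer(K)
        ids[1] <- sample.int(M, 1L)
        if (K > 1L) for (m in 2:K) {
          ids[m] <- if (M == 1L) 1L else
            sample(setdiff(seq_len(M), ids[m - 1L]), 1L)
        }
        d <- split_durations(K, total, cfg$d_min)
        period <- if (is.null(cfg$periods)) NA_character_ else
          cfg$periods[(j - 1L) %% length(cfg$periods) + 1L]
        start_time <- rep(NA_character_, K)
        if (cfg$with_start_times) {
          h0 <- if (is.na(period)) 8 else period_start_hour[[period]]
          offs <- c(0, cumsum(d))[seq_len(K)] / 60
          secs <- round((h0 + offs) * 3600) %% 86400
          start_time <- sprintf("%02d:%02d:%02d", secs %/% 3600,
                                (secs %% 3600) %/% 60, secs %% 60)
        }
        trials[[length(trials) + 1L]] <- trial(
          subjects$subject_id[i], sprintf("t%02d", j),
          events = data.frame(seq_index = seq_len(K),
                              activity = vocab_name(cfg$vocab, ids),
                              activity_id = ids, duration_min = d,
                              start_time = start_time,
                              stringsAsFactors = FALSE),
          window_min = cfg$window_min, period = period,
          d_min = cfg$d_min, k_max = cfg$k_max)
      }
    }
    trials
  })
}

#' Generate questionnaire responses consistent with latent traits
#'
#' Each item equals its keyed trait value (reverse-keyed items inverted as
#' `8 - trait`) plus Gaussian noise of sd `item_noise`, rounded and clipped to
#' the 1..7 grid, so that [score_tipi()] recovers the latent traits in
#' expectation.
#'
#' @inheritParams generate_trials
#' @return Data frame `subject_id`, `item_1` .. `item_10`.
#' @export
generate_questionnaires <- function(subjects, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- nrow(subjects)
  # latent value each item reflects, in TIPI item order 1..10
  trait_of_item <- character(10)
  trait_of_item[TIPI_DIRECT] <- names(TIPI_DIRECT)
  trait_of_item[TIPI_REVERSE] <- names(TIPI_REVERSE)
  latent <- function(tr) {
    if (tr == "stability") 8 - subjects$N else subjects[[substr(toupper(tr), 1, 1)]]
  }
  with_seed(cfg$seed + 2L, {
    items <- matrix(0L, n, 10)
    for (it in 1:10) {
      v <- latent(trait_of_item[it])
      if (it %in% TIPI_REVERSE) v <- 8 - v
      items[, it] <- pmin(7L, pmax(1L, as.integer(round(
        v + stats::rnorm(n, 0, cfg$item_noise)))))
    }
    colnames(items) <- paste0("item_", 1:10)
    cbind(data.frame(subject_id = subjects$subject_id,
                     stringsAsFactors = FALSE),
          as.data.frame(items))
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper drawing subjects, trials and questionnaires from one
#' config, plus the derived trait scores.
#'
#' @param cfg a [cohort_config()].
#' @return List with `subjects`, `trials`, `tipi`, `scores`, and `config`.
#' @export
generate_cohort <- function(cfg) {
  subjects <- generate_subjects(cfg)
  trials <- generate_trials(subjects, cfg)
  tipi <- generate_questionnaires(subjects, cfg)
  list(subjects = subjects, trials = trials, tipi = tipi,
       scores = score_tipi_table(tipi), config = cfg)
}
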