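#' Put a two-cluster model in canonical low/high order
#'
#' Relabels a k = 2 model so that cluster 1 is the one whose centroid has the
#' lower mean; ties keep the original order. Makes cluster indices comparable
#' across the activity and personality sides.
#'
#' @param model a `cluster_model` with `k = 2`.
#' @return The relabeled model. Idempotent.
#' @export
canonical_order <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  abort_if(model$k != 2L, "canonical_order is defined for k = 2 models only")
  m <- rowMeans(model$centroids)
  if (m[2] < m[1]) {
    model$centroids <- model$centroids[c(2, 1), , drop = FALSE]
    model$labels <- 3L - model$labels
    model$sizes <- model$sizes[c(2, 1)]
  }
  model
}

#' Association rate between two binary labelings
#'
#' Fraction of observations assigned to the same group by both labelings,
#' counted after the optimal alignment of the two arbitrary label sets:
#' `max(agreements, n - agreements) / n`. The rate is therefore at least 0.5,
#' symmetric, and invariant to swapping either side's labels.
#'
#' @param labels_a,labels_b vectors of equal length n >= 2, each taking at most
#'   two values.
#' @return Scalar in `[0.5, 1]`.
#' @export
association_rate <- function(labels_a, labels_b) {
  n <- length(labels_a)
  abort_if(length(labels_b) != n, "label vectors have different lengths")
  abort_if(n < 2L, "need at least two observations")
  abort_if(length(unique(labels_a)) > 2L || length(unique(labels_b)) > 2L,
           "labels must be binary")
  agree <- sum(labels_a == labels_a[1] & labels_b == labels_b[1] |
                 labels_a != labels_a[1] & labels_b != labels_b[1])
  max(agree, n - agree) / n
}

#' Phi coefficient and p-value between two binary labelings
#'
#' The phi coefficient is the Pearson correlation of the 0/1 indicator vectors
#' (equivalently the phi of the 2x2 confusion table). The two-tailed p-value
#' uses the t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` against the t
#' distribution with n - 2 degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @inheritParams association_rate
#' @return List with `r` and `p`.
#' @export
phi_correlation <- function(labels_a, labels_b) {
  n <- length(labels_a)
  abort_if(length(labels_b) != n, "label vectors have different lengths")
  abort_if(n < 3L, "need at least three observations")
  # indicator of the higher of the two (sorted) label values, so the sign of
  # phi is well defined and matches the Pearson correlation of 0/1 codes
  a <- as.integer(labels_a == max(labels_a))
  b <- as.integer(labels_b == max(labels_b))
  abort_if(stats::var(a) == 0 || stats::var(b) == 0,
           "phi undefined: a label vector has zero variance")
  r <- stats::cor(a, b)
  list(r = r, p = phi_pvalue(r, n))
}

#' Two-tailed p-value for a correlation via the t transform
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @param n number of paired observations (>= 3).
#' @return p-value in `[0, 1]`; 0 when `|r| = 1`.
#' @examples
#' phi_pvalue(0.34, 29)   # ~0.0712
#' phi_pvalue(2 / 3, 12)  # ~0.0179
#' @export
phi_pvalue <- function(r, n) {
  abort_if(abs(r) > 1 + 1e-12, "r must be in [-1, 1]")
  abort_if(n < 3L, "need n >= 3")
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Association report across periods, personality modes and spectrum features
#'
#' For every cell (period x personality mode x spectrum feature kind) the
#' trials of that period are encoded, both sides are clustered into two groups
#' (raw 200-point spectra or 5-value variability vectors on the activity side;
#' the selected raw trait scores on the personality side, one row per trial),
#' both models are put in canonical low/high order, and the association rate
#' plus phi coefficient with its p-value are reported.
#'
#' Subjects present on only one side are dropped with a warning; the reported
#' `n` is the number of trials entering each cell.
#'
#' @param trials list of `habit_trial` objects.
#' @param scores data frame from [score_tipi_table()] (one row per subject).
#' @param cfg an [encoding_config()].
#' @param periods `NULL` for a single pooled analysis, or a character vector of
#'   day periods analysed independently.
#' @param modes personality feature modes (subset of `"ALL5"`, `"EN"`, `"N"`).
#' @param features spectrum feature kinds (subset of `"spectrum_raw"`,
#'   `"spectrum_variability"`).
#' @param n_restarts,seed clustering settings passed to [kmeans_fit()].
#' @return Data frame with one row per cell: `period`, `personality_mode`,
#'   `spectrum_feature`, `n`, `rate`, `r`, `p`.
#' @export
build_report <- function(trials, scores, cfg, periods = NULL,
                         modes = c("ALL5", "EN", "N"),
                         features = c("spectrum_raw", "spectrum_variability"),
                         n_restarts = 50, seed = 1) {
  abort_if(length(trials) == 0L, "no trials")
  subj <- vapply(trials, `[[`, character(1), "subject_id")
  known <- subj %in% scores$subject_id
  if (!all(known)) {
    warning("dropping ", sum(!known), " trial(s) from subject(s) without scores: ",
            paste(unique(subj[!known]), collapse = ", "))
    trials <- trials[known]
    subj <- subj[known]
  }
  abort_if(length(trials) == 0L, "no trials with matching personality scores")

  cells <- list()
  period_list <- if (is.null(periods)) list(NULL) else as.list(periods)
  cell_seed <- seed
  for (period in period_list) {
    keep <- if (is.null(period)) rep(TRUE, length(trials)) else
      vapply(trials, function(tr) identical(tr$period, period), logical(1))
    abort_if(!any(keep), "no trials in period ", period %||% "<all>")
    tr_p <- trials[keep]
    specset <- encode_trials(tr_p, cfg)
    feats <- variability_table(specset)
    score_rows <- scores[match(specset$meta$subject_id, scores$subject_id), ,
                         drop = FALSE]
    n <- length(tr_p)
    for (feature in features) {
      X_s <- switch(feature,
        spectrum_raw = specset$samples,
        spectrum_variability = as.matrix(
          feats[c("mean", "std", "variation", "autocorr_lag1", "entropy")]),
        stop("unknown spectrum feature: ", feature))
      m_s <- canonical_order(kmeans_fit(X_s, 2, n_restarts = n_restarts,
                                        seed = cell_seed + 1,
                                        feature_kind = feature))
      for (mode in modes) {
        X_p <- select_features(score_rows, mode)
        m_p <- canonical_order(kmeans_fit(X_p, 2, n_restarts = n_restarts,
                                          seed = cell_seed + 2,
                                          feature_kind = "personality"))
        phi <- phi_correlation(m_s$labels, m_p$labels)
        cells[[length(cells) + 1L]] <- data.frame(
          period = period %||% NA_character_,
          personality_mode = mode, spectrum_feature = feature,
          n = n, rate = association_rate(m_s$labels, m_p$labels),
          r = phi$r, p = phi$p, stringsAsFactors = FALSE)
      }
      cell_seed <- cell_seed + 10
    }
  }
  do.call(rbind, cells)
}

#' Write an association report to CSV and JSON
#'
#' @param report data frame from [build_report()].
#' @param path output path without extension, or ending in `.csv`.
#' @return The CSV path, invisibly.
#' @export
write_report <- function(report, path) {
  csv_path <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  out$period[is.na(out$period)] <- ""
  writeLines(
    c(paste(names(out), collapse = ","),
      do.call(paste, c(unname(as.list(out)), sep = ","))),
    con = csv_path, useBytes = TRUE)
  json_path <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(csv_path)
}
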