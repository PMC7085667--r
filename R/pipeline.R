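#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: either file inputs
#' (`activity_log` + `tipi` + `vocab` paths and a window length) or a
#' synthetic cohort (`cohort = cohort_config(...)`), plus clustering settings
#' and the analysis cells. A run is reproducible from the config alone.
#'
#' @param cohort optional [cohort_config()]; when given, inputs are simulated.
#' @param activity_log,tipi,vocab input file paths (used when `cohort` is
#'   `NULL`; `vocab` may be `NULL` for the default vocabulary).
#' @param window_min observation window for file inputs.
#' @param periods `NULL` for a pooled analysis or a character vector of day
#'   periods analysed independently.
#' @param modes,features analysis cells, as in [build_report()].
#' @param n_restarts,seed clustering restarts and master seed.
#' @param elbow_threshold marginal-gain threshold for [select_k_elbow()].
#' @param curve_k_max largest k for the exploratory variance curves.
#' @param out_dir run directory for artifacts.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = NULL, activity_log = NULL, tipi = NULL,
                            vocab = NULL, window_min = NULL, periods = NULL,
                            modes = c("ALL5", "EN", "N"),
                            features = c("spectrum_raw", "spectrum_variability"),
                            n_restarts = 50, seed = 1, elbow_threshold = 0.05,
                            curve_k_max = 10, out_dir = tempfile("habitrun")) {
  if (is.null(cohort)) {
    abort_if(is.null(activity_log) || is.null(tipi),
             "either a cohort config or activity_log + tipi paths are required")
    abort_if(is.null(window_min), "window_min is required for file inputs")
  }
  abort_if(!is.character(modes) || !all(modes %in% PERSONALITY_MODES),
           "modes must be a character subset of ",
           paste(PERSONALITY_MODES, collapse = ", "),
           " (note: quote \"N\" in YAML, where bare N parses as a boolean)")
  abort_if(!is.character(features) ||
             !all(features %in% c("spectrum_raw", "spectrum_variability")),
           "features must be a subset of spectrum_raw, spectrum_variability")
  structure(list(cohort = cohort, activity_log = activity_log, tipi = tipi,
                 vocab = vocab, window_min = window_min, periods = periods,
                 modes = modes, features = features, n_restarts = n_restarts,
                 seed = as.integer(seed), elbow_threshold = elbow_threshold,
                 curve_k_max = as.integer(curve_k_max), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; a `cohort`
#' mapping is passed to [cohort_config()] (with `preset: aal` or `preset: hs`
#' selecting a preset).
#'
#' @param path YAML file path.
#' @param out_dir,seed optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL, seed = NULL) {
  abort_if(!file.exists(path), "config file not found: ", path)
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    spec <- y$cohort
    preset <- spec$preset
    spec$preset <- NULL
    if (!is.null(seed)) spec$seed <- seed
    cohort <- if (identical(preset, "aal")) {
      do.call(cohort_config_aal, spec)
    } else if (identical(preset, "hs")) {
      do.call(cohort_config_hs, spec)
    } else {
      do.call(cohort_config, spec)
    }
  }
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- cohort
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Chains every stage — input (simulate or load), spectrum encoding,
#' variability features, questionnaire scoring, clustering with exploratory
#' variance curves, and the association report — writing each artifact to the
#' run directory. Reruns with the same config produce byte-identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the association `report`, selected elbow
#'   cluster counts, and the artifact `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  paths <- list(log = logfile)

  # --- inputs ----------------------------------------------------------------
  if (!is.null(cfg$cohort)) {
    cohort <- generate_cohort(cfg$cohort)
    trials <- cohort$trials
    tipi <- cohort$tipi
    vocab <- cfg$cohort$vocab
    window_min <- cfg$cohort$window_min
    paths$activity_log <- file.path(cfg$out_dir, "activity_log.csv")
    paths$tipi <- file.path(cfg$out_dir, "tipi.csv")
    write_activity_log(trials, paths$activity_log)
    write_tipi(tipi, paths$tipi)
    log_stage(con, "simulate", sprintf("%d subjects, %d trials generated",
                                       nrow(cohort$subjects), length(trials)))
  } else {
    vocab <- if (is.null(cfg$vocab)) default_activity_vocab() else
      read_activity_vocab(cfg$vocab)
    window_min <- cfg$window_min
    trials <- load_activity_log(cfg$activity_log, vocab, window_min)
    tipi <- load_tipi(cfg$tipi)
    log_stage(con, "load", sprintf("%d trials, %d questionnaires loaded",
                                   length(trials), nrow(tipi)))
  }

  enc <- encoding_config(window_min = window_min, vocab_size = vocab_size(vocab))

  # --- encode ----------------------------------------------------------------
  specset <- encode_trials(trials, enc)
  paths$spectra <- file.path(cfg$out_dir, "spectra.csv")
  write_spectra(specset, paths$spectra)
  log_stage(con, "encode", sprintf("%d spectra of %d samples",
                                   nrow(specset$samples), enc$n_samples))

  # --- features --------------------------------------------------------------
  feats <- variability_table(specset)
  paths$features <- file.path(cfg$out_dir, "features.csv")
  write_variability(feats, paths$features)
  log_stage(con, "features", sprintf("%d feature rows", nrow(feats)))

  # --- score -----------------------------------------------------------------
  scores <- score_tipi_table(tipi)
  paths$scores <- file.path(cfg$out_dir, "scores.csv")
  write_tipi(scores, paths$scores)
  log_stage(con, "score", sprintf("%d subjects scored", nrow(scores)))

  # --- cluster (exploratory curves + headline k = 2 models) -----------------
  feat_mat <- as.matrix(feats[c("mean", "std", "variation", "autocorr_lag1",
                                "entropy")])
  elbow <- list()
  for (mode in cfg$modes) {
    X_p <- select_features(scores, mode)
    kmx <- min(cfg$curve_k_max, nrow(unique(as_feature_matrix(X_p))))
    curve <- variance_curve(X_p, k_max = kmx, n_restarts = cfg$n_restarts,
                            seed = cfg$seed + 100)
    p <- file.path(cfg$out_dir, sprintf("variance_curve_personality_%s.csv", mode))
    utils::write.csv(as.data.frame(curve), p, row.names = FALSE, quote = FALSE)
    paths[[paste0("curve_", mode)]] <- p
    elbow[[mode]] <- select_k_elbow(curve, cfg$elbow_threshold)
  }
  kmx_s <- min(cfg$curve_k_max, nrow(unique(feat_mat)))
  curve_s <- variance_curve(feat_mat, k_max = kmx_s,
                            n_restarts = cfg$n_restarts, seed = cfg$seed + 200,
                            feature_kind = "spectrum_variability")
  p <- file.path(cfg$out_dir, "variance_curve_spectrum_variability.csv")
  utils::write.csv(as.data.frame(curve_s), p, row.names = FALSE, quote = FALSE)
  paths$curve_spectrum <- p
  elbow$spectrum_variability <- select_k_elbow(curve_s, cfg$elbow_threshold)

  m_raw <- canonical_order(kmeans_fit(specset$samples, 2,
                                      n_restarts = cfg$n_restarts,
                                      seed = cfg$seed + 300,
                                      feature_kind = "spectrum_raw"))
  paths$model_raw <- file.path(cfg$out_dir, "model_spectrum_raw.json")
  write_cluster_model(m_raw, paths$model_raw)
  log_stage(con, "cluster",
            sprintf("elbow k: %s; raw-spectrum k=2 sizes [%s]",
                    paste(names(elbow), unlist(elbow), sep = "=", collapse = ", "),
                    paste(m_raw$sizes, collapse = ", ")))

  # --- associate -------------------------------------------------------------
  report <- build_report(trials, scores, enc, periods = cfg$periods,
                         modes = cfg$modes, features = cfg$features,
                         n_restarts = cfg$n_restarts, seed = cfg$seed + 400)
  paths$report <- file.path(cfg$out_dir, "association_report.csv")
  write_report(report, paths$report)
  log_stage(con, "associate", sprintf("%d report cells", nrow(report)))

  invisible(list(report = report, elbow = elbow, paths = paths))
}
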