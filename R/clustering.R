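FEATURE_KINDS <- c("spectrum_raw", "spectrum_variability", "personality")

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1)
  storage.mode(X) <- "double"
  rownames(X) <- NULL
  X
}

# Deterministic k-means++ style seeding over the distinct rows of X.
kmeanspp_centers <- function(ux, k) {
  n <- nrow(ux)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((ux - matrix(ux[idx[1], ], n, ncol(ux), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
        idx[j] <- pool[sample.int(length(pool), 1L)]
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums((ux - matrix(ux[idx[j], ], n, ncol(ux),
                                          byrow = TRUE))^2))
    }
  }
  ux[idx, , drop = FALSE]
}

run_lloyd <- function(X, centers) {
  if (anyDuplicated(centers) > 0L) return(NULL)
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 300,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  fit
}

#' Fit k-means with deterministic best-of-restarts
#'
#' Lloyd iterations from multiple deterministic starts, keeping the restart
#' with the lowest within-cluster sum of squares. Starts are drawn by
#' k-means++ weighting from the distinct data points; for two clusters on
#' small data (at most 12 distinct points) every pair of distinct points is
#' additionally tried, which in practice recovers the exhaustive-partition
#' optimum. Ties between restarts keep the earliest.
#'
#' @param X numeric matrix (rows = observations), data frame, or vector.
#' @param k number of clusters, at most the number of distinct rows.
#' @param n_restarts number of sampled starts (default 50).
#' @param seed integer seed making the fit reproducible.
#' @param feature_kind what the rows represent: `"spectrum_raw"`,
#'   `"spectrum_variability"` or `"personality"`.
#' @param extra_starts optional list of additional center matrices to try
#'   (used by [variance_curve()] for warm starts).
#' @return A `cluster_model`: list with `k`, `centroids` (k x p matrix),
#'   `labels` (1..k per row), `wss`, `sizes`, and `feature_kind`.
#' @export
kmeans_fit <- function(X, k, n_restarts = 50, seed = 1,
                       feature_kind = c("spectrum_raw", "spectrum_variability",
                                        "personality"),
                       extra_starts = NULL) {
  feature_kind <- match.arg(feature_kind)
  X <- as_feature_matrix(X)
  n <- nrow(X)
  abort_if(n < 1L, "empty data")
  ux <- unique(X)
  n_distinct <- nrow(ux)
  abort_if(k < 1L, "k must be at least 1")
  abort_if(k > n_distinct, "k = ", k, " exceeds the number of distinct points (",
           n_distinct, ")")

  if (k == 1L) {
    centroid <- matrix(colMeans(X), 1, ncol(X))
    wss <- sum((X - matrix(centroid, n, ncol(X), byrow = TRUE))^2)
    return(structure(list(k = 1L, centroids = centroid,
                          labels = rep(1L, n), wss = wss, sizes = n,
                          feature_kind = feature_kind),
                     class = "cluster_model"))
  }

  starts <- list()
  if (k == 2L && n_distinct <= 12L) {
    pairs <- utils::combn(n_distinct, 2L)
    starts <- c(starts, lapply(seq_len(ncol(pairs)), function(j) {
      ux[pairs[, j], , drop = FALSE]
    }))
  }
  starts <- c(starts, with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) kmeanspp_centers(ux, k))
  }))
  if (!is.null(extra_starts)) starts <- c(extra_starts, starts)

  best <- NULL
  for (C in starts) {
    fit <- run_lloyd(X, C)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) best <- fit
  }
  abort_if(is.null(best), "k-means failed from every start")
  structure(list(k = as.integer(k), centroids = unname(best$centers),
                 labels = as.integer(best$cluster), wss = best$tot.withinss,
                 sizes = as.integer(best$size), feature_kind = feature_kind),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model (%s): k = %d, sizes = [%s], wss = %.6g\n",
              x$feature_kind, x$k, paste(x$sizes, collapse = ", "), x$wss))
  invisible(x)
}

#' Uncentered explained variance of a clustering
#'
#' The fraction of the total sum of squares about the origin captured by the
#' cluster centroids: `1 - wss / sum(X^2)`. The uncentered convention keeps a
#' single cluster of positive-valued data informative (its explained variance
#' is the squared-mean share, not identically zero), matching how
#' explained-variance-vs-k tables behave for raw Likert-scale scores.
#'
#' @param X the data the model was fitted on.
#' @param model a `cluster_model`.
#' @return Scalar in `[0, 1]`.
#' @export
explained_variance <- function(X, model) {
  X <- as_feature_matrix(X)
  tss0 <- sum(X^2)
  abort_if(tss0 <= 0, "total sum of squares about the origin is zero")
  max(0, min(1, 1 - model$wss / tss0))
}

#' Explained-variance curve over cluster counts
#'
#' Fits k-means for k = 1..`k_max` and reports the uncentered explained
#' variance of each. Each k is additionally warm-started from the previous
#' solution's centroids plus the point farthest from its centroid, which makes
#' the curve non-decreasing by construction.
#'
#' @inheritParams kmeans_fit
#' @param k_max largest cluster count (at most the number of distinct rows).
#' @return A `variance_curve`: data frame with columns `k` and `explained`.
#' @export
variance_curve <- function(X, k_max, n_restarts = 50, seed = 1,
                           feature_kind = "personality") {
  X <- as_feature_matrix(X)
  abort_if(k_max < 1L, "k_max must be at least 1")
  abort_if(k_max > nrow(unique(X)),
           "k_max exceeds the number of distinct points")
  explained <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    extra <- NULL
    if (!is.null(prev) && prev$wss > 0) {
      d2 <- rowSums((X - prev$centroids[prev$labels, , drop = FALSE])^2)
      ord <- order(d2, decreasing = TRUE)
      far <- NULL
      for (i in ord) {  # farthest point not already a centroid
        cand <- X[i, , drop = FALSE]
        if (!any(apply(prev$centroids, 1, function(ctr) all(ctr == cand)))) {
          far <- cand
          break
        }
      }
      if (!is.null(far)) extra <- list(rbind(prev$centroids, far))
    }
    fit <- kmeans_fit(X, k, n_restarts = n_restarts, seed = seed + k,
                      feature_kind = feature_kind, extra_starts = extra)
    explained[k] <- explained_variance(X, fit)
    prev <- fit
  }
  explained <- cummax(explained)
  structure(data.frame(k = seq_len(k_max), explained = explained),
            class = c("variance_curve", "data.frame"))
}

#' Select the cluster count at the elbow of a variance curve
#'
#' Returns the smallest k whose marginal gain `explained(k+1) - explained(k)`
#' falls below `gain_threshold`; if every gain is at least the threshold, the
#' largest k on the curve.
#'
#' @param curve a [variance_curve()] (or data frame with `k` and `explained`).
#' @param gain_threshold minimal marginal gain that still justifies another
#'   cluster (default 0.05).
#' @return Integer cluster count.
#' @examples
#' cv <- data.frame(k = 1:5,
#'                  explained = c(0.640277, 0.821736, 0.911073, 0.951275, 0.975167))
#' select_k_elbow(cv)  # 3
#' @export
select_k_elbow <- function(curve, gain_threshold = 0.05) {
  abort_if(is.null(curve$k) || is.null(curve$explained) || nrow(curve) < 1L,
           "curve must have columns k and explained")
  curve <- curve[order(curve$k), ]
  if (nrow(curve) == 1L) return(as.integer(curve$k[1]))
  gains <- diff(curve$explained)
  below <- which(gains < gain_threshold)
  if (length(below) == 0L) return(as.integer(curve$k[nrow(curve)]))
  as.integer(curve$k[below[1]])
}

#' Assign a spectrum to its nearest habit by MAE
#'
#' Computes the mean absolute error between the spectrum and every centroid of
#' a raw-spectrum cluster model and returns the index of the closest habit
#' (ties broken toward the lowest index) together with all MAE values, so
#' callers can flag unusual behavior when even the best MAE is large.
#'
#' @param model a `cluster_model` with `feature_kind = "spectrum_raw"`.
#' @param x a `behavioral_spectrum` or numeric sample vector.
#' @return List with `cluster` (integer) and `mae` (numeric vector, one per
#'   centroid).
#' @export
assign_habit <- function(model, x) {
  stopifnot(inherits(model, "cluster_model"))
  abort_if(model$feature_kind != "spectrum_raw",
           "assign_habit needs a raw-spectrum model, not ", model$feature_kind)
  s <- if (inherits(x, "behavioral_spectrum")) x$samples else as.numeric(x)
  mae <- apply(model$centroids, 1, function(ctr) spectrum_mae(ctr, s))
  list(cluster = which.min(mae), mae = unname(mae))
}

#' Write a cluster model to JSON
#'
#' @param model a `cluster_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, feature_kind = model$feature_kind,
         centroids = apply(model$centroids, 1, identity, simplify = FALSE),
         labels = model$labels, wss = model$wss, sizes = model$sizes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
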