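test_that("k-means solves separable and trivial instances exactly", {
  m <- kmeans_fit(c(0, 0, 10, 10), 2, seed = 1)
  expect_equal(m$wss, 0)
  expect_setequal(as.numeric(m$centroids), c(0, 10))
  expect_equal(m$sizes, c(2L, 2L))

  m1 <- kmeans_fit(c(3, 5), 1)
  expect_equal(as.numeric(m1$centroids), 4)
  expect_equal(m1$wss, 2)

  expect_error(kmeans_fit(numeric(0), 1), "empty")
  expect_error(kmeans_fit(c(1, 1, 2), 3), "distinct")
})

test_that("best-of-restarts matches the exhaustive 2-partition optimum", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    fit <- kmeans_fit(X, 2, n_restarts = 20, seed = i)
    expect_equal(fit$wss, brute_wss2(X), tolerance = 1e-8)
  }
})

test_that("fits are deterministic given a seed", {
  set.seed(62)
  X <- matrix(rnorm(60), 30, 2)
  a <- kmeans_fit(X, 3, seed = 7)
  b <- kmeans_fit(X, 3, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
})

test_that("uncentered explained variance follows its closed form", {
  X <- c(3, 5)
  expect_equal(explained_variance(X, kmeans_fit(X, 1)), 1 - 2 / 34)
  expect_equal(explained_variance(X, kmeans_fit(X, 2)), 1)
  # all points identical and nonzero: k = 1 already explains everything
  X2 <- rep(2, 5)
  expect_equal(explained_variance(X2, kmeans_fit(X2, 1)), 1)
  expect_error(explained_variance(rep(0, 4), kmeans_fit(rep(0, 4), 1)), "zero")
})

test_that("variance curves are non-decreasing and end at 1 for k = n_distinct", {
  set.seed(63)
  for (i in 1:20) {
    X <- matrix(runif(sample(6:12, 1) * 2, 1, 7), ncol = 2)
    kmx <- nrow(unique(X))
    cv <- variance_curve(X, k_max = kmx, n_restarts = 10, seed = i)
    expect_true(all(diff(cv$explained) >= -1e-12))
    expect_equal(cv$explained[kmx], 1, tolerance = 1e-9)
    expect_gt(cv$explained[1], 0)  # uncentered: k = 1 is not zero
  }
})

test_that("elbow selection applies the marginal-gain rule", {
  flat <- data.frame(k = 1:4, explained = rep(0.8, 4))
  expect_identical(select_k_elbow(flat), 1L)
  steep <- data.frame(k = 1:4, explained = c(0.1, 0.3, 0.5, 0.7))
  expect_identical(select_k_elbow(steep), 4L)  # every gain >= threshold
  expect_identical(select_k_elbow(steep, gain_threshold = 0.25), 1L)
  expect_error(select_k_elbow(data.frame()), "curve")
})

test_that("habit assignment minimises MAE with low-index tie-breaking", {
  model <- structure(list(k = 2L,
                          centroids = rbind(rep(0.25, 200), rep(0.75, 200)),
                          labels = c(1L, 2L), wss = 0, sizes = c(1L, 1L),
                          feature_kind = "spectrum_raw"),
                     class = "cluster_model")
  hit <- assign_habit(model, rep(0.75, 200))
  expect_equal(hit$cluster, 2)
  expect_equal(hit$mae[2], 0)
  tie <- assign_habit(model, rep(0.5, 200))  # equidistant
  expect_equal(tie$cluster, 1)
  bad <- model
  bad$feature_kind <- "personality"
  expect_error(assign_habit(bad, rep(0.4, 200)), "raw-spectrum")
})

test_that("planted two-habit spectra are assigned to their generating habit", {
  set.seed(64)
  v <- worked_vocab()
  cfg <- worked_cfg()
  gen <- function(base, label) {
    d <- base * runif(length(base), 0.95, 1.05)
    ids <- seq_along(base)
    tr <- trial("s", "t", data.frame(seq_index = seq_along(base),
                                     activity = v$activity[ids],
                                     activity_id = ids, duration_min = d),
                window_min = 120)
    encode_trial(tr, cfg)
  }
  habits <- c(rep(1, 20), rep(2, 20))
  specs <- lapply(habits, function(h) {
    if (h == 1) gen(c(50, 25, 10)) else gen(c(15, 80))
  })
  X <- do.call(rbind, lapply(specs, `[[`, "samples"))
  model <- kmeans_fit(X, 2, seed = 2, feature_kind = "spectrum_raw")
  assigned <- vapply(specs, function(sp) assign_habit(model, sp)$cluster, 1L)
  agree <- max(sum((assigned == 1) == (habits == 1)),
               sum((assigned == 2) == (habits == 1)))
  expect_gte(agree / length(habits), 0.95)
})

test_that("cluster models serialize to JSON", {
  m <- kmeans_fit(matrix(c(0, 0, 4, 4, 0.5, 0, 4, 3.5), 4, 2), 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$k, 2)
  expect_equal(sort(back$labels), sort(m$labels))
})
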