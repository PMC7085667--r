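# Shared fixtures: all inputs are built in code.

worked_vocab <- function() {
  activity_vocab(c("eating_breakfast", "watching_tv", "cooking", "drinking",
                   "studying", "sleeping"))
}

# The two-event reference trial: eating breakfast 30 min then TV 60 min in a
# 120-minute window over a six-activity vocabulary.
worked_trial <- function() {
  v <- worked_vocab()
  trial("s1", "t1",
        data.frame(seq_index = 1:2, activity = v$activity[1:2],
                   activity_id = 1:2, duration_min = c(30, 60)),
        window_min = 120)
}

worked_cfg <- function() encoding_config(window_min = 120, vocab_size = 6)

# Random valid trial with K <= k_max events over an M-activity vocabulary.
random_trial <- function(id, M = 6, W = 120, k_max = 20, d_min = 1) {
  K <- sample.int(k_max, 1)
  budget <- max(K * d_min, W * runif(1, 0.3, 1))
  p <- runif(K)
  d <- d_min + p / sum(p) * (budget - K * d_min)
  ids <- sample.int(M, K, replace = TRUE)
  trial("s", paste0("t", id),
        data.frame(seq_index = seq_len(K), activity = paste0("a", ids),
                   activity_id = ids, duration_min = d),
        window_min = W)
}

# Exhaustive-partition k = 2 oracle: minimum within-cluster sum of squares
# over every split of the rows into two non-empty groups.
brute_wss2 <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    wss <- 0
    for (g in list(which(grp), which(!grp))) {
      ctr <- colMeans(X[g, , drop = FALSE])
      wss <- wss + sum((X[g, , drop = FALSE] -
                          matrix(ctr, length(g), ncol(X), byrow = TRUE))^2)
    }
    best <- min(best, wss)
  }
  best
}

# Binary label vectors realizing a 2x2 confusion table [[a, b], [c, d]].
labels_from_table <- function(a, b, c, d) {
  list(x = rep(c(1, 1, 2, 2), c(a, b, c, d)),
       y = rep(c(1, 2, 1, 2), c(a, b, c, d)))
}
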