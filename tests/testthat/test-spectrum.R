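test_that("worked two-event trial encodes to the expected harmonic table", {
  sp <- encode_trial(worked_trial(), worked_cfg())
  expect_equal(sp$harmonics$amplitude, c(0.25, 0.5))
  expect_equal(sp$harmonics$phase, c(2 * pi / 7, 4 * pi / 7))
  expect_equal(sp$a0, 0.75)
  # samples satisfy the synthesis formula and average to the DC term
  n <- 0:199
  manual <- 0.75 + 0.25 * cos(2 * pi * n / 200 + 2 * pi / 7) +
    0.5 * cos(4 * pi * n / 200 + 4 * pi / 7)
  expect_equal(sp$samples, manual, tolerance = 1e-12)
  expect_equal(mean(sp$samples), sp$a0, tolerance = 1e-9)
})

test_that("full-occupancy single activity gives a flat-mean unit spectrum", {
  v <- worked_vocab()
  tr <- trial("s", "t", data.frame(seq_index = 1, activity = v$activity[3],
                                   activity_id = 3, duration_min = 120),
              window_min = 120)
  sp <- encode_trial(tr, worked_cfg())
  expect_equal(sp$a0, 1)
  expect_equal(sp$harmonics$amplitude, 1)
  expect_equal(sp$harmonics$phase, 6 * pi / 7)
  expect_equal(mean(sp$samples), 1, tolerance = 1e-9)
})

test_that("decode inverts encode exactly on IDs and closely on durations", {
  cfg <- worked_cfg()
  dec <- decode_spectrum(encode_trial(worked_trial(), cfg), cfg)
  expect_identical(dec$activity_id, 1:2)
  expect_equal(dec$duration_min, c(30, 60), tolerance = 1e-6)

  set.seed(21)
  for (i in 1:300) {
    tr <- random_trial(i)
    out <- decode_spectrum(encode_trial(tr, cfg), cfg)
    expect_identical(out$activity_id, as.integer(tr$events$activity_id))
    expect_lt(max(abs(out$duration_min - tr$events$duration_min)), 1e-6)
  }
})

test_that("decoder rejects degenerate and malformed spectra", {
  cfg <- worked_cfg()
  expect_error(decode_spectrum(rep(0.4, 200), cfg), "no activities")
  # harmonics at positions 1 and 3 but nothing at 2: a sequence gap
  n <- 0:199
  gappy <- 0.5 + 0.2 * cos(2 * pi * n / 200 + 2 * pi / 7) +
    0.2 * cos(6 * pi * n / 200 + 4 * pi / 7)
  expect_error(decode_spectrum(gappy, cfg), "gap")
  # phase off the M+1 grid
  off <- 0.5 + 0.3 * cos(2 * pi * n / 200 + 2 * pi / 7 + 0.5)
  expect_error(decode_spectrum(off, cfg), "off-grid")
})

test_that("encoding respects the Nyquist guard", {
  expect_error(encoding_config(window_min = 400, vocab_size = 6, k_max = 100),
               "Nyquist")
  v <- activity_vocab(paste0("a", 1:6))
  ids <- rep(1:6, length.out = 95)
  tr_events <- data.frame(seq_index = 1:95, activity = paste0("a", ids),
                          activity_id = ids, duration_min = rep(1, 95))
  expect_error(trial("s", "t", tr_events, window_min = 400), "k_max")
})

test_that("reordering events changes samples but preserves total power", {
  v <- worked_vocab()
  mk <- function(durs) {
    trial("s", "t", data.frame(seq_index = 1:2, activity = v$activity[1:2],
                               activity_id = 1:2, duration_min = durs),
          window_min = 120)
  }
  a <- encode_trial(mk(c(30, 60)), worked_cfg())
  b <- encode_trial(mk(c(60, 30)), worked_cfg())
  expect_gt(spectrum_mae(a, b), 0.01)
  expect_equal(sum(a$harmonics$amplitude^2), sum(b$harmonics$amplitude^2))
  # Parseval at full-period sampling: population sd = sqrt(sum(A^2)/2)
  for (sp in list(a, b)) {
    expect_equal(sqrt(mean((sp$samples - mean(sp$samples))^2)),
                 sqrt(sum(sp$harmonics$amplitude^2) / 2), tolerance = 1e-9)
  }
})

test_that("spectrum MAE has its closed-form values", {
  expect_equal(spectrum_mae(rep(0.3, 200), rep(0.3, 200)), 0)
  expect_equal(spectrum_mae(rep(0.2, 200), rep(0.5, 200)), 0.3)
  expect_error(spectrum_mae(rep(0, 200), rep(0, 100)), "different lengths")
  # one unit harmonic vs a flat signal at the same DC level: mean |cos|
  n <- 0:199
  sig <- 0.5 + cos(2 * pi * n / 200 + 2 * pi / 7)
  expect_equal(spectrum_mae(sig, rep(0.5, 200)),
               mean(abs(cos(2 * pi * n / 200 + 2 * pi / 7))))
  expect_equal(spectrum_mae(sig, rep(0.5, 200)), 2 / pi, tolerance = 1e-3)
})

test_that("spectrum sets write one row per trial with full precision", {
  set.seed(31)
  trials <- lapply(1:4, random_trial)
  specs <- encode_trials(trials, worked_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(specs, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4)
  expect_equal(as.numeric(df[2, paste0("s", 0:199)]),
               specs$samples[2, ], ignore_attr = TRUE)
})
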