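test_that("cohorts are reproducible from their config and seed", {
  cc <- cohort_config_aal(seed = 17)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_equal(a$subjects, b$subjects)
  expect_equal(a$trials, b$trials)
  expect_equal(a$tipi, b$tipi)
  c2 <- generate_cohort(cohort_config_aal(seed = 18))
  expect_false(isTRUE(all.equal(a$subjects, c2$subjects)))
  expect_length(a$trials, 29)
  expect_equal(nrow(a$subjects), 24)
})

test_that("latent traits stay on the 1-7 scale with the stated center", {
  big <- generate_subjects(cohort_config(n_subjects = 10000, seed = 3))
  tr <- as.matrix(big[c("E", "A", "C", "N", "O")])
  expect_true(all(tr >= 1 & tr <= 7))
  expect_true(all(abs(colMeans(tr) - 4) < 0.05))
})

test_that("every generated trial passes the activity-log contract", {
  for (cc in list(cohort_config_aal(seed = 5),
                  cohort_config_hs(seed = 5),
                  cohort_config(n_subjects = 6, trials_per_subject = 2,
                                coupling = 2, base_rate = 5, seed = 5))) {
    trials <- generate_trials(generate_subjects(cc), cc)
    for (tr in trials) expect_silent(validate_trial(tr, d_min = cc$d_min,
                                                    k_max = cc$k_max))
    total <- vapply(trials, function(t) sum(t$events$duration_min), 1)
    expect_true(all(abs(total - cc$occupancy * cc$window_min) < 1e-9))
    # no immediate activity repeats
    for (tr in trials) {
      ids <- tr$events$activity_id
      if (length(ids) > 1) expect_true(all(diff(ids) != 0))
    }
  }
  # HS preset: one trial per subject in each period
  hs <- generate_trials(generate_subjects(cohort_config_hs(seed = 5)),
                        cohort_config_hs(seed = 5))
  expect_equal(as.integer(table(vapply(hs, `[[`, "", "period"))), rep(12L, 3))
})

test_that("zero coupling leaves activity counts independent of neuroticism", {
  cc <- cohort_config(n_subjects = 250, trials_per_subject = 4, coupling = 0,
                      seed = 23)
  subjects <- generate_subjects(cc)
  trials <- generate_trials(subjects, cc)
  K <- vapply(trials, function(t) nrow(t$events), 1L)
  subj <- vapply(trials, `[[`, "", "subject_id")
  neuro <- subjects$N[match(subj, subjects$subject_id)]
  tercile <- cut(neuro, quantile(neuro, c(0, 1/3, 2/3, 1)),
                 include.lowest = TRUE, labels = FALSE)
  tab <- table(tercile, pmin(K, 6))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("strong coupling makes activity counts rise across neuroticism terciles", {
  # lambda spans 2 at N = 1 to 8 at N = 7
  cc <- cohort_config(n_subjects = 200, trials_per_subject = 2, coupling = 1,
                      base_rate = 5, window_min = 60, seed = 29)
  subjects <- generate_subjects(cc)
  trials <- generate_trials(subjects, cc)
  K <- vapply(trials, function(t) nrow(t$events), 1L)
  subj <- vapply(trials, `[[`, "", "subject_id")
  neuro <- subjects$N[match(subj, subjects$subject_id)]
  tercile <- cut(neuro, quantile(neuro, c(0, 1/3, 2/3, 1)),
                 include.lowest = TRUE, labels = FALSE)
  means <- tapply(K, tercile, mean)
  expect_true(all(diff(means) > 0))
})

test_that("questionnaires invert the keying so scoring recovers the traits", {
  cc0 <- cohort_config(n_subjects = 30, item_noise = 0, seed = 31)
  subjects <- generate_subjects(cc0)
  traits <- c("E", "A", "C", "N", "O")
  subjects[traits] <- lapply(subjects[traits], round)  # integer traits: exact recovery
  sc <- score_tipi_table(generate_questionnaires(subjects, cc0))
  expect_equal(sc[traits], subjects[traits], tolerance = 1e-12)

  cc <- cohort_config(n_subjects = 1000, item_noise = 0.8, seed = 37)
  subs <- generate_subjects(cc)
  got <- score_tipi_table(generate_questionnaires(subs, cc))
  expect_true(all(as.matrix(got[c("E", "A", "C", "N", "O")]) >= 1))
  expect_lt(mean(abs(got$N - subs$N)), 0.5)
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(n_subjects = 2, occupancy = 0), "occupancy")
  expect_error(cohort_config(n_subjects = 2, base_rate = 0), "base_rate")
  expect_error(cohort_config(n_subjects = 2, coupling = -1), "coupling")
  expect_error(cohort_config(n_subjects = 2, window_min = 0.5), "window")
  expect_error(cohort_config(n_subjects = 2, periods = "noon"), "periods")
})
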