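test_that("TSST grid matches the blood-draw schedule", {
  g <- tsst_time_grid()
  expect_identical(g, c(-30, -15, 0, 10, 20, 35, 50, 65, 80, 95, 110))
  expect_length(g, 11L)
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(g[g >= 20]) == 15))  # every 15 min after the test
})

write_cohort_csv <- function(df, path = withr::local_tempfile(
                               fileext = ".csv",
                               .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

two_subject_df <- function() {
  g <- tsst_time_grid()
  dplyr::bind_rows(
    tibble::tibble(subject_id = "1", group = "control", time_min = g,
                   acth = 20 + seq_along(g), cortisol = 8 + seq_along(g)),
    tibble::tibble(subject_id = "2", group = "MDD-neither", time_min = g,
                   acth = 30 - seq_along(g), cortisol = 10 - 0.1 * seq_along(g)))
}

test_that("a complete cohort file loads with all subjects", {
  path <- write_cohort_csv(two_subject_df())
  co <- load_cohort(path)
  expect_s3_class(co, "hpa_cohort")
  expect_identical(cohort_subjects(co), c("1", "2"))
  expect_identical(attr(co, "excluded"), character(0))
})

test_that("subjects with missing grid points are excluded with a message", {
  df <- two_subject_df()
  df <- df[!(df$subject_id == "2" & df$time_min == 35), ]
  path <- write_cohort_csv(df)
  expect_message(co <- load_cohort(path), "excluding.*2")
  expect_identical(cohort_subjects(co), "1")
  expect_identical(attr(co, "excluded"), "2")
})

test_that("non-numeric cells fail parsing with a row number", {
  df <- two_subject_df()
  df$cortisol <- as.character(df$cortisol)
  df$cortisol[5] <- "oops"
  path <- write_cohort_csv(df)
  expect_error(suppressWarnings(load_cohort(path)), "row")
})

test_that("empty and malformed files are rejected", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,group,time_min,acth,cortisol", p1)
  expect_error(load_cohort(p1), "empty")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1), p2)
  expect_error(suppressWarnings(load_cohort(p2)), "missing columns")
  expect_error(load_cohort("/nonexistent/file.csv"), "no such file")
})

test_that("cohort round-trips through write_cohort/load_cohort", {
  co <- synth_tsst_cohort(5, seed = 9, anomaly_fraction = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- load_cohort(path)
  expect_identical(tibble::as_tibble(co2)[, c("subject_id", "group",
                                              "time_min", "acth",
                                              "cortisol")],
                   tibble::as_tibble(co)[, c("subject_id", "group",
                                             "time_min", "acth",
                                             "cortisol")])
})

test_that("cohort mean and SD match hand computation and streaming oracle", {
  g <- tsst_time_grid()
  df <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", group = "control", time_min = g,
                   acth = rep(2, 11), cortisol = rep(4, 11)),
    tibble::tibble(subject_id = "b", group = "control", time_min = g,
                   acth = rep(4, 11), cortisol = rep(6, 11)))
  co <- hpavv:::new_cohort(df)
  cm <- cohort_mean(co)
  expect_equal(cm$cortisol, rep(5, 11))
  expect_equal(cm$cortisol_sd, rep(sqrt(2), 11))  # sample SD, n - 1
  expect_equal(cm$acth, rep(3, 11))
  # single subject: mean equals the subject, SD = 0
  one <- hpavv:::new_cohort(df[df$subject_id == "a", ])
  cm1 <- cohort_mean(one)
  expect_equal(cm1$acth, rep(2, 11))
  expect_equal(cm1$acth_sd, rep(0, 11))
  # invariance under subject reordering
  cm_rev <- cohort_mean(hpavv:::new_cohort(df[order(df$subject_id,
                                                    decreasing = TRUE), ]))
  expect_equal(cm_rev$cortisol, cm$cortisol)
  # streaming recomputation oracle
  big <- synth_tsst_cohort(20, seed = 4)
  cmb <- cohort_mean(big)
  tb <- tibble::as_tibble(big)
  for (tp in sample(tsst_time_grid(), 3)) {
    v <- tb$cortisol[tb$time_min == tp]
    n <- 0; mean_s <- 0; m2 <- 0
    for (x in v) {  # Welford
      n <- n + 1; d <- x - mean_s; mean_s <- mean_s + d / n
      m2 <- m2 + d * (x - mean_s)
    }
    expect_equal(cmb$cortisol[cmb$time_min == tp], mean_s,
                 tolerance = 1e-12)
    expect_equal(cmb$cortisol_sd[cmb$time_min == tp],
                 sqrt(m2 / (n - 1)), tolerance = 1e-12)
  }
})

test_that("synthetic TSST cohorts have the expected stress shape", {
  co <- synth_tsst_cohort(50, anomaly_fraction = 0, seed = 21)
  cm <- cohort_mean(co)
  peak_t <- cm$time_min[which.max(cm$cortisol)]
  expect_gte(peak_t, 10); expect_lte(peak_t, 50)
  pre <- mean(cm$cortisol[cm$time_min <= 0])
  expect_lt(abs(cm$cortisol[cm$time_min == 110] - pre) / pre, 0.25)
  # ACTH peak precedes (or ties) the cortisol peak in the mean profile
  expect_lte(cm$time_min[which.max(cm$acth)], peak_t)
  # per-subject shape: pre-test flat-ish, in-test rise, post-test return
  tb <- tibble::as_tibble(co)
  ok <- vapply(split(tb, tb$subject_id), function(s) {
    s <- s[order(s$time_min), ]
    pre_m <- mean(s$cortisol[s$time_min <= 0])
    rise <- max(s$cortisol[s$time_min >= 10 & s$time_min <= 50]) > 1.2 * pre_m
    ret <- abs(s$cortisol[s$time_min == 110] - pre_m) / pre_m < 0.5
    rise && ret
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # everything positive and finite
  expect_true(all(is.finite(tb$acth)), all(tb$acth > 0))
  expect_true(all(is.finite(tb$cortisol)), all(tb$cortisol > 0))
})

test_that("anomalous responders decrease in ACTH and peak cortisol at +50", {
  co <- synth_tsst_cohort(1, anomaly_fraction = 1, seed = 7)
  s <- cohort_subject(co, "1")
  expect_true(all(diff(s$acth) < 0))
  expect_equal(s$time_min[which.max(s$cortisol)], 50)
})

test_that("seeded generators are exactly reproducible", {
  expect_identical(tibble::as_tibble(synth_tsst_cohort(12, seed = 33)),
                   tibble::as_tibble(synth_tsst_cohort(12, seed = 33)))
  expect_false(identical(
    tibble::as_tibble(synth_tsst_cohort(12, seed = 33)),
    tibble::as_tibble(synth_tsst_cohort(12, seed = 34))))
  expect_identical(synth_basal_series(seed = 2), synth_basal_series(seed = 2))
})

test_that("group mix defaults to 15 controls and 43 MDD in a 58-cohort", {
  co <- synth_tsst_cohort(58, seed = 1)
  tb <- dplyr::distinct(tibble::as_tibble(co), .data$subject_id, .data$group)
  expect_identical(nrow(tb), 58L)
  expect_identical(sum(tb$group == "control"), 15L)
  expect_identical(sum(tb$group != "control"), 43L)
})

test_that("basal series shows 12-18 ultradian episodes under a circadian peak", {
  b <- synth_basal_series(seed = 3)
  n_max <- count_local_maxima(b$cortisol)
  expect_gte(n_max, 11); expect_lte(n_max, 19)
  expect_true(all(b$cortisol >= 0), all(b$acth >= 0))
  expect_equal(b$time_min, seq(0, 1440, by = 10))
  # envelope argmax near 8 AM: no pulses, pure envelope
  env <- synth_basal_series(n_pulses = 0, seed = 3)
  argmax <- env$time_min[which.max(env$cortisol)]
  expect_lte(abs(argmax - 480), 30)
  # flat envelope and no pulses: constant series
  flat <- synth_basal_series(circadian_params =
                               circadian_drive(mesor = 1, amplitude = 0),
                             n_pulses = 0, seed = 3)
  expect_equal(diff(range(flat$cortisol)), 0)
})

test_that("save_results writes a reloadable delimited store", {
  m <- hpa_model_minimal()
  sub <- model_subject(m, burn_in = 30, noise_cv = 0.1, seed = 2)
  vr <- run_validation(m, sub, free = c("k_c", "K_i", "w_f"), repeats = 5,
                       popsize = 5, generations = 2, seeds = 11:15,
                       config = cost_config(burn_in = 0),
                       dataset_id = "sim")
  dir <- withr::local_tempdir()
  sols <- tibble::tibble(run_id = "sim-r1", time = c(0, 10),
                         acth = c(1, 2), cortisol = c(3.123456789012, 4))
  files <- save_results(vr, sols, dir)
  expect_true(grepl("sim", basename(files[["parameters"]])))
  back <- load_results(dir)
  expect_identical(nrow(back$parameters), 5L)
  # >= 3 parameter columns + bookkeeping columns
  expect_true(all(c("k_c", "K_i", "w_f", "run_id", "seed",
                    "best_cost") %in% names(back$parameters)))
  # lossless round-trip of doubles
  expect_identical(back$parameters$best_cost,
                   vapply(vr$runs, function(r) r$best_cost, numeric(1)))
  expect_identical(back$solutions$cortisol, sols$cortisol)
})
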