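test_that("differential evolution solves the 3-D sphere to near zero", {
  run <- differential_evolution(function(x) sum(x^2),
                                lower = rep(-5, 3), upper = rep(5, 3),
                                popsize = 15, generations = 200, seed = 42)
  expect_lt(run$best_cost, 1e-6)
  expect_equal(run$best_cost, sum(run$best_params^2))
  expect_true(all(diff(run$trace) <= 0))
})

test_that("every evaluated candidate respects the bounds", {
  seen <- new.env(); seen$bad <- 0L
  lower <- c(-2, 0.5); upper <- c(1, 4)
  obj <- function(x) {
    if (any(x < lower - 1e-12) || any(x > upper + 1e-12))
      seen$bad <- seen$bad + 1L
    sum((x - c(0.2, 2))^2)
  }
  run <- differential_evolution(obj, lower, upper, popsize = 12,
                                generations = 60, seed = 7)
  expect_identical(seen$bad, 0L)
  expect_true(all(run$best_params >= lower & run$best_params <= upper))
})

test_that("1-D convex objective is located precisely", {
  run <- differential_evolution(function(x) (x - 2)^2, 0, 5,
                                popsize = 10, generations = 80, seed = 3)
  expect_lt(abs(run$best_params - 2), 1e-3)
})

test_that("identical seeds give identical runs; different seeds differ", {
  f <- function(x) sum((x - 1)^2)
  r1 <- differential_evolution(f, rep(-3, 2), rep(3, 2), popsize = 8,
                               generations = 25, seed = 99)
  r2 <- differential_evolution(f, rep(-3, 2), rep(3, 2), popsize = 8,
                               generations = 25, seed = 99)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_params, r2$best_params)
  r3 <- differential_evolution(f, rep(-3, 2), rep(3, 2), popsize = 8,
                               generations = 25, seed = 100)
  expect_false(identical(r1$trace, r3$trace))
})

test_that("non-finite objective values are rejected, not fatal", {
  f <- function(x) if (x[1] > 0.5) NaN else sum(x^2)
  run <- differential_evolution(f, -1, 1, popsize = 8, generations = 30,
                                seed = 5)
  expect_true(is.finite(run$best_cost))
  expect_gt(run$n_nonfinite, 0L)
  expect_lte(run$best_params, 0.5)
})

test_that("spread-based termination stops early on flat populations", {
  run <- differential_evolution(function(x) 1, -1, 1, popsize = 6,
                                generations = 500, seed = 1, tol = 1e-12)
  expect_lt(run$generations, 500L)
})

test_that("evaluating generating parameters on self-generated data is free", {
  m <- hpa_model_minimal()
  cc <- cost_config(burn_in = 0)
  sub <- model_subject(m, burn_in = 0)
  bd <- evaluate_params(m, NULL, sub, cc)
  expect_lt(bd$total, 1e-6)
  # any parameters give nonnegative cost
  bd2 <- evaluate_params(m, c(k_c = 0.7), sub, cc)
  expect_gte(bd2$total, 0)
})

test_that("generating truth is locally optimal against 10% perturbations", {
  m <- hpa_model_minimal()
  cc <- cost_config(burn_in = 0)
  sub <- model_subject(m, burn_in = 0)
  base <- evaluate_params(m, NULL, sub, cc)$total
  p0 <- param_defaults(m)[c("k_c", "K_i", "w_f")]
  set.seed(77)
  wins <- 0L
  for (i in 1:20) {
    pert <- p0 * (1 + 0.1 * stats::runif(3, -1, 1))
    tot <- suppressWarnings(evaluate_params(m, pert, sub, cc)$total)
    if (base <= tot) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("integration failure is reported as infinite cost, not an error", {
  m <- hpa_model_minimal()
  sub <- model_subject(m, burn_in = 0)
  bad <- m
  bad$rhs <- function(t, y, params, lagged, drivers) y^2 + 1
  bad$steady_guess <- NULL
  bd <- suppressWarnings(
    evaluate_params(bad, NULL, sub, cost_config(burn_in = 0)))
  expect_identical(bd$total, Inf)
  expect_true(!is.null(bd$failure))
})

test_that("out-of-bounds parameters warn but still evaluate", {
  m <- hpa_model_minimal()
  sub <- model_subject(m, burn_in = 0)
  expect_warning(
    bd <- evaluate_params(m, c(k_c = 10), sub, cost_config(burn_in = 0)),
    "outside declared bounds")
  expect_true(is.finite(bd$total))
})

test_that("run_validation produces one run per distinct seed", {
  m <- hpa_model_minimal()
  sub <- model_subject(m, burn_in = 240, noise_cv = 0.1, seed = 15)
  cc <- recovery_config()
  vr <- run_validation(m, sub, free = c("k_c", "w_f"), repeats = 3,
                       popsize = 5, generations = 3, seeds = c(4, 9, 16),
                       config = cc, dataset_id = "s")
  expect_length(vr$runs, 3L)
  expect_identical(vapply(vr$runs, function(r) r$seed, numeric(1)),
                   c(4, 9, 16))
  # default-member injection: no run is worse than the default cost
  best <- vapply(vr$runs, function(r) r$best_cost, numeric(1))
  expect_true(all(best <= vr$default_cost + 1e-12))
  expect_error(run_validation(m, sub, repeats = 2, seeds = c(1, 1)),
               "distinct")
})

test_that("an empty free set degenerates to a single default evaluation", {
  m <- hpa_model_minimal()
  sub <- model_subject(m, burn_in = 0)
  vr <- run_validation(m, sub, free = character(0), repeats = 5,
                       config = cost_config(burn_in = 0), dataset_id = "d")
  expect_length(vr$runs, 1L)
  expect_equal(vr$runs[[1]]$best_cost, vr$default_cost)
  expect_identical(vr$runs[[1]]$generations, 0L)
})

test_that("per-dataset and overall aggregation match hand computation", {
  tb <- tibble::tibble(dataset = c("a", "a", "a", "b"),
                       cost = c(1, 2, 3, 10))
  agg <- aggregate_costs(tb)
  a <- agg$per_dataset[agg$per_dataset$dataset == "a", ]
  expect_equal(a$mean_cost, 2)
  expect_equal(a$sd_cost, 1)     # sample SD of {1,2,3}
  expect_equal(a$best_cost, 1)
  expect_equal(agg$overall$overall_mean, mean(c(2, 10)))
  expect_equal(agg$overall$overall_sd, stats::sd(c(2, 10)))
  # single dataset: overall equals that dataset's mean
  agg1 <- aggregate_costs(tb[tb$dataset == "a", ])
  expect_equal(agg1$overall$overall_mean, 2)
  expect_equal(agg1$overall$overall_sd, 0)
})

test_that("batch_over_subjects runs the full protocol shape", {
  m <- hpa_model_minimal()
  co <- synth_tsst_cohort(6, anomaly_fraction = 0, seed = 10)
  rep_ <- batch_over_subjects(m, co, subjects = c("2", "5", "mean"),
                              repeats = 2, popsize = 5, generations = 2,
                              base_seed = 3,
                              config = cost_config(burn_in = 60))
  expect_identical(nrow(rep_$per_dataset), 3L)
  expect_identical(sum(rep_$per_dataset$n_runs), 6L)
  expect_equal(rep_$overall$overall_mean,
               mean(rep_$per_dataset$mean_cost))
  # seeds distinct across datasets and repeats
  seeds <- unlist(lapply(rep_$runs, function(vr)
    vapply(vr$runs, function(r) r$seed, numeric(1))))
  expect_false(anyDuplicated(seeds) > 0)
  expect_error(batch_over_subjects(m, co, subjects = "nope"), "unknown")
})

test_that("model ranking sorts ascending by overall mean with name ties", {
  fake <- function(name, overall) {
    structure(list(model_name = name,
                   per_dataset = tibble::tibble(dataset = "d", n_runs = 1L,
                                                mean_cost = overall,
                                                sd_cost = 0,
                                                best_cost = overall,
                                                default_cost = overall),
                   overall = tibble::tibble(overall_mean = overall,
                                            overall_sd = 0)),
              class = "validation_report")
  }
  rk <- rank_models(list(fake("c", 6.8), fake("a", 2.6), fake("b", 0.3)))
  expect_identical(rk$model, c("b", "a", "c"))
  rk2 <- rank_models(list(fake("z", 1), fake("y", 1)))
  expect_identical(rk2$model, c("y", "z"))
})

test_that("generalization matrix is consistent with training runs and groups", {
  m <- hpa_model_minimal()
  cc <- cost_config(burn_in = 60)
  co <- synth_tsst_cohort(4, anomaly_fraction = 0, seed = 19)
  vr <- run_validation(m, cohort_subject(co, "1"),
                       free = c("k_c", "K_i", "w_f"),
                       repeats = 2, popsize = 6, generations = 4,
                       seeds = c(5, 6), config = cc, dataset_id = "1")
  dir <- withr::local_tempdir()
  save_results(vr, NULL, dir)
  saved <- load_results(dir)
  gen <- generalization_matrix(m, saved$parameters, co, config = cc)
  expect_identical(dim(gen$matrix), c(2L, 4L))
  # training cell reproduces the stored best cost
  expect_equal(gen$matrix["1-r1", "1"], vr$runs[[1]]$best_cost,
               tolerance = 1e-9)
  expect_equal(gen$matrix["1-r2", "1"], vr$runs[[2]]$best_cost,
               tolerance = 1e-9)
  # group summary equals hand-computed column means per group
  tb <- dplyr::distinct(tibble::as_tibble(co), .data$subject_id, .data$group)
  for (g in unique(tb$group)) {
    cols <- tb$subject_id[tb$group == g]
    expect_equal(
      gen$by_group$mean_cost[gen$by_group$group == g &
                               gen$by_group$run_id == "1-r1"],
      mean(gen$matrix["1-r1", cols]))
  }
})
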