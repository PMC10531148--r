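small_config <- function(...) {
  experiment_config(n_train_reps = 2L, n_bootstrap = 6L,
                    train_fracs = c(1.0, 0.5),
                    alpha_grid = c(0.1, 0.5, 0.9),
                    min_occupancy_grid = c(40L, 120L),
                    min_occupancy = 40L, seed = 7L, ...)
}

test_that("patient split is a deterministic disjoint partition", {
  ids <- 1:100
  sp <- split_patients(ids, c(0.6, 0.2, 0.2), seed = 3)
  expect_length(sp$train, 60)
  expect_length(sp$validation, 20)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_patients(ids, c(0.6, 0.2, 0.2), seed = 3))
  expect_false(identical(sp, split_patients(ids, c(0.6, 0.2, 0.2), seed = 4)))
  expect_error(split_patients(ids, c(0.7, 0.3, 0)), "fractions")
})

test_that("the pipeline produces all five policies with paired bootstrap", {
  v <- small_cohort()
  res <- run_policy_comparison(v, small_config())
  expect_named(res$policies,
               c("policy_iteration", "q_learning", "clinician", "zero", "random"))
  expect_equal(sort(unique(res$rewards$policy)), sort(POLICY_NAMES))
  counts <- table(res$rewards$policy)
  expect_true(all(counts == 6))          # one value per bootstrap replicate
  expect_equal(nrow(res$actions), n_states(res$state_model))
  # zero and random policies have their defining shapes at pipeline scale
  S <- n_states(res$state_model)
  expect_equal(policy_actions(res$policies$zero), rep(1L, S))
  expect_true(all(res$policies$random == 1 / 6))
})

test_that("the data-size sweep runs per fraction on one state abstraction", {
  v <- small_cohort()
  res <- run_test1(v, small_config())
  expect_named(res, c("frac_1", "frac_0.5"))
  # the fractions share one fitted state model, so rewards are comparable
  expect_identical(res$frac_1$state_model$rules, res$frac_0.5$state_model$rules)
  for (r in res) expect_setequal(unique(r$rewards$policy), POLICY_NAMES)
})

test_that("forgoing treatment scores below the data-driven clinician policy", {
  # under dynamics where no-drugs accelerates cognitive decline in every
  # non-floor state, the zero policy cannot beat the clinician policy;
  # checked at a cohort size where step-WIS noise is well below the gap
  v <- prepare_visits(generate_cohort(
    generator_config(n_patients = 400, seed = 201), default_true_mdp()))
  cfg <- experiment_config(n_train_reps = 2L, n_bootstrap = 6L,
                           train_fracs = 1, min_occupancy = 40L, seed = 1L)
  res <- run_policy_comparison(v, cfg)
  expect_gte(res$point_estimates[["clinician"]], res$point_estimates[["zero"]])
  summ <- compare_policies(res)$summary
  expect_gte(summ$mean[summ$policy == "clinician"],
             summ$mean[summ$policy == "zero"] - 0.5)
})

test_that("test1 result files are byte-identical across reruns", {
  v <- small_cohort()
  cfg <- small_config()
  d1 <- file.path(tempdir(), "t1a"); d2 <- file.path(tempdir(), "t1b")
  run_test1(v, cfg, out_dir = d1)
  run_test1(v, cfg, out_dir = d2)
  for (f in c("test1_rewards.csv", "test1_summary.csv", "test1_actions.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("comorbidity cohorts run with containment and action tables", {
  v <- small_cohort()
  res <- run_test2(v, small_config(), cohorts = c("AD", "AD_HTN"))
  expect_true(all(c("AD", "AD_HTN") %in% names(res)))
  for (r in res) {
    expect_equal(nrow(r$actions), n_states(r$state_model))
    expect_true(all(unlist(r$actions[, -1]) %in% ACTIONS))
  }
  expect_gte(length(unique(build_cohort(v, "AD_HTN")$RID)),
             length(unique(build_cohort(v, "AD")$RID)))
})

test_that("JR/SR stratification partitions patients at the grand mean", {
  v <- small_cohort()
  st <- stratify_jr_sr(v)
  expect_setequal(st$RID, unique(v$RID))
  expect_true(all(st$stratum %in% c("JR", "SR")))
  grand <- mean(st$mean_mmse)
  expect_true(all(st$mean_mmse[st$stratum == "JR"] < grand))
  expect_true(all(st$mean_mmse[st$stratum == "SR"] >= grand))
  # a patient at ceiling MMSE in a declining cohort lands in SR
  expect_equal(st$stratum[which.max(st$mean_mmse)], "SR")
  # SR patients decline more slowly under the severity-coupled dynamics
  obs <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(v, st, by = "RID"), stratum),
    decline = mean(diff(MMSE)[diff(MONTH) > 0]))
  expect_gte(obs$decline[obs$stratum == "SR"],
             obs$decline[obs$stratum == "JR"] - 0.5)
})

test_that("learning-rate sweep covers the grid and rejects bad rates", {
  v <- small_cohort()
  res <- run_test4(v, small_config())
  expect_length(res, 3)
  expect_named(res, c("alpha_0.1", "alpha_0.5", "alpha_0.9"))
  expect_error(experiment_config(alpha_grid = c(0.1, 1.0)), "alpha_grid")
  expect_error(experiment_config(alpha = 0), "alpha")
  # on a deterministic replayed log the converged greedy policy does not
  # depend on the learning rate
  det <- random_deterministic_model(3, 3, seed = 77)
  log <- replay_log(det)
  pols <- lapply(c(0.1, 0.5, 0.9), function(a)
    policy_actions(greedy_policy(q_learning(log, gamma = 0.3, alpha = a,
                                            n_passes = 600, seed = 1,
                                            n_states = 3))))
  expect_identical(pols[[1]], pols[[2]])
  expect_identical(pols[[2]], pols[[3]])
})

test_that("state-count sweep reports non-increasing state counts", {
  v <- small_cohort()
  res <- run_test5(v, small_config())
  expect_length(res, 2)
  ns <- vapply(res, `[[`, integer(1), "n_states")
  expect_true(all(ns >= 1))
  expect_lte(ns[["occ_120"]], ns[["occ_40"]])
})

test_that("policy comparison summarizes, tests and plots", {
  v <- small_cohort()
  res <- run_policy_comparison(v, small_config())
  cmp <- compare_policies(res)
  expect_setequal(cmp$summary$policy, POLICY_NAMES)
  expect_true(all(c("mean", "median", "q25", "q75") %in% names(cmp$summary)))
  expect_equal(dim(cmp$p_values), c(5, 5))
  expect_s3_class(cmp$plot, "ggplot")
  # identical distributions: P ~ 1; far-shifted distributions: P < 0.001
  fake <- res
  fake$rewards <- tibble::tibble(
    policy = rep(c("a", "b"), each = 20), replicate = rep(1:20, 2),
    value = c(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1)))
  cmp2 <- compare_policies(fake)
  expect_lt(cmp2$p_values["a", "b"], 0.001)
  same <- res
  same$rewards <- tibble::tibble(
    policy = rep(c("a", "b"), each = 20), replicate = rep(1:20, 2),
    value = rep(sin(1:20), 2))
  expect_gt(compare_policies(same)$p_values["a", "b"], 0.99)
  bad <- res
  bad$rewards <- bad$rewards[-1, ]
  expect_error(compare_policies(bad), "unequal")
})
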