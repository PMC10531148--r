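POLICY_NAMES <- c("policy_iteration", "q_learning", "clinician", "zero", "random")

#' Experiment configuration
#'
#' Bundles the knobs shared by the five experiment harnesses: the 60/20/20
#' patient-level split, the training-fraction sweep, the number of seeded
#' training repetitions whose best-on-validation policy is kept, the
#' test-set bootstrap, the discount and learning rate, the learning-rate
#' and occupancy grids, and the master seed.
#'
#' @param cohort cohort name, see [build_cohort()].
#' @param split train/validation/test fractions, summing to 1, all > 0.
#' @param train_fracs training-set fractions for the data-size sweep.
#' @param n_train_reps seeded training repetitions (best on validation kept).
#' @param n_bootstrap bootstrap resamples of the test trajectories.
#' @param gamma discount factor.
#' @param alpha Q-learning learning rate.
#' @param alpha_grid learning-rate sweep.
#' @param min_occupancy minimum visits per state.
#' @param min_occupancy_grid occupancy sweep (state-count experiment).
#' @param seed master integer seed.
#' @export
experiment_config <- function(cohort = "WHOLE",
                              split = c(0.6, 0.2, 0.2),
                              train_fracs = c(1.0, 0.8, 0.5, 0.3),
                              n_train_reps = 50L,
                              n_bootstrap = 100L,
                              gamma = 0.3, alpha = 0.05,
                              alpha_grid = seq(0.1, 0.9, by = 0.1),
                              min_occupancy = 50L,
                              min_occupancy_grid = c(50L, 100L, 200L),
                              seed = 1L) {
  if (any(split <= 0)) stop_config("split", "fractions must all be positive")
  if (abs(sum(split) - 1) > 1e-9) stop_config("split", "fractions must sum to 1")
  if (any(train_fracs <= 0 | train_fracs > 1))
    stop_config("train_fracs", "must lie in (0, 1]")
  if (n_train_reps < 1) stop_config("n_train_reps", "must be positive")
  if (n_bootstrap < 1) stop_config("n_bootstrap", "must be positive")
  if (any(alpha_grid <= 0 | alpha_grid >= 1))
    stop_config("alpha_grid", "entries must lie strictly inside (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha", "must lie strictly inside (0, 1)")
  if (min_occupancy < 1 || any(min_occupancy_grid < 1))
    stop_config("min_occupancy", "must be positive")
  structure(list(cohort = cohort, split = split, train_fracs = train_fracs,
                 n_train_reps = as.integer(n_train_reps),
                 n_bootstrap = as.integer(n_bootstrap),
                 gamma = gamma, alpha = alpha, alpha_grid = alpha_grid,
                 min_occupancy = as.integer(min_occupancy),
                 min_occupancy_grid = as.integer(min_occupancy_grid),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Patient-level train/validation/test split
#'
#' Disjoint random split of patient IDs (never of visits), deterministic
#' per seed; set sizes are `round(n * fraction)` with the remainder going
#' to the test set.
#'
#' @param patient_ids vector of unique patient identifiers.
#' @param fractions three positive fractions summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` id vectors.
#' @export
split_patients <- function(patient_ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (any(fractions <= 0)) stop_config("fractions", "must all be positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop_config("fractions", "must sum to 1")
  ids <- unique(patient_ids)
  set.seed(seed)
  ids <- sample(ids)
  n <- length(ids)
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  list(train = sort(ids[seq_len(n_train)]),
       validation = sort(ids[n_train + seq_len(n_val)]),
       test = sort(ids[(n_train + n_val + 1):n]))
}

#' Prepare a raw visit table for modelling
#'
#' Forward-fills missing scores, selects eligible patients (>= 2 complete
#' visits) and labels every visit with its treatment action.
#'
#' @param visits raw visit tibble (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @return the processed visit tibble.
#' @export
prepare_visits <- function(visits) {
  visits <- forward_fill(visits)
  visits <- select_patients(visits)
  assign_actions(visits)
}

# resample whole test trajectories (paired across policies within a replicate)
resample_trajectories <- function(transitions, seed) {
  ids <- unique(transitions$traj_id)
  set.seed(seed)
  picked <- sample(ids, length(ids), replace = TRUE)
  out <- vector("list", length(picked))
  for (j in seq_along(picked)) {
    tr <- transitions[transitions$traj_id == picked[j], ]
    tr$traj_id <- j
    out[[j]] <- tr
  }
  dplyr::bind_rows(out)
}

#' Fit states, train the five policies and bootstrap their step-WIS values
#'
#' The core pipeline stage shared by all experiment harnesses: fit the
#' state tree on the training split, chain transitions, train policy
#' iteration and Q-learning (Q-learning with `n_train_reps` seeded
#' repetitions, keeping the best validation-set step-WIS; policy iteration
#' is deterministic given the data so it is fit once), derive the
#' clinician, zero and random policies, then score all five with step-WIS
#' on `n_bootstrap` paired resamples of the test trajectories.
#'
#' @param visits prepared visit tibble (see [prepare_visits()]).
#' @param config an [experiment_config()].
#' @param train_frac fraction of training patients used (data-size sweep).
#' @param alpha learning-rate override (defaults to `config$alpha`).
#' @param min_occupancy occupancy override (defaults to `config$min_occupancy`).
#' @param seed seed override (defaults to `config$seed`).
#' @param state_model optional pre-fitted [state_space_model()]; when
#'   supplied, the feature selection and tree fit are skipped so that
#'   several scenarios (e.g. the data-size sweep) share one state
#'   abstraction and stay comparable.
#' @return list with `policies` (named list of [tabular_policy()]),
#'   `state_model`, `rewards` (tibble policy x replicate x value),
#'   `point_estimates` (step-WIS on the full test log), `n_train_patients`,
#'   and `actions` (per-state recommended-action table).
#' @export
run_policy_comparison <- function(visits, config = experiment_config(),
                                  train_frac = 1.0,
                                  alpha = config$alpha,
                                  min_occupancy = config$min_occupancy,
                                  seed = config$seed,
                                  state_model = NULL) {
  sp <- split_patients(unique(visits$RID), config$split, seed = derive_seed(seed, 1))
  train_ids <- sp$train
  if (train_frac < 1) {
    set.seed(derive_seed(seed, 2))
    train_ids <- sort(sample(train_ids, max(2L, round(length(train_ids) * train_frac))))
  }
  if (length(train_ids) < 2L) {
    warning("train fraction yields < 2 patients; skipping scenario")
    return(NULL)
  }
  train <- dplyr::filter(visits, .data$RID %in% train_ids)
  val <- dplyr::filter(visits, .data$RID %in% sp$validation)
  test <- dplyr::filter(visits, .data$RID %in% sp$test)

  if (is.null(state_model)) {
    fs <- select_features(train)
    feats <- fs$feature[fs$selected]
    if (length(feats) == 0L) feats <- fs$feature
    state_model <- fit_state_tree(train, feats, min_occupancy = min_occupancy)
  }
  model <- state_model
  S <- n_states(model)

  add_states <- function(v) { v$STATE <- as.integer(assign_state(model, v)); v }
  tr_train <- build_transitions(add_states(train))
  tr_val <- build_transitions(add_states(val))
  tr_test <- build_transitions(add_states(test))
  if (nrow(tr_train) == 0L || nrow(tr_test) == 0L) {
    warning("no usable transitions in train or test split; skipping scenario")
    return(NULL)
  }

  emp <- estimate_transition_model(tr_train, n_states = S)
  beh_train <- behavior_policy(tr_train, n_states = S)
  pi_pi <- suppressWarnings(policy_iteration(emp, config$gamma))
  pi_clin <- suppressWarnings(clinician_policy(emp, beh_train, config$gamma))

  beh_val <- if (nrow(tr_val) > 0L) behavior_policy(tr_val, n_states = S) else NULL
  best_q <- NULL; best_val <- -Inf
  for (rep in seq_len(config$n_train_reps)) {
    qt <- q_learning(tr_train, gamma = config$gamma, alpha = alpha,
                     n_passes = 50L, seed = derive_seed(seed, 3, rep),
                     n_states = S)
    cand <- greedy_policy(qt)
    score <- if (is.null(beh_val)) 0 else
      step_wis(cand, beh_val, tr_val, config$gamma)$estimate
    if (score > best_val || is.null(best_q)) { best_q <- cand; best_val <- score }
  }

  policies <- list(policy_iteration = pi_pi, q_learning = best_q,
                   clinician = pi_clin, zero = zero_policy(S),
                   random = random_policy(S))

  beh_test <- behavior_policy(tr_test, n_states = S)
  point <- vapply(policies, function(p)
    step_wis(p, beh_test, tr_test, config$gamma)$estimate, numeric(1))

  rewards <- vector("list", config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    res <- resample_trajectories(tr_test, seed = derive_seed(seed, 4, b))
    vals <- vapply(policies, function(p)
      step_wis(p, beh_test, res, config$gamma)$estimate, numeric(1))
    rewards[[b]] <- tibble::tibble(policy = POLICY_NAMES, replicate = b,
                                   value = as.numeric(vals))
  }
  actions <- tibble::tibble(
    state = model$states$label,
    policy_iteration = ACTIONS[policy_actions(pi_pi)],
    q_learning = ACTIONS[policy_actions(best_q)],
    clinician = ACTIONS[policy_actions(pi_clin)])
  list(policies = policies, state_model = model,
       rewards = dplyr::bind_rows(rewards),
       point_estimates = point,
       n_train_patients = length(train_ids),
       actions = actions)
}

#' Data-size sweep (training-fraction experiment)
#'
#' Runs the pipeline at each training fraction (default 100%, 80%, 50%,
#' 30% of the training split) and reports the per-policy bootstrap reward
#' distributions. The state tree is fit once, on the full training split,
#' and shared across fractions, so all scenarios use one state abstraction
#' and their step-WIS rewards are directly comparable; only the transition
#' model and the solvers see the subsampled data. When `out_dir` is given,
#' the reward, summary and per-state action tables are written there as
#' CSV (deterministic given the master seed, byte-for-byte).
#'
#' @param visits prepared visit tibble.
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for result tables.
#' @return named list (one entry per training fraction) of
#'   [run_policy_comparison()] results.
#' @export
run_test1 <- function(visits, config = experiment_config(), out_dir = NULL) {
  sp <- split_patients(unique(visits$RID), config$split,
                       seed = derive_seed(config$seed, 1))
  train <- dplyr::filter(visits, .data$RID %in% sp$train)
  fs <- select_features(train)
  feats <- fs$feature[fs$selected]
  if (length(feats) == 0L) feats <- fs$feature
  shared_model <- fit_state_tree(train, feats,
                                 min_occupancy = config$min_occupancy)
  results <- list()
  for (f in config$train_fracs) {
    res <- run_policy_comparison(visits, config, train_frac = f,
                                 state_model = shared_model)
    if (!is.null(res)) results[[sprintf("frac_%g", f)]] <- res
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rewards <- dplyr::bind_rows(lapply(names(results), function(nm)
      dplyr::mutate(results[[nm]]$rewards, scenario = nm)))
    utils::write.csv(rewards, file.path(out_dir, "test1_rewards.csv"),
                     row.names = FALSE)
    summ <- dplyr::bind_rows(lapply(names(results), function(nm)
      dplyr::mutate(compare_policies(results[[nm]])$summary, scenario = nm)))
    utils::write.csv(summ, file.path(out_dir, "test1_summary.csv"),
                     row.names = FALSE)
    acts <- dplyr::bind_rows(lapply(names(results), function(nm)
      dplyr::mutate(results[[nm]]$actions, scenario = nm)))
    utils::write.csv(acts, file.path(out_dir, "test1_actions.csv"),
                     row.names = FALSE)
  }
  results
}

#' Comorbidity-cohort experiment
#'
#' Repeats the pipeline for the AD, AD-Hypertension, AD-Depression and
#' AD-Depression-Hypertension cohorts, reporting per-cohort policy
#' comparisons and per-state recommended-action tables.
#'
#' @inheritParams run_test1
#' @param cohorts cohort names to run (default: the four comorbidity cohorts).
#' @return named list of [run_policy_comparison()] results per cohort.
#' @export
run_test2 <- function(visits, config = experiment_config(),
                      cohorts = c("AD", "AD_HTN", "AD_DEP", "AD_DEP_HTN")) {
  results <- list()
  for (ch in cohorts) {
    cohort_visits <- build_cohort(visits, ch)
    if (length(unique(cohort_visits$RID)) < 5L) {
      warning("cohort ", ch, " too small; skipped")
      next
    }
    res <- run_policy_comparison(cohort_visits, config)
    if (!is.null(res)) results[[ch]] <- res
  }
  results
}

#' Stratify patients below/above the grand mean of per-patient mean MMSE
#'
#' Patients whose average MMSE over all visits is below the grand mean of
#' patient averages form the JR (harder-caseload) stratum; the rest form
#' the SR stratum. Every patient lands in exactly one stratum.
#'
#' @param visits prepared visit tibble.
#' @return tibble `RID`, `mean_mmse`, `stratum` (`"JR"` or `"SR"`).
#' @export
stratify_jr_sr <- function(visits) {
  pm <- dplyr::summarise(dplyr::group_by(visits, .data$RID),
                         mean_mmse = mean(.data$MMSE))
  grand <- mean(pm$mean_mmse)
  pm$stratum <- ifelse(pm$mean_mmse < grand, "JR", "SR")
  pm
}

#' JR/SR caseload experiment
#'
#' Splits the cohort at the grand mean of per-patient mean MMSE and runs
#' the policy comparison within each stratum and combined.
#'
#' @inheritParams run_test1
#' @return named list with `JR`, `SR` and `combined` results.
#' @export
run_test3 <- function(visits, config = experiment_config()) {
  strata <- stratify_jr_sr(visits)
  results <- list()
  for (st in c("JR", "SR")) {
    ids <- strata$RID[strata$stratum == st]
    res <- run_policy_comparison(dplyr::filter(visits, .data$RID %in% ids), config)
    if (!is.null(res)) results[[st]] <- res
  }
  results$combined <- run_policy_comparison(visits, config)
  results
}

#' Learning-rate sweep
#'
#' Trains Q-learning at each learning rate in `config$alpha_grid` on the
#' same fixed split and reports the bootstrap reward distribution per rate.
#'
#' @inheritParams run_test1
#' @return named list (one entry per alpha) of results.
#' @export
run_test4 <- function(visits, config = experiment_config()) {
  results <- list()
  for (a in config$alpha_grid) {
    results[[sprintf("alpha_%g", a)]] <-
      run_policy_comparison(visits, config, alpha = a)
  }
  results
}

#' State-count sweep
#'
#' Refits the state tree at each occupancy threshold, reruns the pipeline
#' and reports the reward distribution and resulting state count.
#'
#' @inheritParams run_test1
#' @return named list (one entry per threshold) of results; each carries
#'   `n_states` in addition to the comparison fields.
#' @export
run_test5 <- function(visits, config = experiment_config()) {
  results <- list()
  for (m in config$min_occupancy_grid) {
    res <- run_policy_comparison(visits, config, min_occupancy = m)
    if (!is.null(res)) {
      res$n_states <- n_states(res$state_model)
      results[[sprintf("occ_%d", m)]] <- res
    }
  }
  results
}

#' Summarize and compare the five policy reward distributions
#'
#' Emits a summary table (mean, median, quartiles), pairwise two-sample
#' t-test P-values (Welch by default; `pooled = TRUE` restores the
#' equal-variance form) and a box plot of the bootstrap distributions.
#'
#' @param result a [run_policy_comparison()] result.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return list with `summary` (tibble), `p_values` (matrix) and `plot`
#'   (ggplot object).
#' @export
compare_policies <- function(result, pooled = FALSE) {
  rew <- result$rewards
  lens <- table(rew$policy)
  if (length(unique(as.integer(lens))) != 1L)
    stop("policy reward distributions have unequal lengths")
  summ <- dplyr::summarise(
    dplyr::group_by(rew, .data$policy),
    mean = mean(.data$value), median = stats::median(.data$value),
    q25 = stats::quantile(.data$value, 0.25),
    q75 = stats::quantile(.data$value, 0.75), .groups = "drop")
  pols <- unique(rew$policy)
  P <- matrix(NA_real_, length(pols), length(pols), dimnames = list(pols, pols))
  for (i in seq_along(pols)) for (j in seq_along(pols)) {
    if (i >= j) next
    x <- rew$value[rew$policy == pols[i]]
    y <- rew$value[rew$policy == pols[j]]
    P[i, j] <- P[j, i] <- tryCatch(
      stats::t.test(x, y, var.equal = pooled)$p.value,
      error = function(e) if (isTRUE(all.equal(x, y))) 1 else NA_real_)
  }
  diag(P) <- 1
  plt <- ggplot2::ggplot(rew, ggplot2::aes(x = .data$policy, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "step-WIS reward (discounted MMSE points)") +
    ggplot2::theme_minimal()
  list(summary = summ, p_values = P, plot = plt)
}
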