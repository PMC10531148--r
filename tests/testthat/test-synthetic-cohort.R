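test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- generator_config(n_patients = 40, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # serialization round-trip is also identical
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("patient streams are stable under a changed patient count", {
  a <- generate_cohort(generator_config(n_patients = 10, seed = 5))
  b <- generate_cohort(generator_config(n_patients = 40, seed = 5))
  expect_identical(a, dplyr::filter(b, RID <= 10))
})

test_that("degenerate prevalence yields no comorbidity flags", {
  v <- generate_cohort(generator_config(n_patients = 60, seed = 3,
                                        hypertension_prevalence = 0))
  expect_false(any(v$HYPERTENSION))
})

test_that("comorbidity prevalence lands in the exact binomial 99% interval", {
  n <- 2000
  v <- generate_cohort(generator_config(n_patients = n, seed = 9,
                                        hypertension_prevalence = 0.3))
  per_patient <- dplyr::summarise(dplyr::group_by(v, RID),
                                  htn = any(HYPERTENSION))
  bounds <- qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(sum(per_patient$htn), bounds[1])
  expect_lte(sum(per_patient$htn), bounds[2])
})

test_that("generated scores respect instrument ranges and visit structure", {
  cfg <- generator_config(n_patients = 80, seed = 7)
  v <- generate_cohort(cfg)
  expect_true(all(v$MMSE >= 0 & v$MMSE <= 30, na.rm = TRUE))
  expect_true(all(v$ADAS13 >= 0 & v$ADAS13 <= 85, na.rm = TRUE))
  expect_true(all(v$CDRSB >= 0 & v$CDRSB <= 18, na.rm = TRUE))
  expect_true(all(v$MOCA >= 0 & v$MOCA <= 30, na.rm = TRUE))
  # baseline ages are drawn in [55, 95]; severity offsets and within-study
  # aging (up to 14 visits at 6 months) can add at most ~12 years
  expect_true(all(v$AGE >= 55 & v$AGE <= 95 + 5 + 84 / 12))
  expect_true(all(tapply(v$AGE, v$RID, function(a) all(diff(a) >= 0))))
  counts <- table(v$RID)
  expect_true(all(counts >= 2 & counts <= 15))
  expect_true(all(v$MONTH %% 6 == 0))
  expect_false(any(is.na(v$MMSE[v$MONTH == 0])))
})

test_that("missing_rate zero leaves no missing cells", {
  v <- generate_cohort(generator_config(n_patients = 30, seed = 2,
                                        missing_rate = 0))
  score_cols <- c("MMSE", "ADAS13", "RAVLT_IMMEDIATE", "RAVLT_LEARNING",
                  "CDRSB", "MOCA", "FDG")
  expect_false(anyNA(v[, score_cols]))
})

test_that("action frequencies match the softmax behavior policy", {
  mdp <- default_true_mdp()
  v <- generate_cohort(generator_config(n_patients = 600, seed = 13), mdp)
  expect_gte(nrow(v), 2000)
  behavior <- t(apply(mdp$behavior_logits, 1, function(x) exp(x) / sum(exp(x))))
  # expected marginal action frequency given the realized latent states
  lat_freq <- as.numeric(table(factor(v$.latent, levels = 1:4))) / nrow(v)
  expected <- as.numeric(lat_freq %*% behavior)
  observed <- as.numeric(table(factor(v$.action, levels = 1:6))) / nrow(v)
  se <- sqrt(expected * (1 - expected) / nrow(v))
  expect_true(all(abs(observed - expected) < 4 * se + 1e-6))
})

test_that("invalid generator configuration names the offending field", {
  expect_error(generator_config(missing_rate = 1.2), "missing_rate")
  expect_error(generator_config(visits_min = 1), "visits_min")
  expect_error(generator_config(hypertension_prevalence = -0.1),
               "hypertension_prevalence")
  expect_error(generator_config(n_latent_states = 1), "n_latent_states")
})

test_that("ground-truth MDP invariants hold and the cohort CSV round-trips", {
  mdp <- default_true_mdp()
  rs <- apply(mdp$transition, c(1, 2), sum)
  expect_true(all(abs(rs - 1) < 1e-12))
  v <- generate_cohort(generator_config(n_patients = 25, seed = 4), mdp)
  f <- tempfile(fileext = ".csv")
  write_cohort(v, f)
  rt <- read_cohort(f)
  expect_equal(rt$MMSE, v$MMSE)
  expect_identical(rt$MEDICATIONS, v$MEDICATIONS)
  expect_identical(rt$HYPERTENSION, v$HYPERTENSION)
})

test_that("true optimal policy: dominant action, myopic limit, enumeration", {
  # an MDP where one action both maximizes MMSE change and leads to the
  # best-emitting state from every latent state: that action everywhere
  S <- 3
  P <- array(0, c(S, 6, S))
  for (s in 1:S) for (a in 1:6) {
    if (a == 2) P[s, a, max(s - 1, 1)] <- 1 else P[s, a, min(s + 1, S)] <- 1
  }
  em <- cbind(MMSE = c(28, 22, 14), ADAS13 = c(10, 25, 40),
              RAVLT_IMMEDIATE = c(45, 30, 15), RAVLT_LEARNING = c(6, 4, 1),
              CDRSB = c(0.5, 4, 9), MOCA = c(27, 18, 10),
              FDG = c(1.3, 1.1, 0.9), AGE_OFFSET = c(0, 2, 4))
  dom <- true_mdp(P, em, behavior_logits = matrix(0, S, 6),
                  init_dist = rep(1 / 3, 3), dx = c("CN", "MCI", "AD"))
  expect_identical(policy_actions(true_optimal_policy(dom, 0.3)), rep(2L, S))

  # gamma = 0 reduces to the argmax of the mean MMSE change
  mdp <- default_true_mdp()
  myopic <- policy_actions(true_optimal_policy(mdp, gamma = 0))
  expect_identical(myopic, as.integer(apply(mdp$mean_mmse_change, 1, which.max)))
  expect_error(true_optimal_policy(mdp, gamma = 1), "gamma")

  # 3-state random MDP vs exhaustive enumeration of deterministic policies
  m <- random_model(3, 3, seed = 11)
  vstar <- enumerate_optimal_value(m, 0.3)
  v_pi <- policy_evaluation(policy_iteration(m, 0.3), m, 0.3)
  expect_lt(max(abs(v_pi - vstar)), 1e-8)
})

test_that("default MDP separates best actions by at least half an MMSE point", {
  qv <- true_q_values(default_true_mdp(), 0.3)
  expect_true(all(qv$gap >= 0.5))
})
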