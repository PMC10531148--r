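test_that("policy evaluation reproduces closed-form values", {
  # one self-looping state with reward 1: v = 1 / (1 - gamma)
  P <- array(0, c(1, 1, 1)); P[1, 1, 1] <- 1
  m <- transition_model(P, matrix(1, 1, 1))
  pol <- tabular_policy(matrix(c(1, 0, 0, 0, 0, 0), 1, 6))
  expect_equal(policy_evaluation(pol, m, 0.3), 1 / 0.7)

  # two-state chain: reward 1 into an absorbing zero-reward state
  P2 <- array(0, c(2, 1, 2)); P2[1, 1, 2] <- 1; P2[2, 1, 2] <- 1
  m2 <- transition_model(P2, matrix(c(1, 0), 2, 1))
  pol2 <- tabular_policy(matrix(rep(c(1, 0, 0, 0, 0, 0), each = 2), 2, 6))
  expect_equal(policy_evaluation(pol2, m2, 0.3), c(1, 0))

  # gamma = 0: expected immediate reward under the policy
  m3 <- random_model(3, 2, seed = 5)
  pol3 <- tabular_policy(cbind(0.4, 0.6, 0, 0, 0, 0)[rep(1, 3), ])
  v0 <- policy_evaluation(pol3, m3, 0)
  expect_equal(v0, as.numeric(m3$reward %*% c(0.4, 0.6)))
  expect_error(policy_evaluation(pol3, m3, 1), "gamma")
})

test_that("policy improvement is greedy over observed actions with tie rules", {
  m <- random_model(3, 3, seed = 7)
  # gamma = 0: argmax of the empirical mean reward
  imp <- policy_improvement(rep(0, 3), m, 0)
  expect_identical(policy_actions(imp),
                   as.integer(apply(m$reward, 1, which.max)))
  # identical actions everywhere: lowest index wins
  P <- array(1 / 2, c(2, 3, 2))
  tie <- transition_model(P, matrix(0, 2, 3))
  expect_identical(policy_actions(policy_improvement(c(0, 0), tie, 0.3)),
                   c(1L, 1L))
  # strictly dominant action is selected
  dom <- random_model(3, 3, seed = 8)
  dom$reward[, 2] <- dom$reward[, 2] + 100
  expect_identical(policy_actions(policy_improvement(rep(0, 3), dom, 0.3)),
                   rep(2L, 3))
  # state with no observed action falls back to NO_DRUGS with a warning
  m2 <- random_model(2, 3, seed = 9)
  m2$support[2, ] <- FALSE
  expect_warning(fb <- policy_improvement(c(0, 0), m2, 0.3), "NO_DRUGS")
  expect_equal(policy_actions(fb)[2], 1L)
})

test_that("policy iteration matches brute-force enumeration on random MDPs", {
  for (k in 1:50) {
    set.seed(k)
    S <- sample(2:4, 1); A <- sample(2:3, 1)
    m <- random_model(S, A, seed = 1000 + k)
    v_pi <- policy_evaluation(policy_iteration(m, 0.3), m, 0.3)
    expect_lt(max(abs(v_pi - enumerate_optimal_value(m, 0.3))), 1e-8)
  }
})

test_that("improvement steps never decrease the value", {
  for (k in 1:10) {
    m <- random_model(4, 3, seed = 300 + k)
    pol <- one_hot_policy(rep(1L, 4))
    for (it in 1:5) {
      v <- policy_evaluation(pol, m, 0.3)
      pol2 <- policy_improvement(v, m, 0.3)
      v2 <- policy_evaluation(pol2, m, 0.3)
      expect_true(all(v2 >= v - 1e-10))
      pol <- pol2
    }
  }
})

test_that("policy iteration respects the observed-action support", {
  # a log repeating a single action: only that action can be returned
  tr <- tibble::tibble(traj_id = 1, step = 1:3, state = c(1L, 2L, 1L),
                       action = 3L, reward = c(1, -1, 0),
                       next_state = c(2L, 1L, 2L),
                       terminal = c(FALSE, FALSE, TRUE))
  m <- estimate_transition_model(tr, n_states = 2)
  expect_identical(policy_actions(policy_iteration(m, 0.3)), c(3L, 3L))
})

test_that("q-learning single update and precondition", {
  tr <- tibble::tibble(traj_id = 1, step = 1, state = 1L, action = 2L,
                       reward = 2, next_state = 1L, terminal = TRUE)
  qt <- q_learning(tr, gamma = 0.3, alpha = 0.05, n_passes = 1, seed = 1,
                   n_states = 1)
  expect_equal(qt$q[1, 2], 0.05 * 2)   # alpha * r from Q = 0
  expect_equal(qt$visits[1, 2], 1L)
  expect_error(q_learning(tr, alpha = 0), "alpha")
  expect_error(q_learning(tr, alpha = 1), "alpha")
})

test_that("q-learning converges to the exact optimum on replayed logs", {
  agree <- 0; worst_resid <- 0
  for (k in 1:4) {
    det <- random_deterministic_model(3, 3, seed = 400 + k)
    target_pi <- policy_iteration(det$model, 0.3)
    log <- replay_log(det)
    for (sd_ in 1:2) {
      qt <- q_learning(log, gamma = 0.3, alpha = 0.05, n_passes = 600,
                       seed = sd_, n_states = 3)
      gq <- greedy_policy(qt)
      agree <- agree + identical(policy_actions(gq), policy_actions(target_pi))
      Qs <- qt$q[, 1:3]
      bellman <- det$reward + 0.3 * apply(Qs, 1, max)[det$nxt]
      worst_resid <- max(worst_resid, max(abs(Qs - bellman)))
    }
  }
  expect_equal(agree, 8)
  expect_lt(worst_resid, 1e-3)
})

test_that("consensus q-learning agrees with the exact optimum and is stable", {
  det <- random_deterministic_model(3, 3, seed = 501)
  log <- replay_log(det)
  opt <- policy_actions(policy_iteration(det$model, 0.3))
  ens <- q_learning_ensemble(log, gamma = 0.3, alpha = 0.05, n_passes = 200,
                             n_reps = 5, seed = 2, n_states = 3)
  expect_identical(policy_actions(ens), opt)
  # deterministic given the seed
  ens2 <- q_learning_ensemble(log, gamma = 0.3, alpha = 0.05, n_passes = 200,
                              n_reps = 5, seed = 2, n_states = 3)
  expect_identical(unclass(ens), unclass(ens2))
})

test_that("greedy policy handles argmax, fallback and ties", {
  q <- matrix(0, 3, 6)
  q[1, ] <- c(0.1, 0.5, 0.2, 0, 0, 0)
  q[3, ] <- c(0, 0, 0.4, 0, 0.4, 0)
  vis <- matrix(1L, 3, 6); vis[2, ] <- 0L
  g <- greedy_policy(q_table(q, 0.05, vis))
  expect_equal(policy_actions(g), c(2L, 1L, 3L))  # argmax; fallback; tie -> lowest
})

test_that("behavior policy is the empirical action frequency", {
  tr <- tibble::tibble(traj_id = 1:3, step = 1,
                       state = c(1L, 1L, 1L), action = c(1L, 1L, 3L),
                       reward = 0, next_state = 2L, terminal = TRUE)
  b <- behavior_policy(tr, n_states = 2)
  expect_equal(as.numeric(b[1, ]), c(2 / 3, 0, 1 / 3, 0, 0, 0))
  expect_equal(as.numeric(b[2, ]), rep(1 / 6, 6))
  expect_equal(rowSums(b), c(1, 1))
})

test_that("clinician policy is one evaluation-improvement cycle", {
  m <- random_model(3, 3, seed = 21)
  b <- behavior_policy(tibble::tibble(
    traj_id = 1:6, step = 1, state = rep(1:3, 2), action = rep(1:2, each = 3),
    reward = 0, next_state = 1L, terminal = TRUE), n_states = 3)
  clin <- clinician_policy(m, b, 0.3)
  manual <- policy_improvement(policy_evaluation(b, m, 0.3), m, 0.3)
  expect_identical(policy_actions(clin), policy_actions(manual))
  # gamma = 0: clinician is the argmax of empirical mean immediate reward
  clin0 <- clinician_policy(m, b, 0)
  expect_identical(policy_actions(clin0),
                   as.integer(apply(m$reward, 1, which.max)))
  # a behavior already greedy w.r.t. its own value is a fixed point
  opt <- policy_iteration(m, 0.3)
  expect_identical(policy_actions(clinician_policy(m, opt, 0.3)),
                   policy_actions(opt))
})

test_that("zero and random policies have the stated shapes", {
  z <- zero_policy(3)
  expect_equal(unname(unclass(z)),
               matrix(rep(c(1, 0, 0, 0, 0, 0), each = 3), 3, 6))
  r <- random_policy(4)
  expect_true(all(r == 1 / 6))
  expect_equal(rowSums(z), rep(1, 3))
  expect_equal(rowSums(r), rep(1, 4))
  expect_error(tabular_policy(matrix(0.5, 2, 6)), "sum to 1")
})
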