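# Shared fixtures: small random MDPs, brute-force policy enumeration, and a
# compact synthetic cohort. Everything is generated in code under fixed seeds.

# Random empirical-style MDP with A supported actions (A <= 6), dense support.
random_model <- function(S, A, seed, reward_range = c(-3, 3)) {
  set.seed(seed)
  P <- array(0, c(S, A, S))
  for (s in seq_len(S)) for (a in seq_len(A)) {
    w <- stats::runif(S)
    P[s, a, ] <- w / sum(w)
  }
  R <- matrix(stats::runif(S * A, reward_range[1], reward_range[2]), S, A)
  transition_model(prob = P, reward = R)
}

# Random MDP with deterministic transitions and rewards (for Q-learning
# fixed-point checks: no sampling noise in the replayed log).
random_deterministic_model <- function(S, A, seed, reward_range = c(-3, 3)) {
  set.seed(seed)
  nxt <- matrix(sample.int(S, S * A, replace = TRUE), S, A)
  R <- matrix(round(stats::runif(S * A, reward_range[1], reward_range[2]), 2), S, A)
  P <- array(0, c(S, A, S))
  for (s in seq_len(S)) for (a in seq_len(A)) P[s, a, nxt[s, a]] <- 1
  list(model = transition_model(prob = P, reward = R), nxt = nxt, reward = R)
}

# Exhaustive enumeration oracle: evaluates every deterministic policy over
# the supported actions by exact linear solve and returns the elementwise
# best value (the optimal value function dominates state-wise).
enumerate_optimal_value <- function(model, gamma) {
  acts <- lapply(seq_len(model$n_states), function(s) which(model$support[s, ]))
  grid <- expand.grid(acts)
  best <- rep(-Inf, model$n_states)
  for (k in seq_len(nrow(grid))) {
    pol <- one_hot_policy(as.integer(grid[k, ]), model$n_states)
    v <- policy_evaluation(pol, model, gamma)
    best <- pmax(best, v)
  }
  best
}

# A log replaying each supported (s, a) exactly once (deterministic MDP).
replay_log <- function(det) {
  S <- nrow(det$nxt); A <- ncol(det$nxt)
  log <- tibble::tibble(
    traj_id = seq_len(S * A), step = 1L,
    state = rep(seq_len(S), A), action = rep(seq_len(A), each = S))
  log$reward <- det$reward[cbind(log$state, log$action)]
  log$next_state <- det$nxt[cbind(log$state, log$action)]
  log$terminal <- FALSE
  log
}

# Small prepared cohort used across tests (cached per session).
small_cohort <- local({
  cache <- NULL
  function(n = 150L, seed = 20L) {
    key <- paste(n, seed)
    if (!is.null(cache) && cache$key == key) return(cache$visits)
    v <- prepare_visits(generate_cohort(
      generator_config(n_patients = n, seed = seed), default_true_mdp()))
    cache <<- list(key = key, visits = v)
    v
  }
})

# Hand-built visit table for cohort-builder unit tests.
toy_visits <- function() {
  tibble::tibble(
    RID = c(1, 1, 2, 3, 3, 3, 4, 4),
    VISCODE = c("bl", "m06", "bl", "bl", "m06", "m12", "bl", "m06"),
    MONTH = c(0, 6, 0, 0, 6, 12, 0, 6),
    AGE = c(70, 70.5, 80, 65, 65.5, 66, 75, 75.5),
    MMSE = c(24, NA, 30, 28, 27, 26, 30, 30),
    ADAS13 = c(20, 22, 5, 12, NA, 14, 6, 6),
    RAVLT_IMMEDIATE = c(30, 28, 50, 40, 41, 39, 52, 51),
    RAVLT_LEARNING = c(4, 3, 7, 5, 5, 4, 8, 7),
    CDRSB = c(2, 2.5, 0, 1, 1, 1.5, 0, 0),
    MOCA = c(20, 19, 28, 24, 23, 23, 29, 28),
    FDG = c(1.1, 1.05, 1.3, 1.2, 1.2, 1.15, 1.35, 1.3),
    DX = c("AD", "AD", "CN", "MCI", "MCI", "MCI", "CN", "CN"),
    HYPERTENSION = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    DEPRESSION = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    MEDICATIONS = c("Donepezil", "Donepezil|Memantine", "Lisinopril",
                    "Memantine", "", "Vitamin E", "", "")
  )
}
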