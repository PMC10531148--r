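#' Ground-truth treatment MDP for the synthetic cohort
#'
#' The generator draws every patient trajectory from a known tabular Markov
#' decision process over a small number of latent disease-severity states.
#' Each latent state emits the clinical assessments (MMSE, ADAS13, RAVLT,
#' CDRSB, MoCA, FDG) around state-specific means; actions (the six
#' medication classes) shift the latent transition probabilities. Because
#' the MDP is known, the exactly optimal policy is known by construction
#' and downstream solvers can be tested for recovery.
#'
#' @param transition numeric array `[S, A, S']`; each `(s, a)` row must sum
#'   to 1 within 1e-12.
#' @param score_emission numeric matrix `S x 8` with columns `MMSE`,
#'   `ADAS13`, `RAVLT_IMMEDIATE`, `RAVLT_LEARNING`, `CDRSB`, `MOCA`, `FDG`,
#'   `AGE_OFFSET` giving per-state emission means. Assessment means must lie
#'   in the instrument ranges (MMSE 0-30, ADAS13 0-85, CDRSB 0-18, MoCA 0-30).
#' @param mean_mmse_change optional `S x A` matrix of expected MMSE change;
#'   when `NULL` it is derived consistently from `transition` and the MMSE
#'   emission means: `sum_s' P(s'|s,a) * (m(s') - m(s))`.
#' @param behavior_logits `S x A` matrix of clinician (behavior-policy)
#'   logits; actions at a visit are drawn from `softmax(logits[s, ] / temp)`.
#' @param init_dist initial latent-state distribution (length S, sums to 1).
#' @param dx per-state diagnosis label, values in `CN`, `MCI`, `AD`.
#' @return an object of class `true_mdp`.
#' @export
true_mdp <- function(transition, score_emission, mean_mmse_change = NULL,
                     behavior_logits, init_dist, dx) {
  S <- dim(transition)[1]
  stopifnot(length(dim(transition)) == 3L, dim(transition)[3] == S,
            dim(transition)[2] == N_ACTIONS)
  if (S < 2) stop_config("n_latent_states", "must be >= 2")
  rs <- apply(transition, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-12))
    stop("transition rows must sum to 1 (max deviation ", format(max(abs(rs - 1))), ")")
  emission_cols <- c("MMSE", "ADAS13", "RAVLT_IMMEDIATE", "RAVLT_LEARNING",
                     "CDRSB", "MOCA", "FDG", "AGE_OFFSET")
  score_emission <- as.matrix(score_emission)
  stopifnot(nrow(score_emission) == S, ncol(score_emission) == length(emission_cols))
  colnames(score_emission) <- emission_cols
  rng <- list(MMSE = c(0, 30), ADAS13 = c(0, 85), CDRSB = c(0, 18), MOCA = c(0, 30))
  for (f in names(rng)) {
    v <- score_emission[, f]
    if (any(v < rng[[f]][1] | v > rng[[f]][2]))
      stop("emission means for ", f, " outside the instrument range")
  }
  if (is.null(mean_mmse_change)) {
    m <- score_emission[, "MMSE"]
    mean_mmse_change <- matrix(0, S, N_ACTIONS)
    for (s in seq_len(S)) for (a in seq_len(N_ACTIONS))
      mean_mmse_change[s, a] <- sum(transition[s, a, ] * (m - m[s]))
  }
  stopifnot(nrow(mean_mmse_change) == S, ncol(mean_mmse_change) == N_ACTIONS,
            nrow(behavior_logits) == S, ncol(behavior_logits) == N_ACTIONS,
            length(init_dist) == S, abs(sum(init_dist) - 1) < 1e-9,
            length(dx) == S, all(dx %in% c("CN", "MCI", "AD")))
  structure(list(
    n_states = S,
    transition = transition,
    score_emission = score_emission,
    mean_mmse_change = mean_mmse_change,
    behavior_logits = behavior_logits,
    init_dist = init_dist,
    dx = dx
  ), class = "true_mdp")
}

#' Default ground-truth MDP: four severity states
#'
#' States are ordered mild to severe: CN (MMSE mean 29), MCI (26),
#' mild AD (21), moderate-severe AD (12). Each action fixes a probability of
#' improving (moving one state up) and of worsening (moving one state down)
#' per state; leftover mass stays. No drugs carries the largest worsening
#' probability everywhere, ChEIs are most protective early, the
#' ChEI+memantine combination in mild AD, and memantine in
#' moderate-severe AD, so the optimal action differs across states.
#' The clinician (behavior) logits favour clinically typical prescribing
#' with full support over all six actions.
#'
#' @return a [true_mdp()].
#' @export
default_true_mdp <- function() {
  S <- 4L
  # columns follow ACTIONS: NO_DRUGS, CHEI, MEMANTINE, CHEI_MEMANTINE, ANTIHTN, SUPPLEMENT
  p_better <- rbind(
    c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00),   # CN: no better state exists
    c(0.02, 0.25, 0.08, 0.12, 0.06, 0.05),
    c(0.02, 0.12, 0.15, 0.25, 0.05, 0.04),
    c(0.00, 0.05, 0.22, 0.12, 0.03, 0.02))
  p_worse <- rbind(
    c(0.35, 0.03, 0.26, 0.26, 0.25, 0.30),
    c(0.30, 0.05, 0.20, 0.15, 0.22, 0.26),
    c(0.32, 0.15, 0.12, 0.06, 0.25, 0.27),
    c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00))   # floor state: cannot worsen further
  P <- array(0, c(S, N_ACTIONS, S))
  for (s in seq_len(S)) for (a in seq_len(N_ACTIONS)) {
    pb <- p_better[s, a]; pw <- p_worse[s, a]
    if (s > 1) P[s, a, s - 1] <- pb else pb <- 0
    if (s < S) P[s, a, s + 1] <- pw else pw <- 0
    P[s, a, s] <- 1 - pb - pw
  }
  emission <- rbind(
    #      MMSE ADAS13 RAVLT_I RAVLT_L CDRSB MOCA  FDG  AGE_OFFSET
    c(29,  8,  45, 6.5,  0.5, 27, 1.35, 0),
    c(26, 14,  35, 5.0,  1.5, 23, 1.20, 2),
    c(21, 24,  25, 3.0,  4.5, 17, 1.05, 4),
    c(12, 40,  14, 1.0, 10.0, 10, 0.90, 5))
  logits <- rbind(
    c( 1.5, -1.5, -1.5, -2.0, 0.0, 1.0),
    c( 0.5,  1.0, -0.5, -1.0, 0.0, 0.5),
    c(-0.5,  1.2,  0.3,  0.8, 0.0, 0.3),
    c(-0.5,  0.2,  1.0,  1.0, 0.0, 0.2))
  true_mdp(
    transition = P,
    score_emission = emission,
    behavior_logits = logits,
    init_dist = c(0.35, 0.30, 0.22, 0.13),
    dx = c("CN", "MCI", "AD", "AD")
  )
}

#' Wrap a ground-truth MDP as a fully supported empirical-style model
#'
#' @param mdp a [true_mdp()].
#' @return a [transition_model()] with full `(s, a)` support, usable by the
#'   same solvers that run on data-derived models.
#' @export
as_transition_model <- function(mdp) {
  stopifnot(inherits(mdp, "true_mdp"))
  transition_model(prob = mdp$transition, reward = mdp$mean_mmse_change)
}

#' Exactly optimal policy of a ground-truth MDP
#'
#' Solved by exact policy iteration on the latent MDP itself (linear-solve
#' policy evaluation and greedy improvement), so it is the construction-time
#' ground truth against which data-driven solvers are scored.
#'
#' @param mdp a [true_mdp()].
#' @param gamma discount factor in `[0, 1)`.
#' @return a one-hot [tabular_policy()].
#' @export
true_optimal_policy <- function(mdp, gamma = 0.3) {
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)")
  policy_iteration(as_transition_model(mdp), gamma = gamma)
}

#' Exact state-action values of a ground-truth MDP under its optimal policy
#'
#' Also reports the per-state gap between the best and second-best action,
#' the quantity that controls how identifiable the optimal policy is from
#' finite data.
#'
#' @inheritParams true_optimal_policy
#' @return list with `q` (`S x A` matrix), `v` (optimal state values) and
#'   `gap` (per-state best-vs-second-best value difference, MMSE points).
#' @export
true_q_values <- function(mdp, gamma = 0.3) {
  model <- as_transition_model(mdp)
  pi_star <- true_optimal_policy(mdp, gamma)
  v <- policy_evaluation(pi_star, model, gamma)
  q <- matrix(0, mdp$n_states, N_ACTIONS)
  for (s in seq_len(mdp$n_states)) for (a in seq_len(N_ACTIONS))
    q[s, a] <- model$reward[s, a] + gamma * sum(model$prob[s, a, ] * v)
  gap <- apply(q, 1L, function(row) {
    o <- sort(row, decreasing = TRUE)
    o[1] - o[2]
  })
  list(q = q, v = v, gap = gap)
}

#' Simulate latent-level trajectories from a tabular MDP and policy
#'
#' Used for Monte-Carlo on-policy values and for generating logged data
#' with an analytically known behavior policy (the off-policy evaluation
#' oracle). Rewards are the expected MMSE change of the sampled transition's
#' `(s, a)` pair plus optional Gaussian noise.
#'
#' @param mdp a [true_mdp()].
#' @param policy a [tabular_policy()] over the latent states.
#' @param n_trajectories number of independent trajectories.
#' @param horizon steps per trajectory.
#' @param seed integer seed.
#' @param reward_noise_sd standard deviation of additive reward noise.
#' @return tibble with columns `traj_id`, `step`, `state`, `action`
#'   (indices), `reward`, `next_state`, `terminal`.
#' @export
simulate_trajectories <- function(mdp, policy, n_trajectories, horizon = 8,
                                  seed = 1L, reward_noise_sd = 0) {
  stopifnot(inherits(mdp, "true_mdp"), nrow(policy) == mdp$n_states)
  set.seed(seed)
  S <- mdp$n_states
  n <- n_trajectories * horizon
  out <- list(traj = integer(n), step = integer(n), state = integer(n),
              action = integer(n), reward = numeric(n), nxt = integer(n))
  k <- 0L
  for (i in seq_len(n_trajectories)) {
    s <- sample.int(S, 1L, prob = mdp$init_dist)
    for (t in seq_len(horizon)) {
      a <- sample.int(N_ACTIONS, 1L, prob = policy[s, ])
      s2 <- sample.int(S, 1L, prob = mdp$transition[s, a, ])
      r <- mdp$mean_mmse_change[s, a]
      if (reward_noise_sd > 0) r <- r + stats::rnorm(1L, 0, reward_noise_sd)
      k <- k + 1L
      out$traj[k] <- i; out$step[k] <- t; out$state[k] <- s
      out$action[k] <- a; out$reward[k] <- r; out$nxt[k] <- s2
      s <- s2
    }
  }
  tibble::tibble(
    traj_id = out$traj, step = out$step, state = out$state,
    action = out$action, reward = out$reward, next_state = out$nxt,
    terminal = out$step == horizon
  )
}
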