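#' Exact policy evaluation
#'
#' Solves the Bellman system `v = r_pi + gamma * P_pi v` by direct linear
#' solve (the state counts in this problem are far below the scale where an
#' iterative solver would be needed). States with no observed action under
#' the model are treated as absorbing with zero reward.
#'
#' @param policy a [tabular_policy()] supported on the model's observed actions.
#' @param model a [transition_model()].
#' @param gamma discount factor in `[0, 1)`.
#' @return numeric vector `v(s)` (discounted MMSE points).
#' @export
policy_evaluation <- function(policy, model, gamma = 0.3) {
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1) (the Bellman system is singular otherwise)")
  S <- model$n_states
  stopifnot(nrow(policy) == S)
  P_pi <- matrix(0, S, S)
  r_pi <- numeric(S)
  for (s in seq_len(S)) {
    if (!any(model$support[s, ])) { P_pi[s, s] <- 1; next }  # absorbing, r = 0
    for (a in seq_len(model$n_actions)) {
      w <- policy[s, a]
      if (w == 0) next
      P_pi[s, ] <- P_pi[s, ] + w * model$prob[s, a, ]
      r_pi[s] <- r_pi[s] + w * model$reward[s, a]
    }
  }
  as.numeric(solve(diag(S) - gamma * P_pi, r_pi))
}

#' Greedy policy improvement
#'
#' Returns the deterministic policy that is greedy with respect to `value`:
#' per state, the argmax over *observed* actions of
#' `R(s,a) + gamma * sum_s' P(s'|s,a) v(s')`. Ties break to the lowest
#' action index; a state with no observed action falls back to `NO_DRUGS`
#' with a warning.
#'
#' @param value numeric state-value vector.
#' @param model a [transition_model()].
#' @param gamma discount factor in `[0, 1)`.
#' @return a one-hot [tabular_policy()].
#' @export
policy_improvement <- function(value, model, gamma = 0.3) {
  stopifnot(all(is.finite(value)), length(value) == model$n_states)
  S <- model$n_states
  best <- integer(S)
  warned <- FALSE
  for (s in seq_len(S)) {
    obs <- which(model$support[s, ])
    if (length(obs) == 0L) {
      best[s] <- 1L   # NO_DRUGS fallback
      warned <- TRUE
      next
    }
    q <- vapply(obs, function(a)
      model$reward[s, a] + gamma * sum(model$prob[s, a, ] * value), numeric(1))
    best[s] <- obs[which.max(q)]   # which.max takes the lowest index on ties
  }
  if (warned) warning("state(s) with no observed action: falling back to NO_DRUGS")
  one_hot_policy(best, S)
}

#' Policy iteration
#'
#' Alternates exact policy evaluation and greedy improvement until the
#' policy no longer changes; returns the deterministic optimal policy of
#' the (empirical) MDP restricted to observed actions.
#'
#' @param model a [transition_model()].
#' @param gamma discount factor in `[0, 1)`.
#' @param max_iter safety cap (finite MDPs converge long before this).
#' @return a one-hot [tabular_policy()].
#' @export
policy_iteration <- function(model, gamma = 0.3, max_iter = 1000L) {
  S <- model$n_states
  first_obs <- apply(model$support, 1L, function(row)
    if (any(row)) which(row)[1] else 1L)
  policy <- one_hot_policy(first_obs, S)
  for (i in seq_len(max_iter)) {
    v <- policy_evaluation(policy, model, gamma)
    improved <- suppressWarnings(policy_improvement(v, model, gamma))
    if (identical(policy_actions(improved), policy_actions(policy))) return(improved)
    policy <- improved
  }
  warning("policy iteration hit max_iter without converging")
  policy
}

#' Tabular Q-table
#'
#' @param q numeric `S x A` matrix of action values.
#' @param alpha learning rate used to train it.
#' @param visits integer `S x A` matrix of update counts.
#' @return object of class `q_table`.
#' @export
q_table <- function(q, alpha, visits) {
  stopifnot(all(is.finite(q)), all(dim(q) == dim(visits)))
  structure(list(q = q, alpha = alpha, visits = visits), class = "q_table")
}

#' Offline tabular Q-learning on logged transitions
#'
#' Replays the logged transitions in randomized sweeps (off-policy temporal
#' difference): `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') -
#' Q(s,a))`, where the max runs over actions observed at `s'` in the log
#' (the data say nothing about unobserved ones). Terminal transitions (last
#' of a trajectory) use the target `r`. Q starts at 0. Deterministic given
#' the seed.
#'
#' @param transitions transition tibble from [build_transitions()].
#' @param gamma discount factor in `[0, 1)`.
#' @param alpha learning rate, strictly inside `(0, 1)`.
#' @param n_passes randomized sweeps over the full log.
#' @param seed integer seed for the sweep order.
#' @param n_states,n_actions table dimensions (defaults from the log).
#' @return a [q_table()].
#' @export
q_learning <- function(transitions, gamma = 0.3, alpha = 0.05, n_passes = 50L,
                       seed = 1L,
                       n_states = max(transitions$state, transitions$next_state),
                       n_actions = N_ACTIONS) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  stopifnot(n_passes >= 1L, nrow(transitions) >= 1L)
  S <- n_states; A <- n_actions
  Q <- matrix(0, S, A)
  visits <- matrix(0L, S, A)
  # actions observed per state, as a logical mask used for the bootstrap max
  obs <- matrix(FALSE, S, A)
  obs[cbind(transitions$state, transitions$action)] <- TRUE

  st <- transitions$state; ac <- transitions$action
  rw <- transitions$reward; nx <- transitions$next_state
  tm <- transitions$terminal
  n <- length(st)
  set.seed(seed)
  for (p in seq_len(n_passes)) {
    ord <- sample.int(n)
    for (i in ord) {
      s <- st[i]; a <- ac[i]
      target <- if (tm[i] || !any(obs[nx[i], ])) rw[i] else
        rw[i] + gamma * max(Q[nx[i], obs[nx[i], ]])
      Q[s, a] <- Q[s, a] + alpha * (target - Q[s, a])
      visits[s, a] <- visits[s, a] + 1L
    }
  }
  q_table(Q, alpha, visits)
}

#' Greedy policy of a Q-table
#'
#' One-hot argmax per state over actions updated at least once; ties break
#' to the lowest action index; states never visited fall back to
#' `NO_DRUGS`.
#'
#' @param q a [q_table()].
#' @return a one-hot [tabular_policy()].
#' @export
greedy_policy <- function(q) {
  S <- nrow(q$q)
  best <- vapply(seq_len(S), function(s) {
    vis <- which(q$visits[s, ] > 0L)
    if (length(vis) == 0L) return(1L)   # NO_DRUGS fallback
    vis[which.max(q$q[s, vis])]
  }, integer(1))
  one_hot_policy(best, S)
}

#' Consensus Q-learning over repeated seeded trainings
#'
#' With a constant learning rate, a tabular Q-table fluctuates around its
#' fixed point with standard deviation of order
#' `sqrt(alpha / (2 - alpha)) * sd(target)`, so the greedy action of a
#' single run can flip at states whose action gap is comparable to that
#' noise. Training repeatedly and taking the per-state majority action
#' over the greedy policies of all repetitions averages this fluctuation
#' away. Ties break to the lowest action index; states unvisited in the
#' log fall back to `NO_DRUGS`.
#'
#' @inheritParams q_learning
#' @param n_reps number of seeded training repetitions (default 50).
#' @return a one-hot [tabular_policy()].
#' @export
q_learning_ensemble <- function(transitions, gamma = 0.3, alpha = 0.05,
                                n_passes = 10L, n_reps = 50L, seed = 1L,
                                n_states = max(transitions$state,
                                               transitions$next_state)) {
  stopifnot(n_reps >= 1L)
  votes <- matrix(0L, n_states, N_ACTIONS)
  for (rep in seq_len(n_reps)) {
    qt <- q_learning(transitions, gamma = gamma, alpha = alpha,
                     n_passes = n_passes, seed = derive_seed(seed, rep),
                     n_states = n_states)
    a <- policy_actions(greedy_policy(qt))
    votes[cbind(seq_len(n_states), a)] <- votes[cbind(seq_len(n_states), a)] + 1L
  }
  one_hot_policy(apply(votes, 1L, which.max), n_states)
}

#' Empirical behavior policy of a log
#'
#' `pi_b(a|s)` is the observed frequency of action `a` at state `s`;
#' states never visited get a uniform row.
#'
#' @param transitions transition tibble.
#' @param n_states number of states (default: max index seen).
#' @return a [tabular_policy()].
#' @export
behavior_policy <- function(transitions,
                            n_states = max(transitions$state,
                                           transitions$next_state)) {
  stopifnot(nrow(transitions) >= 1L)
  counts <- matrix(0, n_states, N_ACTIONS)
  for (i in seq_len(nrow(transitions)))
    counts[transitions$state[i], transitions$action[i]] <-
      counts[transitions$state[i], transitions$action[i]] + 1
  p <- counts / pmax(rowSums(counts), 1)
  p[rowSums(counts) == 0, ] <- 1 / N_ACTIONS
  tabular_policy(p)
}

#' Clinician's policy from the data's transition probabilities
#'
#' One policy-evaluation + policy-improvement cycle applied to the
#' empirical behavior policy on the empirical transition model: the
#' resulting deterministic policy stands in for the clinicians' own
#' decision rule, being derived entirely from their logged prescribing.
#'
#' @param model empirical [transition_model()].
#' @param behavior empirical behavior policy (see [behavior_policy()]).
#' @param gamma discount factor in `[0, 1)`.
#' @return a one-hot [tabular_policy()].
#' @export
clinician_policy <- function(model, behavior, gamma = 0.3) {
  v <- policy_evaluation(behavior, model, gamma)
  policy_improvement(v, model, gamma)
}
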