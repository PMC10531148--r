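#' Stepwise weighted importance sampling (step-WIS)
#'
#' Off-policy value estimate of a target policy from logged trajectories.
#' For trajectory `i` at step `t` the cumulative importance ratio is
#' `w_{i,t} = prod_{u<=t} pi(a_u|s_u) / pi_b(a_u|s_u)`; the per-decision
#' estimate is `sum_t gamma^(t-1) * sum_i w-hat_{i,t} r_{i,t}` with weights
#' self-normalized across trajectories at each step. A trajectory that has
#' ended keeps its final cumulative weight in the normalizer with zero
#' reward (the consistent step-WIS convention), so with target = behavior
#' the estimate reduces exactly to the empirical mean discounted return.
#' A step whose normalizer is zero contributes 0 and is flagged.
#'
#' Trajectory-wise WIS (`"traj_wis"`) and unnormalized per-decision
#' importance sampling (`"is"`) are available for comparison.
#'
#' @param target a [tabular_policy()] (deterministic policies are one-hot).
#' @param behavior a [tabular_policy()]; must give positive probability to
#'   every logged action at its state (guaranteed when it is the empirical
#'   policy of the same log).
#' @param transitions transition tibble from [build_transitions()] or
#'   [simulate_trajectories()].
#' @param gamma discount factor in `[0, 1)`.
#' @param method `"step_wis"` (default), `"traj_wis"`, or `"is"`.
#' @param clip optional upper bound on cumulative ratios (default none).
#' @return object of class `ope_result`: `estimate` (discounted MMSE
#'   points), `weights` (trajectories x steps cumulative-ratio matrix),
#'   `step_normalizer`, `ess` (effective sample size per step),
#'   `n_trajectories`, and `flags`.
#' @export
step_wis <- function(target, behavior, transitions, gamma = 0.3,
                     method = c("step_wis", "traj_wis", "is"), clip = Inf) {
  method <- match.arg(method)
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  stopifnot(nrow(transitions) >= 1L)
  b <- behavior[cbind(transitions$state, transitions$action)]
  if (any(b <= 0))
    stop("logged action has zero behavior probability: inconsistent behavior estimate")
  rho <- target[cbind(transitions$state, transitions$action)] / b

  tid <- match(transitions$traj_id, unique(transitions$traj_id))
  N <- max(tid)
  Tmax <- max(transitions$step)
  W <- matrix(0, N, Tmax)   # cumulative weights; persisted past episode end
  R <- matrix(0, N, Tmax)
  alive <- matrix(FALSE, N, Tmax)
  W_last <- rep(1, N)
  ord <- order(tid, transitions$step)
  for (k in ord) {
    i <- tid[k]; t <- transitions$step[k]
    W_last[i] <- min(W_last[i] * rho[k], clip)
    W[i, t] <- W_last[i]
    R[i, t] <- transitions$reward[k]
    alive[i, t] <- TRUE
  }
  # persist the final weight of ended trajectories through later steps
  for (t in seq_len(Tmax)) {
    ended <- !alive[, t] & (if (t == 1L) rep(FALSE, N) else TRUE)
    if (t > 1L) W[ended, t] <- W[ended, t - 1L]
  }

  flags <- character()
  norm <- colSums(W)
  ess <- ifelse(norm > 0, norm^2 / colSums(W^2), 0)
  disc <- gamma^(seq_len(Tmax) - 1L)

  if (method == "step_wis") {
    per_step <- vapply(seq_len(Tmax), function(t) {
      if (norm[t] <= 0) return(0)
      sum(W[, t] * R[, t]) / norm[t]
    }, numeric(1))
    if (any(norm <= 0)) flags <- c(flags, "zero_normalizer_step")
    estimate <- sum(disc * per_step)
  } else if (method == "is") {
    estimate <- sum(disc * colSums(W * R) / N)
  } else {   # trajectory-wise WIS on full discounted returns
    wT <- vapply(seq_len(N), function(i) {
      ts <- which(alive[i, ]); W[i, max(ts)]
    }, numeric(1))
    G <- vapply(seq_len(N), function(i) sum(disc * R[i, ]), numeric(1))
    estimate <- if (sum(wT) > 0) sum(wT * G) / sum(wT) else 0
  }
  if (all(W[cbind(seq_len(N), vapply(seq_len(N), function(i) max(which(alive[i, ])), integer(1)))] == 0))
    flags <- c(flags, "no_support")
  structure(list(estimate = estimate, method = method, weights = W,
                 step_normalizer = norm, ess = ess,
                 n_trajectories = N, flags = flags),
            class = "ope_result")
}

#' @export
print.ope_result <- function(x, ...) {
  cat("<ope_result> ", x$method, ": estimate = ", format(x$estimate),
      " over ", x$n_trajectories, " trajectories",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Empirical mean discounted return of a log
#'
#' The on-policy value of the behavior itself: the mean over trajectories
#' of `sum_t gamma^(t-1) r_t`.
#'
#' @inheritParams step_wis
#' @export
mean_discounted_return <- function(transitions, gamma = 0.3) {
  g <- dplyr::summarise(
    dplyr::group_by(transitions, .data$traj_id),
    G = discounted_return(.data$reward[order(.data$step)], gamma))
  mean(g$G)
}
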