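#' Empirical transition and reward model
#'
#' Counts `N(s, a, s')` over logged transitions, the row-normalized
#' probabilities, the mean observed reward per `(s, a)` and a support mask
#' of observed pairs. Solvers must respect the support mask: the data carry
#' no information about unobserved `(s, a)` pairs and no synthetic dynamics
#' are fabricated for them.
#'
#' @param counts integer array `[S, A, S']` (optional if `prob` given).
#' @param prob probability array `[S, A, S']`; rows over `s'` must sum to 1
#'   wherever supported.
#' @param reward numeric `S x A` matrix of expected rewards.
#' @param support logical `S x A` mask; defaults to all-TRUE when a full
#'   `prob` is supplied directly (model-as-given, e.g. a ground-truth MDP).
#' @return object of class `transition_model`.
#' @export
transition_model <- function(prob, reward, counts = NULL, support = NULL) {
  S <- dim(prob)[1]
  stopifnot(length(dim(prob)) == 3L, dim(prob)[3] == S)
  A <- dim(prob)[2]
  if (is.null(support)) support <- matrix(TRUE, S, A)
  rs <- apply(prob, c(1, 2), sum)
  if (any(abs(rs[support] - 1) > 1e-12))
    stop("supported transition rows must sum to 1")
  if (is.null(counts)) counts <- array(NA_real_, dim(prob))
  stopifnot(nrow(reward) == S, ncol(reward) == A)
  structure(list(n_states = S, n_actions = A, counts = counts, prob = prob,
                 reward = reward, support = support),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", x$n_states, " states x ", x$n_actions,
      " actions; ", sum(x$support), "/", length(x$support),
      " (s,a) pairs observed\n", sep = "")
  invisible(x)
}

#' Discounted return of a reward sequence
#'
#' `G = sum_k gamma^k * R[k+1]`, the total discounted return of the rewards
#' following one decision point.
#'
#' @param rewards ordered numeric vector of rewards.
#' @param gamma discount factor in `[0, 1)`.
#' @return a number.
#' @export
discounted_return <- function(rewards, gamma = 0.3) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)")
  if (length(rewards) == 0L) return(0)
  sum(gamma^(seq_along(rewards) - 1L) * rewards)
}

#' Chain state-labelled visits into logged transitions
#'
#' Each consecutive visit pair of a patient yields one transition whose
#' action is the earlier visit's action and whose reward is the later
#' visit's MMSE minus the earlier visit's MMSE. Pairs touching an
#' unassigned state are dropped; a drop splits the patient's trajectory
#' into separately chained segments. Patients contributing no usable pair
#' are skipped and counted in the `n_skipped_patients` attribute.
#'
#' @param visits visit tibble with `RID`, `MONTH`, `MMSE`, an `ACTION`
#'   column and a `STATE` column of assigned state indices (`NA` =
#'   unassigned).
#' @return tibble with `patient_id`, `traj_id`, `step`, `state`, `action`
#'   (integer index into [ACTIONS]), `reward`, `next_state`, `terminal`;
#'   attribute `n_skipped_patients`.
#' @export
build_transitions <- function(visits) {
  stopifnot(all(c("RID", "MONTH", "MMSE", "ACTION", "STATE") %in% names(visits)))
  visits <- dplyr::arrange(visits, .data$RID, .data$MONTH)
  ids <- unique(visits$RID)
  out <- vector("list", length(ids))
  n_skipped <- 0L
  traj_counter <- 0L
  for (k in seq_along(ids)) {
    v <- visits[visits$RID == ids[k], ]
    n <- nrow(v)
    if (n < 2L) { n_skipped <- n_skipped + 1L; next }
    from <- seq_len(n - 1L)
    ok <- !is.na(v$STATE[from]) & !is.na(v$STATE[from + 1L])
    if (!any(ok)) { n_skipped <- n_skipped + 1L; next }
    # contiguous runs of usable pairs form separately chained trajectories
    run <- cumsum(c(TRUE, diff(which(ok)) > 1L))
    okf <- from[ok]
    tr <- tibble::tibble(
      patient_id = ids[k],
      traj_id = traj_counter + run,
      state = v$STATE[okf],
      action = action_index(v$ACTION[okf]),
      reward = v$MMSE[okf + 1L] - v$MMSE[okf],
      next_state = v$STATE[okf + 1L])
    traj_counter <- traj_counter + max(run)
    out[[k]] <- tr
  }
  tr <- dplyr::bind_rows(out)
  if (nrow(tr) > 0L) {
    tr <- dplyr::group_by(tr, .data$traj_id)
    tr <- dplyr::mutate(tr, step = dplyr::row_number(),
                        terminal = dplyr::row_number() == dplyr::n())
    tr <- dplyr::ungroup(tr)
    tr <- tr[, c("patient_id", "traj_id", "step", "state", "action",
                 "reward", "next_state", "terminal")]
  }
  structure(tr, n_skipped_patients = n_skipped)
}

#' Estimate the empirical transition and reward model from logged transitions
#'
#' `P(s'|s,a) = N(s,a,s') / N(s,a,.)` and `R(s,a)` is the mean observed
#' reward, over the observed `(s, a)` support.
#'
#' @param transitions transition tibble from [build_transitions()] (or any
#'   tibble with integer `state`, `action`, `reward`, `next_state`).
#' @param n_states number of states (default: max index seen).
#' @param n_actions number of actions (default 6).
#' @return a [transition_model()].
#' @export
estimate_transition_model <- function(transitions,
                                      n_states = max(transitions$state,
                                                     transitions$next_state),
                                      n_actions = N_ACTIONS) {
  stopifnot(nrow(transitions) >= 1L)
  S <- n_states; A <- n_actions
  counts <- array(0, c(S, A, S))
  rsum <- matrix(0, S, A)
  for (i in seq_len(nrow(transitions))) {
    s <- transitions$state[i]; a <- transitions$action[i]
    counts[s, a, transitions$next_state[i]] <- counts[s, a, transitions$next_state[i]] + 1
    rsum[s, a] <- rsum[s, a] + transitions$reward[i]
  }
  nsa <- apply(counts, c(1, 2), sum)
  support <- nsa > 0
  prob <- array(0, c(S, A, S))
  reward <- matrix(0, S, A)
  for (s in seq_len(S)) for (a in seq_len(A)) if (support[s, a]) {
    prob[s, a, ] <- counts[s, a, ] / nsa[s, a]
    reward[s, a] <- rsum[s, a] / nsa[s, a]
  }
  transition_model(prob = prob, reward = reward, counts = counts,
                   support = support)
}
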