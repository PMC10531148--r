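#' Tabular policies
#'
#' A tabular policy is a `states x 6` matrix of action probabilities; each
#' row sums to 1. Deterministic policies are one-hot rows. Rows are named
#' by state label when known, columns by [ACTIONS].
#'
#' @param prob numeric matrix, `n_states x 6`, rows summing to 1.
#' @return an object of class `tabular_policy` (a matrix).
#' @export
tabular_policy <- function(prob) {
  prob <- as.matrix(prob)
  if (ncol(prob) != N_ACTIONS)
    stop("a tabular policy needs exactly ", N_ACTIONS, " action columns")
  if (any(prob < 0)) stop("action probabilities must be non-negative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-12))
    stop("every policy row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  colnames(prob) <- ACTIONS
  structure(prob, class = c("tabular_policy", class(prob)))
}

#' @export
print.tabular_policy <- function(x, ...) {
  cat("<tabular_policy> ", nrow(x), " states x ", ncol(x), " actions\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

one_hot_policy <- function(action_idx, n_states = length(action_idx)) {
  p <- matrix(0, n_states, N_ACTIONS)
  p[cbind(seq_len(n_states), action_idx)] <- 1
  tabular_policy(p)
}

#' Deterministic action of each state under a (one-hot) policy
#' @param policy a [tabular_policy()].
#' @return integer vector of action indices (argmax per row, lowest index on ties).
#' @export
policy_actions <- function(policy) {
  apply(unclass(policy), 1L, which.max)
}

#' Zero policy: no drugs in every state
#' @param n_states number of states.
#' @export
zero_policy <- function(n_states) {
  stopifnot(n_states >= 1)
  one_hot_policy(rep(1L, n_states), n_states)
}

#' Random policy: uniform over the six actions in every state
#' @param n_states number of states.
#' @export
random_policy <- function(n_states) {
  stopifnot(n_states >= 1)
  tabular_policy(matrix(1 / N_ACTIONS, n_states, N_ACTIONS))
}
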