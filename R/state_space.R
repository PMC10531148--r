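#' @importFrom rlang .data :=
NULL

DEFAULT_STATE_FEATURES <- c("ADAS13", "RAVLT_IMMEDIATE", "RAVLT_LEARNING",
                            "CDRSB", "MOCA", "FDG", "AGE")

# ---- interval notation -------------------------------------------------
# Intervals are written "(a,b]" etc.; a missing endpoint means +/-Inf.
# Fitted trees use rpart's native split semantics (x < c goes left), i.e.
# upper-open / lower-closed bounds; the published ruleset keeps its printed
# bracket flags verbatim, where a boundary value belongs to the lower leaf.

parse_interval <- function(txt) {
  m <- regmatches(txt, regexec(
    "^\\s*([\\[(])\\s*([^,]*?)\\s*,\\s*([^])]*?)\\s*([])])\\s*$", txt))[[1]]
  if (length(m) == 0L) stop("cannot parse interval: ", txt)
  lo <- if (nzchar(m[3])) as.numeric(m[3]) else -Inf
  hi <- if (nzchar(m[4])) as.numeric(m[4]) else Inf
  list(lo = lo, lo_closed = m[2] == "[" && is.finite(lo),
       hi = hi, hi_closed = m[5] == "]" && is.finite(hi))
}

format_interval <- function(lo, lo_closed, hi, hi_closed) {
  paste0(if (lo_closed && is.finite(lo)) "[" else "(",
         if (is.finite(lo)) format(lo) else "", ",",
         if (is.finite(hi)) format(hi) else "",
         if (hi_closed && is.finite(hi)) "]" else ")")
}

in_interval <- function(x, lo, lo_closed, hi, hi_closed) {
  ok_lo <- if (lo_closed) x >= lo else x > lo
  ok_hi <- if (hi_closed) x <= hi else x < hi
  ok_lo & ok_hi
}

# ---- feature selection -------------------------------------------------

#' Regression-based feature selection for the state model
#'
#' Fits an ordinary least-squares model of MMSE on the candidate features
#' and marks as selected those with a coefficient p-value below
#' `alpha_sig`. Constant or collinear candidates are excluded with a
#' warning (their coefficient is not estimable).
#'
#' @param visits visit tibble with no missing values in the candidates.
#' @param candidates character vector of feature columns (>= 2).
#' @param alpha_sig significance threshold (default 0.05).
#' @return tibble with `feature`, `coefficient`, `p_value`, `selected`.
#' @export
select_features <- function(visits, candidates = DEFAULT_STATE_FEATURES,
                            alpha_sig = 0.05) {
  stopifnot(length(candidates) >= 2L, all(candidates %in% names(visits)))
  X <- visits[, candidates, drop = FALSE]
  constant <- vapply(X, function(x) stats::sd(x) == 0 || all(is.na(x)), logical(1))
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(candidates[constant], collapse = ", "))
  }
  usable <- candidates[!constant]
  fit <- stats::lm(stats::reformulate(usable, response = "MMSE"),
                   data = visits)
  co <- stats::coef(summary(fit))
  aliased <- setdiff(usable, rownames(co))
  if (length(aliased) > 0L)
    warning("dropping collinear feature(s): ", paste(aliased, collapse = ", "))
  kept <- intersect(usable, rownames(co))
  tibble::tibble(
    feature = candidates,
    coefficient = ifelse(candidates %in% kept, co[match(candidates, rownames(co)), 1], NA_real_),
    p_value = ifelse(candidates %in% kept, co[match(candidates, rownames(co)), 4], NA_real_),
    selected = candidates %in% kept &
      !is.na(co[match(candidates, rownames(co)), 4]) &
      co[match(candidates, rownames(co)), 4] < alpha_sig
  )
}

# ---- state-space model -------------------------------------------------

#' Discrete disease-state model
#'
#' A finite partition of the assessment space into states, each defined by
#' a conjunction of axis-aligned intervals (one rule path per state). States
#' are leaves of a regression tree predicting MMSE, numbered in depth-first
#' order; states kept after pruning all have occupancy >= `min_occupancy`.
#'
#' @param rules tibble with columns `leaf` (1-based dense index), `label`,
#'   `feature`, `lo`, `lo_closed`, `hi`, `hi_closed`; a leaf with no rows in
#'   `rules` is unconstrained (single-state model).
#' @param states tibble with `state`, `label`, `occupancy`, `predicted_mmse`.
#' @param features features the model may reference.
#' @param min_occupancy occupancy threshold used when fitting/pruning.
#' @param anomalies character vector of known defects (for the published
#'   ruleset: the duplicated S41 label and the S33/S27-S28 overlap).
#' @return object of class `state_space_model`.
#' @export
state_space_model <- function(rules, states, features, min_occupancy = 50L,
                              anomalies = character()) {
  stopifnot(all(c("leaf", "feature", "lo", "lo_closed", "hi", "hi_closed")
                %in% names(rules)) || nrow(rules) == 0L,
            all(c("state", "label") %in% names(states)))
  structure(list(rules = rules, states = states, features = features,
                 min_occupancy = as.integer(min_occupancy),
                 anomalies = anomalies),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat("<state_space_model> ", nrow(x$states), " states over features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  for (s in x$states$state) {
    r <- x$rules[x$rules$leaf == s, ]
    path <- if (nrow(r) == 0L) "(unconstrained)" else
      paste(sprintf("%s in %s", r$feature,
                    mapply(format_interval, r$lo, r$lo_closed, r$hi, r$hi_closed)),
            collapse = " & ")
    cat(sprintf("  %-4s %s\n", x$states$label[x$states$state == s], path))
  }
  if (length(x$anomalies)) cat("  anomalies:", paste(x$anomalies, collapse = "; "), "\n")
  invisible(x)
}

#' Number of states of a state-space model
#' @param model a [state_space_model()].
#' @export
n_states <- function(model) nrow(model$states)

#' Fit the disease-state regression tree
#'
#' Fits a binary axis-aligned CART regression tree (squared-error splits,
#' via \pkg{rpart}) of MMSE on the selected features, with minimum leaf
#' size `min_occupancy` and depth capped at `maxdepth`. Leaves become the
#' discrete states, numbered in depth-first order. Deterministic given data
#' and settings. With fewer rows than `min_occupancy` a single-state model
#' is returned with a warning.
#'
#' @param visits visit tibble (complete in `features` and MMSE).
#' @param features feature columns to split on.
#' @param min_occupancy minimum visits per retained state (default 50).
#' @param maxdepth tree depth cap (default 6).
#' @param cp rpart complexity parameter (default 0.01, rpart's standard:
#'   a split must improve relative R-squared by at least `cp`).
#' @return a [state_space_model()].
#' @export
fit_state_tree <- function(visits, features, min_occupancy = 50L,
                           maxdepth = 6L, cp = 0.01) {
  stopifnot(length(features) >= 1L, min_occupancy >= 1L)
  single_state <- function() {
    state_space_model(
      rules = tibble::tibble(leaf = integer(), feature = character(),
                             lo = numeric(), lo_closed = logical(),
                             hi = numeric(), hi_closed = logical()),
      states = tibble::tibble(state = 1L, label = "S0",
                              occupancy = nrow(visits),
                              predicted_mmse = mean(visits$MMSE)),
      features = features, min_occupancy = min_occupancy)
  }
  if (nrow(visits) < min_occupancy) {
    warning("fewer visits than min_occupancy; returning a single-state model")
    return(single_state())
  }
  fit <- rpart::rpart(
    stats::reformulate(features, response = "MMSE"), data = visits,
    method = "anova",
    control = rpart::rpart.control(
      minbucket = min_occupancy, minsplit = 2L * min_occupancy,
      maxdepth = maxdepth, cp = cp, xval = 0L,
      maxcompete = 0L, maxsurrogate = 0L))
  frame <- fit$frame
  if (nrow(frame) == 1L) return(single_state())

  node_ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  # rpart's splits matrix rows follow the primary splits in frame order
  # (one row each because maxcompete = maxsurrogate = 0)
  splits <- fit$splits
  split_rows <- which(!is_leaf)
  split_var <- as.character(frame$var[split_rows])
  split_thr <- splits[, "index"]
  split_dir <- splits[, "ncat"]   # -1: left son gets x < threshold
  names(split_thr) <- names(split_dir) <- as.character(node_ids[split_rows])

  leaf_nodes <- node_ids[is_leaf]   # frame order == depth-first order
  rules <- list()
  for (k in seq_along(leaf_nodes)) {
    node <- leaf_nodes[k]
    cons <- list()
    child <- node
    while (child > 1L) {
      parent <- child %/% 2L
      pkey <- as.character(parent)
      v <- split_var[match(parent, node_ids[split_rows])]
      thr <- split_thr[[pkey]]
      left_is_lt <- split_dir[[pkey]] < 0
      went_left <- child %% 2L == 0L
      # x < thr on one side, x >= thr on the other
      is_lt <- xor(!went_left, left_is_lt)   # TRUE: this branch is x < thr
      cur <- cons[[v]] %||% list(lo = -Inf, lo_closed = FALSE,
                                 hi = Inf, hi_closed = FALSE)
      if (is_lt) {
        if (thr < cur$hi) { cur$hi <- thr; cur$hi_closed <- FALSE }
      } else {
        if (thr > cur$lo) { cur$lo <- thr; cur$lo_closed <- TRUE }
      }
      cons[[v]] <- cur
      child <- parent
    }
    rules[[k]] <- tibble::tibble(
      leaf = k,
      feature = names(cons),
      lo = unname(vapply(cons, `[[`, numeric(1), "lo")),
      lo_closed = unname(vapply(cons, `[[`, logical(1), "lo_closed")),
      hi = unname(vapply(cons, `[[`, numeric(1), "hi")),
      hi_closed = unname(vapply(cons, `[[`, logical(1), "hi_closed")))
  }
  rules <- dplyr::bind_rows(rules)
  occupancy <- frame$n[is_leaf]
  predicted <- frame$yval[is_leaf]

  keep <- occupancy >= min_occupancy
  new_idx <- cumsum(keep)
  rules <- rules[rules$leaf %in% which(keep), ]
  rules$leaf <- new_idx[rules$leaf]
  states <- tibble::tibble(
    state = seq_len(sum(keep)),
    label = paste0("S", seq_len(sum(keep)) - 1L),
    occupancy = occupancy[keep],
    predicted_mmse = predicted[keep])
  state_space_model(rules = rules, states = states, features = features,
                    min_occupancy = min_occupancy)
}

#' Assign visits to discrete states
#'
#' Returns, per visit, the state whose rule intervals all contain the
#' visit's feature values. Visits in regions not covered by any retained
#' state (pruned leaves, or gaps in the published ruleset) get `NA`
#' ("unassigned"). If more than one state matches (possible only for the
#' published ruleset's flagged anomaly), the lowest state index wins and
#' the multiplicity is reported in the `n_matches` attribute.
#'
#' @param model a [state_space_model()].
#' @param visits visit tibble; every feature referenced by the model's
#'   rules must be present and non-missing.
#' @return integer vector of state indices (`NA` = unassigned), with
#'   attribute `n_matches`.
#' @export
assign_state <- function(model, visits) {
  used <- unique(model$rules$feature)
  for (f in used) {
    if (!f %in% names(visits) || anyNA(visits[[f]]))
      stop("assign_state: required feature '", f, "' missing")
  }
  n <- nrow(visits)
  if (nrow(model$rules) == 0L) {
    return(structure(rep(1L, n), n_matches = rep(1L, n)))
  }
  n_match <- integer(n)
  assigned <- rep(NA_integer_, n)
  for (s in rev(model$states$state)) {
    r <- model$rules[model$rules$leaf == s, ]
    ok <- rep(TRUE, n)
    for (j in seq_len(nrow(r))) {
      ok <- ok & in_interval(visits[[r$feature[j]]], r$lo[j], r$lo_closed[j],
                             r$hi[j], r$hi_closed[j])
    }
    n_match <- n_match + ok
    assigned[ok] <- s    # reverse loop => lowest matching index wins
  }
  structure(assigned, n_matches = n_match)
}

#' Load the published decision-tree ruleset
#'
#' Returns the published per-cohort state rules shipped with the package
#' (13 Whole-Data states S0-S12, 9 AD states, 12 AD-Hypertension rows, 9
#' AD-Depression rows), encoded verbatim including two anomalies of the
#' printed table, which are flagged rather than resolved: the AD-Depression
#' list labels two distinct rule paths "S41", and AD-Hypertension row S33
#' overlaps the S27/S28 region. `AD_DEP_HTN` shares the `AD_HTN` ruleset,
#' as published.
#'
#' @param cohort one of `WHOLE`, `AD`, `AD_HTN`, `AD_DEP`, `AD_DEP_HTN`.
#' @return a [state_space_model()].
#' @export
load_published_rules <- function(cohort) {
  if (!is.character(cohort) || length(cohort) != 1L || !(cohort %in% COHORT_NAMES))
    stop_config("cohort", paste0("must be one of ", paste(COHORT_NAMES, collapse = ", ")))
  path <- system.file("extdata", "published_state_rules.csv", package = "regimenrl")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- if (cohort == "AD_DEP_HTN") "AD_HTN" else cohort
  raw <- raw[raw$cohort == key, ]
  parsed <- lapply(raw$interval, parse_interval)
  rules <- tibble::tibble(
    leaf = as.integer(raw$leaf),
    feature = raw$feature,
    lo = vapply(parsed, `[[`, numeric(1), "lo"),
    lo_closed = vapply(parsed, `[[`, logical(1), "lo_closed"),
    hi = vapply(parsed, `[[`, numeric(1), "hi"),
    hi_closed = vapply(parsed, `[[`, logical(1), "hi_closed"))
  leaves <- unique(raw[, c("leaf", "state")])
  anomalies <- character()
  if (any(duplicated(leaves$state)))
    anomalies <- c(anomalies, paste0("duplicated state label: ",
      paste(unique(leaves$state[duplicated(leaves$state)]), collapse = ", ")))
  if (key == "AD_HTN")
    anomalies <- c(anomalies, "S33 overlaps the S27/S28 region as printed")
  state_space_model(
    rules = rules,
    states = tibble::tibble(state = as.integer(leaves$leaf), label = leaves$state,
                            occupancy = NA_integer_, predicted_mmse = NA_real_),
    features = unique(rules$feature),
    min_occupancy = 50L,
    anomalies = anomalies)
}

#' Serialize / parse a state-space model as structured text
#'
#' One rule row per (state, feature) with the interval in the bracketed
#' open/closed notation used throughout; round-trips exactly.
#'
#' @param model a [state_space_model()].
#' @param path file path.
#' @export
write_state_rules <- function(model, path) {
  rules <- model$rules
  out <- data.frame(
    leaf = rules$leaf,
    state = model$states$label[match(rules$leaf, model$states$state)],
    feature = rules$feature,
    interval = mapply(format_interval, rules$lo, rules$lo_closed,
                      rules$hi, rules$hi_closed),
    occupancy = model$states$occupancy[match(rules$leaf, model$states$state)],
    predicted_mmse = model$states$predicted_mmse[match(rules$leaf, model$states$state)])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_state_rules
#' @export
read_state_rules <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  parsed <- lapply(raw$interval, parse_interval)
  rules <- tibble::tibble(
    leaf = as.integer(raw$leaf), feature = raw$feature,
    lo = vapply(parsed, `[[`, numeric(1), "lo"),
    lo_closed = vapply(parsed, `[[`, logical(1), "lo_closed"),
    hi = vapply(parsed, `[[`, numeric(1), "hi"),
    hi_closed = vapply(parsed, `[[`, logical(1), "hi_closed"))
  leaves <- unique(raw[, c("leaf", "state", "occupancy", "predicted_mmse")])
  state_space_model(
    rules = rules,
    states = tibble::tibble(state = as.integer(leaves$leaf), label = leaves$state,
                            occupancy = as.integer(leaves$occupancy),
                            predicted_mmse = as.numeric(leaves$predicted_mmse)),
    features = unique(rules$feature))
}
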