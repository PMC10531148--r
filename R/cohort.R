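#' Carry forward missing score cells within each patient
#'
#' Each missing assessment cell takes the most recent earlier value of the
#' same field for the same patient; cells with no earlier value stay
#' missing. A logical `<field>_imputed` mask records which cells were
#' filled. Idempotent.
#'
#' @param visits visit tibble (registry columns), any row order.
#' @param fields character vector of columns to fill (default: the seven
#'   assessment scores).
#' @return the tibble sorted by patient and month, filled, with mask columns.
#' @export
forward_fill <- function(visits, fields = SCORE_COLS) {
  visits <- dplyr::arrange(visits, .data$RID, .data$MONTH)
  locf <- function(x) {
    i <- cumsum(!is.na(x))
    filled <- x[!is.na(x)][pmax(i, 1L)]
    filled[i == 0L] <- NA
    filled
  }
  for (f in fields) {
    mask_col <- paste0(f, "_imputed")
    pre <- is.na(visits[[f]])
    visits <- dplyr::group_by(visits, .data$RID)
    visits <- dplyr::mutate(visits, !!f := locf(.data[[f]]))
    visits <- dplyr::ungroup(visits)
    visits[[mask_col]] <- pre & !is.na(visits[[f]])
  }
  visits
}

#' Select eligible patients
#'
#' Keeps patients with at least two clinic visits whose records are complete
#' after forward-fill: every field in `required` must be present at every
#' retained visit. Visits of excluded patients are removed entirely. An
#' empty input returns an empty table with a warning rather than an error.
#'
#' @param visits visit tibble, already [forward_fill()]ed (the function
#'   forward-fills itself if the mask columns are absent).
#' @param required fields that must be non-missing at every visit.
#' @param min_visits minimum visit count (default 2).
#' @return the filtered visit tibble.
#' @export
select_patients <- function(visits, required = SCORE_COLS, min_visits = 2L) {
  if (nrow(visits) == 0L) {
    warning("select_patients: empty input, returning empty output")
    return(visits)
  }
  if (!any(grepl("_imputed$", names(visits)))) visits <- forward_fill(visits)
  complete <- rowSums(is.na(visits[, required, drop = FALSE])) == 0L
  keep <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(RID = visits$RID, ok = complete), .data$RID),
    n = dplyr::n(), all_ok = all(.data$ok))
  keep_ids <- keep$RID[keep$n >= min_visits & keep$all_ok]
  dplyr::filter(visits, .data$RID %in% keep_ids)
}

#' Label each visit with its treatment action
#'
#' Applies [map_medications_to_actions()] to every visit's medication cell,
#' adding an `ACTION` column (one of [ACTIONS]); the mapping is total.
#'
#' @param visits visit tibble with a `MEDICATIONS` column.
#' @param drug_dictionary see [default_drug_dictionary()].
#' @return the tibble with an `ACTION` column.
#' @export
assign_actions <- function(visits, drug_dictionary = default_drug_dictionary()) {
  visits$ACTION <- vapply(visits$MEDICATIONS, map_medications_to_actions,
                          character(1), drug_dictionary = drug_dictionary,
                          USE.NAMES = FALSE)
  visits
}

COHORT_NAMES <- c("WHOLE", "AD", "AD_HTN", "AD_DEP", "AD_DEP_HTN")

AD_ACTIONS <- c("CHEI", "MEMANTINE", "CHEI_MEMANTINE")

#' Slice the data into one of the five study cohorts
#'
#' `WHOLE` keeps everyone. `AD` keeps patients diagnosed with AD or MCI at
#' any visit, or prescribed an AD-specific medication (ChEI, memantine or
#' their combination) at any visit. `AD_HTN` additionally keeps hypertensive
#' patients of any cognitive status (including CN), `AD_DEP` depressed
#' patients likewise, and `AD_DEP_HTN` is the union of the two, so the
#' containments `AD` \eqn{\subseteq} `AD_HTN` \eqn{\subseteq} `AD_DEP_HTN`
#' (and via `AD_DEP`) hold by construction.
#'
#' @param visits visit tibble with `ACTION` already assigned.
#' @param cohort one of `WHOLE`, `AD`, `AD_HTN`, `AD_DEP`, `AD_DEP_HTN`.
#' @return the visit tibble restricted to the cohort's patients.
#' @export
build_cohort <- function(visits, cohort) {
  if (!is.character(cohort) || length(cohort) != 1L || !(cohort %in% COHORT_NAMES))
    stop_config("cohort", paste0("must be one of ", paste(COHORT_NAMES, collapse = ", ")))
  if (cohort == "WHOLE") return(visits)
  if (!"ACTION" %in% names(visits)) visits <- assign_actions(visits)
  per_patient <- dplyr::summarise(
    dplyr::group_by(visits, .data$RID),
    ad = any(.data$DX %in% c("AD", "MCI")) | any(.data$ACTION %in% AD_ACTIONS),
    htn = any(.data$HYPERTENSION),
    dep = any(.data$DEPRESSION))
  ids <- switch(cohort,
    AD = per_patient$RID[per_patient$ad],
    AD_HTN = per_patient$RID[per_patient$ad | per_patient$htn],
    AD_DEP = per_patient$RID[per_patient$ad | per_patient$dep],
    AD_DEP_HTN = per_patient$RID[per_patient$ad | per_patient$htn | per_patient$dep])
  dplyr::filter(visits, .data$RID %in% ids)
}
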