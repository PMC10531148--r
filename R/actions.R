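#' The six treatment action classes
#'
#' Every clinic visit is labelled with exactly one of six medication
#' classes: no drugs, cholinesterase inhibitors (ChEI: donepezil,
#' rivastigmine, galantamine), memantine, the ChEI + memantine combination,
#' antihypertensive drugs, and supplements/other. The order here fixes the
#' action indices used by every policy and Q-table (action 1 = NO_DRUGS).
#'
#' @export
ACTIONS <- c("NO_DRUGS", "CHEI", "MEMANTINE", "CHEI_MEMANTINE",
             "ANTIHTN", "SUPPLEMENT")

#' Number of treatment actions (always 6)
#' @export
N_ACTIONS <- length(ACTIONS)

#' Default drug dictionary
#'
#' Maps lowercase substrings of free-text medication entries to a drug
#' class. The class of a whole visit is then resolved by
#' [map_medications_to_actions()]. Users can extend or replace any
#' component (e.g. to add local antihypertensive brand names).
#'
#' @return a named list with character vectors `chei`, `memantine`,
#'   `antihtn`, `supplement` of lowercase name patterns.
#' @export
default_drug_dictionary <- function() {
  list(
    chei       = c("donepezil", "aricept", "rivastigmine", "exelon",
                   "galantamine", "razadyne"),
    memantine  = c("memantine", "namenda"),
    antihtn    = c("lisinopril", "amlodipine", "losartan", "hydrochlorothiazide",
                   "metoprolol", "atenolol", "valsartan", "enalapril",
                   "ramipril", "diltiazem"),
    supplement = c("vitamin", "ginkgo", "fish oil", "omega", "multivitamin",
                   "calcium", "folate", "folic", "coq10", "melatonin")
  )
}

#' Map a visit's medication entries to one of the six action classes
#'
#' Free-text entries are matched case-insensitively against the drug
#' dictionary. When several classes co-occur at one visit the precedence is:
#' ChEI and memantine together give `CHEI_MEMANTINE`; otherwise
#' `CHEI` > `MEMANTINE` > `ANTIHTN` > `SUPPLEMENT`. AD-specific drugs
#' dominate because the reward measures cognition. An empty list is
#' `NO_DRUGS`; entries matching nothing fall through to `SUPPLEMENT`.
#'
#' @param medications character vector of free-text entries for one visit
#'   (may be empty or a single pipe-separated string).
#' @param drug_dictionary mapping as in [default_drug_dictionary()].
#' @return one of [ACTIONS] (character scalar).
#' @export
map_medications_to_actions <- function(medications,
                                       drug_dictionary = default_drug_dictionary()) {
  meds <- unlist(strsplit(as.character(medications %||% character()), "|", fixed = TRUE))
  meds <- tolower(trimws(meds))
  meds <- meds[nzchar(meds)]
  if (length(meds) == 0L) return("NO_DRUGS")

  matches_class <- function(patterns) {
    any(vapply(meds, function(m) any(vapply(patterns, grepl, logical(1), x = m,
                                            fixed = TRUE)), logical(1)))
  }
  has_chei <- matches_class(drug_dictionary$chei)
  has_mem  <- matches_class(drug_dictionary$memantine)
  has_htn  <- matches_class(drug_dictionary$antihtn)

  if (has_chei && has_mem) return("CHEI_MEMANTINE")
  if (has_chei) return("CHEI")
  if (has_mem) return("MEMANTINE")
  if (has_htn) return("ANTIHTN")
  "SUPPLEMENT"  # recognized supplements and unknown entries alike
}

action_index <- function(action) {
  i <- match(action, ACTIONS)
  if (anyNA(i)) stop("unknown action code: ", paste(action[is.na(i)], collapse = ", "))
  i
}
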