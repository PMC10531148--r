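#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the shape of a longitudinal AD registry: 1000-2000
#' patients, 2-15 visits at 6-month spacing, bounded integer-ish assessment
#' scores, comorbidity prevalences, per-visit medication lists from the six
#' treatment classes, and missing score cells that downstream code must
#' forward-fill.
#'
#' @param n_patients number of patients.
#' @param visit_interval_months spacing of visits (months).
#' @param visits_min,visits_max per-patient visit-count bounds (uniform draw).
#' @param hypertension_prevalence,depression_prevalence patient-level
#'   comorbidity probabilities.
#' @param n_latent_states latent states of the ground-truth MDP (>= 2).
#' @param missing_rate probability that a score cell is blanked (MMSE at the
#'   first visit is never blanked).
#' @param score_noise_sd named vector of emission noise SDs per assessment.
#' @param age_mean,age_sd,age_range baseline-age distribution (truncated normal).
#' @param behavior_temperature softmax temperature of the clinician
#'   (behavior) policy over the ground-truth logits.
#' @param seed master integer seed.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_patients = 1500L,
                             visit_interval_months = 6,
                             visits_min = 2L, visits_max = 15L,
                             hypertension_prevalence = 0.40,
                             depression_prevalence = 0.25,
                             n_latent_states = 4L,
                             missing_rate = 0.10,
                             score_noise_sd = c(MMSE = 1.0, ADAS13 = 2.5,
                                                RAVLT_IMMEDIATE = 4, RAVLT_LEARNING = 1,
                                                CDRSB = 0.7, MOCA = 1.5, FDG = 0.06),
                             age_mean = 73, age_sd = 7, age_range = c(55, 95),
                             behavior_temperature = 1,
                             seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) stop_config("n_patients", "must be >= 1")
  if (!is.numeric(visit_interval_months) || visit_interval_months <= 0)
    stop_config("visit_interval_months", "must be positive")
  if (!is.numeric(visits_min) || visits_min < 2) stop_config("visits_min", "must be >= 2")
  if (visits_max < visits_min) stop_config("visits_max", "must be >= visits_min")
  if (!is_prob(hypertension_prevalence))
    stop_config("hypertension_prevalence", "must be a probability in [0, 1]")
  if (!is_prob(depression_prevalence))
    stop_config("depression_prevalence", "must be a probability in [0, 1]")
  if (!is.numeric(n_latent_states) || n_latent_states < 2)
    stop_config("n_latent_states", "must be >= 2")
  if (!is_prob(missing_rate)) stop_config("missing_rate", "must be a probability in [0, 1]")
  if (any(score_noise_sd < 0)) stop_config("score_noise_sd", "must be non-negative")
  if (!is.numeric(behavior_temperature) || behavior_temperature <= 0)
    stop_config("behavior_temperature", "must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    visit_interval_months = visit_interval_months,
    visits_min = as.integer(visits_min), visits_max = as.integer(visits_max),
    hypertension_prevalence = hypertension_prevalence,
    depression_prevalence = depression_prevalence,
    n_latent_states = as.integer(n_latent_states),
    missing_rate = missing_rate,
    score_noise_sd = score_noise_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    behavior_temperature = behavior_temperature,
    seed = as.integer(seed)
  ), class = "generator_config")
}

SCORE_COLS <- c("MMSE", "ADAS13", "RAVLT_IMMEDIATE", "RAVLT_LEARNING",
                "CDRSB", "MOCA", "FDG")

# instrument granularity and valid range per assessment
.score_spec <- list(
  MMSE            = list(step = 1,   range = c(0, 30)),
  ADAS13          = list(step = 1,   range = c(0, 85)),
  RAVLT_IMMEDIATE = list(step = 1,   range = c(0, 75)),
  RAVLT_LEARNING  = list(step = 1,   range = c(-5, 14)),
  CDRSB           = list(step = 0.5, range = c(0, 18)),
  MOCA            = list(step = 1,   range = c(0, 30)),
  FDG             = list(step = NA,  range = c(0.4, 2.0))
)

round_score <- function(x, field) {
  sp <- .score_spec[[field]]
  if (!is.na(sp$step)) x <- round(x / sp$step) * sp$step
  pmin(pmax(x, sp$range[1]), sp$range[2])
}

# drug names emitted per action class; chosen deterministically from the
# patient stream so the medication -> action mapping round-trips
.action_meds <- list(
  NO_DRUGS = character(),
  CHEI = c("Donepezil", "Rivastigmine", "Galantamine"),
  MEMANTINE = c("Memantine"),
  ANTIHTN = c("Lisinopril", "Amlodipine", "Losartan", "Metoprolol"),
  SUPPLEMENT = c("Vitamin E", "Ginkgo Biloba", "Multivitamin", "Fish Oil")
)

meds_for_action <- function(action) {
  if (action == "NO_DRUGS") return("")
  if (action == "CHEI_MEMANTINE") {
    chei <- sample(.action_meds$CHEI, 1L)
    return(paste(chei, "Memantine", sep = "|"))
  }
  pool <- .action_meds[[action]]
  sample(pool, 1L)
}

#' Generate a synthetic longitudinal visit table
#'
#' Each patient follows the ground-truth MDP: a latent severity path whose
#' transitions depend on the prescribed action, assessments emitted as
#' Gaussian noise around the latent state's means (truncated to instrument
#' ranges and rounded to instrument granularity), actions drawn from the
#' state-dependent softmax behavior policy, and score cells blanked at
#' `missing_rate` (never MMSE at the first visit). Each patient has its own
#' derived random stream, so patient `i`'s record does not depend on
#' `n_patients`, and identical config + seed reproduces identical output.
#'
#' @param config a [generator_config()].
#' @param mdp a [true_mdp()]; its state count must match the config.
#' @return a tibble of visit records with the registry-style columns `RID`,
#'   `VISCODE`, `MONTH`, `AGE`, the seven assessments, `DX`, `HYPERTENSION`,
#'   `DEPRESSION`, `MEDICATIONS`, plus generator-truth columns `.latent`
#'   (latent state index) and `.action` (behavior action drawn) that
#'   [write_cohort()] does not serialize.
#' @export
generate_cohort <- function(config = generator_config(), mdp = default_true_mdp()) {
  stopifnot(inherits(config, "generator_config"), inherits(mdp, "true_mdp"))
  if (mdp$n_states != config$n_latent_states)
    stop_config("n_latent_states", "does not match the supplied MDP")

  behavior <- t(apply(mdp$behavior_logits / config$behavior_temperature, 1L, softmax))
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, i))
    n_visits <- sample(config$visits_min:config$visits_max, 1L)
    age0 <- stats::rnorm(1L, config$age_mean, config$age_sd)
    age0 <- min(max(age0, config$age_range[1]), config$age_range[2])
    htn <- stats::runif(1L) < config$hypertension_prevalence
    dep <- stats::runif(1L) < config$depression_prevalence

    # latent path and behavior actions are sequential by nature
    lat <- integer(n_visits)
    act <- integer(n_visits)
    s <- sample.int(mdp$n_states, 1L, prob = mdp$init_dist)
    for (v in seq_len(n_visits)) {
      lat[v] <- s
      act[v] <- sample.int(N_ACTIONS, 1L, prob = behavior[s, ])
      s <- sample.int(mdp$n_states, 1L, prob = mdp$transition[s, act[v], ])
    }
    scores <- matrix(NA_real_, n_visits, length(SCORE_COLS),
                     dimnames = list(NULL, SCORE_COLS))
    for (f in SCORE_COLS) {
      mu <- mdp$score_emission[lat, f]
      scores[, f] <- round_score(
        stats::rnorm(n_visits, mu, config$score_noise_sd[[f]]), f)
    }
    miss <- matrix(stats::runif(n_visits * length(SCORE_COLS)) < config$missing_rate,
                   n_visits, dimnames = list(NULL, SCORE_COLS))
    miss[1L, "MMSE"] <- FALSE
    scores[miss] <- NA_real_
    month <- (seq_len(n_visits) - 1L) * config$visit_interval_months
    patients[[i]] <- tibble::tibble(
      RID = i,
      VISCODE = ifelse(month == 0, "bl", sprintf("m%02d", month)),
      MONTH = month,
      # severity-age association enters through the baseline state only, so
      # each patient ages monotonically between visits
      AGE = round(age0 + mdp$score_emission[lat[1], "AGE_OFFSET"] + month / 12, 1),
      MMSE = scores[, "MMSE"], ADAS13 = scores[, "ADAS13"],
      RAVLT_IMMEDIATE = scores[, "RAVLT_IMMEDIATE"],
      RAVLT_LEARNING = scores[, "RAVLT_LEARNING"],
      CDRSB = scores[, "CDRSB"], MOCA = scores[, "MOCA"], FDG = scores[, "FDG"],
      DX = mdp$dx[lat],
      HYPERTENSION = htn, DEPRESSION = dep,
      MEDICATIONS = vapply(act, function(a) meds_for_action(ACTIONS[a]),
                           character(1)),
      .latent = lat, .action = act
    )
  }
  dplyr::bind_rows(patients)
}

#' Write / read the visit table as comma-separated text
#'
#' The serialized table carries the fixed registry-style header only; the
#' generator-truth columns (`.latent`, `.action`) are dropped. Missing score
#' cells are written as empty fields; an empty `MEDICATIONS` cell means no
#' drugs, and multiple entries within the cell are pipe-separated.
#'
#' @param visits a visit tibble from [generate_cohort()].
#' @param path output file path.
#' @export
write_cohort <- function(visits, path) {
  cols <- c("RID", "VISCODE", "MONTH", "AGE", SCORE_COLS, "DX",
            "HYPERTENSION", "DEPRESSION", "MEDICATIONS")
  out <- as.data.frame(visits[, cols])
  out$HYPERTENSION <- as.integer(out$HYPERTENSION)
  out$DEPRESSION <- as.integer(out$DEPRESSION)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param path input file path.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(VISCODE = "character", DX = "character",
                                       MEDICATIONS = "character"))
  for (f in SCORE_COLS) df[[f]] <- as.numeric(df[[f]])
  df$HYPERTENSION <- df$HYPERTENSION > 0
  df$DEPRESSION <- df$DEPRESSION > 0
  df$MEDICATIONS[is.na(df$MEDICATIONS)] <- ""
  tibble::as_tibble(df)
}
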