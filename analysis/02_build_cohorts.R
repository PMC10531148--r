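#!/usr/bin/env Rscript
# Select eligible patients (>= 2 complete visits after carry-forward
# imputation), map free-text medications to the six action classes, and
# tabulate the five study cohorts.
suppressMessages({library(regimenrl); library(dplyr)})

visits <- read_cohort("results/cohort_visits.csv")
prepared <- prepare_visits(visits)
message(sprintf("eligible: %d of %d patients (%d visits)",
                length(unique(prepared$RID)), length(unique(visits$RID)),
                nrow(prepared)))

action_counts <- count(prepared, ACTION, sort = TRUE)
write.csv(action_counts, "results/action_counts.csv", row.names = FALSE)
print(action_counts)

cohort_sizes <- do.call(rbind, lapply(c("WHOLE", "AD", "AD_HTN", "AD_DEP",
                                        "AD_DEP_HTN"), function(ch) {
  cv <- build_cohort(prepared, ch)
  data.frame(cohort = ch, patients = length(unique(cv$RID)), visits = nrow(cv))
}))
write.csv(cohort_sizes, "results/cohort_sizes.csv", row.names = FALSE)
print(cohort_sizes)

saveRDS_path <- "results/prepared_visits.csv"
write.csv(prepared, saveRDS_path, row.names = FALSE)
message("wrote ", saveRDS_path)
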