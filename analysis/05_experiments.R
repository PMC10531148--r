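#!/usr/bin/env Rscript
# The five experiment harnesses on the synthetic cohort, at desk scale:
#  1 data-size sweep (100/80/50/30% of the training split, shared states)
#  2 comorbidity cohorts (AD, AD-HTN, AD-DEP, AD-DEP-HTN)
#  3 JR/SR caseload strata (below/above the grand mean of patient mean MMSE)
#  4 Q-learning learning-rate sweep (0.1 ... 0.9)
#  5 state-count sweep (occupancy thresholds 50 / 100 / 200)
# Repetition counts are reduced from the headline 50x/100x defaults to keep
# a desk run in minutes; pass full = TRUE below to restore them.
suppressMessages({library(regimenrl); library(dplyr)})

full <- FALSE
prepared <- tibble::as_tibble(read.csv("results/prepared_visits.csv"))
cfg <- experiment_config(
  n_train_reps = if (full) 50L else 5L,
  n_bootstrap = if (full) 100L else 25L,
  seed = 20260105L)

summarize_all <- function(results, file) {
  out <- bind_rows(lapply(names(results), function(nm)
    mutate(compare_policies(results[[nm]])$summary, scenario = nm)))
  write.csv(out, file, row.names = FALSE)
  print(out, n = Inf)
  invisible(out)
}

message("== data-size sweep ==")
t1 <- run_test1(prepared, cfg, out_dir = "results/test1")
summarize_all(t1, "results/test1_policy_summary.csv")

message("== comorbidity cohorts ==")
t2 <- run_test2(prepared, cfg)
summarize_all(t2, "results/test2_policy_summary.csv")

message("== JR/SR strata ==")
t3 <- run_test3(prepared, cfg)
summarize_all(t3, "results/test3_policy_summary.csv")

message("== learning-rate sweep ==")
t4 <- run_test4(prepared, cfg)
ql_by_alpha <- bind_rows(lapply(names(t4), function(nm) {
  s <- compare_policies(t4[[nm]])$summary
  mutate(filter(s, policy == "q_learning"), alpha = nm)
}))
write.csv(ql_by_alpha, "results/test4_qlearning_by_alpha.csv", row.names = FALSE)
print(ql_by_alpha)

message("== state-count sweep ==")
t5 <- run_test5(prepared, cfg)
t5_summary <- bind_rows(lapply(names(t5), function(nm) {
  s <- compare_policies(t5[[nm]])$summary
  mutate(s, scenario = nm, n_states = t5[[nm]]$n_states)
}))
write.csv(t5_summary, "results/test5_policy_summary.csv", row.names = FALSE)
print(filter(t5_summary, policy == "q_learning"))
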