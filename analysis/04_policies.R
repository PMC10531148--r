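#!/usr/bin/env Rscript
# Learn the five policies on the whole-data cohort and compare their
# per-state recommendations: exact policy iteration and offline Q-learning
# (the optimal policies), the clinician policy (one evaluation+improvement
# cycle on the data's transition probabilities), and the zero / random
# reference policies.
suppressMessages({library(regimenrl); library(dplyr)})

prepared <- tibble::as_tibble(read.csv("results/prepared_visits.csv"))
res <- run_policy_comparison(
  prepared,
  experiment_config(n_train_reps = 10L, n_bootstrap = 100L, seed = 20260104L))

write.csv(res$actions, "results/recommended_actions.csv", row.names = FALSE)
print(res$actions)

cmp <- compare_policies(res)
write.csv(cmp$summary, "results/policy_rewards_summary.csv", row.names = FALSE)
print(cmp$summary)
write.csv(round(cmp$p_values, 6), "results/policy_ttest_pvalues.csv")
ggplot2::ggsave("results/policy_rewards_boxplot.png", cmp$plot,
                width = 7, height = 4, dpi = 150)
message("wrote results/policy_rewards_boxplot.png")
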