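#!/usr/bin/env Rscript
# Derive the discrete disease states (regression feature selection + CART
# tree on MMSE), label every visit, and estimate the empirical transition
# and reward model of the whole-data cohort.
suppressMessages({library(regimenrl); library(dplyr)})

prepared <- tibble::as_tibble(read.csv("results/prepared_visits.csv"))

fs <- select_features(prepared)
write.csv(fs, "results/feature_selection.csv", row.names = FALSE)
print(fs)

model <- fit_state_tree(prepared, fs$feature[fs$selected], min_occupancy = 50)
write_state_rules(model, "results/state_rules.csv")
print(model)

prepared$STATE <- as.integer(assign_state(model, prepared))
transitions <- build_transitions(prepared)
message(sprintf("%d transitions from %d trajectories",
                nrow(transitions), length(unique(transitions$traj_id))))
write.csv(transitions, "results/transitions.csv", row.names = FALSE)

emp <- estimate_transition_model(transitions, n_states = n_states(model))
message(sprintf("observed (state, action) support: %d / %d",
                sum(emp$support), length(emp$support)))
reward_table <- as.data.frame(emp$reward)
names(reward_table) <- ACTIONS
reward_table$state <- model$states$label
write.csv(reward_table[, c("state", ACTIONS)],
          "results/empirical_rewards.csv", row.names = FALSE)

# the published decision-tree ruleset ships with the package and can stand
# in for a refit (13 whole-data states)
pub <- load_published_rules("WHOLE")
message("published whole-data ruleset: ", n_states(pub), " states; anomalies: ",
        ifelse(length(pub$anomalies), paste(pub$anomalies, collapse = "; "),
               "none"))
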