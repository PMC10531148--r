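Package: regimenrl
Title: Offline Reinforcement Learning for Alzheimer's Treatment Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns dynamic treatment regimens for Alzheimer's disease from
    longitudinal clinic-visit tables. Visits are abstracted into a finite set
    of disease states by a regression tree on cognitive assessments, visits
    are chained into (state, action, reward, next-state) trajectories with
    the between-visit MMSE change as reward, and tabular policy iteration and
    offline Q-learning are compared against a data-derived clinician policy,
    a no-treatment policy and a random policy using stepwise weighted
    importance sampling. A synthetic cohort generator with a known
    ground-truth Markov decision process makes every stage testable without
    access-controlled registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    rpart,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
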