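Package: castesim
Title: Agent-Based Simulation of Honest Signaling Under Opportunistic
    Punishment in Caste-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of honest and deceptive aggression
    signaling in a population partitioned into three castes that differ in
    endowment, metabolic cost and appropriation power.  Agents meet in
    asymmetric pairwise dominance contests; winners extract a larger share
    of resources from defeated dishonest opponents (opportunistic
    punishment), starved agents are replaced through within-caste binary
    tournaments, and deception rates evolve over millions of encounters.
    Provides a fast compiled engine, a naive reference engine for
    verification, replication and full-factorial parameter-sweep
    harnesses, egalitarian single-caste variants, tidy summaries and
    ggplot2 figures of per-replicate trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
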