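# Small configurations used across the test files.

tiny_config <- function(ticks = 1000, seed = 1, per_caste = 10,
                        snapshot_interval = 100, ...) {
  sim_config(caste_sizes = rep(per_caste, 3), ticks = ticks, seed = seed,
             snapshot_interval = snapshot_interval, ...)
}

# reduced-scale config used for the desk-scale stochastic properties
desk_config <- function(scale = c(1, 1, 1, 1), ticks = 2e5, seed = 5, ...) {
  sim_config(caste_sizes = c(100, 100, 100), ticks = ticks, seed = seed,
             scale = scale, snapshot_interval = 1e4, ...)
}

# per-caste liar count at the final recorded tick of a run
final_liars <- function(run) {
  lc <- liar_counts(run$snapshots)
  lc[lc$tick == max(lc$tick), ]
}

# mean first tick at which a caste's liar count reaches zero (run length if
# never reached), across replicate runs
mean_first_passage <- function(runs, caste) {
  ticks <- vapply(runs, function(r) {
    lc <- liar_counts(r$snapshots)
    lc <- lc[lc$caste == caste, ]
    if (any(lc$n_liars == 0)) min(lc$tick[lc$n_liars == 0]) else max(lc$tick)
  }, numeric(1))
  mean(ticks)
}
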