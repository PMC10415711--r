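# Shared fixtures, built in code. Expensive simulations are computed once per
# test run and memoised in this environment.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small random count table with guaranteed positive column sums.
random_table <- function(n_asv = 12, n_sample = 5, depth = 500, seed = 1) {
  withr::with_seed(seed, {
    m <- sapply(seq_len(n_sample), function(i) {
      p <- rgamma(n_asv, 0.5)
      stats::rmultinom(1, depth, p)[, 1]
    })
    rownames(m) <- paste0("ASV_", seq_len(n_asv))
    colnames(m) <- paste0("s", seq_len(n_sample))
    community_table(m)
  })
}

# Diverse 20-sample pool with the last sample duplicating the first:
# independent lognormal compositions over a 300-ASV universe.
duplicate_pool_table <- function(seed, n_asv = 300, depth = 4000) {
  withr::with_seed(seed, {
    m <- sapply(1:20, function(i) {
      p <- rlnorm(n_asv, 0, 2)
      stats::rmultinom(1, depth, p / sum(p))[, 1]
    })
    rownames(m) <- paste0("ASV_", seq_len(n_asv))
    colnames(m) <- paste0("s", 1:20)
    m[, 20] <- m[, 1]
    community_table(m)
  })
}

# Neutral study simulation at the calibration scale (100 ASVs, depth 5000,
# disturbances at days 0/50/100 removing half the granules), rarefied, with
# patristic distances and the successive/between-reactor comparison series.
neutral_study <- function() memo("neutral_study", function() {
  cfg <- simulation_config(n_asvs = 100, read_depth = 5000, seed = 101)
  sim <- simulate_study(cfg)
  tab <- rarefy(sim$table, 5000, seed = 102)
  ser <- rbind(build_series(sim$metadata, "successive", "R2")[1:2],
               build_series(sim$metadata, "successive", "R3")[1:2],
               build_series(sim$metadata, "between_reactor")[1:2])
  list(sim = sim, table = tab,
       distances = patristic_distances(sim$tree, rownames(tab)),
       series = ser)
})

# Selection-regime simulation: even inoculum, many granules, strong
# tree-correlated selection identical in both reactors.
selection_study <- function() memo("selection_study", function() {
  tree <- simulate_tree(300, seed = 201)
  sel <- tree_selection_coefficients(tree, sd = 0.05, seed = 202)
  cfg <- simulation_config(n_asvs = 300, n_granules = 2000, read_depth = 20000,
                           abundance_sdlog = 1, selection_coefficients = sel,
                           seed = 203)
  sim <- simulate_study(cfg, tree = tree)
  list(sim = sim, table = rarefy(sim$table, 20000, seed = 204))
})
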