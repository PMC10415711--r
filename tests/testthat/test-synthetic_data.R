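# Scaled-down configuration used throughout: sizes small enough for fast
# property checks while keeping the granule structure meaningful.
small_config <- function(seed = 1, ...) {
  defaults <- list(n_asvs = 40, n_granules = 30, individuals_per_granule = 200,
                   founders_per_granule = 5,
                   sampling_days = c(1, 10, 20, 30, 40, 50, 60),
                   disturbance_days = c(0, 30), read_depth = 2000, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

test_that("simulated trees are reproducible rooted trees with positive lengths", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(ape::is.rooted(t2))
  expect_identical(ape::write.tree(simulate_tree(50, seed = 9)),
                   ape::write.tree(simulate_tree(50, seed = 9)))
  t100 <- simulate_tree(100, seed = 2)
  expect_equal(ape::Ntip(t100), 100)
  expect_true(all(t100$edge.length > 0))
  expect_setequal(t100$tip.label, paste0("ASV_", 1:100))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("drift steps conserve granule size and keep fixed granules fixed", {
  cfg <- small_config()
  g <- matrix(0L, 40, 3, dimnames = list(paste0("ASV_", 1:40), NULL))
  g[5, 1] <- 200L                      # fixed granule
  g[c(1, 2, 3), 2] <- c(100L, 60L, 40L)
  g[10:19, 3] <- 20L
  state <- list(granules = g, day = 0L)
  withr::with_seed(1, {
    for (i in 1:20) {
      state <- step_drift_selection(state, cfg)
      expect_true(all(colSums(state$granules) == 200))
      expect_equal(unname(state$granules[5, 1]), 200L)
    }
  })
})

test_that("selection shifts expected frequencies by the logistic closed form", {
  cfg <- small_config()
  cfg$selection_coefficients[2] <- 0.5
  cfg$individuals_per_granule <- 100L
  g <- matrix(0L, 40, 1, dimnames = list(paste0("ASV_", 1:40), NULL))
  g[1, 1] <- 70L; g[2, 1] <- 30L
  p0 <- 0.3; s <- 0.5
  expected <- p0 * exp(s) / (p0 * exp(s) + (1 - p0))
  freqs <- withr::with_seed(2, vapply(1:10000, function(i) {
    st <- step_drift_selection(list(granules = g, day = 0L), cfg)
    st$granules[2, 1] / 100
  }, numeric(1)))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - expected), 4 * se + 1e-6)
})

test_that("granule-mode disturbance removes exactly the configured share", {
  cfg <- small_config(n_granules = 10)
  g <- matrix(5L, 40, 10, dimnames = list(paste0("ASV_", 1:40), NULL))
  state <- list(granules = g, day = 0L)
  survivors <- withr::with_seed(3,
    apply_disturbance(state, cfg, regrow = FALSE)$granules)
  expect_equal(ncol(survivors), 5)

  # different seeds remove different subsets (w.h.p.), same seed the same one
  pick <- function(seed) withr::with_seed(seed, {
    st <- list(granules = g, day = 0L)
    st$granules[1, ] <- 1:10   # tag granules so the surviving subset is identifiable
    sort(apply_disturbance(st, cfg, regrow = FALSE)$granules[1, ])
  })
  expect_identical(pick(4), pick(4))
  expect_false(identical(pick(4), pick(5)))

  # uniform mode shrinks every granule hypergeometrically
  cfg_u <- small_config(n_granules = 10, disturbance_mode = "uniform")
  shrunk <- withr::with_seed(6,
    apply_disturbance(list(granules = g, day = 0L), cfg_u, regrow = FALSE)$granules)
  expect_equal(ncol(shrunk), 10)
  expect_true(all(colSums(shrunk) == 100))

  # regrowth restores carrying capacity
  regrown <- withr::with_seed(7, apply_disturbance(state, cfg))
  expect_equal(ncol(regrown$granules), 10)
  expect_true(all(colSums(regrown$granules) == 200))

  cfg_all <- small_config(n_granules = 10, removal_fraction = 0.99)
  expect_error(withr::with_seed(8, apply_disturbance(state, cfg_all, regrow = FALSE)),
               "all granules")
})

test_that("a simulated study has the experiment's layout and exact depths", {
  cfg <- small_config(seed = 11)
  sim <- simulate_study(cfg)
  md <- sim$metadata
  expect_setequal(unique(md$reactor), c("R1", "R2", "R3"))
  expect_equal(sum(md$role == "inoculum"), 1)
  expect_equal(sum(md$reactor == "R2"), length(cfg$sampling_days))
  expect_true(all(colSums(sim$table) == cfg$read_depth))
  expect_setequal(rownames(sim$table), sim$tree$tip.label)

  # fixed master seed reproduces the full triple bit-identically
  sim2 <- simulate_study(small_config(seed = 11))
  expect_identical(unclass(sim$table), unclass(sim2$table))
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))
})

test_that("replicate reactors start nearly identical and drift apart with time", {
  # day-0/day-1 split noise is small at full depth
  cfg <- simulation_config(n_asvs = 100, sampling_days = c(1, 30, 60, 90, 120, 149),
                           n_granules = 100, individuals_per_granule = 500,
                           founders_per_granule = 10, read_depth = 20000, seed = 21)
  sim <- simulate_study(cfg)
  p <- relative_abundances(sim$table)
  d1 <- taxonomic_dissimilarity(p[, "R2_d001"], p[, "R3_d001"], 1)
  expect_lt(d1, 0.1)

  # median between-replicate dissimilarity increases with day across seeds
  traj <- sapply(1:8, function(s) {
    cfg <- small_config(seed = 30 + s,
                        sampling_days = c(1, 15, 30, 45, 60))
    sim <- simulate_study(cfg)
    p <- relative_abundances(sim$table)
    sapply(c(1, 15, 30, 45, 60), function(d)
      taxonomic_dissimilarity(p[, sprintf("R2_d%03d", d)],
                              p[, sprintf("R3_d%03d", d)], 1))
  })
  med <- apply(traj, 1, median)
  expect_gt(cor(med, c(1, 15, 30, 45, 60), method = "spearman"), 0)
  expect_gt(mean(traj[5, ] > traj[1, ]), 0.5)
})

test_that("granule-mode disturbances jump replicate dissimilarity more than uniform mode", {
  jump <- function(seed, mode) {
    cfg <- small_config(seed = seed, n_granules = 20,
                        sampling_days = c(29, 31),
                        disturbance_days = 30, disturbance_mode = mode,
                        read_depth = 5000)
    sim <- simulate_study(cfg)
    p <- relative_abundances(sim$table)
    post <- taxonomic_dissimilarity(p[, "R2_d031"], p[, "R3_d031"], 1)
    pre <- taxonomic_dissimilarity(p[, "R2_d029"], p[, "R3_d029"], 1)
    post - pre
  }
  withr::with_seed(40, {
    seeds <- sample(1e6, 12)
    gr <- vapply(seeds, jump, numeric(1), mode = "granule")
    un <- vapply(seeds, jump, numeric(1), mode = "uniform")
    expect_gt(mean(gr), mean(un))
    expect_gt(mean(gr > un), 0.5)
  })
})
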