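#' Configuration of the granular-sludge community simulator
#'
#' The simulator emulates the statistical regime of a disturbed
#' granular-sludge reactor experiment: one acclimatized inoculum community
#' whose granules are split between two replicate reactors, neutral
#' Wright-Fisher drift (optionally with selection) within granules, periodic
#' disturbances removing half the biomass, and multinomial read sampling of
#' the homogenized reactor at each sampling day.
#'
#' Default sizes: 200 ASVs with a lognormal rank-abundance inoculum (a few
#' dominant ASVs and a long tail), 200 granules of 2000 individuals founded
#' by 10 individuals each (large within-granule variability), 27 sampling
#' days over 149 days, disturbances at days 0/50/100 removing half the
#' granules, read depth 70492.
#'
#' @param n_asvs number of ASVs in the regional species pool.
#' @param n_granules granules per reactor (carrying capacity in granules).
#' @param individuals_per_granule individuals per granule (carrying capacity).
#' @param founders_per_granule founder individuals seeding each granule.
#' @param sampling_days strictly increasing days at which reads are sampled.
#' @param disturbance_days days on which a disturbance is applied.
#' @param removal_fraction fraction of biomass removed per disturbance,
#'   in (0, 1).
#' @param disturbance_mode `"granule"` (whole random granules removed,
#'   default) or `"uniform"` (every granule loses the fraction of its
#'   individuals, hypergeometrically).
#' @param selection_coefficients per-ASV log-fitness coefficients (default
#'   all 0 = neutral drift). See [tree_selection_coefficients()] for
#'   tree-correlated selection.
#' @param read_depth reads per sample (default 70492).
#' @param abundance_sdlog lognormal sd of the inoculum rank-abundance curve.
#' @param seed master seed; all stochastic steps derive child seeds from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_asvs = 200, n_granules = 200,
                              individuals_per_granule = 2000,
                              founders_per_granule = 10,
                              sampling_days = unique(round(seq(1, 149,
                                                               length.out = 27))),
                              disturbance_days = c(0, 50, 100),
                              removal_fraction = 0.5,
                              disturbance_mode = c("granule", "uniform"),
                              selection_coefficients = NULL,
                              read_depth = 70492,
                              abundance_sdlog = 3,
                              seed = 1) {
  disturbance_mode <- match.arg(disturbance_mode)
  stopifnot(n_asvs >= 2, n_granules >= 2, individuals_per_granule >= 2,
            founders_per_granule >= 1, read_depth >= 1,
            removal_fraction > 0, removal_fraction < 1,
            all(diff(sampling_days) > 0), all(sampling_days >= 0))
  if (is.null(selection_coefficients))
    selection_coefficients <- rep(0, n_asvs)
  if (length(selection_coefficients) != n_asvs)
    stop("selection_coefficients must have length n_asvs")
  structure(list(n_asvs = as.integer(n_asvs),
                 n_granules = as.integer(n_granules),
                 individuals_per_granule = as.integer(individuals_per_granule),
                 founders_per_granule = as.integer(founders_per_granule),
                 sampling_days = as.integer(sampling_days),
                 disturbance_days = as.integer(disturbance_days),
                 removal_fraction = removal_fraction,
                 disturbance_mode = disturbance_mode,
                 selection_coefficients = selection_coefficients,
                 read_depth = as.integer(read_depth),
                 abundance_sdlog = abundance_sdlog,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a random rooted phylogeny for the ASV pool
#'
#' A random bifurcating topology (Yule-type random splits) with
#' exponentially distributed branch lengths, tips labelled `ASV_1..ASV_n`.
#'
#' @param n_asvs number of tips (>= 2).
#' @param seed integer seed.
#' @return A rooted `phylo` object with positive branch lengths.
#' @export
simulate_tree <- function(n_asvs, seed = 1) {
  if (n_asvs < 2) stop("need at least 2 ASVs")
  withr::with_seed(as.integer(seed), {
    tree <- ape::rtree(n_asvs, rooted = TRUE, br = stats::rexp)
    tree$tip.label <- paste0("ASV_", seq_len(n_asvs))
    tree
  })
}

#' Tree-correlated selection coefficients
#'
#' Draws per-ASV log-fitness coefficients from a Brownian walk down the tree
#' (so close relatives have similar fitness), centred and scaled to a given
#' standard deviation. Feeding these into [simulation_config()] gives the
#' deterministic-assembly regime a phylogenetic signal that betaNTI can
#' detect.
#'
#' @param tree `phylo` object whose tips are the ASVs.
#' @param sd standard deviation of the coefficients across ASVs (per
#'   generation log-fitness scale).
#' @param seed integer seed.
#' @return Named numeric vector, one coefficient per tip, ordered ASV_1..n.
#' @export
tree_selection_coefficients <- function(tree, sd = 0.1, seed = 1) {
  s <- withr::with_seed(as.integer(seed),
                        ape::rTraitCont(tree, model = "BM", sigma = 1))
  s <- s - mean(s)
  if (stats::sd(s) > 0) s <- s * sd / stats::sd(s)
  s[order(as.integer(sub("^ASV_", "", names(s))))]
}

#' One Wright-Fisher generation with optional selection
#'
#' Every granule's next-generation composition is a multinomial draw of
#' `individuals_per_granule` individuals with probabilities proportional to
#' `counts * exp(selection_coefficient)`. With all coefficients zero this is
#' pure neutral drift; a granule fixed for one ASV stays fixed.
#'
#' @param state list with element `granules` (ASV x granule integer matrix)
#'   and `day`.
#' @param config a [simulation_config()].
#' @return The updated state. Randomness is taken from the current RNG state.
#' @export
step_drift_selection <- function(state, config) {
  g <- state$granules
  w <- exp(config$selection_coefficients)
  M <- config$individuals_per_granule
  keep <- colSums(g) > 0
  g <- g[, keep, drop = FALSE]
  state$granules <- vapply(seq_len(ncol(g)), function(j) {
    stats::rmultinom(1, M, prob = g[, j] * w)[, 1]
  }, integer(nrow(g)))
  rownames(state$granules) <- rownames(g)
  state
}

#' Apply a disturbance removing a fraction of the biomass
#'
#' In `"granule"` mode a uniformly random subset of `ceiling(fraction * G)`
#' granules is deleted, emulating the withdrawal of settled granules; in
#' `"uniform"` mode every granule loses the fraction of its individuals by a
#' without-replacement (hypergeometric) draw. With `regrow = TRUE` the
#' reactor is brought back to carrying capacity in one composite step:
#' granule count is restored by duplicating surviving granules with
#' multinomial resampling, and each granule is regrown to full size by one
#' [step_drift_selection()] generation.
#'
#' @param state simulator state (see [step_drift_selection()]).
#' @param config a [simulation_config()].
#' @param regrow regrow to carrying capacity after the removal.
#' @return The disturbed (and optionally regrown) state.
#' @export
apply_disturbance <- function(state, config, regrow = TRUE) {
  g <- state$granules
  G <- ncol(g)
  if (G < 2) stop("need at least 2 granules to disturb")
  f <- config$removal_fraction
  if (config$disturbance_mode == "granule") {
    n_remove <- ceiling(f * G)
    if (n_remove >= G) stop("removal_fraction would remove all granules")
    g <- g[, -sample.int(G, n_remove), drop = FALSE]
  } else {
    M <- colSums(g)
    keep_n <- pmax(1L, round((1 - f) * M))
    g <- vapply(seq_len(G), function(j) draw_without_replacement(g[, j], keep_n[j]),
                integer(nrow(g)))
    rownames(g) <- rownames(state$granules)
  }
  state$granules <- g
  if (regrow) state <- regrow_to_capacity(state, config)
  state
}

# Restore granule count by duplicating surviving granules (multinomial
# resampling keeps within-granule variability alive), then one growth step.
regrow_to_capacity <- function(state, config) {
  g <- state$granules
  deficit <- config$n_granules - ncol(g)
  if (deficit > 0) {
    parents <- sample.int(ncol(g), deficit, replace = TRUE)
    M <- config$individuals_per_granule
    clones <- vapply(parents, function(j) {
      stats::rmultinom(1, M, prob = g[, j])[, 1]
    }, integer(nrow(g)))
    g <- cbind(g, clones)
    state$granules <- g
  }
  step_drift_selection(state, config)
}

#' Simulate the full reactor study
#'
#' Builds an inoculum community of founder-seeded granules, splits its
#' granules at random into two replicate reactors (`R2`, `R3`), lets each
#' reactor evolve independently one Wright-Fisher generation per day,
#' applies disturbances on the configured days, and on every sampling day
#' draws a multinomial read sample of the configured depth from the pooled
#' (homogenized) reactor composition. The inoculum itself is sampled once as
#' reactor `R1` with role `"inoculum"`.
#'
#' @param config a [simulation_config()].
#' @param tree optional `phylo` with tips `ASV_1..n`; simulated with
#'   [simulate_tree()] when omitted.
#' @return List with `table` (a [community_table()]), `metadata`, `tree`,
#'   and `truth` (latent relative abundances per reactor and day, the
#'   selection coefficients and the config).
#' @export
simulate_study <- function(config = simulation_config(), tree = NULL) {
  if (is.null(tree))
    tree <- simulate_tree(config$n_asvs, seed = child_seed(config$seed, "tree"))
  asv_ids <- paste0("ASV_", seq_len(config$n_asvs))

  inoculum <- with_child_seed(config$seed, "inoculum", code = {
    # unsorted: abundance rank must stay independent of tip position on the tree
    pool_p <- stats::rlnorm(config$n_asvs, 0, config$abundance_sdlog)
    pool_p <- pool_p / sum(pool_p)
    granules <- vapply(seq_len(config$n_granules), function(j) {
      founders <- stats::rmultinom(1, config$founders_per_granule, pool_p)[, 1]
      stats::rmultinom(1, config$individuals_per_granule, prob = founders)[, 1]
    }, integer(config$n_asvs))
    rownames(granules) <- asv_ids
    granules
  })

  split <- with_child_seed(config$seed, "split", code =
    sample.int(config$n_granules, floor(config$n_granules / 2)))

  samples <- list(); meta <- list(); latent <- list()
  inoc_p <- rowSums(inoculum) / sum(inoculum)
  samples[["R1_inoculum"]] <- with_child_seed(config$seed, "reads", "R1", code =
    stats::rmultinom(1, config$read_depth, inoc_p)[, 1])
  meta[["R1_inoculum"]] <- data.frame(sample_id = "R1_inoculum", reactor = "R1",
                                      day = 0, role = "inoculum",
                                      stringsAsFactors = FALSE)
  latent[["R1_inoculum"]] <- inoc_p

  halves <- list(R2 = inoculum[, split, drop = FALSE],
                 R3 = inoculum[, -split, drop = FALSE])
  horizon <- max(config$sampling_days, config$disturbance_days)
  for (reactor in names(halves)) {
    res <- with_child_seed(config$seed, "evolve", reactor, code = {
      state <- list(granules = halves[[reactor]], day = 0L)
      state <- regrow_to_capacity(state, config)
      out <- list()
      for (day in 0:horizon) {
        state$day <- day
        if (day %in% config$disturbance_days)
          state <- apply_disturbance(state, config)
        if (day %in% config$sampling_days) {
          p <- rowSums(state$granules) / sum(state$granules)
          sid <- sprintf("%s_d%03d", reactor, day)
          out[[sid]] <- list(reads = stats::rmultinom(1, config$read_depth, p)[, 1],
                             latent = p, day = day)
        }
        if (day < horizon) state <- step_drift_selection(state, config)
      }
      out
    })
    for (sid in names(res)) {
      samples[[sid]] <- res[[sid]]$reads
      latent[[sid]] <- res[[sid]]$latent
      meta[[sid]] <- data.frame(sample_id = sid, reactor = reactor,
                                day = res[[sid]]$day, role = "timepoint",
                                stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- asv_ids
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(table = community_table(counts), metadata = metadata, tree = tree,
       truth = list(latent = latent, config = config,
                    selection_coefficients = config$selection_coefficients))
}

# Without-replacement draw of n individuals from integer counts.
draw_without_replacement <- function(counts, n) {
  total <- sum(counts)
  if (n >= total) return(as.integer(counts))
  picked <- sample.int(total, n)
  tabulate(findInterval(picked - 1L, cumsum(counts)) + 1L,
           nbins = length(counts))
}
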