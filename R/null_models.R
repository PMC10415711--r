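#' Configuration for standardized-effect-size null models
#'
#' @param n_randomizations number of null randomizations (default 999).
#' @param threshold significance threshold on `|ses|` (default 2).
#' @param pool_scope `"all_samples"` (default): the regional pool is every
#'   sample of the table; `"per_reactor"`: restrict to the samples named in
#'   `pool_samples` when calling the null-model functions.
#' @param weighting how null ASV identities and reads are weighted:
#'   `"frequency_x_abundance"` (default) draws ASV identities with
#'   probability proportional to occurrence frequency in the regional pool
#'   and allocates reads proportionally to regional relative abundance;
#'   `"frequency"` and `"abundance"` use the named weight for both steps.
#' @param seed master seed; every pair derives its own child seed.
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_randomizations = 999, threshold = 2,
                        pool_scope = c("all_samples", "per_reactor"),
                        weighting = c("frequency_x_abundance", "frequency",
                                      "abundance"),
                        seed = 1) {
  stopifnot(n_randomizations >= 1, threshold > 0)
  structure(list(n_randomizations = as.integer(n_randomizations),
                 threshold = threshold,
                 pool_scope = match.arg(pool_scope),
                 weighting = match.arg(weighting),
                 seed = seed),
            class = "null_config")
}

#' Summarise a regional species pool
#'
#' @param table a [community_table()] (or count matrix) of the pool samples.
#' @return List with `asv_ids` (ASVs present in the pool), `frequency`
#'   (occurrence frequency across pool samples) and `abundance` (mean
#'   relative abundance across pool samples), all restricted to present ASVs.
#' @export
regional_pool <- function(table) {
  m <- unclass(table)
  present <- rowSums(m) > 0
  ra <- relative_abundances(m)
  list(asv_ids = rownames(m)[present],
       frequency = rowMeans(m[present, , drop = FALSE] > 0),
       abundance = rowMeans(ra[present, , drop = FALSE]))
}

#' Assemble one pair of null community samples
#'
#' Each null sample preserves the observed sample's richness and total read
#' count. ASV identities are drawn without replacement from the regional
#' pool with the configured probability weights; reads are then allocated
#' among the chosen ASVs by a multinomial draw proportional to regional
#' relative abundance, with every chosen ASV guaranteed at least one read.
#' Randomness is taken from the current RNG state.
#'
#' @param pool result of [regional_pool()].
#' @param richness,totals integer vectors of length 2: observed nonzero-ASV
#'   counts and read totals of the two samples.
#' @param weighting see [null_config()].
#' @return An integer matrix (pool ASVs x 2) of null counts.
#' @export
assemble_null_pair <- function(pool, richness, totals,
                               weighting = "frequency_x_abundance") {
  n_pool <- length(pool$asv_ids)
  if (any(richness > n_pool))
    stop("sample richness exceeds regional pool richness")
  if (any(richness < 1) || any(totals < richness))
    stop("each sample needs >= 1 ASV and >= richness reads")
  w <- switch(weighting,
              frequency = list(sel = pool$frequency, alloc = pool$frequency),
              abundance = list(sel = pool$abundance, alloc = pool$abundance),
              frequency_x_abundance = list(sel = pool$frequency,
                                           alloc = pool$abundance),
              stop("unknown weighting: ", weighting))
  out <- matrix(0L, n_pool, 2, dimnames = list(pool$asv_ids, NULL))
  for (s in 1:2) {
    chosen <- sample.int(n_pool, richness[s], prob = w$sel)
    alloc <- stats::rmultinom(1, totals[s] - richness[s],
                              prob = w$alloc[chosen])[, 1]
    out[chosen, s] <- 1L + alloc
  }
  out
}

#' Hill-based Raup-Crick standardized effect size for one sample pair
#'
#' The observed taxonomic dissimilarity of a pair is compared with a null
#' distribution of dissimilarities between randomly assembled sample pairs
#' that preserve each sample's richness and read total (999 randomizations
#' by default). The standardized effect size is
#' `(observed - null_mean) / null_sd`; values below -2 indicate the samples
#' share more taxa than expected by chance, above +2 fewer, and `|ses| < 2`
#' is read as stochastic turnover.
#'
#' @param table rarefied [community_table()].
#' @param pair character vector of two sample ids.
#' @param q diversity order.
#' @param config a [null_config()].
#' @param pool_samples sample ids forming the regional pool (default: all
#'   samples of `table`).
#' @param variant overlap transform, see [taxonomic_dissimilarity()].
#' @return One-row data frame (an SES record): `sample_a`, `sample_b`,
#'   `statistic`, `q`, `observed`, `null_mean`, `null_sd`, `ses`,
#'   `n_randomizations`, `significant`, `direction`, `degenerate`.
#' @export
raup_crick <- function(table, pair, q, config = null_config(),
                       pool_samples = NULL, variant = "local") {
  stopifnot(length(pair) == 2, all(pair %in% colnames(table)))
  m <- unclass(table)
  if (is.null(pool_samples)) pool_samples <- colnames(m)
  pool <- regional_pool(m[, pool_samples, drop = FALSE])
  pa <- m[, pair[1]]; pb <- m[, pair[2]]
  observed <- taxonomic_dissimilarity(pa / sum(pa), pb / sum(pb), q,
                                      variant = variant)
  richness <- c(sum(pa > 0), sum(pb > 0))
  totals <- c(sum(pa), sum(pb))
  nulls <- with_child_seed(config$seed, "raup_crick", pair[1], pair[2], q, code = {
    vapply(seq_len(config$n_randomizations), function(i) {
      nm <- assemble_null_pair(pool, richness, totals, config$weighting)
      taxonomic_dissimilarity(nm[, 1] / totals[1], nm[, 2] / totals[2], q,
                              variant = variant)
    }, numeric(1))
  })
  ses_record(pair, paste0("q", q, "RC"), q, observed, nulls, config)
}

#' Abundance-weighted beta mean nearest-taxon distance
#'
#' The mean phylogenetic distance between the most closely related ASVs of
#' two communities:
#' \deqn{\beta MNTD = \frac{1}{2}\left[\sum_i p_i^A \min_{j \in B} d_{ij}
#'   + \sum_j p_j^B \min_{i \in A} d_{ij}\right].}
#' ASVs present in both communities contribute a nearest-taxon distance of 0
#' (self-matches are allowed).
#'
#' @param abund_a,abund_b abundance vectors over the same ASV universe
#'   (named, or matching the distance matrix order).
#' @param distances symmetric patristic distance matrix covering the union
#'   of ASVs with positive abundance.
#' @return A nonnegative number.
#' @export
beta_mntd <- function(abund_a, abund_b, distances) {
  if (sum(abund_a) <= 0 || sum(abund_b) <= 0) stop("empty community")
  if (!is.matrix(distances)) distances <- as.matrix(distances)
  ia <- which(abund_a > 0); ib <- which(abund_b > 0)
  nm <- names(abund_a)
  if (!is.null(nm) && !is.null(rownames(distances))) {
    da <- distances[nm[ia], nm[ib], drop = FALSE]
  } else {
    da <- distances[ia, ib, drop = FALSE]
  }
  pa <- abund_a[ia] / sum(abund_a)
  pb <- abund_b[ib] / sum(abund_b)
  0.5 * (sum(pa * apply(da, 1, min)) + sum(pb * apply(da, 2, min)))
}

#' Beta nearest-taxon index for one sample pair
#'
#' The observed abundance-weighted [beta_mntd()] is compared with a null
#' distribution obtained by randomly shuffling ASV labels across the tips of
#' the regional-pool phylogeny (the same permutation applied to both
#' samples), 999 times by default. `ses < -2` means the two communities are
#' more phylogenetically close to each other than expected by chance;
#' `ses > 2` more distant. A null distribution with zero spread (e.g. all
#' tips equidistant) is flagged degenerate and reported not significant.
#'
#' @inheritParams raup_crick
#' @param distances patristic distance matrix covering the regional pool's
#'   ASVs (see [patristic_distances()]).
#' @return One-row SES data frame, as in [raup_crick()].
#' @export
beta_nti <- function(table, distances, pair, config = null_config(),
                     pool_samples = NULL) {
  stopifnot(length(pair) == 2, all(pair %in% colnames(table)))
  m <- unclass(table)
  if (is.null(pool_samples)) pool_samples <- colnames(m)
  pool_ids <- rownames(m)[rowSums(m[, pool_samples, drop = FALSE]) > 0]
  if (!is.matrix(distances)) distances <- as.matrix(distances)
  missing <- setdiff(pool_ids, rownames(distances))
  if (length(missing))
    stop("distance matrix lacks pool ASVs: ", paste(missing, collapse = ", "))
  d_pool <- unname(distances[pool_ids, pool_ids, drop = FALSE])
  a <- unname(m[pool_ids, pair[1]]); b <- unname(m[pool_ids, pair[2]])
  observed <- beta_mntd(a, b, d_pool)
  n_pool <- length(pool_ids)
  nulls <- with_child_seed(config$seed, "beta_nti", pair[1], pair[2], code = {
    vapply(seq_len(config$n_randomizations), function(i) {
      perm <- sample.int(n_pool)  # relabel tips within the regional pool
      beta_mntd(a, b, d_pool[perm, perm, drop = FALSE])
    }, numeric(1))
  })
  ses_record(pair, "betaNTI", NA_real_, observed, nulls, config)
}

#' Standardized effect sizes along a series of sample pairs
#'
#' Applies [raup_crick()] or [beta_nti()] to every pair of a comparison
#' series (see [build_series()]). Each pair uses a child seed derived from
#' the master seed and the pair ids, so results do not depend on the order
#' of the pairs.
#'
#' @param table rarefied [community_table()].
#' @param pairs data frame with columns `sample_a`, `sample_b` (extra
#'   columns such as `delta_days` are carried through).
#' @param statistic `"qRC"` or `"betaNTI"`.
#' @param q diversity order (qRC only).
#' @param distances patristic distances (betaNTI only).
#' @param config a [null_config()].
#' @param pool_samples optional regional-pool restriction.
#' @return Data frame of SES records, one row per pair.
#' @export
ses_series <- function(table, pairs, statistic = c("qRC", "betaNTI"),
                       q = 1, distances = NULL, config = null_config(),
                       pool_samples = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "betaNTI" && is.null(distances))
    stop("betaNTI needs a distance matrix")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- c(pairs$sample_a[i], pairs$sample_b[i])
    if (statistic == "qRC")
      raup_crick(table, pr, q, config, pool_samples = pool_samples)
    else
      beta_nti(table, distances, pr, config, pool_samples = pool_samples)
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(pairs), c("sample_a", "sample_b"))
  for (col in extra) out[[col]] <- pairs[[col]]
  out
}

# Build one SES record from observed value and null draws.
ses_record <- function(pair, statistic, q, observed, nulls, config) {
  mu <- mean(nulls); sd0 <- stats::sd(nulls)
  degenerate <- !is.finite(sd0) || sd0 < 1e-12
  ses <- if (degenerate) NA_real_ else (observed - mu) / sd0
  significant <- !degenerate && abs(ses) > config$threshold
  direction <- if (degenerate || abs(ses) <= config$threshold) "null"
               else if (ses < 0) "less_than_chance" else "greater_than_chance"
  data.frame(sample_a = pair[1], sample_b = pair[2], statistic = statistic,
             q = q, observed = observed, null_mean = mu, null_sd = sd0,
             ses = ses, n_randomizations = config$n_randomizations,
             significant = significant, direction = direction,
             degenerate = degenerate, stringsAsFactors = FALSE)
}
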