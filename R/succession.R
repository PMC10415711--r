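#' Build a comparison series from sample metadata
#'
#' Three series mirror the standard successional comparisons:
#' `"successive"` pairs adjacent time points within one reactor,
#' `"between_reactor"` pairs equal days across two reactors, and
#' `"vs_inoculum"` pairs every time point with the inoculum sample.
#' The result is a pure function of the metadata (no randomness).
#'
#' @param metadata data frame with `sample_id`, `reactor`, `day`, `role`.
#' @param kind one of `"successive"`, `"between_reactor"`, `"vs_inoculum"`.
#' @param reactor reactor label (required for `"successive"`); for
#'   `"between_reactor"`, a length-2 vector of reactor labels (defaults to
#'   the two reactors with timepoint samples).
#' @return Data frame with columns `sample_a`, `sample_b`, `delta_days` (and
#'   `day` for between-reactor pairs), ordered by day.
#' @export
build_series <- function(metadata,
                         kind = c("successive", "between_reactor", "vs_inoculum"),
                         reactor = NULL) {
  kind <- match.arg(kind)
  md <- validate_metadata(metadata)
  tp <- md[md$role == "timepoint", ]
  if (kind == "successive") {
    if (is.null(reactor)) stop("successive series needs a reactor label")
    r <- tp[tp$reactor == reactor, ]
    r <- r[order(r$day), ]
    if (nrow(r) < 2) stop("fewer than 2 time points for reactor ", reactor)
    data.frame(sample_a = r$sample_id[-nrow(r)], sample_b = r$sample_id[-1],
               delta_days = diff(r$day), stringsAsFactors = FALSE)
  } else if (kind == "between_reactor") {
    if (is.null(reactor)) {
      reactor <- sort(unique(tp$reactor))
      if (length(reactor) != 2)
        stop("specify the two reactors to compare; found: ",
             paste(reactor, collapse = ", "))
    }
    a <- tp[tp$reactor == reactor[1], ]
    b <- tp[tp$reactor == reactor[2], ]
    days <- sort(intersect(a$day, b$day))
    if (!length(days)) stop("no shared sampling days between reactors")
    data.frame(sample_a = a$sample_id[match(days, a$day)],
               sample_b = b$sample_id[match(days, b$day)],
               day = days, delta_days = 0, stringsAsFactors = FALSE)
  } else {
    inoc <- md[md$role == "inoculum", ]
    if (nrow(inoc) != 1) stop("need exactly one inoculum sample, found ", nrow(inoc))
    if (!is.null(reactor)) tp <- tp[tp$reactor %in% reactor, ]
    tp <- tp[order(tp$reactor, tp$day), ]
    data.frame(sample_a = rep(inoc$sample_id, nrow(tp)), sample_b = tp$sample_id,
               delta_days = tp$day, stringsAsFactors = FALSE)
  }
}

#' Time-decay rate of community similarity
#'
#' Dissimilarities are converted to similarities (`s = 1 - d`) and the
#' natural log of similarity is regressed on the time difference between
#' samples by ordinary least squares, over all within-reactor pairs with
#' `delta_days > 0`. The slope is the per-day decay rate of log similarity;
#' pairs with `s <= 0` cannot be log-transformed and are dropped (counted in
#' `n_dropped`).
#'
#' @param dissim long dissimilarity table (from [dissimilarity_matrix()]),
#'   restricted internally to one `q` and `kind`.
#' @param metadata sample metadata.
#' @param reactor reactor label whose samples enter the fit.
#' @param q,kind which dissimilarity records to use.
#' @param day_range optional `c(min, max)` day window (inclusive) for the
#'   samples entering the fit, e.g. one disturbance period.
#' @return One-row data frame: `reactor`, `q`, `kind`, `slope`, `intercept`,
#'   `p_value`, `r_squared`, `n_pairs`, `n_dropped`.
#' @export
time_decay_rate <- function(dissim, metadata, reactor, q = 1,
                            kind = "taxonomic", day_range = NULL) {
  md <- validate_metadata(metadata)
  md <- md[md$role == "timepoint" & md$reactor == reactor, ]
  if (!is.null(day_range))
    md <- md[md$day >= day_range[1] & md$day <= day_range[2], ]
  day <- stats::setNames(md$day, md$sample_id)
  rec <- dissim[dissim$q == q & dissim$kind == kind &
                  dissim$sample_a %in% md$sample_id &
                  dissim$sample_b %in% md$sample_id, ]
  dt <- abs(day[rec$sample_a] - day[rec$sample_b])
  rec <- rec[dt > 0, ]; dt <- dt[dt > 0]
  s <- 1 - rec$value
  usable <- s > 0
  n_dropped <- sum(!usable)
  if (sum(usable) < 2) stop("fewer than 2 usable pairs for the time-decay fit")
  fit <- stats::lm(log(s[usable]) ~ dt[usable])
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  p_value <- unname(sm$coefficients[2, 4])
  # zero-residual fits: an exact line (p = 0) or an exact constant (p = 1)
  if (!is.finite(p_value) ||
      sm$sigma < 1e-12 * (1 + mean(abs(log(s[usable]))))) {
    p_value <- if (abs(slope) > 1e-12) 0 else 1
  }
  data.frame(reactor = reactor, q = q, kind = kind,
             slope = slope,
             intercept = unname(stats::coef(fit)[1]),
             p_value = p_value,
             r_squared = sm$r.squared,
             n_pairs = sum(usable), n_dropped = n_dropped,
             stringsAsFactors = FALSE)
}

#' Permutational multivariate analysis of variance on a dissimilarity matrix
#'
#' A thin wrapper around [vegan::adonis2()]: the pseudo-F statistic from the
#' Gower-centred partitioning of among- and within-group sums of squared
#' dissimilarities, with a permutation p-value
#' `(#\{F_perm >= F_obs\} + 1) / (n_permutations + 1)`.
#'
#' @param dissim square symmetric dissimilarity matrix with sample dimnames
#'   (see [as_dissimilarity_matrix()]).
#' @param groups factor or character vector of group labels, aligned with
#'   the matrix rows (or named by sample id).
#' @param n_permutations number of random relabelings (default 999).
#' @param seed seed for the permutations.
#' @return One-row data frame: `grouping`, `pseudo_F`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(dissim, groups, n_permutations = 999, seed = 1) {
  dissim <- as.matrix(dissim)
  if (max(abs(dissim - t(dissim))) > 1e-9) stop("dissimilarity matrix not symmetric")
  if (!is.null(names(groups)) && !is.null(rownames(dissim)))
    groups <- groups[rownames(dissim)]
  groups <- as.factor(groups)
  if (length(groups) != nrow(dissim)) stop("groups do not match matrix rows")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("singleton group")
  df <- data.frame(groups = groups)
  res <- withr::with_seed(as.integer(seed),
    vegan::adonis2(stats::as.dist(dissim) ~ groups, data = df,
                   permutations = n_permutations))
  data.frame(grouping = paste(levels(groups), collapse = " vs "),
             pseudo_F = res$F[1], p_value = res$`Pr(>F)`[1],
             n_permutations = as.integer(n_permutations),
             stringsAsFactors = FALSE)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' @inheritParams permanova
#' @param adjust p-value adjustment method (`"none"` by default;
#'   `"BH"` for Benjamini-Hochberg).
#' @return Data frame with one row per group pair (`group_a`, `group_b`,
#'   `pseudo_F`, `p_value`, `p_adjusted`, `n_permutations`).
#' @export
pairwise_permanova <- function(dissim, groups, n_permutations = 999, seed = 1,
                               adjust = "none") {
  dissim <- as.matrix(dissim)
  if (!is.null(names(groups)) && !is.null(rownames(dissim)))
    groups <- groups[rownames(dissim)]
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    keep <- groups %in% pairs[, j]
    r <- permanova(dissim[keep, keep, drop = FALSE], groups[keep],
                   n_permutations, seed = child_seed(seed, "permanova", j))
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               pseudo_F = r$pseudo_F, p_value = r$p_value,
               n_permutations = r$n_permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}
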