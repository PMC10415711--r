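#' Hill-number taxonomic alpha-diversity
#'
#' The Hill number of order `q` is the effective number of ASVs,
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)},}
#' with the analytic limit \eqn{\exp(-\sum_i p_i \log p_i)} at `q = 1`.
#' `q = 0` is richness, `q = 1` weights ASVs by abundance ("common" ASVs),
#' `q = 2` emphasises dominant ASVs ("abundant" ASVs, inverse Simpson).
#'
#' @param abundances nonnegative abundance vector (normalised internally).
#' @param q diversity order, a single finite number >= 0.
#' @return The effective number of ASVs (>= 1 for any non-empty sample).
#' @export
#' @examples
#' taxonomic_alpha(c(0.25, 0.25, 0.25, 0.25), q = 0)  # 4
#' taxonomic_alpha(c(0.8, 0.2), q = 1)                # exp(Shannon)
taxonomic_alpha <- function(abundances, q) {
  p <- check_abundances(abundances)
  check_order(q)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Distance-based (phylogenetic) alpha-diversity, total effective distance
#'
#' Computes the attribute-diversity of a sample given pairwise distances
#' between its ASVs. With Rao's quadratic entropy
#' \eqn{Q = \sum_{i,j} d_{ij} p_i p_j}, the Hill number of the
#' distance-weighted pair distribution is
#' \deqn{{}^qD(Q) = \left(\sum_{i,j} \frac{d_{ij}}{Q}(p_i p_j)^q\right)^{1/(2(1-q))}}
#' and the total effective distance between ASVs is
#' \deqn{{}^qPD = ({}^qD(Q))^2 \cdot Q.}
#' For `S` equally abundant, mutually equidistant ASVs at distance `d` this
#' equals `d * S * (S - 1)` for every `q`. A single-ASV sample has `Q = 0`
#' and, by convention, `qPD = 0`.
#'
#' @inheritParams taxonomic_alpha
#' @param distances symmetric distance matrix covering (at least) all ASVs
#'   with positive abundance; dimnames must match `names(abundances)` when
#'   both are named.
#' @return Total effective distance (a nonnegative number).
#' @export
phylo_alpha <- function(abundances, distances, q) {
  if (!is.numeric(abundances) || anyNA(abundances) || any(abundances < 0))
    stop("abundances must be nonnegative numbers")
  check_order(q)
  keep <- abundances > 0
  if (!any(keep)) stop("empty sample: all abundances are zero")
  if (!is.matrix(distances)) distances <- as.matrix(distances)
  if (is.null(names(abundances)) && nrow(distances) == length(abundances))
    distances <- distances[keep, keep, drop = FALSE]
  p <- abundances[keep] / sum(abundances[keep])
  d <- align_distances(distances, names(p), length(p))
  Q <- as.numeric(t(p) %*% d %*% p)
  if (Q <= 0) return(0)
  a <- d / Q
  if (q == 1) {
    pp <- outer(p, p)
    lg <- ifelse(pp > 0, log(pp), 0)
    return(exp(-0.5 * sum(a * pp * lg))^2 * Q)
  }
  s <- sum(a * outer(p, p)^q)
  (s^(1 / (2 * (1 - q))))^2 * Q
}

#' Pairwise taxonomic dissimilarity from Hill-number beta-diversity
#'
#' Gamma diversity of the evenly pooled pair is divided by the mean alpha
#' (equal sample weights), giving a multiplicative beta in `[1, 2]`, which is
#' then mapped to `[0, 1]` by an overlap transform: the local (Sorensen-type)
#' variant \eqn{1 - C_{qN}} by default or the regional (Jaccard-type)
#' \eqn{1 - U_{qN}}. Identical samples give 0; samples sharing no ASVs give 1.
#' At `q = 1` both variants reduce to \eqn{\log\beta / \log 2}.
#'
#' @param abund_a,abund_b abundance vectors over the same ASV universe.
#' @param q diversity order.
#' @param variant `"local"` (default) or `"regional"` overlap transform.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' taxonomic_dissimilarity(c(1, 1, 0), c(0, 1, 1), q = 0)  # 0.5
taxonomic_dissimilarity <- function(abund_a, abund_b, q,
                                    variant = c("local", "regional")) {
  variant <- match.arg(variant)
  check_order(q)
  ab <- pair_support(abund_a, abund_b)
  z <- ab / 2  # equal sample weights; columns sum to 1/2
  gamma <- taxonomic_alpha(rowSums(z), q)
  if (q == 1) {
    lz <- ifelse(z > 0, log(z), 0)
    alpha <- 0.5 * exp(-sum(z * lz))
  } else if (q == 0) {
    alpha <- 0.5 * sum(z > 0)
  } else {
    alpha <- 0.5 * sum(z^q)^(1 / (1 - q))
  }
  beta_to_dissimilarity(gamma / alpha, q, N = 2, variant = variant,
                        pair_exponent = 1)
}

#' Pairwise phylogenetic (distance-based) dissimilarity
#'
#' Beta-diversity of the total effective distance: with equal sample weights,
#' the gamma and alpha attribute-diversities \eqn{{}^qD(Q)} are computed on
#' the pooled pair (both normalised by the pooled quadratic entropy `Q`), and
#' \eqn{\beta = ({}^qD_\gamma / {}^qD_\alpha)^2 \in [1, 4]} is mapped to
#' `[0, 1]` with the overlap transform in which the number of assemblages
#' enters squared. Identical samples give 0, samples sharing no ASVs give 1.
#' A pooled pair with `Q = 0` (e.g. twice the same single ASV) is defined to
#' have dissimilarity 0.
#'
#' @inheritParams taxonomic_dissimilarity
#' @param distances symmetric distance matrix covering the union of ASVs
#'   with positive abundance in either sample.
#' @return Dissimilarity in `[0, 1]`.
#' @export
phylo_dissimilarity <- function(abund_a, abund_b, distances, q,
                                variant = c("local", "regional")) {
  variant <- match.arg(variant)
  check_order(q)
  ab <- pair_support(abund_a, abund_b)
  if (!is.matrix(distances)) distances <- as.matrix(distances)
  if (is.null(rownames(ab)) && nrow(distances) == length(abund_a))
    distances <- distances[attr(ab, "keep"), attr(ab, "keep"), drop = FALSE]
  d <- align_distances(distances, rownames(ab), nrow(ab))
  z <- ab / 2
  pplus <- rowSums(z)
  Q <- as.numeric(t(pplus) %*% d %*% pplus)
  if (Q <= 0) return(0)
  a <- d / Q
  if (q == 1) {
    pp <- outer(pplus, pplus)
    lg <- ifelse(pp > 0, log(pp), 0)
    d_gamma <- exp(-0.5 * sum(a * pp * lg))
    # sum_{k,m} z_ik z_jm log(z_ik z_jm) factorises through row sums
    v <- rowSums(ifelse(z > 0, z * log(z), 0))
    d_alpha <- 0.5 * exp(-0.5 * sum(a * (outer(v, pplus) + outer(pplus, v))))
  } else {
    e <- 1 / (2 * (1 - q))
    d_gamma <- sum(a * outer(pplus, pplus)^q)^e
    u <- rowSums(pow0(z, q))  # sum_k z_ik^q with 0^0 := 0
    d_alpha <- 0.5 * sum(a * outer(u, u))^e
  }
  beta_to_dissimilarity((d_gamma / d_alpha)^2, q, N = 2, variant = variant,
                        pair_exponent = 2)
}

#' Convert a multiplicative beta-diversity to a [0, 1] dissimilarity
#'
#' @param beta multiplicative beta (`gamma / alpha`), in `[1, N]` for
#'   taxonomic or `[1, N^2]` for distance-based diversity.
#' @param q diversity order.
#' @param N number of assemblages (2 for pairwise use).
#' @param variant local (`1 - C_qN`) or regional (`1 - U_qN`).
#' @param pair_exponent 1 for taxonomic, 2 for distance-based beta (whose
#'   maximum is `N^2`).
#' @return Dissimilarity in `[0, 1]`.
#' @export
beta_to_dissimilarity <- function(beta, q, N = 2,
                                  variant = c("local", "regional"),
                                  pair_exponent = 1) {
  variant <- match.arg(variant)
  M <- N^pair_exponent
  beta <- min(max(beta, 1), M)  # guard rounding outside the theoretical range
  if (q == 1) return(log(beta) / log(M))
  e <- if (variant == "local") 1 - q else q - 1
  val <- (1 - beta^e) / (1 - M^e)
  min(max(val, 0), 1)
}

#' All pairwise dissimilarities of a community table
#'
#' @param table a [community_table()] (normally rarefied to even depth).
#' @param q diversity order(s).
#' @param kind `"taxonomic"` or `"phylogenetic"`.
#' @param distances required for `kind = "phylogenetic"`: distance matrix
#'   covering all ASVs of the table (see [patristic_distances()]).
#' @param variant overlap transform, see [taxonomic_dissimilarity()].
#' @return A long data frame with columns `sample_a`, `sample_b`, `q`,
#'   `kind`, `value`, one row per unordered sample pair and order.
#' @export
dissimilarity_matrix <- function(table, q = c(0, 1, 2),
                                 kind = c("taxonomic", "phylogenetic"),
                                 distances = NULL,
                                 variant = c("local", "regional")) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (kind == "phylogenetic" && is.null(distances))
    stop("phylogenetic dissimilarity needs a distance matrix")
  p <- relative_abundances(table)
  ids <- colnames(p)
  pairs <- utils::combn(length(ids), 2)
  out <- vector("list", length(q))
  for (k in seq_along(q)) {
    vals <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      ia <- pairs[1, j]; ib <- pairs[2, j]
      vals[j] <- if (kind == "taxonomic")
        taxonomic_dissimilarity(p[, ia], p[, ib], q[k], variant = variant)
      else
        phylo_dissimilarity(p[, ia], p[, ib], distances, q[k], variant = variant)
    }
    out[[k]] <- data.frame(sample_a = ids[pairs[1, ]], sample_b = ids[pairs[2, ]],
                           q = q[k], kind = kind, value = vals,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-sample alpha-diversity table
#'
#' @param table a [community_table()].
#' @param q diversity orders.
#' @param distances optional distance matrix; when supplied, the total
#'   effective distance `qPD` is reported alongside `qTD`.
#' @return Data frame with columns `sample_id`, `q`, `qTD` and (optionally)
#'   `qPD`.
#' @export
alpha_table <- function(table, q = c(0, 1, 2), distances = NULL) {
  p <- relative_abundances(table)
  grid <- expand.grid(sample_id = colnames(p), q = q,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$qTD <- mapply(function(s, qq) taxonomic_alpha(p[, s], qq),
                     grid$sample_id, grid$q)
  if (!is.null(distances))
    grid$qPD <- mapply(function(s, qq) phylo_alpha(p[, s], distances, qq),
                       grid$sample_id, grid$q)
  grid[order(grid$sample_id, grid$q), ]
}

#' Convert a long dissimilarity table to a square matrix
#'
#' @param dissim data frame from [dissimilarity_matrix()], restricted to one
#'   `q` and one `kind`.
#' @return Symmetric matrix with zero diagonal.
#' @export
as_dissimilarity_matrix <- function(dissim) {
  if (length(unique(dissim$q)) > 1 || length(unique(dissim$kind)) > 1)
    stop("restrict to a single q and kind first")
  ids <- unique(c(dissim$sample_a, dissim$sample_b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(dissim$sample_a, dissim$sample_b)] <- dissim$value
  m[cbind(dissim$sample_b, dissim$sample_a)] <- dissim$value
  m
}

# --- internal helpers -------------------------------------------------------

check_order <- function(q) {
  if (length(q) != 1 || !is.finite(q) || q < 0)
    stop("diversity order q must be a single finite number >= 0")
  invisible(q)
}

check_abundances <- function(p, keep_names = FALSE) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0))
    stop("abundances must be nonnegative numbers")
  keep <- p > 0
  if (!any(keep)) stop("empty sample: all abundances are zero")
  p <- p[keep]
  out <- p / sum(p)
  if (!keep_names) names(out) <- NULL
  out
}

# restrict two abundance vectors to their joint support, normalised columns
pair_support <- function(a, b) {
  if (length(a) != length(b))
    stop("abundance vectors must be over the same ASV universe")
  nm <- names(a)
  if (!is.null(nm) && !is.null(names(b)) && !identical(nm, names(b)))
    stop("abundance vectors have mismatched ASV names")
  if (sum(a) <= 0 || sum(b) <= 0) stop("empty sample in pair")
  keep <- a > 0 | b > 0
  m <- cbind(a = a[keep] / sum(a), b = b[keep] / sum(b))
  rownames(m) <- nm[keep]
  attr(m, "keep") <- keep
  m
}

align_distances <- function(distances, ids, n) {
  if (!is.matrix(distances)) distances <- as.matrix(distances)
  if (!is.null(ids) && !is.null(rownames(distances))) {
    missing <- setdiff(ids, rownames(distances))
    if (length(missing))
      stop("distance matrix lacks ids: ", paste(missing, collapse = ", "))
    d <- distances[ids, ids, drop = FALSE]
  } else {
    if (nrow(distances) != n)
      stop("distance matrix dimension does not match abundances")
    d <- distances
  }
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  diag(d) <- 0
  d
}

pow0 <- function(x, q) {
  if (q == 0) return((x > 0) * 1)
  x^q
}
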