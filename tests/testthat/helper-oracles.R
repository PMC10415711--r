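# Independent brute-force oracles, deliberately written as literal formula
# evaluations (explicit loops, no shared code with the package internals).

# Hill number by direct formula evaluation.
oracle_hill <- function(p, q) {
  p <- unname(p[p > 0] / sum(p[p > 0]))
  if (q == 1) return(exp(-sum(p * log(p))))
  if (q == 0) return(length(p))
  sum(p^q)^(1 / (1 - q))
}

# Total effective distance by naive double sums.
oracle_qpd <- function(p, d, q) {
  keep <- p > 0
  p <- unname(p[keep] / sum(p[keep]))
  d <- d[keep, keep, drop = FALSE]
  S <- length(p)
  Q <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) Q <- Q + d[i, j] * p[i] * p[j]
  if (Q == 0) return(0)
  acc <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (d[i, j] > 0) {
      acc <- acc + if (q == 1) (d[i, j] / Q) * p[i] * p[j] * log(p[i] * p[j])
                   else (d[i, j] / Q) * (p[i] * p[j])^q
    }
  }
  dq <- if (q == 1) exp(-0.5 * acc) else acc^(1 / (2 * (1 - q)))
  dq^2 * Q
}

# Pairwise taxonomic dissimilarity (local overlap) by literal evaluation.
oracle_tax_dissim <- function(pa, pb, q) {
  pa <- unname(pa / sum(pa)); pb <- unname(pb / sum(pb))
  z <- cbind(pa, pb) / 2
  gamma <- oracle_hill(rowSums(z), q)
  zv <- z[z > 0]
  alpha <- if (q == 1) 0.5 * exp(-sum(zv * log(zv)))
           else if (q == 0) 0.5 * length(zv)
           else 0.5 * sum(zv^q)^(1 / (1 - q))
  beta <- gamma / alpha
  unname(if (q == 1) log(beta) / log(2) else (1 - beta^(1 - q)) / (1 - 2^(1 - q)))
}

# Pairwise functional dissimilarity by literal four-index sums.
oracle_phylo_dissim <- function(pa, pb, d, q) {
  keep <- pa > 0 | pb > 0
  pa <- unname(pa[keep] / sum(pa)); pb <- unname(pb[keep] / sum(pb))
  d <- d[keep, keep, drop = FALSE]
  z <- cbind(pa, pb) / 2
  S <- nrow(z)
  pp <- rowSums(z)
  Q <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) Q <- Q + d[i, j] * pp[i] * pp[j]
  if (Q == 0) return(0)
  sg <- 0; sa <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (d[i, j] == 0) next
    if (q == 1) {
      if (pp[i] * pp[j] > 0)
        sg <- sg + (d[i, j] / Q) * pp[i] * pp[j] * log(pp[i] * pp[j])
      for (k in 1:2) for (m in 1:2)
        if (z[i, k] * z[j, m] > 0)
          sa <- sa + (d[i, j] / Q) * z[i, k] * z[j, m] * log(z[i, k] * z[j, m])
    } else {
      if (pp[i] * pp[j] > 0) sg <- sg + (d[i, j] / Q) * (pp[i] * pp[j])^q
      for (k in 1:2) for (m in 1:2)
        if (z[i, k] * z[j, m] > 0) sa <- sa + (d[i, j] / Q) * (z[i, k] * z[j, m])^q
    }
  }
  if (q == 1) { dg <- exp(-0.5 * sg); da <- 0.5 * exp(-0.5 * sa) }
  else { e <- 1 / (2 * (1 - q)); dg <- sg^e; da <- 0.5 * sa^e }
  beta <- (dg / da)^2
  unname(if (q == 1) log(beta) / log(4) else (1 - beta^(1 - q)) / (1 - 4^(1 - q)))
}

# betaMNTD by naive double loop over the supports.
oracle_beta_mntd <- function(pa, pb, d) {
  pa <- unname(pa / sum(pa)); pb <- unname(pb / sum(pb))
  ia <- which(pa > 0); ib <- which(pb > 0)
  s1 <- 0
  for (i in ia) {
    best <- Inf
    for (j in ib) if (d[i, j] < best) best <- d[i, j]
    s1 <- s1 + pa[i] * best
  }
  s2 <- 0
  for (j in ib) {
    best <- Inf
    for (i in ia) if (d[i, j] < best) best <- d[i, j]
    s2 <- s2 + pb[j] * best
  }
  0.5 * (s1 + s2)
}

# Patristic distance by explicit path enumeration via node paths.
oracle_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  tot <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1] |
                 tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k])
    tot <- tot + tree$edge.length[e]
  }
  tot
}

# Random community pair over a shared ASV universe.
random_pair <- function(S, zero_frac = 0.2) {
  pa <- rgamma(S, 1); pb <- rgamma(S, 1)
  nz <- rbinom(S, 1, zero_frac) == 1
  pa[nz & runif(S) < 0.5] <- 0
  pb[nz & runif(S) >= 0.5] <- 0
  if (all(pa == 0)) pa[1] <- 1
  if (all(pb == 0)) pb[1] <- 1
  list(a = pa, b = pb)
}
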