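#' Construct and validate a community table
#'
#' A community table is a nonnegative integer matrix of read counts with
#' ASVs as rows and samples as columns. It is the universe on which all
#' diversity statistics in the package are computed.
#'
#' @param counts numeric matrix of nonnegative integers with unique rownames
#'   (ASV ids) and unique colnames (sample ids).
#' @return An integer matrix of class `community_table`.
#' @export
#' @examples
#' m <- matrix(c(5L, 5L, 0L, 0L, 5L, 5L), nrow = 3,
#'             dimnames = list(paste0("ASV_", 1:3), c("s1", "s2")))
#' community_table(m)
community_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("community table needs ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0))
    stop("negative count at ",
         paste(which(counts < 0, arr.ind = TRUE)[1, ], collapse = ","))
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("non-integer count found")
  if (ncol(counts) == 0 || nrow(counts) == 0) stop("empty community table")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("samples with zero total reads: ",
         paste(colnames(counts)[zero], collapse = ", "))
  storage.mode(counts) <- "integer"
  class(counts) <- c("community_table", "matrix", "array")
  counts
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x), "ASVs x", ncol(x), "samples;",
      "depth range", paste(range(colSums(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Read an ASV count table from a tab-separated file
#'
#' The expected layout is one ASV per row: first column holds the ASV id,
#' the header row holds the sample ids. With `orientation = "auto"` and a
#' metadata table the reader transposes the matrix if the row labels, rather
#' than the column labels, match the metadata sample ids.
#'
#' @param path path to a TSV file.
#' @param orientation `"columns"` (samples in columns, default), `"rows"`,
#'   or `"auto"` (requires `metadata`).
#' @param metadata optional metadata data frame (see [read_metadata()]) used
#'   for orientation detection.
#' @return A [community_table()].
#' @export
read_counts <- function(path, orientation = c("columns", "rows", "auto"),
                        metadata = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty or malformed count table: ", path)
  ids <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v))
      stop("non-numeric cell in column '", names(body)[j], "'")
    if (any(abs(v - round(v)) > 1e-9))
      stop("non-integer count in column '", names(body)[j], "', row ",
           which(abs(v - round(v)) > 1e-9)[1])
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "auto") {
    if (is.null(metadata)) stop("orientation = 'auto' requires metadata")
    col_hits <- mean(colnames(m) %in% metadata$sample_id)
    row_hits <- mean(rownames(m) %in% metadata$sample_id)
    if (row_hits > col_hits) m <- t(m)
  } else if (orientation == "rows") {
    m <- t(m)
  }
  community_table(m)
}

#' Write a community table as TSV
#'
#' @param table a [community_table()].
#' @param path output path.
#' @param id_column header name of the ASV id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path, id_column = "asv_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `reactor`, `day` and an
#' optional `role` column (`"inoculum"` or `"timepoint"`; defaults to
#' `"timepoint"` when absent).
#'
#' @param path path to a TSV file.
#' @param require_inoculum if `TRUE`, exactly one inoculum row is required.
#' @return A data frame with columns `sample_id`, `reactor`, `day`, `role`.
#' @export
read_metadata <- function(path, require_inoculum = FALSE) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  validate_metadata(md, require_inoculum = require_inoculum)
}

#' Validate a metadata data frame
#'
#' @param md data frame with at least `sample_id`, `reactor`, `day`.
#' @inheritParams read_metadata
#' @return The validated data frame (with `role` filled in).
#' @export
validate_metadata <- function(md, require_inoculum = FALSE) {
  need <- c("sample_id", "reactor", "day")
  miss <- setdiff(need, names(md))
  if (nrow(md) == 0) stop("empty metadata table")
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$reactor <- as.character(md$reactor)
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  if (!is.numeric(md$day) || anyNA(md$day) || any(md$day < 0))
    stop("day must be a nonnegative number")
  if (is.null(md$role)) md$role <- "timepoint"
  md$role[is.na(md$role) | md$role == ""] <- "timepoint"
  bad <- setdiff(unique(md$role), c("inoculum", "timepoint"))
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "))
  n_inoc <- sum(md$role == "inoculum")
  if (require_inoculum && n_inoc != 1)
    stop("expected exactly one inoculum sample, found ", n_inoc)
  md[c("sample_id", "reactor", "day", "role")]
}

#' Write sample metadata as TSV
#'
#' @param metadata data frame as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that every sample of a count table is described by the metadata
#'
#' @param table a [community_table()].
#' @param metadata metadata data frame.
#' @return `TRUE`, invisibly; errors listing offending ids otherwise.
#' @export
check_samples_covered <- function(table, metadata) {
  missing <- setdiff(colnames(table), metadata$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a rooted phylogenetic tree in Newick format
#'
#' @param path path to a Newick file.
#' @param require_tips optional character vector of ASV ids that must be
#'   present as tips; missing ids raise an error listing them.
#' @param negative_lengths how to treat negative branch lengths (which some
#'   tree builders emit): `"clamp"` sets them to zero with a warning,
#'   `"error"` rejects the tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, require_tips = NULL,
                        negative_lengths = c("clamp", "error")) {
  negative_lengths <- match.arg(negative_lengths)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick file ", path)
  validate_tree(tree, require_tips = require_tips,
                negative_lengths = negative_lengths)
}

#' Validate a phylo object for use in diversity computations
#'
#' @param tree an [ape] `phylo` object with branch lengths.
#' @inheritParams read_newick
#' @return The (possibly clamped) tree.
#' @export
validate_tree <- function(tree, require_tips = NULL,
                          negative_lengths = c("clamp", "error")) {
  negative_lengths <- match.arg(negative_lengths)
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  if (any(tree$edge.length < 0)) {
    if (negative_lengths == "error") stop("negative branch length in tree")
    warning("negative branch lengths clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (!is.null(require_tips)) {
    missing <- setdiff(require_tips, tree$tip.label)
    if (length(missing))
      stop("tips missing from tree: ", paste(missing, collapse = ", "))
  }
  tree
}

#' Patristic distances between tips of a tree
#'
#' The patristic distance between two tips is the sum of branch lengths on
#' the path connecting them. These distances underlie the distance-based
#' diversity (`qPD`) and the nearest-taxon statistics.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param ids optional subset (and ordering) of tip labels.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
patristic_distances <- function(tree, ids = NULL) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(ids)) {
    missing <- setdiff(ids, rownames(d))
    if (length(missing))
      stop("ids not in tree: ", paste(missing, collapse = ", "))
    d <- d[ids, ids, drop = FALSE]
  }
  diag(d) <- 0
  d
}

#' Rarefy a community table to even depth
#'
#' Each sample is subsampled *without replacement* to exactly `depth` reads
#' (a draw from the multivariate hypergeometric distribution on its counts).
#' Samples with fewer than `depth` total reads are dropped with a warning.
#' Each sample's draw uses a child seed derived from `seed` and the sample
#' id, so the result does not depend on sample order.
#'
#' @param table a [community_table()].
#' @param depth target reads per sample (default 70492).
#' @param seed master seed.
#' @return A rarefied [community_table()] whose column sums all equal `depth`.
#' @export
rarefy <- function(table, depth = 70492, seed = 1) {
  stopifnot(inherits(table, "community_table"))
  if (length(depth) != 1 || !is.finite(depth) || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(round(depth))
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample has at least ", depth, " reads")
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) with fewer than ", depth,
            " reads: ", paste(colnames(table)[!keep], collapse = ", "))
  out <- matrix(0L, nrow(table), sum(keep),
                dimnames = list(rownames(table), colnames(table)[keep]))
  for (j in seq_len(ncol(out))) {
    sid <- colnames(out)[j]
    col <- table[, sid]
    if (totals[sid] == depth) {
      out[, j] <- col
    } else {
      out[, j] <- with_child_seed(seed, "rarefy", sid, code =
        draw_without_replacement(col, depth))
    }
  }
  community_table(out)
}

#' Relative abundances of a community table
#'
#' @param table a [community_table()] or count matrix with positive column sums.
#' @return A numeric matrix whose columns sum to 1.
#' @export
relative_abundances <- function(table) {
  m <- unclass(table)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("all-zero sample")
  sweep(m, 2, tot, "/")
}
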