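#' Derive a child seed from a master seed and a tag
#'
#' All stochastic operations in the package draw their randomness from a
#' child seed derived from a single master seed and a short tag naming the
#' operation (and, where relevant, the sample or pair index). Results are
#' therefore independent of the order in which stages run.
#'
#' @param master integer master seed.
#' @param ... character or numeric components identifying the operation,
#'   e.g. `child_seed(1, "rarefy", 3)`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, "rarefy", 1)
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  tag <- paste(vapply(list(...), function(x) paste(format(x), collapse = "_"),
                      character(1)), collapse = ":")
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.double(master) %% m)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a child seed, restoring the RNG state
#'
#' @param master,... passed to [child_seed()].
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_child_seed <- function(master, ..., code) {
  withr::with_seed(child_seed(master, ...), code)
}
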