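#' Sample partitions
#'
#' Discretizing a genomic feature over a cohort induces a partition of the
#' sample set: one block per observed code value.  All entropy and mutual
#' information in this package is computed from block sizes of such
#' partitions (and their cell-wise intersections), in bits.
#'
#' @param codes integer (or factor/character) vector of per-sample codes.
#'   One block is created per distinct value; empty blocks cannot arise.
#' @return An object of class `sample_partition` with fields `blocks`
#'   (list of disjoint sample-index vectors) and `n_samples`.
#' @examples
#' p <- partition_from_codes(c(0, 0, 1, 1))
#' entropy(p)  # 1 bit: two equal blocks
#' @export
partition_from_codes <- function(codes) {
  if (length(codes) == 0L) stop("cannot partition an empty sample set")
  if (anyNA(codes)) stop("codes contain missing values")
  blocks <- split(seq_along(codes), factor(codes))
  structure(list(blocks = unname(blocks), n_samples = length(codes)),
            class = "sample_partition")
}

#' @export
print.sample_partition <- function(x, ...) {
  cat(sprintf("<sample_partition: %d blocks over %d samples>\n",
              length(x$blocks), x$n_samples))
  invisible(x)
}

as_partition <- function(x) {
  if (inherits(x, "sample_partition")) x else partition_from_codes(x)
}

# membership codes 1..k; validates that blocks are disjoint and cover 1..n
.partition_codes <- function(p) {
  n <- p$n_samples
  codes <- integer(n)
  for (b in seq_along(p$blocks)) {
    idx <- p$blocks[[b]]
    if (any(idx < 1L | idx > n)) stop("partition block index out of range")
    if (any(codes[idx] != 0L)) stop("partition blocks are not disjoint")
    codes[idx] <- b
  }
  if (any(codes == 0L)) stop("partition blocks do not cover all samples")
  codes
}

# entropy in bits from block counts; 0 * log 0 := 0 (zero counts dropped)
.ent_counts <- function(counts, n) {
  pr <- counts[counts > 0] / n
  -sum(pr * log2(pr))
}

#' Entropy of a sample partition
#'
#' Shannon entropy \eqn{H(X) = -\sum_i |A_i|/|S| \log_2 |A_i|/|S|} of the
#' block-size proportions, in bits.  The \eqn{0 \log 0} term is taken as 0.
#'
#' @param p a `sample_partition`, or a code vector coerced via
#'   [partition_from_codes()].
#' @return Entropy in bits, in `[0, log2(n_blocks)]`.
#' @export
entropy <- function(p) {
  p <- as_partition(p)
  .ent_counts(lengths(p$blocks), p$n_samples)
}

#' Joint entropy of several partitions over the same samples
#'
#' Entropy of the meet (cell-wise intersection) partition:
#' \eqn{H(X,Y) = -\sum_{ij} |A_i \cap B_j|/|S| \log_2 |A_i \cap B_j|/|S|},
#' extended to any number of partitions.
#'
#' @param ps list of `sample_partition`s (or code vectors) over an
#'   identical sample set.
#' @return Joint entropy in bits.  Always at least the largest single
#'   entropy and at most their sum.
#' @export
joint_entropy <- function(ps) {
  if (!is.list(ps) || length(ps) == 0L)
    stop("'ps' must be a non-empty list of partitions")
  ps <- lapply(ps, as_partition)
  ns <- vapply(ps, function(p) p$n_samples, integer(1))
  if (length(unique(ns)) != 1L)
    stop("partitions cover different sample sets")
  codes <- lapply(ps, .partition_codes)
  key <- do.call(paste, c(codes, sep = "\r"))
  .ent_counts(tabulate(factor(key)), ns[[1L]])
}

#' Mutual information between a feature and the outcome
#'
#' Plug-in estimate \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)} in bits, computed
#' on the empirical partitions.
#'
#' @param x,y partitions (or code vectors) over the same samples; `y` is
#'   conventionally the binarized clinical outcome.
#' @return Non-negative mutual information in bits, at most `entropy(y)`.
#' @export
single_outcome_mi <- function(x, y) {
  x <- as_partition(x); y <- as_partition(y)
  mi <- entropy(x) + entropy(y) - joint_entropy(list(x, y))
  max(mi, 0)
}

#' Mutual information between a gene pair and the outcome
#'
#' The extended score \eqn{I(X_1,X_2;Y) = H(X_1,X_2) + H(Y) -
#' H(X_1,X_2,Y)}: how much the joint state of two genes tells about the
#' outcome.  It is symmetric in the two genes and never below either
#' single-gene mutual information.
#'
#' @param x1,x2,y partitions (or code vectors) over the same samples.
#' @return Score in bits, in `[0, entropy(y)]`.
#' @export
pair_outcome_mi <- function(x1, x2, y) {
  x1 <- as_partition(x1); x2 <- as_partition(x2); y <- as_partition(y)
  mi <- joint_entropy(list(x1, x2)) + entropy(y) -
    joint_entropy(list(x1, x2, y))
  max(mi, 0)
}
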