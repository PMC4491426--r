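# Permutation-derived significance threshold for the pair MI scan.
#
# One permuted label vector is drawn per run p and shared by every gene
# pair in that run, so I_avg(i,j) = mean_p I(g_i, g_j; Y_p) and the
# threshold is theta = max_{i<j} I_avg(i,j).

#' Permutation test configuration
#'
#' @param n_permutations number of label permutations (default 30).
#' @param seed integer seed for the permutation stream, or `NULL` to use
#'   the current RNG state.
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 30, seed = NULL) {
  if (n_permutations < 1) stop("need at least one permutation")
  structure(list(n_permutations = as.integer(n_permutations), seed = seed),
            class = "permutation_config")
}

#' Randomly permute outcome labels
#'
#' Rearranges the label vector uniformly at random (class sizes are
#' preserved exactly); patient ids are untouched.  Uses the current RNG
#' state, so seed with `set.seed()` for reproducibility.
#'
#' @param y an `outcome_labels` object.
#' @return An `outcome_labels` object with permuted labels.
#' @export
permute_labels <- function(y) {
  stopifnot(inherits(y, "outcome_labels"))
  y$labels <- y$labels[sample.int(length(y$labels))]
  y
}

#' Number of unordered gene pairs
#'
#' @param n_genes gene count.
#' @return `n_genes * (n_genes - 1) / 2`, the number of pairs the scan
#'   enumerates.
#' @export
n_gene_pairs <- function(n_genes) {
  n_genes <- as.numeric(n_genes)
  n_genes * (n_genes - 1) / 2
}

# pair index (i < j in profile gene order), columns of a 2 x m matrix
.pair_index <- function(n) {
  if (n < 2L) stop("need at least two genes to form pairs")
  utils::combn(n, 2L)
}

# MI of every gene pair against each outcome column.
# codes: genes x patients 0-based integer matrix; ymat: patients x P
# matrix of 0/1 outcome codes.  Returns n_pairs x P matrix (bits).
.pair_mi_scan <- function(codes, ymat, B) {
  n <- ncol(codes)
  stopifnot(nrow(ymat) == n)
  pairs <- .pair_index(nrow(codes))
  B2 <- as.integer(B)^2
  P <- ncol(ymat)
  hy <- vapply(seq_len(P), function(p) .ent_counts(tabulate(ymat[, p] + 1L, 2L), n),
               numeric(1))
  out <- matrix(0, ncol(pairs), P)
  for (k in seq_len(ncol(pairs))) {
    z <- codes[pairs[1L, k], ] * as.integer(B) + codes[pairs[2L, k], ]
    hz <- .ent_counts(tabulate(z + 1L, B2), n)
    z2 <- z * 2L
    for (p in seq_len(P)) {
      hzy <- .ent_counts(tabulate(z2 + ymat[, p] + 1L, 2L * B2), n)
      out[k, p] <- hz + hy[p] - hzy
    }
  }
  pmax(out, 0)
}

# align outcome to a profile's patient order; returns 0/1 vector
.aligned_outcome <- function(profile, y) {
  stopifnot(inherits(profile, "discretized_profile"),
            inherits(y, "outcome_labels"))
  if (!setequal(profile$patient_ids, y$patient_ids))
    stop("profile and outcome labels cover different patients")
  .outcome_codes(y, profile$patient_ids)
}

#' Mutual information of every gene pair with the outcome
#'
#' Computes \eqn{I(g_i, g_j; Y)} for all unordered gene pairs of a
#' discretized profile against the (real) outcome labels.
#'
#' @param profile a `discretized_profile`.
#' @param y aligned `outcome_labels`.
#' @return data.frame with columns `gene_i`, `gene_j` (lexicographically
#'   ordered within each pair) and `mi` (bits).
#' @export
mi_scan <- function(profile, y) {
  yc <- .aligned_outcome(profile, y)
  mi <- .pair_mi_scan(profile$codes, matrix(yc, ncol = 1L), profile$B)[, 1L]
  pairs <- .pair_index(length(profile$gene_ids))
  a <- profile$gene_ids[pairs[1L, ]]
  b <- profile$gene_ids[pairs[2L, ]]
  data.frame(gene_i = pmin(a, b), gene_j = pmax(a, b), mi = mi,
             stringsAsFactors = FALSE)
}

#' Average pairwise MI under permuted outcome labels
#'
#' For each of `cfg$n_permutations` runs one permuted label vector is
#' drawn and shared across all pairs; the per-pair null score is the
#' arithmetic mean of \eqn{I(g_i, g_j; Y_p)} over runs.
#'
#' @param profile a `discretized_profile`.
#' @param y aligned `outcome_labels`.
#' @param cfg a [permutation_config()].
#' @return data.frame with `gene_i`, `gene_j`, `avg_mi` (bits).
#' @export
average_permuted_mi <- function(profile, y, cfg = permutation_config()) {
  stopifnot(inherits(cfg, "permutation_config"))
  yc <- .aligned_outcome(profile, y)
  n <- length(yc)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ymat <- vapply(seq_len(cfg$n_permutations),
                 function(p) yc[sample.int(n)], integer(n))
  mi <- .pair_mi_scan(profile$codes, ymat, profile$B)
  pairs <- .pair_index(length(profile$gene_ids))
  a <- profile$gene_ids[pairs[1L, ]]
  b <- profile$gene_ids[pairs[2L, ]]
  data.frame(gene_i = pmin(a, b), gene_j = pmax(a, b),
             avg_mi = rowMeans(mi), stringsAsFactors = FALSE)
}

#' Derive the permutation significance threshold
#'
#' \eqn{\theta = \max_{i \ne j} I_{avg}(i, j)}: the largest pairwise MI
#' the permuted (null) labels could produce, averaged over runs.
#'
#' @param avgs output of [average_permuted_mi()] (or a numeric vector of
#'   per-pair averages).
#' @return A `threshold_result` with `theta` (bits) and the per-pair
#'   averages.
#' @export
derive_threshold <- function(avgs) {
  vals <- if (is.data.frame(avgs)) avgs$avg_mi else as.numeric(avgs)
  if (length(vals) == 0L) stop("no gene pairs: cannot derive a threshold")
  structure(list(theta = max(vals), avg_mi = avgs),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: theta = %.6f bits over %d pairs>\n",
              x$theta, if (is.data.frame(x$avg_mi)) nrow(x$avg_mi)
                       else length(x$avg_mi)))
  invisible(x)
}

#' Scale the threshold by the significance multiplier alpha
#'
#' Working threshold \eqn{\theta (1 + \alpha)}; larger `alpha` gives
#' sparser, higher-confidence networks.
#'
#' @param theta base threshold in bits.
#' @param alpha non-negative significance multiplier.
#' @return `theta * (1 + alpha)`.
#' @examples
#' scale_threshold(0.0763, 0.5)
#' @export
scale_threshold <- function(theta, alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  theta * (1 + alpha)
}

#' Select gene pairs whose MI with the outcome reaches a threshold
#'
#' @param profile a `discretized_profile`.
#' @param y aligned `outcome_labels`.
#' @param threshold MI threshold in bits (typically
#'   `scale_threshold(theta, alpha)`).
#' @param strict if `TRUE` require `mi > threshold`; default keeps
#'   `mi >= threshold` (the formal network definition).
#' @return data.frame of `PairScore`s (`gene_i`, `gene_j`, `mi`) sorted
#'   by decreasing MI, ties broken by gene ids.
#' @export
select_pairs <- function(profile, y, threshold, strict = FALSE) {
  if (threshold < 0) stop("'threshold' must be non-negative")
  sc <- mi_scan(profile, y)
  keep <- if (strict) sc$mi > threshold else sc$mi >= threshold
  sc <- sc[keep, , drop = FALSE]
  sc <- sc[order(-sc$mi, sc$gene_i, sc$gene_j), , drop = FALSE]
  rownames(sc) <- NULL
  sc
}
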