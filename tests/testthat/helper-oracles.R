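# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# entropy from explicit value counting
oracle_entropy <- function(codes) {
  n <- length(codes)
  h <- 0
  for (v in unique(codes)) {
    p <- sum(codes == v) / n
    h <- h - p * log2(p)
  }
  h
}

# joint entropy by explicit contingency enumeration over value tuples
oracle_joint_entropy <- function(...) {
  vecs <- list(...)
  n <- length(vecs[[1]])
  grids <- lapply(vecs, unique)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  h <- 0
  for (r in seq_len(nrow(combos))) {
    hit <- rep(TRUE, n)
    for (k in seq_along(vecs)) hit <- hit & (vecs[[k]] == combos[r, k])
    cnt <- sum(hit)
    if (cnt > 0) h <- h - (cnt / n) * log2(cnt / n)
  }
  h
}

oracle_single_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) - oracle_joint_entropy(x, y)
}

oracle_pair_mi <- function(x1, x2, y) {
  oracle_joint_entropy(x1, x2) + oracle_entropy(y) -
    oracle_joint_entropy(x1, x2, y)
}

# two-group log-rank from an explicit per-event-time risk table
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# product-limit estimate evaluated term by term
oracle_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# closed-form simple least squares R^2
oracle_r2 <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - (a + b * x))^2) / sum((y - mean(y))^2)
}

# outcome labels built directly (bypasses binarize_survival)
make_labels <- function(labels, ids = sprintf("p%04d", seq_along(labels)),
                        cutoff = 36) {
  structure(list(patient_ids = ids,
                 labels = factor(labels, levels = c("short", "long")),
                 cutoff_months = cutoff),
            class = "outcome_labels")
}

# discretized profile built directly from a 0-based code matrix
make_profile <- function(codes, B = max(codes) + 1L) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("g%04d", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("p%04d", seq_len(ncol(codes)))
  structure(list(gene_ids = rownames(codes), patient_ids = colnames(codes),
                 codes = codes, B = as.integer(B),
                 ranges = cbind(min = rep(0, nrow(codes)),
                                max = rep(B - 1, nrow(codes)))),
            class = "discretized_profile")
}

# small random network over a letter alphabet
random_network <- function(n_edges, genes = paste0("G", 1:12), tag = NA) {
  pairs <- t(combn(genes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  build_network(data.frame(gene_i = pairs[pick, 1], gene_j = pairs[pick, 2],
                           mi = runif(length(pick), 0.05, 0.3)),
                profile = tag)
}
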