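# Outcome-guided networks: genes as nodes, an edge wherever the pair's
# joint MI with the outcome reached the working threshold.

.edge_key <- function(e) paste(e$gene_i, e$gene_j, sep = "\r")

.empty_edges <- function() {
  data.frame(gene_i = character(), gene_j = character(), mi = numeric(),
             profiles = character(), stringsAsFactors = FALSE)
}

new_outcome_network <- function(edges, profile = NA_character_,
                                alpha = NA_real_, threshold = NA_real_) {
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, profile = profile, alpha = alpha,
                 threshold = threshold),
            class = "outcome_network")
}

#' Build an outcome-guided network from selected gene pairs
#'
#' One undirected edge per selected pair; the node set is exactly the
#' edge endpoints (no isolated nodes), with no self-loops or parallel
#' edges.
#'
#' @param pairs data.frame of pair scores (`gene_i`, `gene_j`, `mi`), as
#'   returned by [select_pairs()]; must already be filtered at
#'   `threshold`.
#' @param profile profile tag stored on the edges (e.g. `"mRNA"`).
#' @param alpha,threshold the significance multiplier and working
#'   threshold used for selection (metadata).
#' @return An `outcome_network`.
#' @export
build_network <- function(pairs, profile = NA_character_,
                          alpha = NA_real_, threshold = NA_real_) {
  if (nrow(pairs) == 0L)
    return(new_outcome_network(.empty_edges(), profile, alpha, threshold))
  gi <- pmin(as.character(pairs$gene_i), as.character(pairs$gene_j))
  gj <- pmax(as.character(pairs$gene_i), as.character(pairs$gene_j))
  if (any(gi == gj)) stop("self-loop: a gene paired with itself")
  edges <- data.frame(gene_i = gi, gene_j = gj, mi = pairs$mi,
                      profiles = profile, stringsAsFactors = FALSE)
  if (anyDuplicated(.edge_key(edges))) stop("duplicate gene pair in input")
  new_outcome_network(edges, profile, alpha, threshold)
}

#' @export
print.outcome_network <- function(x, ...) {
  cat(sprintf("<outcome_network%s: %d nodes, %d edges>\n",
              if (is.na(x$profile)) "" else paste0(" [", x$profile, "]"),
              length(network_nodes(x)), nrow(x$edges)))
  invisible(x)
}

#' Node set of an outcome network
#' @param net an `outcome_network`.
#' @return Sorted character vector of gene ids appearing on edges.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$edges$gene_i, net$edges$gene_j)))
}

#' Convert an outcome network to an igraph graph
#' @param net an `outcome_network`.
#' @return An undirected [igraph::igraph] graph with `mi` and `profiles`
#'   edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "outcome_network"))
  if (nrow(net$edges) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(net$edges, directed = FALSE)
}

#' Intersect outcome networks across profiles
#'
#' The co-occurrence network \eqn{I^\forall}: an edge survives only if it
#' is present in every input network.  Surviving edges keep the maximum
#' MI and the union of source-profile tags.
#'
#' @param nets list of two or more `outcome_network`s.
#' @return An `outcome_network`.
#' @export
intersect_networks <- function(nets) {
  stopifnot(length(nets) >= 2L)
  keys <- lapply(nets, function(g) .edge_key(g$edges))
  common <- Reduce(intersect, keys)
  .merge_edges(nets, common)
}

#' Union of outcome networks across profiles
#'
#' The one-or-more occurrence network \eqn{I^\exists}: an edge survives
#' if present in at least one input network, keeping the maximum MI and
#' the union of source-profile tags.
#'
#' @param nets list of `outcome_network`s.
#' @return An `outcome_network`.
#' @export
union_networks <- function(nets) {
  stopifnot(length(nets) >= 1L)
  keys <- lapply(nets, function(g) .edge_key(g$edges))
  .merge_edges(nets, Reduce(union, keys))
}

.merge_edges <- function(nets, keys) {
  if (length(keys) == 0L) return(new_outcome_network(.empty_edges()))
  all_edges <- do.call(rbind, lapply(nets, function(g) g$edges))
  all_edges <- all_edges[.edge_key(all_edges) %in% keys, , drop = FALSE]
  k <- .edge_key(all_edges)
  mi <- tapply(all_edges$mi, k, max)
  tags <- tapply(as.character(all_edges$profiles), k, function(p)
    paste(sort(unique(unlist(strsplit(p[!is.na(p)], ";")))), collapse = ";"))
  uk <- names(mi)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  edges <- data.frame(gene_i = parts[, 1L], gene_j = parts[, 2L],
                      mi = as.numeric(mi),
                      profiles = ifelse(tags == "", NA_character_, tags),
                      stringsAsFactors = FALSE)
  new_outcome_network(edges)
}

#' Connected components of an outcome network
#'
#' @param net an `outcome_network`.
#' @return List of node-id character vectors, sorted by decreasing size.
#' @export
network_components <- function(net) {
  if (nrow(net$edges) == 0L) return(list())
  comp <- igraph::components(as_igraph(net))
  out <- split(names(comp$membership), comp$membership)
  out <- lapply(out, sort)
  unname(out[order(-vapply(out, length, integer(1)))])
}

#' Empirical degree distribution
#'
#' @param net an `outcome_network` with at least one edge.
#' @return data.frame with columns `degree` (observed k, all >= 1) and
#'   `freq` (fraction of nodes with that degree; sums to 1).
#' @export
degree_distribution <- function(net) {
  if (nrow(net$edges) == 0L) stop("degree distribution of an empty network")
  deg <- igraph::degree(as_igraph(net))
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)),
             freq = as.numeric(tab) / length(deg))
}

#' Scale-freeness index R-squared
#'
#' Coefficient of determination of the ordinary least-squares fit of
#' `log2 p(k)` on `log2 k` over the observed degrees: values near 1
#' indicate a power-law (scale-free) degree distribution.  The choice of
#' log base does not affect R-squared.  With fewer than two distinct
#' degrees the index is undefined and `NA` is returned.
#'
#' @param dist degree distribution data.frame from
#'   [degree_distribution()] (columns `degree`, `freq`), or an
#'   `outcome_network`.
#' @return R-squared in `[0, 1]`, or `NA` if undefined.
#' @export
scale_freeness_r2 <- function(dist) {
  if (inherits(dist, "outcome_network")) {
    if (nrow(dist$edges) == 0L) return(NA_real_)
    dist <- degree_distribution(dist)
  }
  dist <- dist[dist$freq > 0, , drop = FALSE]
  if (nrow(dist) < 2L) return(NA_real_)
  x <- log2(dist$degree)
  yv <- log2(dist$freq)
  fit <- stats::lm(yv ~ x)
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((yv - mean(yv))^2)
  if (sstot <= .Machine$double.eps * max(1, sum(yv^2)))
    return(1.0)  # SSres <= SStot = 0: the fit is exact
  max(0, min(1, 1 - ssres / sstot))
}

#' Topological summary of an outcome network
#'
#' @param net an `outcome_network`.
#' @return One-row data.frame: `vertices`, `edges`, `components`,
#'   `largest_component`, `r_squared` (`NA` when undefined).
#' @export
topology_summary <- function(net) {
  comps <- network_components(net)
  data.frame(vertices = length(network_nodes(net)),
             edges = nrow(net$edges),
             components = length(comps),
             largest_component = if (length(comps)) length(comps[[1L]]) else 0L,
             r_squared = scale_freeness_r2(net))
}
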