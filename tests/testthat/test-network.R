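# Outcome-guided network construction, integration and topology.

test_that("build_network creates one edge per pair over its endpoints", {
  empty <- build_network(data.frame(gene_i = character(),
                                    gene_j = character(), mi = numeric()))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(network_nodes(empty), character())

  path <- build_network(data.frame(gene_i = c("a", "b"), gene_j = c("b", "c"),
                                   mi = c(0.2, 0.1)))
  expect_identical(network_nodes(path), c("a", "b", "c"))
  expect_identical(nrow(path$edges), 2L)
  expect_identical(length(network_components(path)), 1L)

  dup <- data.frame(gene_i = c("a", "b"), gene_j = c("b", "a"), mi = c(.1, .2))
  expect_error(build_network(dup), "duplicate")
  expect_error(build_network(data.frame(gene_i = "a", gene_j = "a", mi = .1)),
               "self-loop")
})

test_that("node/edge counts of a random network match set arithmetic", {
  set.seed(20)
  genes <- sprintf("G%03d", 1:30)
  pairs <- t(combn(genes, 2))
  pick <- sample(nrow(pairs), 100)
  df <- data.frame(gene_i = pairs[pick, 1], gene_j = pairs[pick, 2],
                   mi = runif(100))
  net <- build_network(df)
  expect_identical(nrow(net$edges), 100L)
  expect_identical(network_nodes(net),
                   sort(unique(c(df$gene_i, df$gene_j))))
})

test_that("intersection and union of networks follow edge-set arithmetic", {
  set.seed(21)
  g1 <- random_network(15, tag = "mRNA")
  g2 <- random_network(15, tag = "CNA")
  g3 <- random_network(15, tag = "METH")

  key <- function(net) paste(net$edges$gene_i, net$edges$gene_j)
  self <- intersect_networks(list(g1, g1))
  expect_setequal(key(self), key(g1))
  expect_setequal(key(union_networks(list(g1, empty <- build_network(
    data.frame(gene_i = character(), gene_j = character(), mi = numeric()))))),
    key(g1))

  both <- intersect_networks(list(g1, g2, g3))
  expect_setequal(key(both), Reduce(intersect, list(key(g1), key(g2), key(g3))))
  any_net <- union_networks(list(g1, g2, g3))
  expect_setequal(key(any_net), Reduce(union, list(key(g1), key(g2), key(g3))))

  # disjoint edge sets intersect to nothing, union to the sum
  h1 <- build_network(data.frame(gene_i = "a", gene_j = "b", mi = .1))
  h2 <- build_network(data.frame(gene_i = "c", gene_j = "d", mi = .2))
  expect_identical(nrow(intersect_networks(list(h1, h2))$edges), 0L)
  expect_identical(nrow(union_networks(list(h1, h2))$edges), 2L)

  # union keeps the max MI and merges the source tags
  o1 <- build_network(data.frame(gene_i = "x", gene_j = "y", mi = .1), "mRNA")
  o2 <- build_network(data.frame(gene_i = "x", gene_j = "y", mi = .3), "CNA")
  u <- union_networks(list(o1, o2))
  expect_equal(u$edges$mi, 0.3)
  expect_identical(u$edges$profiles, "CNA;mRNA")
})

test_that("containment: intersection within each profile within union", {
  set.seed(22)
  key <- function(net) paste(net$edges$gene_i, net$edges$gene_j)
  for (rep in 1:10) {
    nets <- list(random_network(12), random_network(12), random_network(12))
    inter <- key(intersect_networks(nets))
    uni <- key(union_networks(nets))
    for (g in nets) {
      expect_true(all(inter %in% key(g)))
      expect_true(all(key(g) %in% uni))
    }
  }
})

test_that("components are found and sorted by size", {
  tri2 <- build_network(data.frame(
    gene_i = c("a", "b", "a", "x", "y", "x"),
    gene_j = c("b", "c", "c", "y", "z", "z"), mi = runif(6)))
  comps <- network_components(tri2)
  expect_identical(lengths(comps), c(3L, 3L))

  set.seed(23)
  net <- random_network(20, genes = sprintf("G%02d", 1:20))
  comps <- network_components(net)
  # BFS oracle via igraph on an independently rebuilt graph
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, 1:2]), directed = FALSE)
  expect_identical(length(comps), as.integer(igraph::components(g)$no))
  expect_identical(length(comps[[1]]),
                   as.integer(max(igraph::components(g)$csize)))
})

test_that("degree distribution is a frequency map over observed degrees", {
  star <- build_network(data.frame(gene_i = "hub", gene_j = paste0("l", 1:5),
                                   mi = runif(5)))
  d <- degree_distribution(star)
  expect_equal(d$freq[d$degree == 1], 5 / 6)
  expect_equal(d$freq[d$degree == 5], 1 / 6)
  expect_equal(sum(d$freq), 1)

  tri <- build_network(data.frame(gene_i = c("a", "b", "a"),
                                  gene_j = c("b", "c", "c"), mi = runif(3)))
  expect_equal(degree_distribution(tri),
               data.frame(degree = 2L, freq = 1))
  empty <- build_network(data.frame(gene_i = character(),
                                    gene_j = character(), mi = numeric()))
  expect_error(degree_distribution(empty), "empty")
})

test_that("scale-freeness R2 is exact on power laws and matches least squares", {
  k <- c(1, 2, 4, 8)
  p <- k^-2 / sum(k^-2)
  expect_equal(scale_freeness_r2(data.frame(degree = k, freq = p)), 1.0)
  # two distinct degrees always fit a line exactly
  expect_equal(scale_freeness_r2(data.frame(degree = c(1, 3), freq = c(.7, .3))),
               1.0)
  expect_true(is.na(scale_freeness_r2(data.frame(degree = 2, freq = 1))))

  # preferential-attachment degree sequence vs closed-form least squares
  set.seed(24)
  g <- igraph::sample_pa(400, directed = FALSE)
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  dist <- data.frame(degree = as.integer(names(tab)),
                     freq = as.numeric(tab) / length(deg))
  expect_equal(scale_freeness_r2(dist),
               oracle_r2(log2(dist$degree), log2(dist$freq)),
               tolerance = 1e-10)
  # R2 does not depend on the log base
  expect_equal(oracle_r2(log(dist$degree), log(dist$freq)),
               oracle_r2(log2(dist$degree), log2(dist$freq)),
               tolerance = 1e-12)
})

test_that("topology_summary aggregates counts consistently", {
  path <- build_network(data.frame(gene_i = c("a", "b"), gene_j = c("b", "c"),
                                   mi = c(.2, .1)))
  ts <- topology_summary(path)
  expect_identical(ts$vertices, 3L)
  expect_identical(ts$edges, 2L)
  expect_identical(ts$components, 1L)
  expect_identical(ts$largest_component, 3L)
  expect_equal(ts$r_squared, 1.0)  # degrees {1, 2}: two points

  empty <- build_network(data.frame(gene_i = character(),
                                    gene_j = character(), mi = numeric()))
  tse <- topology_summary(empty)
  expect_identical(unlist(tse[1, 1:4], use.names = FALSE), rep(0L, 4))
  expect_true(is.na(tse$r_squared))

  set.seed(25)
  net <- random_network(18)
  ts <- topology_summary(net)
  expect_identical(ts$vertices, length(network_nodes(net)))
  expect_identical(ts$edges, nrow(net$edges))
  expect_identical(ts$largest_component,
                   length(network_components(net)[[1]]))
})
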