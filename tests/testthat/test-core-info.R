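# Discretization, partitions, entropy and the pairwise outcome MI.

test_that("bin_index follows the equal-width binning formula", {
  expect_identical(bin_index(3.9, 0, 10, 5), 1L)   # width 2, 3.9 in [2, 4)
  expect_identical(bin_index(10, 0, 10, 5), 4L)    # max clamps to last bin
  expect_identical(bin_index(0.0763, 0, 1, 5), 0L)
  expect_identical(bin_index(c(0, 2, 4, 6, 8, 10), 0, 10, 5),
                   c(0L, 1L, 2L, 3L, 4L, 4L))
  expect_identical(bin_index(7, 7, 7, 5), 0L)      # degenerate range
  expect_error(bin_index(11, 0, 10, 5), "outside")
  expect_error(bin_index(-0.1, 0, 10, 5), "outside")
})

test_that("discretize_profile bins each gene by its own range", {
  m <- rbind(a = c(3, 3, 3, 3, 3, 3), b = c(0, 2, 4, 6, 8, 10))
  colnames(m) <- paste0("p", 1:6)
  d <- discretize_profile(m, B = 5)
  expect_identical(unname(d$codes["a", ]), rep(0L, 6))  # constant gene
  expect_identical(unname(d$codes["b", ]), c(0L, 1L, 2L, 3L, 4L, 4L))

  set.seed(41)
  m2 <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("p", 1:4)))
  d2 <- discretize_profile(m2, B = 3)
  for (g in 1:3) for (p in 1:4)
    expect_identical(d2$codes[g, p],
                     bin_index(m2[g, p], min(m2[g, ]), max(m2[g, ]), 3))

  m2[1, 1] <- NA
  expect_error(discretize_profile(m2, B = 3), "missing")
})

test_that("GISTIC codes are shifted order-preservingly onto 0..4", {
  m <- matrix(c(-2, -1, 0, 1, 2, 0), 2, 3,
              dimnames = list(c("g1", "g2"), c("p1", "p2", "p3")))
  d <- discretize_profile(m, kind = "gistic")
  expect_identical(as.integer(d$codes), as.integer(m) + 2L)
  expect_identical(d$B, 5L)
  m[1, 1] <- 3
  expect_error(discretize_profile(m, kind = "gistic"), "-2..2")
})

test_that("binarize_survival labels and excludes patients per the cutoff rule", {
  clin <- data.frame(
    patient_id = paste0("p", 1:8),
    months = c(20, 20, 80, 36, 36, NA, 50, 10),
    status = c("deceased", "living", "living", "living", "deceased",
               "deceased", NA, "deceased"))
  y <- binarize_survival(clin, cutoff = 36)
  expect_setequal(y$patient_ids, c("p1", "p3", "p5", "p8"))
  lab <- setNames(as.character(y$labels), y$patient_ids)
  expect_identical(lab[["p1"]], "short")   # deceased at 20
  expect_identical(lab[["p3"]], "long")    # alive past cutoff
  expect_identical(lab[["p5"]], "short")   # died at exactly C
  expect_false("p2" %in% y$patient_ids)    # alive below cutoff: ambiguous
  expect_false("p4" %in% y$patient_ids)    # alive at exactly C: ambiguous
  expect_error(binarize_survival(transform(clin, months = -months), 36),
               "egative")
})

test_that("partition_from_codes groups samples by distinct code", {
  p <- partition_from_codes(c(0, 0, 1, 1))
  expect_identical(p$blocks, list(1:2, 3:4))
  expect_identical(length(partition_from_codes(c(2, 2, 2))$blocks), 1L)
  p3 <- partition_from_codes(c(0, 1, 0, 2, 1))
  expect_setequal(lengths(p3$blocks), c(2L, 2L, 1L))
})

test_that("entropy matches the block-proportion formula in bits", {
  expect_equal(entropy(c(0, 0, 0, 0, 1, 1, 1, 1)), 1.0)
  expect_equal(entropy(rep(7, 5)), 0.0)
  expect_equal(entropy(c(rep(0, 5), rep(1, 3))), 0.954434, tolerance = 1e-6)
})

test_that("joint entropy equals entropy of the meet partition", {
  x <- c(0, 0, 1, 1)
  expect_equal(joint_entropy(list(x, x)), entropy(x))
  expect_equal(joint_entropy(list(c(0, 0, 1, 1), c(0, 1, 0, 1))), 2.0)
  set.seed(5)
  a <- sample(0:2, 12, TRUE); b <- sample(0:1, 12, TRUE); c3 <- sample(0:3, 12, TRUE)
  expect_equal(joint_entropy(list(a, b, c3)), oracle_joint_entropy(a, b, c3),
               tolerance = 1e-12)
  expect_error(joint_entropy(list(a, b[1:6])), "different sample sets")
})

test_that("pairwise outcome MI is forced to 1 bit by a noiseless XOR design", {
  x1 <- c(0, 0, 1, 1)
  x2 <- c(0, 1, 0, 1)
  y <- bitwXor(x1, x2)
  expect_equal(pair_outcome_mi(x1, x2, y), 1.0)
  expect_equal(single_outcome_mi(x1, y), 0.0)
  expect_equal(single_outcome_mi(x2, y), 0.0)
  expect_equal(pair_outcome_mi(x1, x2, rep(1, 4)), 0.0)  # constant outcome
})

test_that("single-feature MI behaves on identical and independent designs", {
  y <- c(0, 0, 1, 1)
  expect_equal(single_outcome_mi(y, y), entropy(y))
  # product design: every (x, y) cell equally filled
  x <- c(0, 1, 0, 1)
  expect_equal(single_outcome_mi(x, y), 0.0)
})

test_that("entropy and MI agree with the contingency-count oracle", {
  set.seed(90)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    x1 <- sample(0:4, n, TRUE)
    x2 <- sample(0:4, n, TRUE)
    y <- sample(0:1, n, TRUE)
    expect_equal(entropy(x1), oracle_entropy(x1), tolerance = 1e-12)
    expect_equal(single_outcome_mi(x1, y), oracle_single_mi(x1, y),
                 tolerance = 1e-12)
    expect_equal(pair_outcome_mi(x1, x2, y), oracle_pair_mi(x1, x2, y),
                 tolerance = 1e-12)
  }
})

test_that("MI obeys bounds, monotonicity, symmetry and relabeling invariance", {
  set.seed(91)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    x1 <- sample(0:3, n, TRUE)
    x2 <- sample(0:3, n, TRUE)
    y <- sample(0:1, n, TRUE)
    mi <- pair_outcome_mi(x1, x2, y)
    expect_gte(mi, 0)
    expect_lte(mi, entropy(y) + 1e-12)
    expect_gte(mi + 1e-12, single_outcome_mi(x1, y))
    expect_gte(mi + 1e-12, single_outcome_mi(x2, y))
    expect_identical(mi, pair_outcome_mi(x2, x1, y))
    # permute the code alphabet: nothing changes
    relab <- sample(0:3)
    expect_equal(pair_outcome_mi(relab[x1 + 1], x2, y), mi, tolerance = 1e-12)
    expect_equal(entropy(relab[x1 + 1]), entropy(x1), tolerance = 1e-12)
  }
})
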