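test_that("consensus distances follow the normalization-and-average formula", {
  d1 <- matrix(c(0, 2, 2, 0), 2)
  d2 <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(combine_distances(d1, d2)[1, 2], 1)
  # proportional matrices coincide after normalization
  set.seed(90)
  a <- random_dist(5)
  expect_equal(combine_distances(a, 2 * a), a / max(a), ignore_attr = TRUE)
  # direct-formula oracle on random 6x6 pairs
  for (r in 1:20) {
    x <- random_dist(6)
    y <- random_dist(6)
    expect_lt(max(abs(combine_distances(x, y) -
                        0.5 * (x / max(x) + y / max(y)))), 1e-12)
  }
  # separate rescaling changes nothing
  x <- random_dist(6)
  y <- random_dist(6)
  expect_equal(combine_distances(x, y), combine_distances(3 * x, 0.2 * y),
               tolerance = 1e-12)
  expect_error(combine_distances(matrix(0, 3, 3)), "max")
})

test_that("SCNA-only samples fall back to the normalized SCNA distance", {
  ids <- c("S1", "S2", "S3", "S4")
  d1 <- random_dist(4)
  dimnames(d1) <- list(ids, ids)
  d2 <- random_dist(3)
  dimnames(d2) <- list(ids[1:3], ids[1:3])
  d0 <- combine_distances(d1, d2)
  expect_equal(d0["S1", "S4"], d1["S1", "S4"] / max(d1))
  expect_equal(d0["S1", "S2"],
               0.5 * (d1["S1", "S2"] / max(d1) + d2["S1", "S2"] / max(d2)))
})

test_that("three-leaf trees solve the three-point closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_tree(d)
  # three-point formulas: x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 3
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("additive distances recover the generating topology exactly", {
  set.seed(91)
  for (r in 1:10) {
    tr <- ape::rtree(6, rooted = FALSE)
    d <- cophenetic(tr)
    built <- build_tree(d)
    expect_equal(tree_distance(built, tr)$rf, 0)
  }
})

test_that("a star-like matrix yields near-zero internal branches", {
  d <- matrix(1, 5, 5)
  diag(d) <- 0
  tr <- build_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_lt(max(tr$edge.length[internal]), 1e-8)
})

test_that("rooting on a reference leaf keeps the leaf set", {
  d <- random_dist(5)
  rownames(d) <- colnames(d) <- c(paste0("T", 1:4), "N")
  tr <- build_tree(d, root_on = "N")
  expect_true(ape::is.rooted(tr))
  expect_setequal(tr$tip.label, rownames(d))
  expect_error(build_tree(d, root_on = "missing"), "not in the tree")
  expect_error(build_tree(d[1:2, 1:2]), "at least 3")
})

test_that("congruence is 1 / -1 under monotone transforms", {
  set.seed(92)
  d1 <- list(random_dist(5))
  up <- list(d1[[1]]^2) # monotone increasing
  down <- list(max(d1[[1]]) * 1.1 - d1[[1]])
  diag(down[[1]]) <- 0
  expect_equal(congruence(d1, up, n_perm = 0)$rho, 1)
  expect_equal(congruence(d1, down, n_perm = 0)$rho, -1)
  expect_error(congruence(list(matrix(0, 2, 2)), list(matrix(0, 2, 2)),
                          n_perm = 0), "3 sample pairs")
})

test_that("permutation p agrees with exhaustive enumeration on 4 samples", {
  set.seed(93)
  d1 <- random_dist(4)
  d2 <- random_dist(4)
  v1 <- d1[upper.tri(d1)]
  rho_obs <- cor(v1, d2[upper.tri(d2)], method = "spearman")
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rho_all <- apply(perms, 1, function(p) {
    b <- d2[p, p]
    cor(v1, b[upper.tri(b)], method = "spearman")
  })
  p_exh <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  res <- congruence(list(d1), list(d2), n_perm = 4000, seed = 9)
  expect_lt(abs(res$p - p_exh), 0.05)
})

test_that("Robinson-Foulds distance matches a bipartition enumeration oracle", {
  biparts <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    keep <- vapply(pp, function(b)
      length(b) >= 2 && length(b) <= length(labs) - 2, logical(1))
    sets <- lapply(pp[keep], function(b) {
      s <- sort(labs[b])
      o <- sort(setdiff(labs, s))
      paste(min(paste(s, collapse = "|"), paste(o, collapse = "|")))
    })
    unique(unlist(sets))
  }
  set.seed(94)
  for (r in 1:8) {
    t1 <- ape::rtree(8, rooted = FALSE)
    t2 <- ape::rtree(8, rooted = FALSE)
    b1 <- biparts(t1)
    b2 <- biparts(t2)
    brute <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
    expect_equal(tree_distance(t1, t2)$rf, brute)
  }
  t1 <- ape::rtree(6, rooted = FALSE)
  expect_equal(tree_distance(t1, t1)$rf, 0)
  # two distinct 4-leaf topologies differ in their single internal edge
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(tree_distance(a, b)$rf_normalized, 1)
  expect_error(tree_distance(a, ape::rtree(5)), "leaf set")
})

test_that("probe masks select homogeneous and neutral regions", {
  st <- cbind(c(2L, 3L, 3L, 0L), c(2L, 3L, 2L, 0L))
  expect_equal(probe_mask(st, "homogeneous"), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(probe_mask(st, "neutral"), c(TRUE, FALSE, FALSE, FALSE))
})
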