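test_that("apith reproduces forced examples and rejects k < 2", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2)
  expect_equal(apith(d), 0.3) # k = 2: the single pair
  d3 <- matrix(0, 3, 3)
  d3[upper.tri(d3)] <- c(0.1, 0.2, 0.3)
  d3 <- d3 + t(d3)
  expect_equal(apith(d3), 0.2)
  dc <- matrix(0.4, 4, 4)
  diag(dc) <- 0
  expect_equal(apith(dc), 0.4) # all distances equal
  expect_error(apith(matrix(0, 1, 1)), "fewer than 2")
})

test_that("apith equals brute-force pair enumeration on random matrices", {
  set.seed(70)
  for (r in 1:200) {
    k <- sample(2:9, 1)
    d <- random_dist(k)
    brute <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) brute <- brute + d[i, j]
    brute <- brute * 2 / (k * (k - 1))
    expect_identical(apith(d), brute)
  }
})

test_that("SCNA distance counts differing statuses, with subsets", {
  p1 <- c(2L, 2L, 3L, 3L, 0L, 2L, 2L, 1L, 2L, 2L)
  p2 <- c(2L, 2L, 3L, 2L, 0L, 2L, 2L, 2L, 3L, 2L)
  # differs at probes 4, 8, 9 -> 0.3 (brute-force element count)
  expect_equal(scna_distance(p1, p2), sum(p1 != p2) / 10)
  expect_equal(scna_distance(p1, p2), 0.3)
  expect_equal(scna_distance(p1, p1), 0)
  expect_equal(scna_distance(p1, (p1 + 1L) %% 4L), 1) # differs everywhere
  sub <- 3:7
  expect_equal(scna_distance(p1, p2, sub), scna_distance(p1[sub], p2[sub]))
  expect_error(scna_distance(p1, p2[1:5]), "equal length")
})

test_that("methylation distance: forced values and direct-formula oracle", {
  expect_equal(methylation_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(methylation_distance(c(1, 0), c(0, 1), scaled = TRUE), 1)
  expect_error(methylation_distance(runif(5), runif(5),
                                    probe_subset = integer(0)), "empty")
  set.seed(71)
  b1 <- runif(5000)
  b2 <- runif(5000)
  expect_equal(methylation_distance(b1, b2), sqrt(sum((b1 - b2)^2)),
               tolerance = 1e-12)
  expect_equal(methylation_distance(b1, b2, scaled = TRUE),
               sqrt(mean((b1 - b2)^2)), tolerance = 1e-12)
})

test_that("naive ITH counts private disruption and grows with samples", {
  # 10 probes, 3 samples: probes 1-2 AMP in all (public), 3-5 AMP in one
  st <- matrix(2L, 10, 3)
  st[1:2, ] <- 3L
  st[3:5, 1] <- 3L
  expect_equal(naive_ith(st), 0.3)
  expect_equal(naive_ith(st, denominator = "disrupted"), 3 / 5)
  expect_equal(naive_ith(matrix(2L, 10, 3)), 0)
  # identical samples -> 0
  expect_equal(naive_ith(cbind(st[, 1], st[, 1])), 0)
  # nested sample sets: adding a sample never decreases the index
  set.seed(72)
  big <- matrix(sample(0:3, 20 * 6, TRUE, prob = c(.1, .1, .6, .2)), 20, 6)
  vals <- vapply(2:6, function(k) naive_ith(big[, 1:k]), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("variance model falls back gracefully when all k = 2", {
  set.seed(73)
  dl <- lapply(1:30, function(i) matrix(c(0, runif(1), runif(1), 0), 2))
  dl <- lapply(dl, function(d) (d + t(d)) / 2)
  expect_warning(vm <- estimate_variance_model(dl), "k >= 3")
  expect_equal(vm$c, 0)
  w <- apith_weights(rep(2, 30), vm, dist_list = dl)
  expect_equal(w, rep(1, 30)) # all weights equal
})

test_that("Var(APITH) decreases in k and weights are scale invariant", {
  vm <- structure(list(sigma2_d = 0.04, c = 0.004), class = "apith_variance_model")
  v <- apith_variance(2:10, vm)
  expect_true(all(diff(v) < 0))
  set.seed(74)
  cfg <- small_config()
  cfg$branch_rate <- 5
  tree <- simulate_clone_tree(4, cfg)
  D <- apith:::clone_dist_fast(tree)
  ks <- sample(2:7, 40, TRUE)
  dl <- lapply(ks, function(k) clone_lookup_draw(D, k))
  w1 <- apith_weights(ks, dist_list = dl)
  w2 <- apith_weights(ks, dist_list = lapply(dl, function(d) 7.3 * d))
  expect_equal(w1, w2, tolerance = 1e-10)
  expect_equal(mean(w1), 1)
})

test_that("moment estimator recovers the true distance moments", {
  set.seed(75)
  cfg <- small_config()
  cfg$branch_rate <- 6
  tree <- simulate_clone_tree(5, cfg)
  D <- apith:::clone_dist_fast(tree)
  C <- nrow(D)
  s2_true <- mean(D^2) - mean(D)^2
  c_true <- mean(rowMeans(D)^2) - mean(D)^2
  dl <- lapply(1:3000, function(i) clone_lookup_draw(D, sample(3:8, 1)))
  vm <- estimate_variance_model(dl)
  expect_lt(abs(vm$sigma2_d - s2_true) / s2_true, 0.1)
  expect_lt(abs(vm$c - c_true), 0.15 * s2_true)
})

test_that("region APITH is zero for constant betas and ranks planted contrasts", {
  ann <- small_annotation()
  np <- nrow(ann)
  flat <- matrix(0.5, np, 4)
  pat <- c("P1", "P1", "P2", "P2")
  res <- region_apith(flat, pat, ann, region_by = "cpg_context") |>
    suppressWarnings()
  expect_true(all(res$apith == 0))
  # planted heterogeneity only in gene-body probes (plus faint noise so
  # the group contrast has nonzero within-group variance)
  set.seed(76)
  b <- matrix(0.5, np, 4) + matrix(rnorm(np * 4, 0, 0.005), np, 4)
  body <- which(ann$gene_context == "body")
  b[body, c(2, 4)] <- b[body, c(2, 4)] + 0.3
  res2 <- region_apith(b, pat, ann, region_by = "gene_context") |>
    suppressWarnings()
  for (p in c("P1", "P2")) {
    bd <- res2$apith[res2$patient_id == p & res2$region == "body"]
    pr <- res2$apith[res2$patient_id == p & res2$region == "TSS200"]
    expect_gt(bd, pr)
  }
  tt <- region_apith_test(res2, "body", c("TSS200", "TSS1500"))
  expect_s3_class(tt, "htest")
})

test_that("public/private classification follows the all-samples rule", {
  ev <- data.frame(
    patient_id = rep("P1", 6),
    sample_id = rep(c("S1", "S2", "S3"), 2),
    event_id = rep(c("snv_a", "snv_b"), each = 3),
    present = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  res <- classify_public_private(ev)
  expect_equal(res$classification[res$event_id == "snv_a"], "public")
  expect_equal(res$classification[res$event_id == "snv_b"], "private")
  one <- data.frame(patient_id = "P2", sample_id = "S1",
                    event_id = "snv_c", present = TRUE)
  expect_error(classify_public_private(one), "one sample")
})

test_that("variant filter applies the printed thresholds exactly", {
  v <- expand.grid(alt_count = c(3, 4), depth_tumor = c(2, 3),
                   depth_normal = c(2, 3), vaf = c(0.0999, 0.1))
  kept <- filter_somatic_variants(v)
  expect_true(all(kept$alt_count > 3 & kept$depth_tumor > 2 &
                    kept$depth_normal > 2 & kept$vaf >= 0.1))
  expect_equal(nrow(kept), 1L) # only the all-pass corner survives
  expect_true(4 %in% kept$alt_count && 0.1 %in% kept$vaf)
  # boundary rows: alt_count = 3 out (strict), vaf = 0.1 in (inclusive)
  expect_false(any(kept$alt_count == 3))
  expect_false(any(kept$vaf < 0.1))
  empty <- v[0, ]
  expect_equal(nrow(filter_somatic_variants(empty)), 0L)
})
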