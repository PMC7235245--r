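test_that("clone tree simulation is deterministic and validates input", {
  cfg <- small_config()
  t1 <- simulate_clone_tree(4, cfg, seed = 11)
  t2 <- simulate_clone_tree(4, cfg, seed = 11)
  expect_identical(t1$scna_events, t2$scna_events)
  expect_identical(t1$parent, t2$parent)
  expect_error(simulate_clone_tree(0, cfg), "positive")
  # tree is connected: every clone reaches the founder
  for (cl in seq_len(t1$n_clones))
    expect_identical(apith:::clone_path(t1, cl)[1], 1L)
})

test_that("single-clone tree yields identical samples and zero true APITH", {
  cfg <- small_config(purity_range = c(1, 1), beta_noise_sd = 0,
                      baf_noise_sd = 0, lrr_noise_sd = 0)
  tree <- simulate_clone_tree(1, cfg, seed = 3, annotation = small_annotation())
  pt <- simulate_patient(tree, k = 3, cfg, seed = 4,
                         annotation = small_annotation())
  expect_equal(pt$apith_true_scna, 0)
  expect_equal(pt$apith_true_meth, 0)
  expect_identical(pt$beta[, 1], unname(pt$beta[, 2]), ignore_attr = TRUE)
  expect_identical(pt$tracks[[1]]$baf, pt$tracks[[2]]$baf)
})

test_that("private event count per branch matches the configured rate", {
  cfg <- small_config(founder_rate = 0)
  cfg$branch_rate <- 3
  n_branch_events <- vapply(1:400, function(s) {
    tr <- simulate_clone_tree(3, cfg, seed = s)
    sum(tr$scna_events$clone > 1)
  }, numeric(1))
  # 2 branches at rate 3 -> mean 6; MC se = sqrt(6/400) ~ 0.12
  expect_lt(abs(mean(n_branch_events) - 6) / 6, 0.1)
})

test_that("observed beta follows the purity mixing model", {
  # fully methylated tumor probe, beta_normal = 0.2, pi = 0.7, noise 0.02:
  # expected observed beta = 0.7 * 1 + 0.3 * 0.2 = 0.76
  set.seed(5)
  draws <- pmin(pmax(0.7 * 1 + 0.3 * 0.2 + rnorm(10000, 0, 0.02), 0), 1)
  expect_lt(abs(mean(draws) - 0.76), 0.002)
  # and the simulator reproduces it end to end (noise-free check of the
  # same linear mixture)
  ann <- small_annotation()
  cfg <- small_config(beta_noise_sd = 0)
  tree <- simulate_clone_tree(3, cfg, seed = 6, annotation = ann)
  pt <- simulate_patient(tree, k = 2, cfg, seed = 7, annotation = ann,
                         tracks = FALSE)
  expected <- pt$purity[1] * pt$profiles$beta[pt$clone_of[1], ] +
    (1 - pt$purity[1]) * pt$beta_normal
  expect_equal(unname(pt$beta[, 1]), expected, tolerance = 1e-12)
})

test_that("patient simulation enforces k >= 2 and records true distances", {
  cfg <- small_config()
  tree <- simulate_clone_tree(3, cfg, seed = 8)
  expect_error(simulate_patient(tree, k = 1, cfg), "k must be >= 2")
  pt <- simulate_patient(tree, k = 5, cfg, seed = 9, annotation = NULL,
                         tracks = FALSE, meth = FALSE)
  expect_equal(pt$apith_true_scna, apith(pt$true_dist_scna))
  expect_true(all(rowSums(pt$mixture) == 1))
  expect_true(isSymmetric(pt$true_dist_scna))
})

test_that("fast clone distances agree with probe-level profiles", {
  cfg <- small_config()
  for (s in 1:10) {
    tree <- simulate_clone_tree(sample(2:5, 1), cfg, seed = s)
    expect_equal(apith:::clone_dist_fast(tree),
                 clone_profiles(tree)$dist_scna, tolerance = 1e-12)
  }
})

test_that("cohort simulation is deterministic and writes valid clinical data", {
  cfg <- small_config(n_patients = 30, k_min = 2, k_max = 6)
  c1 <- simulate_cohort(cfg, seed = 20)
  c2 <- simulate_cohort(cfg, seed = 20)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$apith, c2$apith)
  expect_true(all(c1$clinical$time > 0))
  expect_true(all(c1$clinical$event %in% 0:1))
  expect_equal(c1$apith$apith,
               vapply(c1$patients, function(p) apith(p$dist), numeric(1)))
})

test_that("full censoring yields zero events and the Cox fit refuses", {
  cfg <- small_config(n_patients = 25, censoring_rate = 1)
  coh <- simulate_cohort(cfg, seed = 21)
  expect_equal(sum(coh$clinical$event), 0)
  expect_error(fit_cox(coh$clinical, coh$apith, "os"), "no events")
})

test_that("true APITH is invariant in expectation to the drawn k-subset", {
  cfg <- small_config()
  cfg$branch_rate <- 6
  tree <- simulate_clone_tree(4, cfg, seed = 30)
  D <- apith:::clone_dist_fast(tree)
  set.seed(31)
  m3 <- mean(replicate(1500, apith(clone_lookup_draw(D, 3))))
  m7 <- mean(replicate(1500, apith(clone_lookup_draw(D, 7))))
  expect_lt(abs(m3 - m7) / mean(c(m3, m7)), 0.06)
})

test_that("patient writer emits the documented per-sample files", {
  cfg <- small_config()
  tree <- simulate_clone_tree(2, cfg, seed = 40, annotation = small_annotation())
  pt <- simulate_patient(tree, k = 2, cfg, seed = 41,
                         annotation = small_annotation())
  dir <- withr::local_tempdir()
  files <- write_patient(pt, dir, prefix = "pt")
  expect_true(all(file.exists(files)))
  tr <- read.delim(files[1])
  expect_named(tr, c("probe_id", "chrom", "pos", "lrr", "baf", "gt"))
  expect_equal(nrow(tr), cfg$n_probes)
})
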