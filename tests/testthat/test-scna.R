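test_that("a flat BAF track produces one segment per chromosome", {
  set.seed(1)
  n <- 2000
  chrom <- rep(1:2, each = n / 2)
  baf <- pmin(pmax(rnorm(n, 0.5, 0.02), 0), 1)
  seg <- segment_baf(baf, chrom, rep(TRUE, n))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start_idx, c(1L, 1001L))
  expect_equal(seg$end_idx, c(1000L, 2000L))
})

test_that("planted mirrored-BAF segments are recovered within 10 probes", {
  for (s in 1:5) {
    set.seed(s)
    mb <- c(rep(0, 400), rep(0.2, 300), rep(0, 300))
    baf <- 0.5 + sample(c(-1, 1), 1000, TRUE) * mb + rnorm(1000, 0, 0.02)
    baf <- pmin(pmax(baf, 0), 1)
    seg <- segment_baf(baf, rep(1L, 1000), rep(TRUE, 1000))
    expect_equal(nrow(seg), 3L)
    expect_lt(abs(seg$end_idx[1] - 400), 10.5)
    expect_lt(abs(seg$end_idx[2] - 700), 10.5)
  }
})

test_that("min_probes larger than any true segment merges everything", {
  set.seed(2)
  mb <- c(rep(0, 300), rep(0.2, 200), rep(0, 500))
  baf <- pmin(pmax(0.5 + sample(c(-1, 1), 1000, TRUE) * mb +
                     rnorm(1000, 0, 0.02), 0), 1)
  seg <- segment_baf(baf, rep(1L, 1000), rep(TRUE, 1000), min_probes = 600L)
  expect_equal(nrow(seg), 1L)
})

test_that("segment classification recovers AMP, DEL and copy-neutral LOH", {
  set.seed(3)
  n <- 2000
  is_het <- rep(TRUE, n)
  chrom <- rep(1L, n)
  # layout: neutral 1-800 | AMP 801-1300 (LRR +0.4) | LOH 1301-1700 | neutral
  mb <- c(rep(0, 800), rep(0.15, 500), rep(0.4, 400), rep(0, 300))
  baf <- pmin(pmax(0.5 + sample(c(-1, 1), n, TRUE) * mb + rnorm(n, 0, 0.02),
                   0), 1)
  lrr <- c(rep(0, 800), rep(0.4, 500), rep(0, 400), rep(0, 300)) +
    rnorm(n, 0, 0.15)
  seg <- segment_baf(baf, chrom, is_het)
  seg <- classify_segments(seg, lrr, baf, is_het)
  st <- rep(seg$status, seg$end_idx - seg$start_idx + 1L)
  expect_gt(mean(st[801:1300] == "AMP"), 0.95)
  expect_gt(mean(st[1301:1700] == "LOH"), 0.95)
  expect_gt(mean(st[c(1:800, 1701:2000)] == "NEUTRAL"), 0.95)
  # planted DEL: LRR shift -0.4
  lrr2 <- c(rep(0, 800), rep(-0.4, 500), rep(0, 400), rep(0, 300)) +
    rnorm(n, 0, 0.15)
  seg2 <- classify_segments(segment_baf(baf, chrom, is_het), lrr2, baf, is_het)
  st2 <- rep(seg2$status, seg2$end_idx - seg2$start_idx + 1L)
  expect_gt(mean(st2[801:1300] == "DEL"), 0.95)
})

test_that("alpha = 0 turns every BAF-deviant segment into LOH", {
  set.seed(4)
  n <- 1500
  mb <- c(rep(0, 700), rep(0.3, 400), rep(0, 400))
  baf <- pmin(pmax(0.5 + sample(c(-1, 1), n, TRUE) * mb + rnorm(n, 0, 0.02),
                   0), 1)
  lrr <- c(rep(0, 700), rep(0.5, 400), rep(0, 400)) + rnorm(n, 0, 0.1)
  seg <- classify_segments(segment_baf(baf, rep(1L, n), rep(TRUE, n)),
                           lrr, baf, rep(TRUE, n), alpha = 0)
  expect_true(all(seg$status %in% c("NEUTRAL", "LOH")))
  expect_true(any(seg$status == "LOH"))
})

test_that("classification contrasts are invariant to global LRR shifts", {
  set.seed(5)
  n <- 1500
  mb <- c(rep(0, 700), rep(0.3, 400), rep(0, 400))
  baf <- pmin(pmax(0.5 + sample(c(-1, 1), n, TRUE) * mb + rnorm(n, 0, 0.02),
                   0), 1)
  lrr <- c(rep(0, 700), rep(0.4, 400), rep(0, 400)) + rnorm(n, 0, 0.12)
  seg <- segment_baf(baf, rep(1L, n), rep(TRUE, n))
  s1 <- classify_segments(seg, lrr, baf, rep(TRUE, n))
  s2 <- classify_segments(seg, lrr + 5, baf, rep(TRUE, n))
  expect_identical(s1$status, s2$status)
  expect_equal(s1$p_adj, s2$p_adj, tolerance = 1e-8)
})

test_that("shrinking alpha never converts LOH into AMP or DEL", {
  set.seed(6)
  n <- 1500
  mb <- c(rep(0, 700), rep(0.25, 400), rep(0, 400))
  baf <- pmin(pmax(0.5 + sample(c(-1, 1), n, TRUE) * mb + rnorm(n, 0, 0.02),
                   0), 1)
  lrr <- c(rep(0, 700), rep(0.1, 400), rep(0, 400)) + rnorm(n, 0, 0.3)
  seg <- segment_baf(baf, rep(1L, n), rep(TRUE, n))
  alphas <- c(0.2, 0.05, 0.01, 0.001, 0)
  calls <- lapply(alphas, function(a)
    classify_segments(seg, lrr, baf, rep(TRUE, n), alpha = a)$status)
  for (i in seq_along(alphas)[-1]) {
    was_loh <- calls[[i - 1]] == "LOH"
    expect_true(all(calls[[i]][was_loh] == "LOH"))
  }
})

test_that("probe status vectors expand, detect gaps, and round-trip", {
  seg <- data.frame(start_idx = c(1L, 101L), end_idx = c(100L, 200L),
                    status = c("AMP", "NEUTRAL"), cn = c(4L, 2L))
  prof <- probe_status_vector(seg, 200L, "S1")
  expect_equal(prof$status, rep(c(3L, 2L), each = 100))
  expect_equal(prof$cn, rep(c(4L, 2L), each = 100))
  expect_error(probe_status_vector(seg[2:1, ][1, , drop = FALSE], 200L),
               "partition")
  gap <- data.frame(start_idx = c(1L, 120L), end_idx = c(100L, 200L),
                    status = c("AMP", "NEUTRAL"), cn = c(4L, 2L))
  expect_error(probe_status_vector(gap, 200L), "partition")
  back <- profile_to_segments(prof)
  expect_equal(back$start_idx, seg$start_idx)
  expect_equal(back$end_idx, seg$end_idx)
  expect_equal(back$status, seg$status)
})

test_that("driver SCNA rules fire exactly at CN >= 4 and CN = 0", {
  ann <- small_annotation()
  onc <- unique(ann$gene[ann$driver_class == "oncogene"])[1]
  tsg <- unique(ann$gene[ann$driver_class == "TSG"])[1]
  prof <- list(status = rep(2L, nrow(ann)), cn = rep(2L, nrow(ann)))
  prof$cn[ann$gene %in% onc] <- 4L
  prof$cn[ann$gene %in% tsg] <- 0L
  ev <- call_driver_scna(prof, ann)
  expect_setequal(ev$gene, c(onc, tsg))
  expect_equal(ev$event[ev$gene == onc], "amplification")
  expect_equal(ev$event[ev$gene == tsg], "deletion")
  # below-threshold copy numbers yield no events
  prof$cn[ann$gene %in% onc] <- 3L
  prof$cn[ann$gene %in% tsg] <- 1L
  expect_equal(nrow(call_driver_scna(prof, ann)), 0L)
})

test_that("end-to-end caller reaches 95% probe status accuracy", {
  ann <- small_annotation()
  cfg <- small_config()
  tree <- simulate_clone_tree(3, cfg, seed = 50, annotation = ann)
  pt <- simulate_patient(tree, k = 2, cfg, seed = 51, annotation = ann,
                         meth = FALSE)
  for (s in 1:2) {
    called <- call_scna(pt$tracks[[s]], purity = pt$purity[s])
    truth <- pt$profiles$status[pt$clone_of[s], ]
    expect_gt(mean(called$profile$status == truth), 0.95)
  }
})
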