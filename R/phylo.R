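#' Combine SCNA and methylation distances into a consensus matrix
#'
#' Each matrix is rescaled by its maximum entry so the two data types are
#' comparable, then averaged:
#' `d0_ij = 0.5 * (d1_ij / max(d1) + d2_ij / max(d2))`.
#' Samples present only in the SCNA matrix fall back to the normalized
#' SCNA term alone: `d0_ij = d1_ij / max(d1)`.
#'
#' @param d1 SCNA distance matrix (all samples).
#' @param d2 methylation distance matrix over a subset (or all) of the
#'   samples of `d1`, or `NULL`.
#' @return consensus symmetric matrix over the samples of `d1`, zero
#'   diagonal, entries in \[0, 1\].
#' @export
combine_distances <- function(d1, d2 = NULL) {
  d1 <- as.matrix(d1)
  if (max(d1) <= 0) stop("cannot normalize: max of the SCNA matrix is 0")
  d0 <- d1 / max(d1)
  if (!is.null(d2)) {
    d2 <- as.matrix(d2)
    if (max(d2) <= 0)
      stop("cannot normalize: max of the methylation matrix is 0")
    common <- intersect(rownames(d1), rownames(d2))
    if (is.null(rownames(d1)) || is.null(rownames(d2))) {
      if (!all(dim(d2) == dim(d1)))
        stop("unnamed matrices must have identical dimensions")
      common <- seq_len(nrow(d1))
    }
    if (length(common) >= 2) {
      n2 <- d2 / max(d2)
      d0[common, common] <- 0.5 * (d1[common, common] / max(d1) +
                                     n2[common, common])
    }
  }
  diag(d0) <- 0
  (d0 + t(d0)) / 2
}

#' Build a tumor phylogeny from a distance matrix
#'
#' Distance-based tree by balanced minimum evolution (FastME with NNI and
#' SPR refinement; neighbor joining as fallback engine). Negative branch
#' lengths are clamped to 0. Optionally rooted on a normal/reference leaf.
#'
#' @param d symmetric distance matrix with sample names (>= 3 leaves).
#' @param root_on optional leaf label to root the tree on (e.g. the normal
#'   sample).
#' @param engine `"bme"` (balanced minimum evolution) or `"nj"`.
#' @return an [ape::phylo] tree.
#' @export
build_tree <- function(d, root_on = NULL, engine = c("bme", "nj")) {
  engine <- match.arg(engine)
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("tree building needs at least 3 leaves")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("S%02d", seq_len(nrow(d)))
  }
  tr <- if (engine == "bme")
    ape::fastme.bal(d, nni = TRUE, spr = TRUE, tbr = FALSE)
  else ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(root_on)) {
    if (!root_on %in% tr$tip.label) stop("root leaf not in the tree")
    tr <- ape::root(tr, outgroup = root_on, resolve.root = TRUE)
  }
  tr
}

#' Congruence of SCNA and methylation pairwise distances
#'
#' Pools the within-patient sample-pair distances of the two data types and
#' computes their Spearman rank correlation; significance is assessed by a
#' Mantel-style permutation that relabels samples within each patient
#' independently. Cross-patient pairs are never used.
#'
#' @param d1_list,d2_list named lists of per-patient distance matrices; the
#'   two lists must cover the same patients with the same samples.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed for the permutations.
#' @return list with `rho` (pooled Spearman), `p` (permutation p-value or
#'   `NA`), `per_patient` (named vector of per-patient rho), `n_pairs`.
#' @export
congruence <- function(d1_list, d2_list, n_perm = 999L, seed = NULL) {
  stopifnot(length(d1_list) == length(d2_list))
  local_rng(seed)
  pool <- function(perm = FALSE) {
    v1 <- numeric(0)
    v2 <- numeric(0)
    for (i in seq_along(d1_list)) {
      a <- as.matrix(d1_list[[i]])
      b <- as.matrix(d2_list[[i]])
      stopifnot(all(dim(a) == dim(b)))
      if (perm) {
        pp <- sample.int(nrow(b))
        b <- b[pp, pp, drop = FALSE]
      }
      v1 <- c(v1, a[upper.tri(a)])
      v2 <- c(v2, b[upper.tri(b)])
    }
    list(v1 = v1, v2 = v2)
  }
  obs <- pool()
  if (length(obs$v1) < 3) stop("need at least 3 sample pairs")
  rho <- stats::cor(obs$v1, obs$v2, method = "spearman")
  per_patient <- vapply(seq_along(d1_list), function(i) {
    a <- as.matrix(d1_list[[i]])
    b <- as.matrix(d2_list[[i]])
    if (nrow(a) < 3) return(NA_real_)
    suppressWarnings(stats::cor(a[upper.tri(a)], b[upper.tri(b)],
                                method = "spearman"))
  }, numeric(1))
  names(per_patient) <- names(d1_list)
  p <- NA_real_
  if (n_perm > 0) {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      pm <- pool(perm = TRUE)
      rr <- suppressWarnings(stats::cor(pm$v1, pm$v2, method = "spearman"))
      if (!is.na(rr) && abs(rr) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(rho = rho, p = p, per_patient = per_patient,
       n_pairs = length(obs$v1))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the non-trivial bipartitions of two
#' unrooted trees on the same leaves, plus the normalized value (divided by
#' 2(n-3), the maximum for binary trees).
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return list with `rf` (count) and `rf_normalized`.
#' @export
tree_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  t1 <- ape::unroot(t1)
  t2 <- ape::unroot(t2)
  rf <- phangorn::RF.dist(t1, t2, normalize = FALSE)
  n <- length(t1$tip.label)
  denom <- 2 * (n - 3)
  list(rf = rf, rf_normalized = if (denom > 0) rf / denom else 0)
}

#' Probe masks for SCNA sensitivity analyses
#'
#' Probes with identical copy-number status across all of a patient's
#' samples ("homogeneous") or NEUTRAL in all samples ("neutral").
#'
#' @param status probes x samples status matrix.
#' @param type `"homogeneous"` or `"neutral"`.
#' @param neutral_code status code of NEUTRAL (default 2).
#' @return logical probe mask.
#' @export
probe_mask <- function(status, type = c("homogeneous", "neutral"),
                       neutral_code = 2L) {
  type <- match.arg(type)
  status <- as.matrix(status)
  same <- apply(status, 1L, function(r) all(r == r[1]))
  if (type == "homogeneous") same
  else same & status[, 1] == neutral_code
}
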