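#' Average pairwise intratumor heterogeneity (APITH)
#'
#' For a patient with k tumor samples and pairwise distances d_ij, APITH is
#' the average distance over all k(k-1)/2 sample pairs:
#' \deqn{APITH = \frac{2}{k(k-1)} \sum_{1 \le i < j \le k} d_{ij}.}
#' Being a U-statistic of degree 2, its expectation does not depend on k
#' (under exchangeable sampling of tumor regions), unlike "fraction of the
#' genome with private alterations" indices, which grow with k.
#'
#' @param d symmetric distance matrix (k x k, zero diagonal) or a `dist`.
#' @return the APITH value (scalar).
#' @export
apith <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  k <- nrow(d)
  if (k < 2) stop("APITH is undefined for fewer than 2 samples")
  up <- d[upper.tri(d)]
  if (any(is.na(up))) stop("distance matrix contains NA")
  if (any(up < 0)) stop("distances must be nonnegative")
  mean(up)
}

#' SCNA distance between two copy-number profiles
#'
#' The proportion of probes whose 4-level copy-number status (DEL / LOH /
#' NEUTRAL / AMP) differs between the two samples, optionally restricted to
#' a probe subset (e.g. driver-gene regions). Probes missing (NA) in either
#' profile are dropped pairwise, with the denominator reduced accordingly.
#'
#' @param p1,p2 per-probe status vectors over a shared probe set (integer
#'   codes or factors; compared with `!=`).
#' @param probe_subset optional integer/logical index restricting the
#'   comparison.
#' @return proportion in \[0, 1\].
#' @export
scna_distance <- function(p1, p2, probe_subset = NULL) {
  if (length(p1) != length(p2))
    stop("profiles must share one probe set (equal length)")
  if (!is.null(probe_subset)) {
    p1 <- p1[probe_subset]
    p2 <- p2[probe_subset]
  }
  ok <- !is.na(p1) & !is.na(p2)
  if (!any(ok)) stop("no probes left to compare")
  mean(p1[ok] != p2[ok])
}

#' Methylation distance between two beta profiles
#'
#' Euclidean distance over a probe set; with `scaled = TRUE`, the
#' root-mean-square difference (Euclidean norm divided by the square root
#' of the probe count), which makes distances comparable across genomic
#' regions with different probe counts.
#'
#' @param m1,m2 beta vectors on a shared probe set (purity-adjusted).
#' @param probe_subset optional index restricting the computation.
#' @param scaled return the per-probe-scaled (RMS) distance.
#' @return nonnegative scalar.
#' @export
methylation_distance <- function(m1, m2, probe_subset = NULL, scaled = FALSE) {
  if (length(m1) != length(m2)) stop("profiles must share one probe set")
  if (!is.null(probe_subset)) {
    m1 <- m1[probe_subset]
    m2 <- m2[probe_subset]
  }
  ok <- !is.na(m1) & !is.na(m2)
  if (!any(ok)) stop("empty probe subset")
  ss <- sum((m1[ok] - m2[ok])^2)
  if (scaled) sqrt(ss / sum(ok)) else sqrt(ss)
}

#' Pairwise distance matrix over a set of profiles
#'
#' @param x probes x samples matrix: integer status codes for
#'   `metric = "scna"`, betas for the methylation metrics.
#' @param metric `"scna"` (proportion of differing statuses),
#'   `"meth"` (Euclidean) or `"meth_rms"` (per-probe scaled).
#' @param probe_subset optional probe index.
#' @return symmetric matrix with the sample columns as dimnames; the
#'   `metric` is recorded in `attr(, "metric")`.
#' @export
distance_matrix <- function(x, metric = c("scna", "meth", "meth_rms"),
                            probe_subset = NULL) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (!is.null(probe_subset)) x <- x[probe_subset, , drop = FALSE]
  k <- ncol(x)
  d <- matrix(0, k, k, dimnames = list(colnames(x), colnames(x)))
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- switch(metric,
      scna = scna_distance(x[, i], x[, j]),
      meth = methylation_distance(x[, i], x[, j]),
      meth_rms = methylation_distance(x[, i], x[, j], scaled = TRUE))
  }
  attr(d, "metric") <- switch(metric, scna = "scna_proportion",
                              meth = "methylation_euclidean",
                              meth_rms = "methylation_rms")
  d
}

#' Naive ITH index (fraction of genome disrupted by private SCNAs)
#'
#' The fraction of probes that are non-NEUTRAL in at least one sample but do
#' not carry an identical non-NEUTRAL status across all samples. This index
#' grows with the number of samples k (more samples reveal more private
#' events), which is the bias APITH avoids.
#'
#' @param status probes x samples matrix of status codes (2 = NEUTRAL).
#' @param denominator `"genome"` (all probes; default) or `"disrupted"`
#'   (probes non-NEUTRAL in at least one sample).
#' @param neutral_code status code for NEUTRAL (default 2).
#' @return fraction in \[0, 1\].
#' @export
naive_ith <- function(status, denominator = c("genome", "disrupted"),
                      neutral_code = 2L) {
  denominator <- match.arg(denominator)
  status <- as.matrix(status)
  if (ncol(status) < 2) stop("naive ITH requires at least 2 samples")
  any_dis <- rowSums(status != neutral_code) > 0
  shared <- any_dis & apply(status, 1L, function(r) all(r == r[1]))
  private <- any_dis & !shared
  denom <- if (denominator == "genome") nrow(status) else sum(any_dis)
  if (denom == 0) return(0)
  sum(private) / denom
}

#' Estimate the pairwise-distance variance model of a cohort
#'
#' Under exchangeable sampling of regions within a tumor, APITH is a
#' U-statistic of degree 2 with variance
#' \deqn{Var(APITH | k) = \frac{\sigma^2_d + 2(k-2)c}{k(k-1)/2},}
#' where \eqn{\sigma^2_d} is the variance of a single pairwise distance and
#' c the covariance of two distances sharing one sample. Both are assumed
#' shared across patients and estimated by pooled method of moments: for
#' each patient the within-centered sum of squares and the sum of
#' cross-products over distance pairs sharing a sample have expectations
#' linear in (\eqn{\sigma^2_d}, c) with known finite-sample coefficients;
#' the pooled linear system is solved by least squares, making the
#' estimator unbiased despite the within-patient centering.
#'
#' @param dist_list list of per-patient symmetric distance matrices
#'   (patients with k = 2 contribute no information and are skipped).
#' @return object of class `apith_variance_model`: list with `sigma2_d`,
#'   `c`, `n_patients_used`, `method`.
#' @export
estimate_variance_model <- function(dist_list) {
  rows <- list()
  rhs <- numeric(0)
  used <- 0L
  for (d in dist_list) {
    d <- as.matrix(d)
    k <- nrow(d)
    if (k < 3) next
    used <- used + 1L
    m <- k * (k - 1) / 2
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    dv <- d[upper.tri(d)]
    e <- dv - mean(dv)
    A <- sum(e^2)
    # cross-products over unordered pairs of distance-pairs sharing exactly
    # one sample, via the per-sample sums T_s = sum of e over pairs
    # containing s:  sum_s T_s^2 = 2*sum(e^2) + 2*B
    Ts <- vapply(seq_len(k), function(s)
      sum(e[pairs[, 1] == s | pairs[, 2] == s]), numeric(1))
    B <- (sum(Ts^2) - 2 * A) / 2
    nshare <- k * (k - 1) * (k - 2) / 2
    # rows scaled by their term counts so patients with different k
    # contribute on comparable scales
    rows[[length(rows) + 1L]] <- c(1, -2 * (k - 2) / (m - 1))
    rhs <- c(rhs, A / (m - 1))
    rows[[length(rows) + 1L]] <- c(-1 / m, 1 - 2 * (k - 2) / m)
    rhs <- c(rhs, B / nshare)
  }
  if (!length(rows)) {
    warning("no patient with k >= 3: covariance term not estimable; ",
            "using between-patient distance variance with c = 0")
    dv <- unlist(lapply(dist_list, function(d) {
      d <- as.matrix(d)
      d[upper.tri(d)]
    }))
    return(structure(list(sigma2_d = stats::var(dv), c = 0,
                          n_patients_used = 0L, method = "fallback_pooled"),
                     class = "apith_variance_model"))
  }
  X <- do.call(rbind, rows)
  est <- as.numeric(stats::coef(stats::lm.fit(X, rhs)))
  s2 <- max(est[1], 1e-12)
  cc <- max(min(est[2], s2), -s2)
  structure(list(sigma2_d = s2, c = cc, n_patients_used = used,
                 method = "pooled_moments"),
            class = "apith_variance_model")
}

#' Variance of APITH for a patient with k samples
#'
#' @param k number of samples (scalar or vector, each >= 2).
#' @param model an `apith_variance_model`.
#' @return Var(APITH | k), vectorized over k. A sampling-noise-driven
#'   negative `c` estimate could make the formula nonpositive at large k;
#'   the result is floored at 5% of the `sigma2_d / m` term so downstream
#'   inverse-variance weights stay finite and positive.
#' @export
apith_variance <- function(k, model) {
  stopifnot(all(k >= 2))
  m <- k * (k - 1) / 2
  pmax((model$sigma2_d + 2 * (k - 2) * model$c) / m,
       0.05 * model$sigma2_d / m)
}

#' Jackknife variance of APITH (delete-one-sample)
#'
#' Alternative, per-patient variance estimate used to cross-validate the
#' pooled U-statistic model: recompute APITH leaving out one sample at a
#' time and apply the delete-1 jackknife formula. Because APITH is a
#' U-statistic of degree 2, the raw delete-1 jackknife is biased upward in
#' finite samples — its expectation is
#' \eqn{4(\sigma^2_d + (k-4)c) / (k(k-2))}, roughly twice the true
#' variance when \eqn{\sigma^2_d} dominates. With `correct = TRUE` (the
#' default) the jackknife value is combined with the within-patient
#' distance variance to solve for (\eqn{\sigma^2_d}, c) per patient and
#' plug them into the exact variance formula; the corrected estimator is
#' unbiased for k >= 4 (at k = 3 the two moments coincide and c is taken
#' as 0, leaving a bias of order c).
#'
#' @param d symmetric distance matrix (k >= 3).
#' @param correct apply the finite-sample bias correction.
#' @return variance estimate (scalar).
#' @export
apith_variance_jackknife <- function(d, correct = TRUE) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (k < 3) stop("jackknife requires k >= 3")
  m <- k * (k - 1) / 2
  loo <- vapply(seq_len(k), function(i) apith(d[-i, -i, drop = FALSE]),
                numeric(1))
  vj <- (k - 1) / k * sum((loo - mean(loo))^2)
  if (!correct) return(vj)
  dv <- d[upper.tri(d)]
  s2 <- stats::var(dv) # expectation sigma2 - 4c/(k+1)
  v1 <- vj * k * (k - 2) / 4 # expectation sigma2 + (k-4)c
  if (k == 3) return(max(v1, 0) / m) # sigma2 and c not separable: biased O(c)
  if (k == 4) return(max(6 * v1 - 5 * s2, 0) / 6) # exact linear solution
  cc <- (v1 - s2) / ((k - 4) + 4 / (k + 1))
  sig2 <- max(s2 + 4 * cc / (k + 1), 0)
  cc <- max(min(cc, sig2), -sig2)
  (sig2 + 2 * (k - 2) * cc) / m
}

#' Jackknife-moment variance model for a cohort
#'
#' Cross-validates the pooled method-of-moments model with an estimator
#' built from different moments: for every patient with k >= 3, the
#' delete-1 jackknife of APITH (expectation
#' \eqn{4(\sigma^2_d + (k-4)c)/(k(k-2))}) and the within-patient distance
#' variance (expectation \eqn{\sigma^2_d - 4c/(k+1)}) contribute two
#' linear equations in (\eqn{\sigma^2_d}, c); the stacked system is solved
#' by least squares. With a mix of sample counts the two parameters are
#' identified, so the resulting [apith_variance()] predictions are
#' unbiased at every k (including k = 3, where the single-patient
#' jackknife is not).
#'
#' @param dist_list list of per-patient symmetric distance matrices.
#' @return an `apith_variance_model` (method tag "jackknife_moments").
#' @export
estimate_variance_model_jackknife <- function(dist_list) {
  rows <- list()
  rhs <- numeric(0)
  used <- 0L
  for (d in dist_list) {
    d <- as.matrix(d)
    k <- nrow(d)
    if (k < 3) next
    used <- used + 1L
    loo <- vapply(seq_len(k), function(i) apith(d[-i, -i, drop = FALSE]),
                  numeric(1))
    vj <- (k - 1) / k * sum((loo - mean(loo))^2)
    dv <- d[upper.tri(d)]
    rows[[length(rows) + 1L]] <- c(1, k - 4)
    rhs <- c(rhs, vj * k * (k - 2) / 4)
    rows[[length(rows) + 1L]] <- c(1, -4 / (k + 1))
    rhs <- c(rhs, stats::var(dv))
  }
  if (!length(rows)) stop("no patient with k >= 3")
  est <- as.numeric(stats::coef(stats::lm.fit(do.call(rbind, rows), rhs)))
  if (anyNA(est)) { # all k = 3: the two moment rows coincide
    warning("c not identifiable from this cohort (all k = 3); using c = 0")
    est <- c(mean(rhs), 0)
  }
  s2 <- max(est[1], 1e-12)
  cc <- max(min(est[2], s2), -s2)
  structure(list(sigma2_d = s2, c = cc, n_patients_used = used,
                 method = "jackknife_moments"),
            class = "apith_variance_model")
}

#' Precision weights for a cohort of APITH estimates
#'
#' Patients with more tumor samples have more precise APITH estimates and
#' are weighted up in association analyses. By default weight_i is
#' proportional to the inverse *total* variance
#' `1 / (V_between + Var(APITH_i | k_i))`, where `V_between` is the
#' between-patient variance of true ITH (estimated as the cohort variance
#' of the APITH values minus the mean within-patient sampling variance,
#' floored at 10% of the cohort variance). This is the efficient weighting
#' for a covariate measured with heteroscedastic error — the same form as
#' random-effects meta-analysis weights: once sampling noise is small
#' relative to the biological spread, further precision buys little, so
#' weights flatten instead of exploding. `between = "none"` gives the raw
#' inverse sampling variance `1 / Var(APITH_i | k_i)`.
#'
#' Extreme weights (from noisy or degenerate variance-model estimates)
#' destabilize the weighted partial likelihood; as in survey practice they
#' are trimmed: weights above `trim` times the mean are capped, then the
#' vector is renormalized to mean 1.
#'
#' @param k vector of per-patient sample counts.
#' @param model an `apith_variance_model`; if missing, estimated from
#'   `dist_list`.
#' @param dist_list optional list of per-patient distance matrices; also
#'   used to compute APITH values for the between-patient variance when
#'   `apith_values` is not given.
#' @param apith_values per-patient APITH estimates (same order as `k`),
#'   needed for the default total-variance weighting.
#' @param between `"auto"` (total-variance weights, default) or `"none"`
#'   (raw inverse sampling variance).
#' @param trim cap on the weight-to-mean ratio (`Inf` disables trimming).
#' @return numeric vector of weights (mean 1).
#' @export
apith_weights <- function(k, model = NULL, dist_list = NULL,
                          apith_values = NULL, between = c("auto", "none"),
                          trim = 10) {
  between <- match.arg(between)
  if (is.null(model)) {
    if (is.null(dist_list)) stop("supply a variance model or dist_list")
    model <- estimate_variance_model(dist_list)
  }
  v <- apith_variance(k, model)
  if (between == "auto") {
    if (is.null(apith_values)) {
      if (is.null(dist_list))
        stop("total-variance weights need apith_values (or dist_list)")
      apith_values <- vapply(dist_list, apith, numeric(1))
    }
    v_tot <- stats::var(apith_values)
    v_b <- max(v_tot - mean(v), 0.1 * v_tot)
    w <- 1 / (v_b + v)
  } else {
    w <- 1 / v
  }
  w <- w / mean(w)
  w <- pmin(w, trim)
  w / mean(w)
}

#' Regression-calibrated APITH values
#'
#' APITH estimates carry heteroscedastic sampling noise (more samples,
#' less noise), which attenuates hazard-ratio estimates when APITH enters
#' a regression as a covariate. Regression calibration replaces each
#' estimate by its best linear predictor of the patient's true ITH,
#' shrinking toward the cohort mean by the per-patient reliability
#' `lambda_i = V_between / (V_between + Var(APITH_i | k_i))`, and scales
#' by the estimated sd of true ITH, so a coefficient on the calibrated
#' value is a log hazard ratio per sd of *true* ITH, approximately free of
#' attenuation.
#'
#' @param apith_values per-patient APITH estimates.
#' @param k per-patient sample counts.
#' @param model an `apith_variance_model`.
#' @return list with `x` (calibrated, standardized values),
#'   `v_between` (estimated between-patient variance of true ITH) and
#'   `reliability` (per-patient lambda).
#' @export
calibrate_apith <- function(apith_values, k, model) {
  stopifnot(length(apith_values) == length(k))
  vi <- apith_variance(k, model)
  vt <- stats::var(apith_values)
  vb <- max(vt - mean(vi), 0.1 * vt)
  lam <- vb / (vb + vi)
  list(x = lam * (apith_values - mean(apith_values)) / sqrt(vb),
       v_between = vb, reliability = lam)
}

#' Per-region methylation APITH
#'
#' For each genomic region class (CpG context, gene context, or driver
#' class), selects the top 10% most variable probes in the region (variance
#' across tumor samples), computes per-probe-scaled (RMS) pairwise
#' distances within each patient, and averages them into a per-patient,
#' per-region APITH. Regions contributing fewer than `min_probes` probes
#' are skipped with a warning.
#'
#' @param beta probes x samples matrix of purity-adjusted tumor betas.
#' @param patient_of character/factor of length ncol(beta): patient of each
#'   sample column.
#' @param annotation probe annotation table.
#' @param region_by which annotation column defines regions:
#'   `"cpg_context"`, `"gene_context"` or `"driver_class"`.
#' @param top_frac fraction of most-variable probes retained per region.
#' @param min_probes minimum region probe count.
#' @return data.frame with columns `patient_id`, `region`, `k`, `apith`.
#' @export
region_apith <- function(beta, patient_of, annotation,
                         region_by = c("cpg_context", "gene_context",
                                       "driver_class"),
                         top_frac = 0.1, min_probes = 10L) {
  region_by <- match.arg(region_by)
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == nrow(annotation),
            length(patient_of) == ncol(beta))
  regions <- unique(annotation[[region_by]])
  regions <- regions[!is.na(regions)]
  out <- list()
  for (rg in regions) {
    idx <- which(annotation[[region_by]] == rg)
    if (length(idx) < min_probes) {
      warning(sprintf("region '%s' has < %d probes; skipped", rg, min_probes))
      next
    }
    n_top <- max(1L, floor(top_frac * length(idx)))
    sel <- idx[select_top_variable(beta[idx, , drop = FALSE], n_top)]
    for (p in unique(patient_of)) {
      cols <- which(patient_of == p)
      if (length(cols) < 2) next
      d <- distance_matrix(beta[, cols, drop = FALSE], metric = "meth_rms",
                           probe_subset = sel)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, region = rg, k = length(cols), apith = apith(d),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-sample t-test between region APITH groups
#'
#' Unpaired two-sided t-test comparing per-patient APITH values of two
#' region groups (e.g. promoter vs non-promoter contexts).
#'
#' @param region_df output of [region_apith()].
#' @param regions_a,regions_b character vectors of region labels in each
#'   group.
#' @return the `htest` object from [stats::t.test()].
#' @export
region_apith_test <- function(region_df, regions_a, regions_b) {
  a <- region_df$apith[region_df$region %in% regions_a]
  b <- region_df$apith[region_df$region %in% regions_b]
  stats::t.test(a, b)
}

#' Classify multi-region events as public or private
#'
#' An event (e.g. an SNV) is public within a patient if every tumor sample
#' of that patient carries it, private otherwise.
#'
#' @param events data.frame with columns `patient_id`, `sample_id`,
#'   `event_id`, `present` (logical or 0/1). Every sample of a patient must
#'   appear for every event considered (absent rows count as not carried
#'   only if `samples_per_patient` is supplied).
#' @param samples_per_patient optional named vector giving the number of
#'   tumor samples per patient; defaults to the number of distinct
#'   `sample_id`s seen per patient.
#' @return data.frame `patient_id`, `event_id`, `n_carrying`, `k`,
#'   `classification` ("public"/"private").
#' @export
classify_public_private <- function(events, samples_per_patient = NULL) {
  stopifnot(all(c("patient_id", "sample_id", "event_id", "present")
                %in% names(events)))
  if (is.null(samples_per_patient)) {
    tab <- tapply(events$sample_id, events$patient_id,
                  function(s) length(unique(s)))
    samples_per_patient <- tab
  }
  if (any(samples_per_patient < 2))
    stop("public/private labels are undefined for patients with one sample")
  key <- interaction(events$patient_id, events$event_id, drop = TRUE)
  n_car <- tapply(as.logical(events$present), key, sum)
  pid <- tapply(as.character(events$patient_id), key, `[`, 1L)
  eid <- tapply(as.character(events$event_id), key, `[`, 1L)
  k <- as.numeric(samples_per_patient[pid])
  data.frame(patient_id = unname(pid), event_id = unname(eid),
             n_carrying = as.integer(n_car), k = as.integer(k),
             classification = ifelse(n_car == k, "public", "private"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter somatic variant calls
#'
#' Keeps calls with variant allele count > 3, coverage > 2 in both tumor
#' and normal, and variant allele fraction >= 0.1 (strict/inclusive exactly
#' as stated).
#'
#' @param variants data.frame with columns `alt_count`, `depth_tumor`,
#'   `depth_normal`, `vaf` (other columns pass through).
#' @return the filtered data.frame (possibly zero rows).
#' @export
filter_somatic_variants <- function(variants) {
  need <- c("alt_count", "depth_tumor", "depth_normal", "vaf")
  stopifnot(all(need %in% names(variants)))
  keep <- variants$alt_count > 3 &
    variants$depth_tumor > 2 &
    variants$depth_normal > 2 &
    variants$vaf >= 0.1
  variants[which(keep), , drop = FALSE]
}
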