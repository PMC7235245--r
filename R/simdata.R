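#' Status codes used for copy-number profiles
#'
#' Per-probe SCNA status is stored as an integer code: 0 = DEL, 1 = LOH,
#' 2 = NEUTRAL, 3 = AMP (the order used in the exported status matrices).
#' @return character vector of the four status labels in code order.
#' @export
status_levels <- function() c("DEL", "LOH", "NEUTRAL", "AMP")

#' Simulation configuration
#'
#' Collects all tunable parameters of the synthetic multi-region tumor
#' cohort generator. Defaults emulate the study conditions of a
#' multi-region lung adenocarcinoma cohort: 2 to 11 tumor samples per
#' patient, tumor purity at least 50%, desk-scale probe counts, and SCNA
#' divergence spread producing a cohort APITH distribution with mean near
#' 0.18.
#'
#' @param n_patients cohort size.
#' @param n_probes number of array probes (shared by SCNA and methylation
#'   tracks).
#' @param n_chrom number of chromosomes.
#' @param k_min,k_max range of tumor samples per patient (uniform draw).
#' @param n_clones_range range of clone counts per patient tree.
#' @param founder_rate expected number of truncal (public) SCNA events.
#' @param branch_rate_range range of the per-branch expected private SCNA
#'   event count; drawn per patient to spread true ITH across the cohort.
#' @param seg_frac_mean,seg_frac_min segment length distribution, as
#'   fractions of the probe set (scale-free in the probe count, so the
#'   same configuration yields the same ITH at any `n_probes`).
#' @param scna_type_probs probabilities of event types DEL (CN=1), LOH
#'   (copy-neutral), AMP (CN=3), AMP (CN=4+).
#' @param driver_event_prob probability per branch of a targeted driver
#'   event (oncogene amplification to CN>=4 or TSG homozygous deletion).
#' @param meth_founder_rate,meth_branch_rate expected methylation shift
#'   events on the trunk / per branch.
#' @param meth_event_probes probes affected by one methylation shift event.
#' @param meth_delta_range absolute delta-beta range of one shift event.
#' @param meth_driver_prob probability that a methylation event targets a
#'   driver gene promoter island (hypermethylation).
#' @param het_frac fraction of array probes heterozygous in the germline.
#' @param baf_noise_sd,lrr_noise_sd,beta_noise_sd technical noise (sd).
#' @param purity_range tumor purity range (uniform draw per sample).
#' @param gamma LRR compression factor (Illumina-type arrays ~0.55).
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param beta_ith log hazard ratio per standard deviation of true ITH
#'   for overall survival.
#' @param beta_ith_met log hazard ratio per sd of true ITH for distant
#'   metastasis.
#' @param censoring_rate target fraction of censored survival times.
#' @param corr_k_ith if `TRUE`, sample count k is drawn higher for
#'   patients with higher true ITH (to probe confounding by k).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100L,
                       n_probes = 20000L,
                       n_chrom = 4L,
                       k_min = 2L, k_max = 11L,
                       n_clones_range = c(2L, 5L),
                       founder_rate = 3,
                       branch_rate_range = c(0, 12),
                       seg_frac_mean = 0.05, seg_frac_min = 0.004,
                       scna_type_probs = c(DEL = 0.35, LOH = 0.30,
                                           AMP3 = 0.20, AMP4 = 0.15),
                       driver_event_prob = 0.25,
                       meth_founder_rate = 4,
                       meth_branch_rate = 3,
                       meth_event_probes = 40,
                       meth_delta_range = c(0.15, 0.45),
                       meth_driver_prob = 0.2,
                       het_frac = 1 / 3,
                       baf_noise_sd = 0.03,
                       lrr_noise_sd = 0.15,
                       beta_noise_sd = 0.02,
                       purity_range = c(0.5, 0.95),
                       gamma = 0.55,
                       baseline_hazard = 0.01,
                       beta_ith = log(1.5),
                       beta_ith_met = 0.8 * log(1.5),
                       censoring_rate = 0.3,
                       corr_k_ith = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$n_probes >= 100, cfg$k_min >= 2,
            cfg$k_max >= cfg$k_min, all(cfg$scna_type_probs >= 0),
            cfg$founder_rate >= 0, all(cfg$branch_rate_range >= 0),
            cfg$censoring_rate >= 0, cfg$censoring_rate <= 1,
            all(cfg$purity_range > 0), all(cfg$purity_range <= 1),
            cfg$het_frac > 0, cfg$het_frac < 1)
  cfg$scna_type_probs <- cfg$scna_type_probs / sum(cfg$scna_type_probs)
  class(cfg) <- "sim_config"
  cfg
}

# chromosome block of each probe index (matches simulate_probe_annotation)
probe_chrom <- function(n_probes, n_chrom) {
  sort(rep_len(seq_len(n_chrom), n_probes))
}

# draw `n` SCNA events (probe range + status + copy number); vectorized;
# `clone` is a scalar or a length-n vector of owning clones
draw_scna_events <- function(config, clone, n) {
  if (n == 0L) return(NULL)
  np <- config$n_probes
  chrom_size <- tabulate(probe_chrom(np, config$n_chrom), config$n_chrom)
  chrom_lo <- cumsum(c(0L, utils::head(chrom_size, -1L))) + 1L
  cc <- sample.int(config$n_chrom, n, replace = TRUE)
  len_min <- max(2L, round(config$seg_frac_min * np))
  len_mean <- max(len_min + 1L, round(config$seg_frac_mean * np))
  len <- len_min + stats::rgeom(n, 1 / (len_mean - len_min))
  len <- pmin(len, chrom_size[cc])
  start <- chrom_lo[cc] +
    floor(stats::runif(n) * (chrom_size[cc] - len + 1L))
  type <- sample(names(config$scna_type_probs), n, replace = TRUE,
                 prob = config$scna_type_probs)
  status <- c(DEL = "DEL", LOH = "LOH", AMP3 = "AMP", AMP4 = "AMP")[type]
  cn <- ifelse(type == "DEL", 1L,
        ifelse(type == "LOH", 2L,
        ifelse(type == "AMP3", 3L, sample(4:5, n, replace = TRUE))))
  # plain-list data.frame construction (hot path: one call per clone tree)
  structure(list(clone = rep_len(clone, n), chrom = cc,
                 start_idx = as.integer(start),
                 end_idx = as.integer(start + len - 1L),
                 status = unname(status), cn = as.integer(cn)),
            class = "data.frame", row.names = c(NA_integer_, -n))
}

# targeted driver event at a random oncogene (amplification) or TSG
# (homozygous deletion nested in a wider hemizygous loss)
draw_driver_event <- function(config, clone, annotation) {
  chrom_vec <- probe_chrom(config$n_probes, config$n_chrom)
  onc <- annotation$driver_class == "oncogene"
  tsg <- annotation$driver_class == "TSG"
  as_amp <- stats::runif(1) < 0.5
  idx <- if (as_amp) which(onc) else which(tsg)
  if (!length(idx)) return(NULL)
  g <- sample(unique(annotation$gene[idx]), 1L)
  gi <- range(which(annotation$gene %in% g))
  cc <- chrom_vec[gi[1]]
  bounds <- range(which(chrom_vec == cc))
  pad <- function(p) c(max(bounds[1], gi[1] - p), min(bounds[2], gi[2] + p))
  if (as_amp) {
    r <- pad(120L)
    data.frame(clone = clone, chrom = cc, start_idx = r[1], end_idx = r[2],
               status = "AMP", cn = sample(4:5, 1L), stringsAsFactors = FALSE)
  } else {
    outer <- pad(300L)
    inner <- pad(60L)
    rbind(
      data.frame(clone = clone, chrom = cc, start_idx = outer[1],
                 end_idx = outer[2], status = "DEL", cn = 1L,
                 stringsAsFactors = FALSE),
      data.frame(clone = clone, chrom = cc, start_idx = inner[1],
                 end_idx = inner[2], status = "DEL", cn = 0L,
                 stringsAsFactors = FALSE))
  }
}

# draw methylation shift events for one clone
draw_meth_events <- function(config, clone, n_events, annotation) {
  if (n_events == 0L) return(NULL)
  out <- vector("list", n_events)
  pil <- if (!is.null(annotation))
    promoter_island_probes(annotation, driver_only = TRUE) else list()
  for (e in seq_len(n_events)) {
    if (length(pil) && stats::runif(1) < config$meth_driver_prob) {
      g <- sample(names(pil), 1L)
      probes <- pil[[g]]
      delta <- stats::runif(1, 0.35, 0.5) # promoter hypermethylation
      gene <- g
    } else {
      w <- max(2L, stats::rpois(1L, config$meth_event_probes))
      start <- sample.int(config$n_probes - w, 1L)
      probes <- start:(start + w - 1L)
      delta <- sample(c(-1, 1), 1L) *
        stats::runif(1, config$meth_delta_range[1], config$meth_delta_range[2])
      gene <- NA_character_
    }
    out[[e]] <- data.frame(clone = clone, probe = probes, delta = delta,
                           gene = gene, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a clone tree with SCNA and methylation events
#'
#' Draws a random rooted clone tree. The founder clone carries truncal
#' ("public") events present in every descendant; each non-founder clone
#' adds private events at the configured rates. Events accumulate along
#' the root-to-clone path, later events overriding earlier ones on
#' overlapping probes.
#'
#' @param n_clones number of clones (>= 1); clone 1 is the founder.
#' @param config a [sim_config()]; `founder_rate` and `branch_rate` set the
#'   expected event counts. A scalar `config$branch_rate` may be set
#'   directly; otherwise the midpoint of `branch_rate_range` is used.
#' @param seed integer seed (optional).
#' @param annotation optional probe annotation enabling targeted driver
#'   events.
#' @return object of class `clone_tree`: list with `n_clones`, `parent`,
#'   `scna_events`, `meth_events`, `config`.
#' @export
simulate_clone_tree <- function(n_clones, config = sim_config(), seed = NULL,
                                annotation = NULL) {
  if (length(n_clones) != 1L || is.na(n_clones) || n_clones < 1)
    stop("n_clones must be a positive integer")
  n_clones <- as.integer(n_clones)
  local_rng(seed)
  branch_rate <- if (!is.null(config[["branch_rate"]])) config[["branch_rate"]]
                 else mean(config$branch_rate_range)
  parent <- c(NA_integer_,
              if (n_clones > 1L)
                vapply(2:n_clones, function(i) sample.int(i - 1L, 1L),
                       integer(1)))

  ev <- list()
  counts <- c(stats::rpois(1L, config$founder_rate),
              if (n_clones > 1L) stats::rpois(n_clones - 1L, branch_rate))
  ev[[1L]] <- draw_scna_events(config, rep(seq_len(n_clones), counts),
                               sum(counts))
  if (!is.null(annotation)) for (cl in seq_len(n_clones))
    if (stats::runif(1) < config$driver_event_prob)
      ev[[length(ev) + 1L]] <- draw_driver_event(config, cl, annotation)
  scna_events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(clone = integer(), chrom = integer(), start_idx = integer(),
               end_idx = integer(), status = character(), cn = integer(),
               stringsAsFactors = FALSE)

  me <- list()
  me[[1L]] <- draw_meth_events(config, 1L,
                               stats::rpois(1L, config$meth_founder_rate),
                               annotation)
  if (n_clones > 1L) for (cl in 2:n_clones)
    me[[length(me) + 1L]] <-
      draw_meth_events(config, cl, stats::rpois(1L, config$meth_branch_rate),
                       annotation)
  meth_events <- do.call(rbind, me)

  structure(list(n_clones = n_clones, parent = parent,
                 scna_events = scna_events, meth_events = meth_events,
                 config = config),
            class = "clone_tree")
}

# Exact clone-pair SCNA distance matrix computed on the partition induced
# by event breakpoints (no per-probe materialization); agrees with
# clone_profiles()$dist_scna.
clone_dist_fast <- function(tree) {
  C <- tree$n_clones
  ev <- tree$scna_events
  np <- tree$config$n_probes
  D <- matrix(0, C, C)
  if (is.null(ev) || !nrow(ev) || C < 2) return(D)
  cuts <- sort(unique(c(0L, ev$start_idx - 1L, ev$end_idx, np)))
  len <- diff(cuts)
  M <- length(len) # interval j spans probes (cuts[j], cuts[j+1]]
  s_int <- match(ev$start_idx - 1L, cuts)
  e_int <- match(ev$end_idx, cuts) - 1L
  codes <- c(DEL = 0L, LOH = 1L, NEUTRAL = 2L, AMP = 3L)
  ev_code <- unname(codes[ev$status])
  st <- matrix(2L, C, M)
  for (cl in seq_len(C)) {
    path <- clone_path(tree, cl)
    rows <- which(ev$clone %in% path)
    rows <- rows[order(match(ev$clone[rows], path))]
    v <- rep(2L, M)
    for (r in rows) v[s_int[r]:e_int[r]] <- ev_code[r]
    st[cl, ] <- v
  }
  for (a in 1:(C - 1)) for (b in (a + 1):C)
    D[a, b] <- D[b, a] <- sum(len[st[a, ] != st[b, ]]) / np
  D
}

# clones on the path root -> clone, in order
clone_path <- function(tree, clone) {
  path <- clone
  while (!is.na(tree$parent[path[1]])) path <- c(tree$parent[path[1]], path)
  path
}

#' Materialize per-clone genomic profiles from a clone tree
#'
#' @param tree a `clone_tree`.
#' @param beta_normal optional normal methylation profile (numeric vector of
#'   length `n_probes`); when supplied, clone beta profiles are returned.
#' @return list with `status` (clones x probes integer matrix, codes of
#'   [status_levels()]), `cn` (clones x probes), `beta` (clones x probes or
#'   `NULL`), and `dist_scna` / `dist_meth` clone-pair distance matrices.
#' @export
clone_profiles <- function(tree, beta_normal = NULL) {
  np <- tree$config$n_probes
  C <- tree$n_clones
  status <- matrix(2L, C, np) # NEUTRAL
  cn <- matrix(2L, C, np)
  codes <- c(DEL = 0L, LOH = 1L, NEUTRAL = 2L, AMP = 3L)
  ev_clone <- tree$scna_events$clone
  ev_s <- tree$scna_events$start_idx
  ev_e <- tree$scna_events$end_idx
  ev_code <- unname(codes[tree$scna_events$status])
  ev_cn <- tree$scna_events$cn
  for (cl in seq_len(C)) {
    path <- clone_path(tree, cl)
    rows <- which(ev_clone %in% path)
    rows <- rows[order(match(ev_clone[rows], path))] # path order: later wins
    st_cl <- rep(2L, np)
    cn_cl <- rep(2L, np)
    for (r in rows) {
      idx <- ev_s[r]:ev_e[r]
      st_cl[idx] <- ev_code[r]
      cn_cl[idx] <- ev_cn[r]
    }
    status[cl, ] <- st_cl
    cn[cl, ] <- cn_cl
  }
  beta <- NULL
  if (!is.null(beta_normal)) {
    stopifnot(length(beta_normal) == np)
    beta <- matrix(rep(beta_normal, each = C), C, np)
    me <- tree$meth_events
    if (!is.null(me) && nrow(me)) {
      for (cl in seq_len(C)) {
        path <- clone_path(tree, cl)
        b_cl <- beta[cl, ]
        rows <- which(me$clone %in% path)
        if (length(rows)) {
          add <- tapply(me$delta[rows], me$probe[rows], sum)
          pr <- as.integer(names(add))
          b_cl[pr] <- b_cl[pr] + as.numeric(add)
        }
        beta[cl, ] <- b_cl
      }
      beta <- pmin(pmax(beta, 0), 1)
    }
  }
  d_scna <- matrix(0, C, C)
  d_meth <- if (!is.null(beta)) matrix(0, C, C) else NULL
  if (C > 1L) for (a in 1:(C - 1L)) for (b in (a + 1L):C) {
    d_scna[a, b] <- d_scna[b, a] <- mean(status[a, ] != status[b, ])
    if (!is.null(beta))
      d_meth[a, b] <- d_meth[b, a] <- sqrt(sum((beta[a, ] - beta[b, ])^2))
  }
  list(status = status, cn = cn, beta = beta,
       dist_scna = d_scna, dist_meth = d_meth)
}

#' Simulate one multi-region patient
#'
#' Draws k tumor samples from a clone tree: each sample takes the profile of
#' one clone (drawn uniformly) and is observed at a per-sample tumor purity.
#' Probe-level SNP-array tracks (BAF/LRR around the germline genotypes) and
#' methylation beta profiles (purity-weighted tumor/normal mixture) are
#' generated on request.
#'
#' The observed beta of a tumor sample is
#' `pi * beta_clone + (1 - pi) * beta_normal + noise`; BAF of a probe with
#' tumor B-allele count nB and total copy number c is
#' `(pi*nB + (1-pi)*nB_germline) / (pi*c + (1-pi)*2)` plus truncated
#' Gaussian noise, and LRR is `gamma * log2(c_mix / 2)` plus noise.
#'
#' @param tree a `clone_tree`.
#' @param k number of tumor samples (>= 2).
#' @param config a [sim_config()].
#' @param seed integer seed (optional).
#' @param annotation probe annotation (required when `tracks` or `meth`).
#' @param tracks generate probe-level BAF/LRR tracks.
#' @param meth generate methylation profiles.
#' @return object of class `patient_sim`: clone assignment, purity,
#'   noise-free true distance matrices and true APITH per metric, latent
#'   expected ITH `theta_*`, plus `tracks` (list of per-sample data.frames),
#'   `beta` (probes x samples), `beta_normal`, `beta_normal_obs`,
#'   `germline_gt`, and per-clone ground truth (`profiles`).
#' @export
simulate_patient <- function(tree, k, config = tree$config, seed = NULL,
                             annotation = NULL, tracks = TRUE, meth = TRUE) {
  if (length(k) != 1L || is.na(k) || k < 2) stop("k must be >= 2")
  k <- as.integer(k)
  local_rng(seed)
  np <- config$n_probes
  purity <- stats::runif(k, config$purity_range[1], config$purity_range[2])
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")

  beta_normal <- NULL
  if ((meth || tracks) && is.null(annotation) && meth)
    stop("annotation is required to generate methylation profiles")
  if (meth) beta_normal <- simulate_normal_beta(annotation,
                                                seed = sample.int(2^30, 1L))
  prof <- clone_profiles(tree, beta_normal)
  clone_of <- sample.int(tree$n_clones, k, replace = TRUE)
  sample_ids <- sprintf("S%02d", seq_len(k))

  true_dist_scna <- prof$dist_scna[clone_of, clone_of, drop = FALSE]
  dimnames(true_dist_scna) <- list(sample_ids, sample_ids)
  true_dist_meth <- NULL
  if (!is.null(prof$dist_meth)) {
    true_dist_meth <- prof$dist_meth[clone_of, clone_of, drop = FALSE]
    dimnames(true_dist_meth) <- list(sample_ids, sample_ids)
  }
  theta_scna <- mean(prof$dist_scna)
  theta_meth <- if (!is.null(prof$dist_meth)) mean(prof$dist_meth) else NA_real_

  germline_gt <- sample(c("AA", "AB", "BB"), np, replace = TRUE,
                        prob = c((1 - config$het_frac) / 2, config$het_frac,
                                 (1 - config$het_frac) / 2))
  nB_n <- c(AA = 0L, AB = 1L, BB = 2L)[germline_gt]
  # phase: whether the B allele sits on the haplotype that events treat as
  # "major"; a property of the patient's genome, shared by all samples
  b_on_major <- stats::runif(np) < 0.5

  track_list <- NULL
  if (tracks) {
    chrom_vec <- probe_chrom(np, config$n_chrom)
    pos <- if (!is.null(annotation)) annotation$pos else seq_len(np) * 1000L
    pid <- if (!is.null(annotation)) annotation$probe_id else
      sprintf("p%06d", seq_len(np))
    track_list <- vector("list", k)
    names(track_list) <- sample_ids
    for (s in seq_len(k)) {
      cl <- clone_of[s]
      pi_s <- purity[s]
      cn_t <- prof$cn[cl, ]
      st <- prof$status[cl, ]
      # allele split (major, minor) per probe given status/copy number
      minor <- ifelse(st == 2L & cn_t == 2L, 1L,
               ifelse(st == 3L, 1L, 0L))
      major <- cn_t - minor
      # B-allele count in tumor: hets follow the patient-level phase;
      # homs keep their single allele
      nB_t <- ifelse(germline_gt == "AB",
                     ifelse(b_on_major, major, minor),
                     ifelse(germline_gt == "BB", cn_t, 0L))
      cn_mix <- pi_s * cn_t + (1 - pi_s) * 2
      baf <- (pi_s * nB_t + (1 - pi_s) * nB_n) / pmax(cn_mix, 1e-6)
      baf <- pmin(pmax(baf + stats::rnorm(np, 0, config$baf_noise_sd), 0), 1)
      lrr <- config$gamma * log2(pmax(cn_mix, 0.05) / 2) +
        stats::rnorm(np, 0, config$lrr_noise_sd)
      track_list[[s]] <- data.frame(
        probe_id = pid, chrom = chrom_vec, pos = pos,
        lrr = lrr, baf = baf, gt = germline_gt, stringsAsFactors = FALSE)
    }
  }

  beta <- beta_normal_obs <- NULL
  if (meth) {
    beta <- matrix(NA_real_, np, k, dimnames = list(NULL, sample_ids))
    for (s in seq_len(k)) {
      mix <- purity[s] * prof$beta[clone_of[s], ] +
        (1 - purity[s]) * beta_normal
      beta[, s] <- pmin(pmax(mix + stats::rnorm(np, 0, config$beta_noise_sd),
                             0), 1)
    }
    beta_normal_obs <- pmin(pmax(beta_normal +
                                   stats::rnorm(np, 0, config$beta_noise_sd),
                                 0), 1)
  }

  structure(list(
    k = k, sample_ids = sample_ids, clone_of = clone_of, purity = purity,
    mixture = diag(tree$n_clones)[clone_of, , drop = FALSE],
    true_dist_scna = true_dist_scna, true_dist_meth = true_dist_meth,
    apith_true_scna = if (k >= 2) mean(true_dist_scna[upper.tri(true_dist_scna)]),
    apith_true_meth = if (!is.null(true_dist_meth))
      mean(true_dist_meth[upper.tri(true_dist_meth)]) else NA_real_,
    theta_scna = theta_scna, theta_meth = theta_meth,
    tracks = track_list, beta = beta, beta_normal = beta_normal,
    beta_normal_obs = beta_normal_obs, germline_gt = germline_gt,
    profiles = prof, tree = tree
  ), class = "patient_sim")
}

#' Simulate a multi-region tumor cohort with survival outcomes
#'
#' Generates `n_patients` clone trees (with per-patient divergence rates),
#' draws k tumor samples per patient, computes noise-free SCNA pairwise
#' distances and APITH, and simulates survival and distant-metastasis times
#' from a proportional-hazards model whose linear predictor is
#' `beta_ith * standardized latent ITH` plus stage, age and smoking
#' effects. Censoring is uniform over an interval calibrated to the
#' configured censoring rate.
#'
#' Probe tracks and methylation matrices are not materialized here (use
#' [simulate_patient()] for that); the cohort carries per-patient distance
#' matrices, APITH values and the clinical table, which is what the
#' association machinery consumes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `ith_cohort`: list with `patients` (per-patient
#'   list: k, clone assignment, distance matrix, apith, theta), `apith`
#'   (data.frame patient_id, k, apith, theta), `clinical` (data.frame), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  local_rng(seed)
  n <- config$n_patients
  patients <- vector("list", n)
  ids <- sprintf("P%04d", seq_len(n))

  theta <- numeric(n)
  clone_dists <- vector("list", n)
  cfg_i <- config
  cfg_i$meth_founder_rate <- 0 # beta matrices are not materialized here
  cfg_i$meth_branch_rate <- 0
  for (i in seq_len(n)) {
    cfg_i$branch_rate <- stats::runif(1, config$branch_rate_range[1],
                                      config$branch_rate_range[2])
    C <- sample(config$n_clones_range[1]:config$n_clones_range[2], 1L)
    tree <- simulate_clone_tree(C, cfg_i)
    clone_dists[[i]] <- clone_dist_fast(tree)
    theta[i] <- mean(clone_dists[[i]])
  }

  k_vec <- sample(config$k_min:config$k_max, n, replace = TRUE)
  if (isTRUE(config$corr_k_ith)) {
    # couple k to latent ITH: patients with higher theta get larger k
    ord <- order(theta + stats::rnorm(n, 0, stats::sd(theta) + 1e-12))
    k_vec[ord] <- sort(k_vec)
  }

  apith_vec <- numeric(n)
  for (i in seq_len(n)) {
    C <- nrow(clone_dists[[i]])
    clone_of <- sample.int(C, k_vec[i], replace = TRUE)
    d <- clone_dists[[i]][clone_of, clone_of, drop = FALSE]
    sid <- sprintf("S%02d", seq_len(k_vec[i]))
    dimnames(d) <- list(sid, sid)
    apith_vec[i] <- mean(d[upper.tri(d)])
    patients[[i]] <- list(patient_id = ids[i], k = k_vec[i],
                          clone_of = clone_of, dist = d,
                          apith = apith_vec[i], theta = theta[i])
  }

  stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
  age <- round(stats::rnorm(n, 66, 8))
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.2, 0.4, 0.4))
  smoke_code <- match(smoking, c("never", "former", "current")) - 1L

  sd_theta <- stats::sd(theta)
  z <- if (sd_theta > 0) (theta - mean(theta)) / sd_theta else rep(0, n)
  lp <- config$beta_ith * z + 0.35 * (stage - 2) + 0.02 * (age - 66) +
    0.2 * smoke_code
  lp <- lp - mean(lp)
  time_ev <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  lp_met <- config$beta_ith_met * z + 0.3 * (stage - 2)
  lp_met <- lp_met - mean(lp_met)
  time_met_ev <- stats::rexp(n, rate = 0.8 * config$baseline_hazard *
                               exp(lp_met))

  cens <- censor_times(time_ev, config$censoring_rate)
  time <- pmin(time_ev, cens)
  event <- as.integer(time_ev <= cens)
  cens_m <- censor_times(time_met_ev, config$censoring_rate)
  time_met <- pmin(time_met_ev, cens_m)
  metastasis <- as.integer(time_met_ev <= cens_m)

  clinical <- data.frame(patient_id = ids, time = time, event = event,
                         time_met = time_met, metastasis = metastasis,
                         stage = stage, age = age, smoking = smoking,
                         stringsAsFactors = FALSE)
  apith_df <- data.frame(patient_id = ids, k = k_vec, apith = apith_vec,
                         theta = theta, metric = "scna_proportion",
                         stringsAsFactors = FALSE)
  structure(list(patients = patients, apith = apith_df, clinical = clinical,
                 config = config),
            class = "ith_cohort")
}

# uniform censoring times calibrated so the expected censored fraction
# matches `rate`
censor_times <- function(time_ev, rate) {
  n <- length(time_ev)
  if (rate <= 0) return(rep(Inf, n))
  if (rate >= 1) return(stats::runif(n, 0, 1e-6)) # censor (nearly) at entry
  # P(C < T) with C ~ U(0, cmax) is mean(pmin(T/cmax, 1))
  f <- function(cmax) mean(pmin(time_ev / cmax, 1)) - rate
  upper <- max(time_ev) * 2
  if (f(upper) > 0) return(stats::runif(n, 0, upper))
  cmax <- stats::uniroot(f, c(min(time_ev) * 1e-3, upper))$root
  stats::runif(n, 0, cmax)
}

#' Write a patient's simulated assay files to disk
#'
#' Emits one probe TSV per tumor sample (`probe_id, chrom, pos, lrr, baf,
#' gt`), the methylation beta matrix (probes x samples, plus the matched
#' normal), and a ground-truth JSON-free TSV summary of the true pairwise
#' distances.
#'
#' @param patient a `patient_sim`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the vector of files written.
#' @export
write_patient <- function(patient, dir, prefix = "patient") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(patient$tracks)) for (s in names(patient$tracks)) {
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, s))
    utils::write.table(patient$tracks[[s]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(patient$beta)) {
    b <- cbind(patient$beta, normal = patient$beta_normal_obs)
    f <- file.path(dir, sprintf("%s_beta.tsv", prefix))
    utils::write.table(data.frame(probe_id = sprintf("p%06d",
                                                     seq_len(nrow(b))), b),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  d <- patient$true_dist_scna
  f <- file.path(dir, sprintf("%s_truedist.tsv", prefix))
  utils::write.table(d, f, sep = "\t", quote = FALSE)
  files <- c(files, f)
  invisible(files)
}

#' Write the cohort clinical table as CSV
#' @param cohort an `ith_cohort`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_clinical <- function(cohort, file) {
  utils::write.csv(cohort$clinical, file, row.names = FALSE)
  invisible(file)
}
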