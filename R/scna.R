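#' Segment a BAF track by penalized changepoint detection
#'
#' Allele-aware segmentation that relies only on B-allele frequencies:
#' the mirrored BAF signal |BAF - 0.5| of heterozygous probes is segmented
#' per chromosome by recursive binary splitting under a squared-error cost,
#' accepting a split only when the cost reduction exceeds a BIC-like
#' penalty. Homozygous probes carry no allelic signal and are assigned to
#' the segment spanning them afterwards. Segments shorter than `min_probes`
#' (heterozygous probes) are merged into their closer neighbor.
#'
#' @param baf numeric BAF in \[0, 1\], ordered by genomic position.
#' @param chrom chromosome of each probe (same length).
#' @param is_het logical: heterozygous (informative) probes.
#' @param min_probes minimum heterozygous probes per segment.
#' @param penalty multiplier of the BIC penalty `sigma^2 * log(n)`; larger
#'   values yield fewer segments.
#' @return data.frame of segments: `chrom`, `start_idx`, `end_idx` (1-based
#'   inclusive probe indices into the input), `n_probes`, `n_het`,
#'   `mean_mbaf` (mean mirrored BAF over heterozygous probes).
#' @export
segment_baf <- function(baf, chrom, is_het, min_probes = 15L, penalty = 6) {
  stopifnot(length(baf) == length(chrom), length(is_het) == length(baf))
  if (all(is.na(baf))) stop("all BAF values are missing")
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) stop("BAF must lie in [0, 1]")
  out <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    if (!length(idx)) next
    het <- idx[which(is_het[idx] & !is.na(baf[idx]))]
    if (length(het) < 2L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start_idx = idx[1], end_idx = idx[length(idx)],
        n_probes = length(idx), n_het = length(het),
        mean_mbaf = if (length(het)) mean(abs(baf[het] - 0.5)) else NA_real_)
      next
    }
    x <- abs(baf[het] - 0.5)
    cuts <- binseg_cuts(x, min_probes, penalty) # cuts in het-index units
    # het-unit boundaries -> full probe boundaries (midpoint between the
    # flanking heterozygous probes)
    bnd <- c(idx[1] - 1L,
             vapply(cuts, function(cu)
               (het[cu] + het[cu + 1L]) %/% 2L, integer(1)),
             idx[length(idx)])
    for (s in seq_len(length(bnd) - 1L)) {
      lo <- bnd[s] + 1L
      hi <- bnd[s + 1L]
      hseg <- het[het >= lo & het <= hi]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start_idx = lo, end_idx = hi,
        n_probes = hi - lo + 1L, n_het = length(hseg),
        mean_mbaf = mean(abs(baf[hseg] - 0.5)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# binary segmentation on x: returns sorted cut positions (segment ends, in
# 1..length(x)-1), accepting splits whose RSS reduction exceeds
# penalty * sigma2 * log(n)
binseg_cuts <- function(x, min_len, penalty) {
  n <- length(x)
  if (n < 2L * min_len) return(integer(0))
  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- max(stats::var(x), 1e-8)
  pen <- penalty * sigma2 * log(n)
  cuts <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_len) return(invisible(NULL))
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    tot <- cs[len]
    tau <- min_len:(len - min_len) # candidate left-segment lengths
    # RSS reduction of splitting after position tau:
    # gain = n_l*n_r/n * (mean_l - mean_r)^2
    mean_l <- cs[tau] / tau
    mean_r <- (tot - cs[tau]) / (len - tau)
    gain <- tau * (len - tau) / len * (mean_l - mean_r)^2
    b <- which.max(gain)
    if (gain[b] > pen) {
      cut <- lo + tau[b] - 1L
      cuts <<- c(cuts, cut)
      recurse(lo, cut)
      recurse(cut + 1L, hi)
    }
    invisible(NULL)
  }
  recurse(1L, n)
  sort(cuts)
}

#' Classify BAF segments with a t-test on LRR
#'
#' Segments whose mean mirrored BAF deviates from 0.5 (beyond a data-driven
#' threshold: median + 3 x MAD of the heterozygous-probe mirrored BAF in
#' the sample) are SCNA candidates; their LRR values are compared against
#' the pooled LRR of all BAF-neutral segments with a two-sided Student's
#' t-test. After Benjamini-Hochberg adjustment across candidate segments,
#' significantly higher LRR means AMP, significantly lower means DEL, and
#' non-significant deviation means copy-neutral LOH. BAF-neutral segments
#' are NEUTRAL with p fixed at 1.
#'
#' Integer copy number is estimated per segment from the mean LRR as
#' `CN = round(2 * 2^(LRR/gamma))`, floored at 0; when the tumor purity is
#' known, the normal-cell contribution is removed first:
#' `CN = round((2 * 2^(LRR/gamma) - 2 (1 - purity)) / purity)`.
#'
#' @param segments output of [segment_baf()].
#' @param lrr per-probe LRR vector (full probe set of the track).
#' @param baf per-probe BAF vector.
#' @param is_het logical heterozygous mask.
#' @param alpha significance level after adjustment.
#' @param adjust multiple-testing method (see [stats::p.adjust()]).
#' @param gamma LRR compression factor.
#' @param purity known tumor purity in (0, 1\]; 1 = no correction.
#' @param mad_mult multiplier of the MAD-based BAF-deviation threshold.
#' @param min_lrr_diff minimal absolute LRR shift (vs the neutral
#'   reference) for an AMP/DEL call: with hundreds of probes per segment
#'   the t-test detects shifts far smaller than any real copy-number
#'   change, so significance alone would relabel LOH segments. The default
#'   0.1 is about half the one-copy LRR shift at 50% purity.
#' @return `segments` with added columns `status`, `cn`, `p_adj`,
#'   `mean_lrr`.
#' @export
classify_segments <- function(segments, lrr, baf, is_het, alpha = 0.05,
                              adjust = "BH", gamma = 0.55, purity = 1,
                              mad_mult = 3, min_lrr_diff = 0.1) {
  stopifnot(purity > 0, purity <= 1)
  # BAF-deviation threshold anchored on the most allele-balanced segment:
  # a genome-wide MAD would be inflated when a large genome fraction is
  # altered, so the spread is taken from the probes of the segment with
  # the smallest mean mirrored BAF (the provisional neutral reference)
  ok_seg <- which(!is.na(segments$mean_mbaf) & segments$n_het >= 2)
  if (!length(ok_seg))
    stop("no segment with heterozygous probes; cannot classify")
  ref_seg <- ok_seg[which.min(segments$mean_mbaf[ok_seg])]
  ref_idx <- segments$start_idx[ref_seg]:segments$end_idx[ref_seg]
  ref_mbaf <- abs(baf[ref_idx][is_het[ref_idx]] - 0.5)
  thr <- stats::median(ref_mbaf, na.rm = TRUE) +
    mad_mult * stats::mad(ref_mbaf, na.rm = TRUE)
  dev <- !is.na(segments$mean_mbaf) & segments$mean_mbaf > thr
  if (!any(!dev))
    stop("no BAF-neutral reference segment found; supply a fallback ",
         "reference (e.g. recalibrate against the genome-wide median LRR)")
  seg_lrr <- lapply(seq_len(nrow(segments)), function(s)
    lrr[segments$start_idx[s]:segments$end_idx[s]])
  ref <- unlist(seg_lrr[!dev])
  # homozygous deletions are allele-balanced (pure normal-cell signal) and
  # would otherwise contaminate the neutral LRR reference: trim reference
  # probes with outlying LRR before testing
  ref_med <- stats::median(ref)
  ref_mad <- stats::mad(ref)
  if (ref_mad > 0) ref <- ref[abs(ref - ref_med) <= 4 * ref_mad]

  p <- rep(NA_real_, nrow(segments))
  higher <- rep(NA, nrow(segments))
  for (s in which(dev)) {
    p[s] <- tryCatch(
      stats::t.test(seg_lrr[[s]], ref, var.equal = TRUE)$p.value,
      error = function(e) # noise-free limit: constant data
        if (isTRUE(all.equal(mean(seg_lrr[[s]]), mean(ref)))) 1 else 0)
    higher[s] <- mean(seg_lrr[[s]]) > mean(ref)
  }
  p_adj <- rep(1, nrow(segments))
  p_adj[dev] <- stats::p.adjust(p[dev], method = adjust)

  big_shift <- vapply(seg_lrr, function(x)
    abs(mean(x) - mean(ref)) >= min_lrr_diff, logical(1))
  status <- rep("NEUTRAL", nrow(segments))
  status[dev] <- ifelse(p_adj[dev] < alpha & big_shift[dev],
                        ifelse(higher[dev], "AMP", "DEL"), "LOH")
  mean_lrr <- vapply(seg_lrr, mean, numeric(1))
  raw_cn <- 2 * 2^(mean_lrr / gamma)
  cn <- as.integer(pmax(round((raw_cn - 2 * (1 - purity)) / purity), 0))
  # a BAF-neutral segment with copy number 0 is a homozygous deletion: it
  # carries no allelic signal (only normal cells contribute alleles), so
  # the BAF rule alone would mislabel it NEUTRAL
  homdel <- !dev & cn == 0L
  status[homdel] <- "DEL"
  segments$status <- status
  segments$cn <- cn
  segments$p_adj <- p_adj
  segments$mean_lrr <- mean_lrr
  segments
}

#' Expand classified segments into a per-probe copy-number profile
#'
#' @param segments classified segments (with `status` and `cn`) that
#'   partition `1:n_probes` without gaps or overlaps.
#' @param n_probes total probe count.
#' @param sample_id optional sample label.
#' @return object of class `cn_profile`: list with `sample_id`, `status`
#'   (integer codes, see [status_levels()]) and `cn` vectors of length
#'   `n_probes`.
#' @export
probe_status_vector <- function(segments, n_probes, sample_id = NA_character_) {
  o <- order(segments$start_idx)
  segments <- segments[o, , drop = FALSE]
  expect <- 1L
  for (s in seq_len(nrow(segments))) {
    if (segments$start_idx[s] != expect)
      stop("segments do not partition the probe range (gap or overlap at ",
           expect, ")")
    expect <- segments$end_idx[s] + 1L
  }
  if (expect != n_probes + 1L)
    stop("segments do not cover probes up to ", n_probes)
  codes <- c(DEL = 0L, LOH = 1L, NEUTRAL = 2L, AMP = 3L)
  len <- segments$end_idx - segments$start_idx + 1L
  structure(list(sample_id = sample_id,
                 status = rep(unname(codes[segments$status]), len),
                 cn = rep(segments$cn, len)),
            class = "cn_profile")
}

#' Collapse a per-probe profile back into segments
#'
#' Inverse of [probe_status_vector()] (up to segment boundaries between
#' runs of identical status and copy number).
#'
#' @param profile a `cn_profile`.
#' @param chrom optional per-probe chromosome; runs never straddle
#'   chromosomes when given.
#' @return data.frame `start_idx`, `end_idx`, `status`, `cn`.
#' @export
profile_to_segments <- function(profile, chrom = NULL) {
  key <- paste(profile$status, profile$cn)
  if (!is.null(chrom)) key <- paste(key, chrom)
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- c(1L, utils::head(end, -1L) + 1L)
  data.frame(start_idx = start, end_idx = end,
             status = status_levels()[profile$status[start] + 1L],
             cn = profile$cn[start], stringsAsFactors = FALSE)
}

#' Call SCNAs for one sample track
#'
#' Convenience wrapper: [segment_baf()] then [classify_segments()] then
#' [probe_status_vector()].
#'
#' @param track data.frame with columns `chrom`, `lrr`, `baf` and `gt`
#'   (germline genotype, "AB" = heterozygous) or logical `is_het`.
#' @param sample_id sample label.
#' @param purity known tumor purity (default 1).
#' @param ... passed to [segment_baf()] and [classify_segments()].
#' @inheritParams classify_segments
#' @inheritParams segment_baf
#' @return list with `profile` (a `cn_profile`) and `segments`.
#' @export
call_scna <- function(track, sample_id = NA_character_, purity = 1,
                      min_probes = 15L, penalty = 6, alpha = 0.05,
                      adjust = "BH", gamma = 0.55, mad_mult = 3) {
  is_het <- if ("is_het" %in% names(track)) track$is_het else track$gt == "AB"
  seg <- segment_baf(track$baf, track$chrom, is_het,
                     min_probes = min_probes, penalty = penalty)
  seg <- classify_segments(seg, track$lrr, track$baf, is_het, alpha = alpha,
                           adjust = adjust, gamma = gamma, purity = purity,
                           mad_mult = mad_mult)
  prof <- probe_status_vector(seg, nrow(track), sample_id = sample_id)
  list(profile = prof, segments = seg)
}

#' Call candidate SCNA driver events
#'
#' Per gene: an amplification driver event is emitted when an oncogene
#' reaches copy number >= 4 (max over its probes), a deletion driver event
#' when a tumor suppressor gene reaches copy number 0 (min over its
#' probes).
#'
#' @param profile a `cn_profile` (per-probe copy numbers).
#' @param annotation probe annotation table aligned with the profile.
#' @return data.frame `gene`, `driver_class`, `event` ("amplification" /
#'   "deletion"), `cn` (the extreme copy number reached).
#' @export
call_driver_scna <- function(profile, annotation) {
  stopifnot(length(profile$cn) == nrow(annotation))
  drv <- !is.na(annotation$gene) &
    annotation$driver_class %in% c("oncogene", "TSG")
  out <- list()
  for (g in unique(annotation$gene[drv])) {
    idx <- which(annotation$gene %in% g)
    cls <- annotation$driver_class[idx[1]]
    if (cls == "oncogene" && max(profile$cn[idx]) >= 4L)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, driver_class = cls, event = "amplification",
        cn = max(profile$cn[idx]), stringsAsFactors = FALSE)
    if (cls == "TSG" && min(profile$cn[idx]) == 0L)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, driver_class = cls, event = "deletion",
        cn = min(profile$cn[idx]), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), driver_class = character(),
                      event = character(), cn = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
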