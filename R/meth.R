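#' Purity-adjust methylation beta values
#'
#' The observed beta of a tumor sample is a purity-weighted linear mixture
#' of the tumor-cell and contaminating-normal signal:
#' `beta_obs = pi * beta_tumor + (1 - pi) * beta_normal`. Given the purity
#' and a normal reference profile, the tumor component is recovered as
#' `beta_tumor = (beta_obs - (1 - pi) * beta_normal) / pi`, clipped to
#' \[0, 1\]. All downstream methylation analyses are meant to consume
#' adjusted betas.
#'
#' @param beta_obs observed beta vector (or probes x samples matrix).
#' @param beta_normal matched-normal beta vector on the same probe set;
#'   when the matched normal is missing, pass the per-probe mean over all
#'   normals (see [mean_normal_beta()]).
#' @param purity tumor purity in (0, 1\] (scalar, or one per column of a
#'   matrix input).
#' @return adjusted betas, same shape as `beta_obs`, clipped to \[0, 1\].
#' @export
adjust_purity <- function(beta_obs, beta_normal, purity) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must lie in (0, 1]")
  if (is.matrix(beta_obs)) {
    stopifnot(nrow(beta_obs) == length(beta_normal),
              length(purity) %in% c(1L, ncol(beta_obs)))
    purity <- rep_len(purity, ncol(beta_obs))
    adj <- (beta_obs - outer(beta_normal, 1 - purity)) /
      matrix(purity, nrow(beta_obs), ncol(beta_obs), byrow = TRUE)
    return(pmin(pmax(adj, 0), 1))
  }
  stopifnot(length(beta_obs) == length(beta_normal), length(purity) == 1L)
  pmin(pmax((beta_obs - (1 - purity) * beta_normal) / purity, 0), 1)
}

#' Mean-of-normals reference profile
#'
#' Imputation used when a tumor lacks a matched normal: the per-probe mean
#' methylation over all available normal samples.
#'
#' @param beta_normals probes x samples matrix of normal betas.
#' @return per-probe mean vector.
#' @export
mean_normal_beta <- function(beta_normals) {
  rowMeans(as.matrix(beta_normals), na.rm = TRUE)
}

#' Select the most variable probes
#'
#' Probes ranked by variance across (tumor) samples; the top `n` are
#' returned, ties broken by probe order.
#'
#' @param beta probes x samples matrix.
#' @param n number of probes (or, if < 1, the fraction of probes) to keep.
#' @return integer vector of probe indices, sorted by decreasing variance.
#' @export
select_top_variable <- function(beta, n) {
  beta <- as.matrix(beta)
  if (ncol(beta) < 2) stop("variance ranking needs at least 2 samples")
  if (n < 1) n <- max(1L, floor(n * nrow(beta)))
  n <- as.integer(n)
  if (n > nrow(beta)) {
    warning("n exceeds the probe count; returning all probes")
    n <- nrow(beta)
  }
  v <- apply(beta, 1L, stats::var)
  order(-v, seq_along(v))[seq_len(n)]
}

#' Call CpG island methylator phenotype (CIMP) per sample
#'
#' Hierarchical clustering (Euclidean distance, average linkage by default)
#' of tumor samples on the 5000 most variable CpG probes mapping to gene
#' promoter and CpG island regions, cut into two groups; the group with the
#' higher mean promoter-island beta relative to the normal reference is
#' labelled CIMP-H, the other CIMP-L. Samples from the same tumor may
#' receive discordant labels.
#'
#' @param beta probes x samples matrix of (purity-adjusted) tumor betas.
#' @param beta_normal normal reference beta vector (orientation only).
#' @param annotation probe annotation table aligned to the rows.
#' @param n_probes number of most-variable promoter-island probes used.
#' @param linkage,dist_method clustering parameters.
#' @return character vector of per-sample labels ("CIMP-H" / "CIMP-L").
#' @export
call_cimp <- function(beta, beta_normal, annotation, n_probes = 5000L,
                      linkage = "average", dist_method = "euclidean") {
  beta <- as.matrix(beta)
  if (ncol(beta) < 3) stop("CIMP clustering needs at least 3 tumor samples")
  stopifnot(nrow(beta) == nrow(annotation),
            length(beta_normal) == nrow(beta))
  prom <- annotation$gene_context %in% c("TSS1500", "TSS200", "5'UTR",
                                         "first_exon")
  isl <- annotation$cpg_context == "island"
  idx <- which(prom & isl)
  if (length(idx) < 2) stop("annotation has no promoter CpG island probes")
  sel <- idx[select_top_variable(beta[idx, , drop = FALSE],
                                 min(n_probes, length(idx)))]
  hc <- stats::hclust(stats::dist(t(beta[sel, , drop = FALSE]),
                                  method = dist_method), method = linkage)
  grp <- stats::cutree(hc, k = 2)
  # orient: hypermethylation relative to normal at the clustering probes
  excess <- colMeans(beta[sel, , drop = FALSE] - beta_normal[sel])
  g_mean <- tapply(excess, grp, mean)
  high <- as.integer(names(which.max(g_mean)))
  # both groups at the normal baseline => no CIMP-H group at all
  if (max(g_mean) <= 0.05) return(stats::setNames(rep("CIMP-L", ncol(beta)),
                                                  colnames(beta)))
  stats::setNames(ifelse(grp == high, "CIMP-H", "CIMP-L"), colnames(beta))
}

#' Call candidate driver methylation events
#'
#' For each driver gene, the mean (purity-adjusted) beta over its promoter
#' CpG island probes is compared between each tumor sample and the normal
#' reference; an event is called when the absolute difference reaches the
#' cutoff (default 0.3), with the direction (hyper/hypo) recorded.
#'
#' @param beta_tumor probes x samples matrix of adjusted tumor betas (a
#'   vector is treated as one sample).
#' @param beta_normal normal reference beta vector.
#' @param annotation probe annotation table.
#' @param cutoff absolute delta-beta required to call an event.
#' @return data.frame `sample_id`, `gene`, `driver_class`, `delta_beta`,
#'   `direction` ("hyper"/"hypo"); zero rows when nothing is called.
#' @export
call_driver_methylation <- function(beta_tumor, beta_normal, annotation,
                                    cutoff = 0.3) {
  if (!is.matrix(beta_tumor))
    beta_tumor <- matrix(beta_tumor, ncol = 1,
                         dimnames = list(NULL, "S01"))
  stopifnot(nrow(beta_tumor) == nrow(annotation),
            length(beta_normal) == nrow(beta_tumor))
  pil <- promoter_island_probes(annotation, driver_only = TRUE)
  drv_genes <- unique(annotation$gene[!is.na(annotation$gene) &
    annotation$driver_class %in% c("oncogene", "TSG")])
  skipped <- setdiff(drv_genes, names(pil))
  if (length(skipped))
    warning("driver gene(s) without promoter-island probes skipped: ",
            paste(skipped, collapse = ", "))
  sids <- colnames(beta_tumor)
  if (is.null(sids)) sids <- sprintf("S%02d", seq_len(ncol(beta_tumor)))
  out <- list()
  for (g in names(pil)) {
    idx <- pil[[g]]
    mn <- mean(beta_normal[idx])
    cls <- annotation$driver_class[idx[1]]
    mt <- colMeans(beta_tumor[idx, , drop = FALSE])
    db <- mt - mn
    hit <- which(abs(db) >= cutoff)
    for (s in hit)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sids[s], gene = g, driver_class = cls,
        delta_beta = db[s],
        direction = if (db[s] > 0) "hyper" else "hypo",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene = character(),
                      driver_class = character(), delta_beta = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
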