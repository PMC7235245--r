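#' Simulate a probe annotation table
#'
#' Builds a synthetic array annotation shared by the SCNA and methylation
#' modules: probes laid out along chromosomes with CpG context (island /
#' shore / shelf / open sea, with north/south orientation for shores and
#' shelves), gene context (TSS1500, TSS200, 5'UTR, first exon, body, 3'UTR,
#' or intergenic) and a driver class per gene (oncogene, TSG, other).
#' Gene blocks mimic the structure of a methylation array: promoter probes
#' sit inside a CpG island, flanked by shores and shelves, with open sea in
#' gene bodies and intergenic gaps.
#'
#' @param n_probes total number of probes.
#' @param n_chrom number of chromosomes the probes are spread over.
#' @param gene_density fraction of probes falling in gene blocks.
#' @param frac_oncogene,frac_tsg fraction of genes labelled oncogene / TSG.
#' @param probe_spacing mean genomic spacing between adjacent probes (bp).
#' @param seed integer seed; the table is deterministic given the seed.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `cpg_context`, `cpg_orient`, `gene_context`, `gene`, `driver_class`,
#'   sorted by chromosome and position.
#' @export
simulate_probe_annotation <- function(n_probes = 20000L, n_chrom = 4L,
                                      gene_density = 0.7,
                                      frac_oncogene = 0.08, frac_tsg = 0.10,
                                      probe_spacing = 3000, seed = 1L) {
  stopifnot(n_probes >= 100L, n_chrom >= 1L)
  rs <- local_rng(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), n_probes))
  pos <- integer(n_probes)
  for (cc in seq_len(n_chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(1L + stats::rpois(length(idx), probe_spacing))
  }

  cpg_context <- rep("open_sea", n_probes)
  cpg_orient <- rep(NA_character_, n_probes)
  gene_context <- rep("intergenic", n_probes)
  gene <- rep(NA_character_, n_probes)

  # tile gene blocks: promoter island + shores/shelves + body + 3'UTR
  i <- 1L
  gid <- 0L
  target_gene_probes <- round(gene_density * n_probes)
  gene_probes <- 0L
  while (i <= n_probes - 40L && gene_probes < target_gene_probes) {
    gap <- stats::rpois(1L, 6L)
    i <- i + gap
    len <- 24L + stats::rpois(1L, 16L)
    if (i + len - 1L > n_probes) break
    if (chrom[i + len - 1L] != chrom[i]) { # do not straddle chromosomes
      i <- i + len
      next
    }
    gid <- gid + 1L
    idx <- i:(i + len - 1L)
    gname <- sprintf("G%04d", gid)
    gene[idx] <- gname
    # gene context, 5' to 3'
    nb <- len - 10L
    gene_context[idx] <- c("TSS1500", "TSS1500", "TSS200", "TSS200",
                           "5'UTR", "5'UTR", "first_exon", "first_exon",
                           rep("body", nb), "3'UTR", "3'UTR")
    # CpG context: island over the promoter, shores then shelves flanking
    cpg_context[idx[1:8]] <- "island"
    cpg_context[idx[9:12]] <- "shore"
    cpg_orient[idx[9:12]] <- "S"
    if (len >= 16L) {
      cpg_context[idx[13:16]] <- "shelf"
      cpg_orient[idx[13:16]] <- "S"
    }
    if (i > 4L && chrom[i - 4L] == chrom[i] && all(is.na(gene[(i - 4L):(i - 1L)]))) {
      cpg_context[(i - 2L):(i - 1L)] <- "shore"
      cpg_orient[(i - 2L):(i - 1L)] <- "N"
      cpg_context[(i - 4L):(i - 3L)] <- "shelf"
      cpg_orient[(i - 4L):(i - 3L)] <- "N"
    }
    gene_probes <- gene_probes + len
    i <- i + len
  }

  genes <- unique(gene[!is.na(gene)])
  n_onc <- max(1L, round(frac_oncogene * length(genes)))
  n_tsg <- max(1L, round(frac_tsg * length(genes)))
  cls <- rep("other", length(genes))
  pick <- sample.int(length(genes), n_onc + n_tsg)
  cls[pick[seq_len(n_onc)]] <- "oncogene"
  cls[pick[n_onc + seq_len(n_tsg)]] <- "TSG"
  names(cls) <- genes
  driver_class <- ifelse(is.na(gene), "other", cls[gene])

  ann <- data.frame(
    probe_id = sprintf("p%06d", seq_len(n_probes)),
    chrom = chrom, pos = pos,
    cpg_context = cpg_context, cpg_orient = cpg_orient,
    gene_context = gene_context, gene = gene,
    driver_class = unname(driver_class),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Probes in promoter CpG islands of a gene
#'
#' @param annotation a probe annotation table.
#' @param genes optional character vector of gene symbols; default all genes.
#' @param driver_only restrict to oncogene/TSG genes.
#' @return named list mapping gene to integer probe indices (promoter
#'   context and CpG island).
#' @export
promoter_island_probes <- function(annotation, genes = NULL, driver_only = FALSE) {
  prom <- annotation$gene_context %in% c("TSS1500", "TSS200", "5'UTR", "first_exon")
  isl <- annotation$cpg_context == "island"
  keep <- prom & isl & !is.na(annotation$gene)
  if (driver_only) keep <- keep & annotation$driver_class %in% c("oncogene", "TSG")
  if (!is.null(genes)) keep <- keep & annotation$gene %in% genes
  split(which(keep), annotation$gene[keep])
}

#' Baseline (normal tissue) methylation profile for an annotation
#'
#' Draws a 450K-like bimodal normal beta profile: CpG island probes are
#' mostly unmethylated, open-sea and gene-body probes mostly methylated,
#' shores/shelves intermediate.
#'
#' @param annotation probe annotation table.
#' @param seed integer seed.
#' @return numeric vector of betas in \[0, 1\], one per probe.
#' @export
simulate_normal_beta <- function(annotation, seed = 1L) {
  rs <- local_rng(seed)
  n <- nrow(annotation)
  mu <- c(island = 0.12, shore = 0.35, shelf = 0.55, open_sea = 0.78)
  m <- mu[annotation$cpg_context]
  b <- stats::rbeta(n, m * 18, (1 - m) * 18)
  pmin(pmax(b, 0), 1)
}

# Seed the RNG when a seed is supplied; NULL leaves the stream untouched.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
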