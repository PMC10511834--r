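#' Set low-depth genotypes to missing
#'
#' Genotype calls whose total read depth (ref + alt) falls below
#' \code{min_depth} are masked as missing. Depths themselves are retained, so
#' downstream read-based statistics still see the reads.
#'
#' @param gm a \code{genotype_matrix} with depths
#' @param min_depth minimum total reads for a genotype call (default 8)
#' @return the filtered \code{genotype_matrix}
#' @export
apply_depth_filter <- function(gm, min_depth = 8) {
  if (is.null(gm$ref_depth)) stop("depth data required", call. = FALSE)
  if (min_depth > 0) {
    low <- (gm$ref_depth + gm$alt_depth) < min_depth
    gm$genotypes[low] <- NA_integer_
  }
  gm
}

#' HDplot paralog-screening statistics
#'
#' Per locus: \code{H}, the proportion of genotyped individuals called
#' heterozygous, and \code{D}, the read-ratio deviation among heterozygotes.
#' With \code{A} reference and \code{B} alternate reads summed over
#' heterozygous individuals and \code{n = A + B}, \code{D} is the z-score of
#' \code{A} under Binomial(n, 1/2): \code{D = (A - n/2) / sqrt(n/4)}.
#' Collapsed paralogs show excess H and |D| because reads from two loci are
#' pooled into one call.
#'
#' @param gm a \code{genotype_matrix} with depths
#' @return data frame with columns \code{locus}, \code{H}, \code{D},
#'   \code{n_het}, and \code{d_defined} (FALSE where no heterozygote reads
#'   exist; \code{D} is reported as 0 there)
#' @export
hdplot <- function(gm) {
  if (is.null(gm$ref_depth)) stop("depth data required", call. = FALSE)
  het <- !is.na(gm$genotypes) & gm$genotypes == 1L
  n_gt <- colSums(!is.na(gm$genotypes))
  n_het <- colSums(het)
  A <- colSums(gm$ref_depth * het)
  B <- colSums(gm$alt_depth * het)
  ntot <- A + B
  D <- ifelse(ntot > 0, (A - ntot / 2) / sqrt(ntot / 4), 0)
  data.frame(
    locus = gm$loci$locus,
    H = ifelse(n_gt > 0, n_het / n_gt, 0),
    D = D,
    n_het = n_het,
    d_defined = ntot > 0
  )
}

#' Remove putative paralogs flagged by HDplot
#'
#' Loci with heterozygosity strictly greater than \code{max_H} or absolute
#' read-ratio deviation strictly greater than \code{max_absD} are dropped.
#'
#' @param gm a \code{genotype_matrix}
#' @param stats output of \code{\link{hdplot}} on \code{gm}
#' @param max_H heterozygosity ceiling (default 0.6)
#' @param max_absD |D| ceiling (default 7)
#' @return the filtered \code{genotype_matrix}
#' @export
filter_paralogs <- function(gm, stats = hdplot(gm), max_H = 0.6, max_absD = 7) {
  stopifnot(nrow(stats) == ncol(gm$genotypes))
  keep <- !(stats$H > max_H | abs(stats$D) > max_absD)
  gm[, keep]
}

#' Exact Hardy-Weinberg test per locus
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts no more likely
#' than the observed one. Monomorphic loci return p = 1. With a population
#' factor, p-values are computed per population and a locus is flagged as
#' deviating only when p < \code{alpha} in every population.
#'
#' @param gm a \code{genotype_matrix}
#' @param pops optional factor of population labels per individual
#' @param alpha per-population significance level for flagging (default 0.05)
#' @return with \code{pops = NULL}, a numeric vector of p-values; otherwise a
#'   list with the p-value matrix (loci x populations) and the logical
#'   \code{flagged} vector
#' @export
hwe_test <- function(gm, pops = NULL, alpha = 0.05) {
  pv_one <- function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_p(sum(g == 1L), sum(g == 0L), sum(g == 2L))
  }
  if (is.null(pops)) {
    return(apply(gm$genotypes, 2, pv_one))
  }
  pops <- as.factor(pops)
  pmat <- sapply(levels(pops), function(lv)
    apply(gm$genotypes[pops == lv, , drop = FALSE], 2, pv_one))
  flagged <- apply(pmat, 1, function(p) all(!is.na(p) & p < alpha))
  list(p = pmat, flagged = flagged)
}

# Exact HWE p-value from genotype counts (n_het heterozygotes, n_hom1 and
# n_hom2 homozygotes), conditional on allele counts; two-sided by summing
# probabilities <= that of the observed configuration.
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n == 0 || n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log-prob of each possible heterozygote count given allele counts
  lp <- sapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  })
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- which(hets == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' Baseline locus filters: bait targeting and call rate
#'
#' Drops loci not targeted by the RAD-capture bait panel (unless
#' \code{baited_only = FALSE}) and loci genotyped in fewer than
#' \code{min_call} of individuals (boundary inclusive).
#'
#' @param gm a \code{genotype_matrix}
#' @param min_call minimum genotyped fraction (default 0.8)
#' @param baited_only require the baited flag (default TRUE)
#' @return the filtered \code{genotype_matrix}
#' @export
base_filters <- function(gm, min_call = 0.8, baited_only = TRUE) {
  keep <- call_rate(gm) >= min_call
  if (baited_only) keep <- keep & gm$loci$baited
  gm[, keep]
}

#' Select the linkage-disequilibrium SNP set
#'
#' One SNP per RAD-capture tag: among the tag's SNPs with minor allele
#' frequency at least \code{min_maf}, keep the one with the highest call
#' rate. Ties break to the lower position, then the lower column index. Tags
#' with no SNP passing the MAF floor contribute nothing.
#'
#' @param gm a \code{genotype_matrix}
#' @param min_maf minor-allele-frequency floor (default 0.05)
#' @return the selected \code{genotype_matrix}
#' @export
select_ld_set <- function(gm, min_maf = 0.05) {
  m <- maf(gm); cr <- call_rate(gm)
  ok <- which(!is.na(m) & m >= min_maf)
  if (!length(ok)) return(gm[, integer(0)])
  ord <- ok[order(-cr[ok], gm$loci$pos[ok], ok)]
  keep <- ord[!duplicated(gm$loci$tag[ord])]
  gm[, sort(keep)]
}

#' Select the pedigree-reconstruction SNP set
#'
#' Non-overlapping windows of \code{window_bp} are tiled from position 0
#' along each chromosome; within each window the single SNP maximizing
#' MAF x call-rate is kept (ties as in \code{\link{select_ld_set}}), which
#' biases selection toward informative, well-genotyped SNPs while enforcing
#' at most one SNP per window.
#'
#' @param gm a \code{genotype_matrix}
#' @param window_bp window width in bp (default 1e6)
#' @return the selected \code{genotype_matrix}
#' @export
select_pedigree_set <- function(gm, window_bp = 1e6) {
  m <- maf(gm); cr <- call_rate(gm)
  score <- m * cr
  win <- paste(gm$loci$chrom, floor(gm$loci$pos / window_bp))
  idx <- seq_along(score)
  ok <- idx[!is.na(score)]
  if (!length(ok)) return(gm[, integer(0)])
  ord <- ok[order(-score[ok], gm$loci$pos[ok], ok)]
  keep <- ord[!duplicated(win[ord])]
  gm[, sort(keep)]
}
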