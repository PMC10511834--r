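#' Breeding and genotyping configuration for cohort simulation
#'
#' Defines the demographic and genotyping conditions of one simulated spawning
#' event. Matings are two-level: each sire takes a number of mates
#' (1 + Poisson(\code{mate_mean} - 1) dams, drawn with replacement), and each
#' sire-dam pair produces a number of offspring from \code{offspring_dist}
#' (Poisson, or negative binomial when \code{offspring_dispersion} is finite).
#' The two levels make the variance in reproductive success (Vk) and the
#' density of half-sib connections independently tunable.
#'
#' @param n_sires,n_dams numbers of candidate parents of each sex.
#' @param mate_mean mean number of mates per sire (>= 1).
#' @param offspring_mean mean offspring per mating pair.
#' @param offspring_dispersion negative-binomial size parameter for offspring
#'   per pair; \code{Inf} gives Poisson numbers. Smaller values give more
#'   overdispersion, hence larger Vk.
#' @param n_chromosomes,chromosome_length genome layout; positions only feed
#'   window tiling and inter-chromosomal pair selection.
#' @param n_loci number of biallelic SNPs.
#' @param maf_min,maf_max minor-allele-frequency range; parental allele
#'   frequencies are drawn uniformly on this interval.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model per
#'   genotype (mean reads; dispersion \code{Inf} = Poisson).
#' @param genotyping_error probability a called genotype is replaced by one of
#'   the other two codes.
#' @param missing_rate probability a genotype call is missing.
#' @param paralog_fraction fraction of loci emitted as the merge of two
#'   independent loci (summed reads), emulating collapsed paralogs.
#' @param tag_pair_rate probability that a SNP shares its RAD tag with the
#'   previous SNP on the same chromosome.
#' @param baited_fraction fraction of loci flagged as targeted by the bait
#'   panel.
#' @param n_sites number of stream sampling sites available.
#' @param site_clustering spatial concentration of each family: 0 spreads a
#'   family's offspring uniformly over sites; larger values localize each
#'   family at essentially one site, so a one-site sample holds few families.
#' @param n_burnin_generations generations of the same breeding regime
#'   simulated before the focal spawning event, so the parental population
#'   carries the standing (drift-recombination equilibrium) linkage
#'   disequilibrium that LD-based estimation assumes. Unlinked-locus LD loses
#'   half its value per generation, so the default converges well within 1%.
#'   0 gives parents drawn from linkage equilibrium.
#' @param seed global integer seed; each simulation stage derives its own
#'   named RNG stream from it.
#' @return an object of class \code{breeding_config}.
#' @export
breeding_config <- function(n_sires = 25, n_dams = 25,
                            mate_mean = 2, offspring_mean = 8,
                            offspring_dispersion = Inf,
                            n_chromosomes = 84, chromosome_length = 3e7,
                            n_loci = 1500, maf_min = 0.05, maf_max = 0.5,
                            depth_mean = 26, depth_dispersion = 8,
                            genotyping_error = 0, missing_rate = 0,
                            paralog_fraction = 0, tag_pair_rate = 0.5,
                            baited_fraction = 1,
                            n_sites = 1, site_clustering = 0,
                            n_burnin_generations = 8, seed = 1) {
  cfg <- list(
    n_sires = stopifnot_count(n_sires, "n_sires"),
    n_dams = stopifnot_count(n_dams, "n_dams"),
    mate_mean = mate_mean, offspring_mean = offspring_mean,
    offspring_dispersion = offspring_dispersion,
    n_chromosomes = stopifnot_count(n_chromosomes, "n_chromosomes"),
    chromosome_length = chromosome_length,
    n_loci = stopifnot_count(n_loci, "n_loci"),
    maf_min = maf_min, maf_max = maf_max,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    genotyping_error = stopifnot_prob(genotyping_error, "genotyping_error"),
    missing_rate = stopifnot_prob(missing_rate, "missing_rate"),
    paralog_fraction = stopifnot_prob(paralog_fraction, "paralog_fraction"),
    tag_pair_rate = stopifnot_prob(tag_pair_rate, "tag_pair_rate"),
    baited_fraction = stopifnot_prob(baited_fraction, "baited_fraction"),
    n_sites = stopifnot_count(n_sites, "n_sites"),
    site_clustering = site_clustering,
    n_burnin_generations = stopifnot_count(n_burnin_generations,
                                           "n_burnin_generations", min = 0L),
    seed = as.integer(seed)
  )
  if (cfg$maf_min <= 0 || cfg$maf_max > 0.5 || cfg$maf_min > cfg$maf_max)
    stop("MAF range must satisfy 0 < maf_min <= maf_max <= 0.5", call. = FALSE)
  if (cfg$mate_mean < 1) stop("mate_mean must be >= 1", call. = FALSE)
  if (cfg$offspring_mean <= 0) stop("offspring_mean must be positive", call. = FALSE)
  if (cfg$site_clustering < 0) stop("site_clustering must be >= 0", call. = FALSE)
  class(cfg) <- "breeding_config"
  cfg
}

#' Simulate the true pedigree of one spawning event
#'
#' Draws matings and offspring numbers under a \code{breeding_config} and
#' returns the full cohort pedigree (before any sampling), with each full-sib
#' family allocated to one of the stream's sampling sites.
#'
#' @param config a \code{breeding_config}
#' @return a data frame of class \code{pedigree} with columns
#'   \code{offspring}, \code{sire}, \code{dam}, \code{site}; attributes carry
#'   the number of configured sites and \code{source = "true"}.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "breeding_config"))
  with_seed(stage_seed(config$seed, "pedigree"), {
    n_mates <- 1L + rpois(config$n_sires, config$mate_mean - 1)
    sire_idx <- rep(seq_len(config$n_sires), n_mates)
    dam_idx <- unlist(lapply(n_mates, function(k)
      sample.int(config$n_dams, k, replace = TRUE)))
    # collapse duplicate pairs from with-replacement mate draws
    pair_key <- paste(sire_idx, dam_idx)
    keep <- !duplicated(pair_key)
    sire_idx <- sire_idx[keep]; dam_idx <- dam_idx[keep]
    n_pairs <- length(sire_idx)
    n_off <- if (is.finite(config$offspring_dispersion)) {
      rnbinom(n_pairs, size = config$offspring_dispersion,
              mu = config$offspring_mean)
    } else {
      rpois(n_pairs, config$offspring_mean)
    }
    if (sum(n_off) == 0)
      stop("simulated cohort has zero offspring; increase offspring_mean",
           call. = FALSE)
    fam_of_off <- rep(seq_len(n_pairs), n_off)
    ped <- data.frame(
      offspring = paste0("off_", seq_len(sum(n_off))),
      sire = paste0("S", rep(sire_idx, n_off)),
      dam = paste0("D", rep(dam_idx, n_off)),
      site = allocate_sites(fam_of_off, config$n_sites, config$site_clustering),
      stringsAsFactors = FALSE
    )
    attr(ped, "n_sites") <- config$n_sites
    attr(ped, "source") <- "true"
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

# Assign each offspring a site. clustering controls how spatially localized
# a full-sib family is: each family draws its own site-weight vector from a
# Dirichlet with concentration 1/clustering. clustering = 0 spreads every
# family's offspring uniformly over sites; large values put each family
# almost entirely at a single site, so a one-site sample sees few families.
allocate_sites <- function(fam_of_off, n_sites, clustering) {
  if (n_sites == 1L) return(rep(1L, length(fam_of_off)))
  n_fam <- max(fam_of_off)
  sites <- integer(length(fam_of_off))
  for (f in seq_len(n_fam)) {
    idx <- which(fam_of_off == f)
    if (!length(idx)) next
    if (clustering <= 0) {
      probs <- rep(1 / n_sites, n_sites)
    } else {
      g <- rgamma(n_sites, shape = 1 / clustering, rate = 1)
      if (sum(g) == 0) g[sample.int(n_sites, 1)] <- 1
      probs <- g / sum(g)
    }
    sites[idx] <- sample.int(n_sites, length(idx), replace = TRUE, prob = probs)
  }
  sites
}

#' Demographic effective number of breeders of a pedigree
#'
#' Oracle used for parameter-recovery tests: the separate-sexes variance
#' effective size computed from realized offspring numbers of contributing
#' parents. Per sex, \eqn{N_e = (N k - 1) / (k - 1 + V_k / k)} with
#' \eqn{k} the mean and \eqn{V_k} the sample variance of offspring number,
#' and the sexes combine as \eqn{N_b = 4 N_{e,m} N_{e,f} / (N_{e,m} + N_{e,f})}.
#' Only parents with at least one sampled offspring contribute. The formula
#' value is returned as-is in degenerate cases (it can be negative when a
#' single parent has k = 1).
#'
#' @param ped a pedigree data frame with \code{sire} and \code{dam} columns
#' @return demographic Nb (scalar)
#' @export
demographic_nb <- function(ped) {
  ne_sex <- function(k) {
    n <- length(k); kbar <- mean(k)
    vk <- if (n > 1) var(k) else 0
    (n * kbar - 1) / (kbar - 1 + vk / kbar)
  }
  ks <- as.vector(table(ped$sire))
  kd <- as.vector(table(ped$dam))
  if (!length(ks) || !length(kd))
    stop("pedigree must have at least one sire and one dam", call. = FALSE)
  nm <- ne_sex(ks); nf <- ne_sex(kd)
  4 * nm * nf / (nm + nf)
}

#' Sample a larval cohort from a pedigree
#'
#' Emulates clustered opportunistic stream sampling: full-sib families are
#' (re)allocated to the stream's sites with concentration \code{clustering},
#' \code{n_sites} non-empty sites are then chosen at random, and \code{n}
#' offspring are drawn uniformly without replacement from those sites.
#'
#' @param ped a pedigree from \code{\link{simulate_pedigree}}
#' @param n number of offspring to sample (at most the cohort size)
#' @param n_sites number of sites to sample from (at most the configured
#'   total; capped at the number of occupied sites)
#' @param clustering site-concentration parameter (see
#'   \code{\link{breeding_config}})
#' @param seed integer seed
#' @return the sampled subset, a \code{pedigree} with site indices
#' @export
sample_cohort <- function(ped, n, n_sites, clustering, seed) {
  total_sites <- attr(ped, "n_sites")
  if (is.null(total_sites)) total_sites <- max(ped$site)
  if (n_sites > total_sites)
    stop("n_sites exceeds the configured number of sites", call. = FALSE)
  if (n > nrow(ped)) stop("n exceeds the cohort size", call. = FALSE)
  with_seed(stage_seed(seed, "sampling"), {
    fam <- paste(ped$sire, ped$dam)
    fam_ids <- unique(fam)
    ped$site <- allocate_sites(match(fam, fam_ids), total_sites, clustering)
    occupied <- unique(ped$site)
    chosen <- if (length(occupied) <= n_sites) occupied else
      sample(occupied, n_sites)
    pool <- which(ped$site %in% chosen)
    take <- if (length(pool) <= n) pool else sample(pool, n)
    out <- ped[sort(take), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_sites") <- total_sites
    attr(out, "source") <- attr(ped, "source")
    class(out) <- c("pedigree", "data.frame")
    out
  })
}

#' Simulate cohort genotypes with read depths and artifacts
#'
#' Parent genotypes are drawn from Hardy-Weinberg proportions at loci whose
#' alternate-allele frequencies come from the configured MAF range; offspring
#' genotypes follow Mendelian transmission. Per-genotype read depths are drawn
#' from the configured depth distribution and split binomially between
#' alleles. A configurable fraction of loci is emitted as the elementwise
#' merge of two independent loci (summed reads, genotype called from the
#' merged reads), producing the heterozygote excess and read-ratio deviation
#' signature of collapsed paralogs. Genotyping errors and missingness are
#' applied last.
#'
#' @param ped pedigree of the (sampled) cohort
#' @param config a \code{breeding_config}
#' @return a \code{genotype_matrix} for the offspring in \code{ped}
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "breeding_config"))
  L <- config$n_loci
  if (config$tag_pair_rate > 0 && L < 2 * config$n_chromosomes)
    stop("tag sharing requires at least 2 loci per chromosome on average; ",
         "increase n_loci or set tag_pair_rate = 0", call. = FALSE)
  n <- nrow(ped)
  if (n == 0) stop("pedigree is empty", call. = FALSE)
  with_seed(stage_seed(config$seed, "genotypes"), {
    loci <- simulate_loci(config)
    sires_p <- sort(unique(ped$sire)); dams_p <- sort(unique(ped$dam))
    if (length(sires_p) > config$n_sires || length(dams_p) > config$n_dams)
      stop("pedigree references more parents than the config provides",
           call. = FALSE)
    p <- loci$p_alt
    # hidden duplicate locus for paralog-merged loci
    is_par <- loci$paralog
    p2 <- runif(L, config$maf_min, config$maf_max)

    # Adult population at the focal spawning event, after burn-in under the
    # same breeding regime so standing LD is at drift-recombination
    # equilibrium for the regime's effective size. Loci segregate freely
    # (physical linkage within chromosomes is not modelled).
    n_ad <- config$n_sires + config$n_dams
    freqs <- c(p, p2)
    Gad <- matrix(rbinom(n_ad * 2 * L, 2, rep(freqs, each = n_ad)), n_ad, 2 * L)
    for (gen in seq_len(config$n_burnin_generations)) {
      n_mates <- 1L + rpois(config$n_sires, config$mate_mean - 1)
      si <- rep(seq_len(config$n_sires), n_mates)
      di <- unlist(lapply(n_mates, function(k)
        sample.int(config$n_dams, k, replace = TRUE)))
      keep <- !duplicated(paste(si, di))
      si <- si[keep]; di <- di[keep]
      no <- if (is.finite(config$offspring_dispersion))
        rnbinom(length(si), size = config$offspring_dispersion,
                mu = config$offspring_mean)
      else rpois(length(si), config$offspring_mean)
      if (sum(no) < 2) next
      gs <- Gad[rep(si, no), , drop = FALSE]
      gd <- Gad[config$n_sires + rep(di, no), , drop = FALSE]
      pool <- matrix(rbinom(length(gs), 1, gs / 2) +
                       rbinom(length(gd), 1, gd / 2), nrow(gs), ncol(gs))
      # next generation's adults drawn proportionally to family size
      # (largest-remainder quotas), so survival to adulthood adds no drift
      # beyond the reproductive variance of the regime itself
      fam_of <- rep(seq_along(no), no)
      quota <- no * n_ad / sum(no)
      take <- floor(quota)
      rem <- n_ad - sum(take)
      if (rem > 0) {
        extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      take <- pmin(take, no)
      if (nrow(pool) <= n_ad) {
        idx <- sample.int(nrow(pool), n_ad, replace = nrow(pool) < n_ad)
      } else {
        short <- n_ad - sum(take)   # families smaller than their quota
        idx <- unlist(lapply(seq_along(no), function(fm) {
          members <- which(fam_of == fm)
          members[sample.int(length(members), take[fm])]
        }))
        if (short > 0) {
          left <- setdiff(seq_len(nrow(pool)), idx)
          idx <- c(idx, left[sample.int(length(left), short)])
        }
      }
      Gad <- pool[idx, , drop = FALSE]
    }
    filler <- function(prefix, k)
      if (k > 0) paste0(prefix, seq_len(k)) else character(0)
    rownames(Gad) <- c(sires_p,
                       filler(".S", config$n_sires - length(sires_p)),
                       dams_p,
                       filler(".D", config$n_dams - length(dams_p)))

    mendel <- function(cols) {
      gs <- Gad[ped$sire, cols, drop = FALSE]
      gd <- Gad[ped$dam, cols, drop = FALSE]
      matrix(rbinom(n * L, 1, gs / 2) + rbinom(n * L, 1, gd / 2), n, L)
    }
    G1 <- mendel(seq_len(L))            # primary locus, all loci
    G2 <- mendel(L + seq_len(L))        # hidden duplicate, used at paralog loci

    draw_depth <- function() {
      if (is.finite(config$depth_dispersion))
        matrix(rnbinom(n * L, size = config$depth_dispersion,
                       mu = config$depth_mean), n, L)
      else
        matrix(rpois(n * L, config$depth_mean), n, L)
    }
    split_reads <- function(G, D) {
      alt <- matrix(rbinom(n * L, D, G / 2), n, L)
      list(ref = D - alt, alt = alt)
    }
    d1 <- draw_depth()
    r1 <- split_reads(G1, d1)
    ref <- r1$ref; alt <- r1$alt
    if (any(is_par)) {
      d2 <- draw_depth()
      r2 <- split_reads(G2, d2)
      pc <- which(is_par)
      ref[, pc] <- ref[, pc] + r2$ref[, pc]
      alt[, pc] <- alt[, pc] + r2$alt[, pc]
    }

    geno <- G1
    if (any(is_par)) {
      # paralog call comes from merged reads: both alleles seen => het
      pc <- which(is_par)
      rm_ <- ref[, pc, drop = FALSE]; am_ <- alt[, pc, drop = FALSE]
      g <- ifelse(am_ > 0 & rm_ > 0, 1L, ifelse(am_ > 0, 2L, 0L))
      g[rm_ + am_ == 0] <- NA_integer_
      geno[, pc] <- g
    }
    if (config$genotyping_error > 0) {
      flip <- matrix(runif(n * L) < config$genotyping_error, n, L) & !is.na(geno)
      if (any(flip)) {
        shift <- 1L + (runif(sum(flip)) < 0.5)      # +1 or +2 mod 3
        geno[flip] <- (geno[flip] + shift) %% 3L
      }
    }
    geno[ref + alt == 0] <- NA_integer_
    if (config$missing_rate > 0) {
      geno[matrix(runif(n * L) < config$missing_rate, n, L)] <- NA_integer_
    }
    rownames(geno) <- rownames(ref) <- rownames(alt) <- ped$offspring
    colnames(geno) <- colnames(ref) <- colnames(alt) <- loci$locus
    storage.mode(geno) <- "integer"
    storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
    out <- genotype_matrix(geno, loci[, c("locus", "chrom", "pos", "tag", "baited")],
                           ref, alt)
    attr(out, "paralog") <- loci$paralog
    # true parental genotypes (primary loci), for validation
    attr(out, "parent_genotypes") <- Gad[c(sires_p, dams_p), seq_len(L),
                                         drop = FALSE]
    attr(out, "true_freqs") <- loci$p_alt   # base-population allele frequencies
    out
  })
}

# Locus map: chromosomes drawn uniformly, positions uniform on the chromosome,
# consecutive same-tag SNP pairs created at tag_pair_rate (second SNP placed
# ~100 bp downstream, same chromosome/tag).
simulate_loci <- function(config) {
  L <- config$n_loci
  chrom <- integer(L); pos <- numeric(L); tag <- integer(L)
  cur_tag <- 0L
  i <- 1L
  while (i <= L) {
    cur_tag <- cur_tag + 1L
    chrom[i] <- sample.int(config$n_chromosomes, 1L)
    pos[i] <- floor(runif(1, 1, config$chromosome_length))
    tag[i] <- cur_tag
    if (i < L && runif(1) < config$tag_pair_rate) {
      chrom[i + 1L] <- chrom[i]
      pos[i + 1L] <- pos[i] + 100
      tag[i + 1L] <- cur_tag
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  ord <- order(chrom, pos)
  data.frame(
    locus = paste0("snp_", seq_len(L)),
    chrom = paste0("chr", chrom[ord]),
    pos = pos[ord],
    tag = paste0("tag_", tag[ord]),
    baited = runif(L) < config$baited_fraction,
    p_alt = runif(L, config$maf_min, config$maf_max),
    paralog = runif(L) < config$paralog_fraction
  )
}

#' Write a pedigree truth table
#'
#' Tab-separated \code{offspring}, \code{sire}, \code{dam}, \code{site}.
#' @param ped a pedigree
#' @param path output path
#' @export
write_pedigree_truth <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
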