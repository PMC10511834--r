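# Sibship reconstruction from pairwise relationship likelihoods, and the
# pedigree statistics consumed downstream (SF-Nb, Ns, kbar, Vk).

# Per-locus 3x3 joint genotype probability under an IBD-coefficient model
# (k0, k1, k2), Hardy-Weinberg parental genotypes at alt frequency p, and a
# symmetric call-error model (true genotype replaced by either other code
# with probability error/2 each).
joint_genotype_probs <- function(p, k, error) {
  q <- 1 - p
  P <- c(q^2, 2 * p * q, p^2)
  T1 <- rbind(c(q, p, 0),
              c(q / 2, 1 / 2, p / 2),
              c(0, q, p))
  J <- k[1] * tcrossprod(P) +
    k[2] * P * T1 +
    k[3] * diag(P)
  if (error > 0) {
    E <- matrix(error / 2, 3, 3); diag(E) <- 1 - error
    J <- t(E) %*% J %*% E
  }
  J
}

ibd_models <- list(
  U = c(1, 0, 0),
  HS = c(0.5, 0.5, 0),
  FS = c(0.25, 0.5, 0.25)
)

# Log-likelihood lookup tables: one L x 10 matrix per model; columns 1..9
# index the joint genotype code 3*g_i + g_j (+1), column 10 is the zero
# contribution of a missing comparison.
pair_luts <- function(p, error) {
  L <- length(p)
  luts <- lapply(ibd_models, function(k) matrix(0, L, 10))
  for (l in seq_len(L)) {
    for (m in names(ibd_models)) {
      J <- joint_genotype_probs(p[l], ibd_models[[m]], error)
      luts[[m]][l, 1:9] <- log(pmax(as.vector(t(J)), 1e-300))
    }
  }
  luts
}

#' Relationship likelihoods for one offspring pair
#'
#' Classifies a pair of individuals as unrelated (U), half-sib (HS) or
#' full-sib (FS) by summed per-locus log-likelihoods under the IBD-coefficient
#' models (k0,k1,k2) = (1,0,0), (0.5,0.5,0) and (0.25,0.5,0.25), with allele
#' frequencies estimated from the cohort and genotyping error folded in.
#' Missing loci are skipped; a pair with zero overlapping loci is returned as
#' unrelated with \code{classifiable = FALSE}.
#'
#' @param gm a \code{genotype_matrix}
#' @param i,j individual indices or ids
#' @param error assumed genotyping error rate
#' @param allele_freqs optional per-locus alternate-allele frequencies; by
#'   default estimated from the cohort itself. Note that cohort-internal
#'   frequencies make a cohort consisting of a single family unidentifiable
#'   (conditional on its parents, full sibs are independent draws, and the
#'   family fixes the frequency estimates), so reference frequencies should
#'   be supplied when the sample may be one or very few families.
#' @return a list: \code{pair}, \code{loglik} (named U/HS/FS),
#'   \code{relationship}, \code{n_loci}, \code{classifiable}
#' @export
pair_likelihoods <- function(gm, i, j, error = 0.01, allele_freqs = NULL) {
  if (is.character(i)) i <- match(i, rownames(gm$genotypes))
  if (is.character(j)) j <- match(j, rownames(gm$genotypes))
  p <- if (is.null(allele_freqs)) allele_freq(gm) else allele_freqs
  ok <- !is.na(p)
  luts <- pair_luts(p[ok], error)
  gi <- gm$genotypes[i, ok]; gj <- gm$genotypes[j, ok]
  code <- ifelse(is.na(gi) | is.na(gj), 9L, 3L * gi + gj)
  L <- sum(ok)
  lin <- seq_len(L) + code * L
  ll <- vapply(luts, function(m) sum(m[lin]), numeric(1))
  n_used <- sum(code != 9L)
  rel <- if (n_used == 0) "U" else names(ll)[which.max(ll)]
  list(pair = c(rownames(gm$genotypes)[i], rownames(gm$genotypes)[j]),
       loglik = ll, relationship = rel, n_loci = n_used,
       classifiable = n_used > 0)
}

# Classify all pairs. Returns a data frame (i, j, ll_U, ll_HS, ll_FS,
# n_loci, rel) with i < j as row indices into gm.
classify_pairs <- function(gm, error = 0.01, allele_freqs = NULL) {
  G <- gm$genotypes
  n <- nrow(G)
  p <- if (is.null(allele_freqs)) allele_freq(gm) else allele_freqs
  ok <- which(!is.na(p))
  luts <- pair_luts(p[ok], error)
  G <- G[, ok, drop = FALSE]
  L <- length(ok)
  Gc <- G; Gc[is.na(Gc)] <- -1000L   # forces code outside 0..8 -> missing
  out_i <- out_j <- integer(0)
  llu <- llh <- llf <- nl <- list()
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    codes <- matrix(3L * Gc[i, ], length(js), L, byrow = TRUE) +
      Gc[js, , drop = FALSE]
    miss <- codes < 0L | codes > 8L
    codes[miss] <- 9L
    lin <- matrix(rep(seq_len(L), each = length(js)), length(js), L) +
      codes * L
    llu[[i]] <- rowSums(matrix(luts$U[lin], length(js), L))
    llh[[i]] <- rowSums(matrix(luts$HS[lin], length(js), L))
    llf[[i]] <- rowSums(matrix(luts$FS[lin], length(js), L))
    nl[[i]] <- rowSums(!miss)
    out_i <- c(out_i, rep(i, length(js)))
    out_j <- c(out_j, js)
  }
  d <- data.frame(i = out_i, j = out_j,
                  ll_U = unlist(llu), ll_HS = unlist(llh), ll_FS = unlist(llf),
                  n_loci = unlist(nl))
  rel <- c("U", "HS", "FS")[max.col(d[, c("ll_U", "ll_HS", "ll_FS")],
                                    ties.method = "first")]
  rel[d$n_loci == 0] <- "U"
  d$rel <- rel
  d
}

#' Reconstruct a sibship pedigree from genotypes
#'
#' Full-sib families are the connected components of the FS-classified pair
#' graph after triangle-consistency pruning: an FS edge is kept only if some
#' third individual is FS with both ends (or HS with both ends), unless the
#' edge is an isolated dyad. Families then receive two parent labels each, and
#' a parent label is merged between two families when the majority of their
#' cross-family pairs classify as half-sibs; merges are processed by
#' descending support with slot-consistency checks so the two parent-label
#' pools stay disjoint. Remaining singletons get two unique labels.
#'
#' @param gm a \code{genotype_matrix}
#' @param error assumed genotyping error rate (default 0.01)
#' @param allele_freqs optional reference allele frequencies (see
#'   \code{\link{pair_likelihoods}})
#' @return a \code{pedigree} data frame (offspring, sire, dam) with
#'   \code{source = "reconstructed"}
#' @export
reconstruct <- function(gm, error = 0.01, allele_freqs = NULL) {
  n <- nrow(gm$genotypes)
  if (n < 2) stop("need at least two individuals", call. = FALSE)
  cp <- classify_pairs(gm, error, allele_freqs)
  cp$lr_fs <- cp$ll_FS - cp$ll_U
  fs <- cp[cp$rel == "FS", , drop = FALSE]
  fs <- fs[order(-fs$lr_fs), , drop = FALSE]

  # adjacency sets for triangle support
  fs_adj <- hs_adj <- vector("list", n)
  add_edge <- function(adj, a, b) { adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a); adj }
  for (r in which(cp$rel == "FS")) fs_adj <- add_edge(fs_adj, cp$i[r], cp$j[r])
  for (r in which(cp$rel == "HS")) hs_adj <- add_edge(hs_adj, cp$i[r], cp$j[r])
  fs_deg <- lengths(fs_adj)

  keep <- logical(nrow(fs))
  if (nrow(fs)) for (r in seq_len(nrow(fs))) {
    i <- fs$i[r]; j <- fs$j[r]
    dyad <- fs_deg[i] == 1L && fs_deg[j] == 1L
    tri <- length(intersect(fs_adj[[i]], fs_adj[[j]])) > 0 ||
      length(intersect(hs_adj[[i]], hs_adj[[j]])) > 0
    keep[r] <- dyad || tri
  }
  fs <- fs[keep, , drop = FALSE]

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(fs)) g <- igraph::add_edges(g, rbind(fs$i, fs$j))
  fam <- igraph::components(g)$membership
  nf <- max(fam)

  # parent-slot labels per family; slot pools stay disjoint
  slots <- cbind(seq_len(nf), nf + seq_len(nf))
  shared <- matrix(FALSE, nf, 2)   # slot label shared with another family?

  # half-sib support between family pairs: cross-family pair log-likelihoods
  # are pooled, so several weak pairwise signals can still establish a shared
  # parent between small families
  fam_i <- fam[cp$i]; fam_j <- fam[cp$j]
  cross <- fam_i != fam_j
  if (any(cross)) {
    a <- pmin(fam_i[cross], fam_j[cross]); b <- pmax(fam_i[cross], fam_j[cross])
    key <- paste(a, b)
    tot_u <- tapply(cp$ll_U[cross], key, sum)
    tot_h <- tapply(cp$ll_HS[cross], key, sum)
    tot_f <- tapply(cp$ll_FS[cross], key, sum)
    support <- tot_h - pmax(tot_u, tot_f)
    cand <- names(support)[support > 0]
    if (length(cand)) {
      ord <- order(-support[cand], cand)
      hs_keys <- new.env(parent = emptyenv())
      for (k in cand) assign(k, TRUE, envir = hs_keys)
      is_hs_pair <- function(f1, f2)
        exists(paste(min(f1, f2), max(f1, f2)), envir = hs_keys)
      label_fams <- function(lab) which(slots[, 1] == lab | slots[, 2] == lab)
      free_slot <- function(fm) which(!shared[fm, ])[1]  # NA when both shared
      for (k in cand[ord]) {
        fg <- as.integer(strsplit(k, " ")[[1]])
        f <- fg[1]; gfam <- fg[2]
        if (length(intersect(slots[f, ], slots[gfam, ]))) next
        merged <- FALSE
        # join an existing shared-parent group when every member of that
        # group is also half-sib-supported with the joining family
        for (fg_pair in list(c(f, gfam), c(gfam, f))) {
          donor <- fg_pair[1]; joiner <- fg_pair[2]
          for (s in 1:2) {
            mem <- setdiff(label_fams(slots[donor, s]), donor)
            sj <- free_slot(joiner)
            if (length(mem) && !is.na(sj) &&
                all(vapply(mem, is_hs_pair, logical(1), f2 = joiner))) {
              slots[joiner, sj] <- slots[donor, s]
              shared[joiner, sj] <- TRUE
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) {
          s_f <- free_slot(f); s_g <- free_slot(gfam)
          if (!is.na(s_f) && !is.na(s_g)) {
            slots[gfam, s_g] <- slots[f, s_f]
            shared[f, s_f] <- TRUE
            shared[gfam, s_g] <- TRUE
          }
        }
      }
    }
  }

  ped <- data.frame(
    offspring = rownames(gm$genotypes),
    sire = paste0("P", slots[fam, 1]),
    dam = paste0("P", slots[fam, 2]),
    stringsAsFactors = FALSE
  )
  attr(ped, "source") <- "reconstructed"
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Sibship-frequency estimate of the effective number of breeders
#'
#' Over all offspring pairs, \code{Q_pat} and \code{Q_mat} are the fractions
#' sharing a sire and a dam; the random-mating sibship-frequency estimator is
#' \eqn{1/\hat N_b = (Q_{pat} + Q_{mat}) / 4}. Parent sharing is counted by
#' label across both parent slots (identical to the per-slot count when the
#' sire and dam label pools are disjoint, as in true or external pedigrees,
#' but robust to arbitrary slot assignment in reconstructed ones). The 95%
#' interval is a nonparametric percentile bootstrap over offspring.
#'
#' @param ped a pedigree data frame (\code{sire}, \code{dam})
#' @param n_boot bootstrap draws (default 1000; 0 skips the interval)
#' @param seed integer seed for the bootstrap
#' @return an \code{nb_estimate} with \code{method = "SF"}
#' @export
sibship_nb <- function(ped, n_boot = 1000, seed = 1) {
  n <- nrow(ped)
  if (n < 2) stop("need at least two offspring", call. = FALSE)
  # pairs of two copies of the same resampled individual are excluded from
  # both numerator and denominator (they trivially share both parents);
  # shared parents are counted per label over both slots
  nb_of <- function(idx) {
    m <- length(idx)
    pairs2 <- function(x) { t <- tabulate(factor(x)); sum(t * (t - 1)) / 2 }
    self <- pairs2(idx)
    denom <- m * (m - 1) / 2 - self
    shared <- pairs2(c(ped$sire[idx], ped$dam[idx])) - 2 * self
    q_tot <- shared / denom          # Q_pat + Q_mat
    if (q_tot == 0) Inf else 4 / q_tot
  }
  point <- nb_of(seq_len(n))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bs <- with_seed(stage_seed(seed, "sf-bootstrap"), {
      vapply(seq_len(n_boot), function(b) {
        nb_of(sample.int(n, n, replace = TRUE))
      }, numeric(1))
    })
    ci <- unname(quantile(bs, c(0.025, 0.975), names = FALSE, type = 1))
  }
  structure(
    list(method = "SF", point = point, ci_low = ci[1], ci_high = ci[2],
         n_offspring = n,
         ci_method = "percentile bootstrap over offspring"),
    class = "nb_estimate"
  )
}

#' Pedigree summary statistics: Ns, kbar, Vk
#'
#' \code{Ns} counts distinct parent labels across both parent slots;
#' \code{k} is the number of offspring per contributing parent, summarized by
#' its mean \code{kbar} and sample variance \code{Vk} (divisor Ns - 1;
#' 0 when a single parent contributes).
#'
#' @param ped a pedigree data frame
#' @return list with \code{ns}, \code{kbar}, \code{vk}, and the named
#'   per-parent count vector \code{k}
#' @export
sibship_stats <- function(ped) {
  if (!nrow(ped)) stop("pedigree is empty", call. = FALSE)
  k <- table(c(ped$sire, ped$dam))
  kv <- as.vector(k)
  list(ns = length(kv),
       kbar = mean(kv),
       vk = if (length(kv) > 1) var(kv) else 0,
       k = setNames(kv, names(k)))
}

#' Read and write external pedigrees
#'
#' Reads a BestConfig-style tab- or whitespace-separated table
#' (OffspringID, FatherID, MotherID; a header row is tolerated) as emitted by
#' full-likelihood sibship software, so externally reconstructed pedigrees can
#' replace the built-in reconstruction.
#'
#' @param path input file
#' @return a \code{pedigree} with \code{source = "external"}
#' @export
read_pedigree <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1)), "[\t ]+")[[1]]
  has_header <- any(grepl("offspring", first, ignore.case = TRUE))
  d <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  d <- d[, 1:3]
  names(d) <- c("offspring", "sire", "dam")
  if (length(intersect(unique(d$sire), unique(d$dam))))
    warning("sire and dam label sets overlap; overlapping labels are ",
            "treated as the same spawner in downstream statistics")
  attr(d, "source") <- "external"
  class(d) <- c("pedigree", "data.frame")
  d
}

#' @rdname read_pedigree
#' @param ped pedigree to write
#' @export
write_pedigree <- function(ped, path) {
  d <- data.frame(OffspringID = ped$offspring, FatherID = ped$sire,
                  MotherID = ped$dam)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a COLONY-style offspring genotype file
#'
#' Two integer allele columns per locus (1 = ref, 2 = alt, 0 0 = missing),
#' offspring id first, for users running external full-likelihood software.
#'
#' @param gm a \code{genotype_matrix}
#' @param path output file
#' @export
write_colony_genotypes <- function(gm, path) {
  G <- gm$genotypes
  a1 <- ifelse(is.na(G), 0L, ifelse(G >= 1L, 2L, 1L))
  a2 <- ifelse(is.na(G), 0L, ifelse(G == 2L, 2L, 1L))
  L <- ncol(G)
  out <- matrix(0L, nrow(G), 2L * L)
  out[, seq(1, 2 * L, by = 2)] <- a1
  out[, seq(2, 2 * L, by = 2)] <- a2
  d <- data.frame(id = rownames(G), out)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
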