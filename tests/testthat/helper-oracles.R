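# Independent oracles used across tests. These deliberately use direct
# enumeration / naive loops, not the package's vectorized or compiled paths.

# Build a genotype_matrix from a plain matrix plus minimal locus metadata.
make_gm <- function(G, chrom = NULL, pos = NULL, tag = NULL, baited = NULL,
                    ref_depth = NULL, alt_depth = NULL) {
  L <- ncol(G)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000
  if (is.null(tag)) tag <- paste0("t", seq_len(L))
  if (is.null(baited)) baited <- rep(TRUE, L)
  genotype_matrix(G,
                  data.frame(locus = paste0("L", seq_len(L)), chrom = chrom,
                             pos = pos, tag = tag, baited = baited),
                  ref_depth, alt_depth)
}

# Burrows composite r2 for one locus pair by direct enumeration of the 3x3
# genotype contingency table over jointly non-missing individuals.
oracle_burrows_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  S <- length(x)
  if (S < 2) return(NA_real_)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(S)) tab[x[i] + 1, y[i] + 1] <- tab[x[i] + 1, y[i] + 1] + 1
  xs <- 0:2; ys <- 0:2
  sum_x <- sum(rowSums(tab) * xs); sum_y <- sum(colSums(tab) * ys)
  sum_xy <- 0
  for (a in 1:3) for (b in 1:3) sum_xy <- sum_xy + tab[a, b] * xs[a] * ys[b]
  cov_xy <- (sum_xy - sum_x * sum_y / S) / (S - 1)
  delta <- cov_xy / 2
  pa <- sum_x / (2 * S); pb <- sum_y / (2 * S)
  p2a <- sum(tab[3, ]) / S; p2b <- sum(tab[, 3]) / S
  pia <- pa * (1 - pa) + (p2a - pa^2)
  pib <- pb * (1 - pb) + (p2b - pb^2)
  if (pia <= 0 || pib <= 0) return(NA_real_)
  delta^2 / (pia * pib)
}

# Mendelian transmission probability P(g_off | g_sire, g_dam) for 0/1/2 codes.
oracle_mendel <- function(g_off, g_s, g_d) {
  p_gamete <- function(g) c(`0` = 1 - g / 2, `1` = g / 2)  # P(transmits ref/alt)
  ps <- p_gamete(g_s); pd <- p_gamete(g_d)
  tot <- 0
  for (as_ in 0:1) for (ad in 0:1)
    if (as_ + ad == g_off) tot <- tot + ps[[as_ + 1]] * pd[[ad + 1]]
  tot
}

# Joint genotype probability of two offspring under an explicit parental
# configuration model, enumerated over all parent genotypes at alt freq p.
#  rel = "FS": same sire and dam; "HS": shared sire, independent dams;
#  "U": all four parents independent.
oracle_joint_prob <- function(g1, g2, p, rel) {
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  tot <- 0
  for (gs in 0:2) for (gd1 in 0:2) {
    pr_base <- hw[gs + 1] * hw[gd1 + 1]
    if (rel == "FS") {
      tot <- tot + pr_base * oracle_mendel(g1, gs, gd1) * oracle_mendel(g2, gs, gd1)
    } else if (rel == "HS") {
      for (gd2 in 0:2)
        tot <- tot + pr_base * hw[gd2 + 1] *
          oracle_mendel(g1, gs, gd1) * oracle_mendel(g2, gs, gd2)
    } else {
      for (gs2 in 0:2) for (gd2 in 0:2)
        tot <- tot + pr_base * hw[gs2 + 1] * hw[gd2 + 1] *
          oracle_mendel(g1, gs, gd1) * oracle_mendel(g2, gs2, gd2)
    }
  }
  tot
}

# Adjusted Rand index between two partitions (vectors of group labels).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Fast non-CI LD point estimate for simulation loops.
ld_point <- function(gm) ld_nb(gm, ci = FALSE)$point
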