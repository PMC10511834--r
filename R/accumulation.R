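#' Pedigree accumulation curve
#'
#' Number of unique parental genotypes as a function of the number of
#' offspring sampled, averaged over random offspring orderings: the
#' pedigree analogue of a species accumulation curve, with parents as
#' species and offspring as incidence samples.
#'
#' @param ped a pedigree data frame
#' @param n_perm number of random orderings (default 100)
#' @param seed integer seed
#' @return an \code{accumulation_curve} data frame with columns \code{m}
#'   (offspring sampled), \code{mean}, \code{lower}, \code{upper}
#'   (2.5/97.5 percentiles over orderings)
#' @export
accumulation_curve <- function(ped, n_perm = 100, seed = 1) {
  n <- nrow(ped)
  if (!n) stop("pedigree is empty", call. = FALSE)
  counts <- with_seed(stage_seed(seed, "accumulation"), {
    vapply(seq_len(n_perm), function(b) {
      o <- sample.int(n)
      labs <- rbind(ped$sire[o], ped$dam[o])  # interleave sire/dam per offspring
      newp <- !duplicated(as.vector(labs))
      cumsum(newp)[seq(2, 2 * n, by = 2)]
    }, numeric(n))
  })
  counts <- matrix(counts, nrow = n)
  out <- data.frame(
    m = seq_len(n),
    mean = rowMeans(counts),
    lower = apply(counts, 1, quantile, probs = 0.025, names = FALSE),
    upper = apply(counts, 1, quantile, probs = 0.975, names = FALSE)
  )
  attr(out, "n_permutations") <- n_perm
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Chao extrapolation of the total number of spawners
#'
#' Treats each parent as a species and each offspring as an incidence
#' sample (a parent's incidence is its number of sampled offspring, pooled
#' across both parent slots), and applies the bias-corrected incidence-based
#' Chao estimator:
#' \deqn{\hat S = S_{obs} + \frac{N-1}{N} \frac{q_1 (q_1 - 1)}{2 (q_2 + 1)}}
#' with \eqn{q_1}, \eqn{q_2} the numbers of parents seen in exactly one and
#' two offspring and \eqn{N} the number of offspring. The standard error uses
#' the variance of the bias-corrected form (0 when \eqn{q_1 = 0}: the
#' accumulation curve has reached its asymptote).
#'
#' @param ped a pedigree data frame
#' @return a \code{chao_estimate} list: \code{s_obs}, \code{q1}, \code{q2},
#'   \code{n}, \code{point}, \code{se}, \code{ci_low}, \code{ci_high}
#'   (point +/- 1.96 se, floored at \code{s_obs})
#' @export
chao_estimate <- function(ped) {
  n <- nrow(ped)
  if (!n) stop("pedigree is empty", call. = FALSE)
  inc <- table(c(ped$sire, ped$dam))
  s_obs <- length(inc)
  q1 <- sum(inc == 1); q2 <- sum(inc == 2)
  A <- (n - 1) / n
  point <- s_obs + A * q1 * (q1 - 1) / (2 * (q2 + 1))
  if (q1 == 0) {
    v <- 0
  } else if (q2 > 0) {
    v <- A * q1 * (q1 - 1) / (2 * (q2 + 1)) +
      A^2 * q1 * (2 * q1 - 1)^2 / (4 * (q2 + 1)^2) +
      A^2 * q1^2 * q2 * (q1 - 1)^2 / (4 * (q2 + 1)^4)
  } else {
    t_hat <- point
    v <- A * q1 * (q1 - 1) / 2 + A^2 * q1 * (2 * q1 - 1)^2 / 4 -
      A^2 * q1^4 / (4 * t_hat)
    v <- max(v, 0)
  }
  se <- sqrt(v)
  structure(
    list(s_obs = s_obs, q1 = q1, q2 = q2, n = n,
         point = point, se = se,
         ci_low = max(s_obs, point - 1.96 * se),
         ci_high = point + 1.96 * se),
    class = "chao_estimate"
  )
}

#' @export
print.chao_estimate <- function(x, ...) {
  cat(sprintf(
    "Chao spawner estimate: %.1f +/- %.1f SE (observed Ns = %d, q1 = %d, q2 = %d, N = %d)\n",
    x$point, x$se, x$s_obs, x$q1, x$q2, x$n))
  invisible(x)
}

#' Plot a pedigree accumulation curve
#'
#' Mean unique-parent count with the 2.5-97.5 percentile band over random
#' offspring orderings; an optional Chao estimate is drawn as a horizontal
#' asymptote line.
#'
#' @param curve an \code{\link{accumulation_curve}}
#' @param chao optional \code{\link{chao_estimate}}
#' @return a ggplot object
#' @export
plot_accumulation <- function(curve, chao = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$m, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Offspring sampled",
                  y = "Unique parental genotypes") +
    ggplot2::theme_minimal()
  if (!is.null(chao))
    p <- p + ggplot2::geom_hline(yintercept = chao$point,
                                 colour = "darkred", linewidth = 0.8)
  p
}
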