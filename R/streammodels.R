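# Cross-stream statistical layer: correlations with census size, VIF
# screening, all-subsets gaussian models with AICc, and model averaging.

#' Load the packaged per-stream cohort records
#'
#' Transcription of the study's per-stream covariates and derived genetic
#' estimates for 17 Great Lakes tributaries: sampling design (sample size,
#' sites, distance), stream covariates (drainage area, years since lampricide
#' treatment), capture-mark-recapture census size (\code{nc}, with the year
#' it refers to: only values matching the cohort's spawning year are used in
#' correlations), and the genetic estimates (LD and SF Nb with intervals, Ns,
#' Chao, kbar, Vk).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return a data frame, one row per stream
#' @export
read_cohort_records <- function(path = system.file("extdata", "tables_1_2.csv",
                                                   package = "breedsize")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Pearson correlation with t-test
#'
#' @param x,y numeric vectors of equal length; rows with a missing value in
#'   either are dropped (pairwise complete).
#' @return list with \code{r}, \code{p} (two-sided), \code{n}, and
#'   \code{defined} (FALSE when a vector is constant)
#' @export
pearson <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Correlations of genetic estimates with census size
#'
#' Pearson correlations of LD-Nb, SF-Nb and a spawner-count estimate against
#' the census size Nc, using only streams whose Nc refers to the cohort's
#' spawning year, optionally restricted to streams with at least \code{min_n}
#' sampled offspring. Because the study leaves ambiguous whether the third
#' series is the observed Ns or the Chao-extrapolated total, the spawner
#' column is selectable.
#'
#' @param records cohort records (see \code{\link{read_cohort_records}})
#' @param min_n minimum sample size retained (default 0 = all)
#' @param spawner which spawner-count column to correlate: "chao" or "ns"
#' @return data frame with rows for each estimate: \code{estimate}, \code{r},
#'   \code{p}, \code{n_streams}
#' @export
nc_correlations <- function(records, min_n = 0, spawner = c("chao", "ns")) {
  spawner <- match.arg(spawner)
  usable <- !is.na(records$nc) &
    !is.na(records$nc_year) & records$nc_year == records$spawning_year &
    records$sample_size >= min_n
  d <- records[usable, , drop = FALSE]
  cols <- c(nb_ld = "nb_ld", nb_sf = "nb_sf", spawner = spawner)
  out <- lapply(names(cols), function(nm) {
    if (sum(complete.cases(d[[cols[[nm]]]], d$nc)) < 3)
      return(data.frame(estimate = cols[[nm]], r = NA_real_, p = NA_real_,
                        n_streams = nrow(d), flagged = TRUE))
    pr <- pearson(d[[cols[[nm]]]], d$nc)
    data.frame(estimate = cols[[nm]], r = pr$r, p = pr$p, n_streams = pr$n,
               flagged = !pr$defined)
  })
  do.call(rbind, out)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} regresses predictor j on
#' all others. With continuous predictors this equals the generalized VIF.
#' Perfect collinearity yields \code{Inf}.
#'
#' @param design data frame of numeric predictors (>= 2 columns, more rows
#'   than columns)
#' @return named numeric vector of VIFs
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) stop("need at least two predictors", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("need more rows than predictors", call. = FALSE)
  vapply(names(design), function(j) {
    fit <- lm(reformulate(setdiff(names(design), j), response = j),
              data = design)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# AICc of an lm fit: AIC + small-sample correction, K counting coefficients
# plus the residual variance. Returns NA when n - K - 1 <= 0.
aicc_lm <- function(fit) {
  ll <- logLik(fit)
  K <- attr(ll, "df")
  n <- nobs(fit)
  if (n - K - 1 <= 0) return(NA_real_)
  -2 * as.numeric(ll) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' All-subsets gaussian model selection with AICc
#'
#' Fits ordinary least squares (gaussian, identity link) models for every
#' subset of the predictors, with interaction terms admitted only alongside
#' both main effects (marginality). Models are ranked by AICc (small-sample
#' corrected AIC); the confidence set contains models with delta AICc < 2.
#' Subsets whose residual degrees of freedom would make the correction
#' undefined are skipped with a warning.
#'
#' @param records data frame of model inputs
#' @param response response column name
#' @param predictors character vector of predictor column names
#' @param interactions character vector of interactions as "a:b" pairs
#' @return a \code{model_set}: table of all models (terms, K, AICc, delta,
#'   weight among the confidence set), the fitted lm objects, and the
#'   confidence-set indices
#' @export
dredge_aicc <- function(records, response, predictors,
                        interactions = character()) {
  d <- records[complete.cases(records[c(response, predictors)]), , drop = FALSE]
  n <- nrow(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(predictors)))
  terms_list <- list()
  for (r in seq_len(nrow(subsets))) {
    main <- predictors[unlist(subsets[r, ])]
    terms_list[[length(terms_list) + 1L]] <- main
    for (ia in interactions) {
      parts <- strsplit(ia, ":")[[1]]
      if (all(parts %in% main))
        terms_list[[length(terms_list) + 1L]] <- c(main, ia)
    }
  }
  fits <- list(); rows <- list()
  skipped <- 0L
  for (tm in terms_list) {
    fml <- if (length(tm)) reformulate(tm, response = response) else
      as.formula(paste(response, "~ 1"))
    fit <- lm(fml, data = d)
    a <- aicc_lm(fit)
    if (is.na(a)) { skipped <- skipped + 1L; next }
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      model = if (length(tm)) paste(tm, collapse = " + ") else "(intercept)",
      K = attr(logLik(fit), "df"),
      AICc = a
    )
  }
  if (skipped) warning(sprintf("%d subset(s) skipped: too few residual df", skipped))
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  ord <- order(tab$delta)
  tab <- tab[ord, , drop = FALSE]; fits <- fits[ord]
  rownames(tab) <- NULL
  conf <- which(tab$delta < 2)
  w <- exp(-tab$delta[conf] / 2)
  tab$weight <- NA_real_
  tab$weight[conf] <- w / sum(w)
  structure(list(response = response, table = tab, fits = fits,
                 confidence_set = conf, n = n),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("All-subsets AICc model set for %s (n = %d; %d models, %d in confidence set)\n",
              x$response, x$n, nrow(x$table), length(x$confidence_set)))
  print(head(x$table, 10), digits = 4)
  invisible(x)
}

#' Average coefficients across the AICc confidence set
#'
#' Akaike-weighted averages over models with delta AICc < 2. Both
#' conventions are reported: the full average (a coefficient contributes 0
#' where its model omits it) and the conditional average (over models
#' containing it only). Unconditional standard errors follow the
#' model-averaging variance that adds the between-model spread to the
#' within-model variance; intervals are estimate +/- 1.96 SE, and a
#' coefficient "overlaps zero" when its full-average interval contains 0.
#'
#' @param ms a \code{model_set} from \code{\link{dredge_aicc}}
#' @return data frame, one row per coefficient: \code{term},
#'   \code{estimate_full}, \code{estimate_conditional}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{overlaps_zero}, \code{weight_sum}
#'   (summed weight of models containing the term)
#' @export
model_average <- function(ms) {
  conf <- ms$confidence_set
  if (!length(conf)) stop("confidence set is empty", call. = FALSE)
  w <- ms$table$weight[conf]
  fits <- ms$fits[conf]
  terms_all <- unique(unlist(lapply(fits, function(f) names(coef(f)))))
  out <- lapply(terms_all, function(tm) {
    b <- vapply(fits, function(f) {
      cf <- coef(f); if (tm %in% names(cf)) unname(cf[tm]) else 0
    }, numeric(1))
    s <- vapply(fits, function(f) {
      cf <- coef(f)
      if (tm %in% names(cf)) sqrt(vcov(f)[tm, tm]) else 0
    }, numeric(1))
    present <- vapply(fits, function(f) tm %in% names(coef(f)), logical(1))
    est_full <- sum(w * b)
    est_cond <- sum(w[present] * b[present]) / sum(w[present])
    se <- sum(w * sqrt(s^2 + (b - est_full)^2))
    data.frame(term = tm,
               estimate_full = est_full,
               estimate_conditional = est_cond,
               se = se,
               ci_low = est_full - 1.96 * se,
               ci_high = est_full + 1.96 * se,
               overlaps_zero = (est_full - 1.96 * se) <= 0 &
                 (est_full + 1.96 * se) >= 0,
               weight_sum = sum(w[present]))
  })
  do.call(rbind, out)
}

#' Column summary for report tables
#'
#' Mean, minimum and maximum of each numeric column, rounded to one decimal.
#'
#' @param records data frame
#' @return data frame with rows mean/min/max
#' @export
column_summary <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  num <- vapply(records, is.numeric, logical(1))
  d <- records[num]
  out <- data.frame(
    column = names(d),
    mean = round(vapply(d, function(x) mean(x, na.rm = TRUE), numeric(1)), 1),
    min = round(vapply(d, function(x) min(x, na.rm = TRUE), numeric(1)), 1),
    max = round(vapply(d, function(x) max(x, na.rm = TRUE), numeric(1)), 1)
  )
  rownames(out) <- NULL
  out
}
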