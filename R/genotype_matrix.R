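#' Construct a genotype matrix
#'
#' The central container for cohort SNP data: a matrix of diploid genotype
#' codes (0/1/2 copies of the alternate allele, \code{NA} for missing) with
#' optional per-genotype allele depths and per-locus metadata (chromosome,
#' position, RAD tag, baited flag).
#'
#' @param genotypes integer matrix, individuals x loci, values in
#'   \{0, 1, 2, NA\}. Row names are individual ids, column names locus ids.
#' @param loci data frame with one row per locus: columns \code{locus},
#'   \code{chrom}, \code{pos}, \code{tag}, \code{baited}.
#' @param ref_depth,alt_depth optional matrices of reference / alternate read
#'   counts, same dimensions as \code{genotypes}. Missing genotypes keep their
#'   depths: a genotype can be missing at nonzero depth (e.g. failed call).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(genotypes, loci, ref_depth = NULL, alt_depth = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(genotypes) <- "integer"
  if (nrow(loci) != ncol(genotypes))
    stop("`loci` must have one row per genotype column", call. = FALSE)
  need <- c("locus", "chrom", "pos", "tag", "baited")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("`loci` lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(loci$pos < 0)) stop("locus positions must be non-negative", call. = FALSE)
  if (is.null(colnames(genotypes))) colnames(genotypes) <- loci$locus
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind_", seq_len(nrow(genotypes)))
  for (d in list(ref_depth, alt_depth)) {
    if (!is.null(d) && !identical(dim(d), dim(genotypes)))
      stop("depth matrices must match genotype dimensions", call. = FALSE)
  }
  if (xor(is.null(ref_depth), is.null(alt_depth)))
    stop("supply both or neither of ref_depth/alt_depth", call. = FALSE)
  structure(
    list(genotypes = genotypes, loci = as.data.frame(loci),
         ref_depth = ref_depth, alt_depth = alt_depth),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d chromosome(s), %s depths)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$loci$chrom)),
              if (is.null(x$ref_depth)) "no" else "with"))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# Subset a genotype matrix by individuals (i) and/or loci (j).
#' Subset a genotype matrix
#' @param x a \code{genotype_matrix}
#' @param i individual index (rows), \code{j} locus index (columns)
#' @param j see \code{i}
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  genotype_matrix(
    x$genotypes[i, j, drop = FALSE],
    x$loci[j, , drop = FALSE],
    if (!is.null(x$ref_depth)) x$ref_depth[i, j, drop = FALSE],
    if (!is.null(x$alt_depth)) x$alt_depth[i, j, drop = FALSE]
  )
}

#' Per-locus alternate allele frequency, minor allele frequency, and call rate
#'
#' Frequencies are computed over non-missing genotypes only.
#'
#' @param gm a \code{genotype_matrix}
#' @return \code{allele_freq}: alternate-allele frequency per locus (NaN for
#'   fully missing loci); \code{maf}: minor allele frequency; \code{call_rate}:
#'   fraction of individuals genotyped.
#' @export
allele_freq <- function(gm) {
  colMeans(gm$genotypes, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(gm) {
  p <- allele_freq(gm)
  pmin(p, 1 - p)
}

#' @rdname allele_freq
#' @export
call_rate <- function(gm) {
  colMeans(!is.na(gm$genotypes))
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCFv4.2 with GT and AD fields and contig headers; locus
#' metadata travels in the ID column (locus id) and INFO (\code{TAG},
#' \code{BAITED}). Output is gzip-compressed (\code{.vcf.gz}) as written by
#' \pkg{vcfR}.
#'
#' @param gm a \code{genotype_matrix} with depths
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- nrow(gm$genotypes); L <- ncol(gm$genotypes)
  contigs <- unique(gm$loci$chrom)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", contigs, ">"),
            "##INFO=<ID=TAG,Number=1,Type=String,Description=\"RAD-capture tag id\">",
            "##INFO=<ID=BAITED,Number=1,Type=Integer,Description=\"Locus targeted by bait panel\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">")
  fix <- cbind(CHROM = as.character(gm$loci$chrom),
               POS = as.character(gm$loci$pos),
               ID = as.character(gm$loci$locus),
               REF = "A", ALT = "C", QUAL = ".", FILTER = "PASS",
               INFO = paste0("TAG=", gm$loci$tag, ";BAITED=",
                             as.integer(gm$loci$baited)))
  gt_code <- matrix("./.", n, L)
  gt_code[!is.na(gm$genotypes)] <-
    c("0/0", "0/1", "1/1")[gm$genotypes[!is.na(gm$genotypes)] + 1L]
  if (is.null(gm$ref_depth)) {
    body <- gt_code
    fmt <- "GT"
  } else {
    rd <- gm$ref_depth; ad <- gm$alt_depth
    rd[is.na(rd)] <- 0L; ad[is.na(ad)] <- 0L
    body <- matrix(paste0(gt_code, ":", rd, ",", ad), n, L)
    fmt <- "GT:AD"
  }
  gt <- cbind(FORMAT = fmt, t(body))
  colnames(gt) <- c("FORMAT", rownames(gm$genotypes))
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Reads GT and (when present) AD fields. Tag ids and bait flags are taken
#' from the INFO column when written by \code{\link{write_vcf}}; otherwise a
#' sidecar locus table (columns \code{locus}, \code{chrom}, \code{pos},
#' \code{tag}, \code{baited}) is authoritative.
#'
#' @param path VCF file (optionally gzipped)
#' @param loci optional sidecar locus table overriding VCF-derived metadata
#' @return a \code{genotype_matrix}
#' @export
read_vcf_genotypes <- function(path, loci = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  geno <- t(code)
  has_ad <- any(grepl("AD", v@gt[, "FORMAT"]))
  rd <- ad <- NULL
  if (has_ad) {
    adm <- vcfR::extract.gt(v, element = "AD")
    rd <- t(apply(adm, 2, function(x) as.integer(sub(",.*", "", x))))
    ad <- t(apply(adm, 2, function(x) as.integer(sub(".*,", "", x))))
    dimnames(rd) <- dimnames(ad) <- dimnames(geno)
    rd[is.na(rd)] <- 0L; ad[is.na(ad)] <- 0L
  }
  if (is.null(loci)) {
    info <- v@fix[, "INFO"]
    tag <- sub(".*TAG=([^;]+).*", "\\1", info)
    baited <- suppressWarnings(as.integer(sub(".*BAITED=([0-9]+).*", "\\1", info)))
    baited[is.na(baited)] <- 1L
    loci <- data.frame(
      locus = ifelse(is.na(v@fix[, "ID"]) | v@fix[, "ID"] == ".",
                     paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"]), v@fix[, "ID"]),
      chrom = v@fix[, "CHROM"],
      pos = as.numeric(v@fix[, "POS"]),
      tag = tag,
      baited = as.logical(baited)
    )
  }
  genotype_matrix(geno, loci, rd, ad)
}
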