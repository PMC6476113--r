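## Genotype QC and measured-genotype association within a QTL region.

#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

.minorOrient <- function(dosage, info) {
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosage[flip, ] <- 2 - dosage[flip, ]
    if (all(c("alleleRef", "alleleAlt") %in% names(info))) {
      tmp <- info$alleleRef[flip]
      info$alleleRef[flip] <- info$alleleAlt[flip]
      info$alleleAlt[flip] <- tmp
    }
  }
  info$maf <- rowMeans(dosage, na.rm = TRUE) / 2
  info$maf[is.nan(info$maf)] <- NA_real_
  info$nCopies <- rowSums(dosage, na.rm = TRUE)
  list(dosage = dosage, info = info)
}

#' Construct a genotype table
#'
#' Orients every SNP to its minor allele (dosages are flipped to count the
#' rarer allele, allele labels swapped accordingly), computes minor-allele
#' frequency and copy counts per SNP and call rate per individual.
#'
#' @param dosage numeric matrix of allele dosages, SNPs x individuals,
#'   values 0/1/2/NA.
#' @param snpInfo data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{posBP} and optionally \code{alleleRef}, \code{alleleAlt}.
#' @param ids individual identifiers (defaults to dosage column names).
#' @return a \linkS4class{GenotypeTable}.
#' @export
genotypeTable <- function(dosage, snpInfo, ids = colnames(dosage)) {
  snpInfo <- as.data.frame(snpInfo)
  stopifnot(nrow(dosage) == nrow(snpInfo), !is.null(ids))
  o <- .minorOrient(as.matrix(dosage), snpInfo)
  callRate <- colMeans(!is.na(o$dosage))
  dimnames(o$dosage) <- list(snpInfo$snp_id, ids)
  se <- SummarizedExperiment(
    assays = list(dosage = o$dosage),
    rowData = DataFrame(o$info, row.names = snpInfo$snp_id),
    colData = DataFrame(callRate = callRate, row.names = ids))
  new("GenotypeTable", se)
}

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeTable",
          function(x) assay(x, "dosage"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeTable",
          function(x) as.data.frame(rowData(x)))

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object), "SNPs x", ncol(object), "individuals\n")
  cr <- colData(object)$callRate
  cat(sprintf("  call rate: median %.3f (min %.3f)\n", median(cr), min(cr)))
})

.autosomes <- as.character(1:22)

#' Genotype quality-control filter
#'
#' Applies the two table-level cleaning rules used before association:
#' non-autosomal SNPs are removed, then individuals whose autosomal
#' call rate falls below 0.95 are removed (the threshold is inclusive:
#' exactly 95 percent is retained). Minor-allele orientation, MAF and copy
#' counts are recomputed on the filtered table, so the filter is idempotent.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param minCallRate per-person call-rate threshold (default 0.95).
#' @return the filtered \linkS4class{GenotypeTable}.
#' @export
qcFilter <- function(gt, minCallRate = 0.95) {
  info <- snpInfo(gt)
  keepSnp <- as.character(info$chrom) %in% .autosomes
  d <- dosages(gt)[keepSnp, , drop = FALSE]
  if (nrow(d) == 0) stop("no autosomal SNPs left after filtering")
  cr <- colMeans(!is.na(d))
  keepInd <- cr >= minCallRate
  if (!any(keepInd)) stop("no individuals left after call-rate filtering")
  genotypeTable(d[, keepInd, drop = FALSE],
                info[keepSnp, setdiff(names(info), c("maf", "nCopies")),
                     drop = FALSE],
                ids = colnames(d)[keepInd])
}

#' Minimum minor-allele copy filter
#'
#' Retains SNPs whose observed minor-allele copy count (sum of dosages over
#' non-missing genotypes) is at least \code{minCopies}; rare and
#' monomorphic SNPs are removed so every tested SNP supports a stable
#' regression.
#'
#' @param gt a QC-filtered \linkS4class{GenotypeTable}.
#' @param minCopies copy-count threshold (default 5).
#' @return the filtered \linkS4class{GenotypeTable}.
#' @export
copyFilter <- function(gt, minCopies = 5) {
  keep <- snpInfo(gt)$nCopies >= minCopies
  gt[keep, ]
}

#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests performed (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test threshold \code{alpha / nTests}.
#' @examples
#' bonferroniThreshold(852)          # 5.87e-5
#' -log10(bonferroniThreshold(852))  # 4.23
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(nTests >= 1)
  alpha / nTests
}

#' Variance explained by a SNP (additive HWE approximation)
#'
#' \eqn{100 \cdot 2\,maf(1-maf)\,\beta^2 / \sigma^2_{trait}} percent, the
#' additive single-locus variance under Hardy-Weinberg proportions relative
#' to the (covariate-adjusted) trait variance.
#'
#' @param beta additive effect per copy of the minor allele.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param traitVariance variance basis (> 0), by convention the
#'   covariate-adjusted trait variance of the fitted model.
#' @return percent of trait variance.
#' @export
varianceExplained <- function(beta, maf, traitVariance) {
  stopifnot(all(maf > 0 & maf <= 0.5), traitVariance > 0)
  100 * 2 * maf * (1 - maf) * beta^2 / traitVariance
}

#' Measured-genotype association at one SNP
#'
#' Tests a SNP's additive effect inside the polygenic variance-component
#' model: the dosage (0/1/2 copies of the minor allele) is appended to the
#' covariate design and the model is refitted by full joint ML (variance
#' components re-estimated with the SNP in the model). \code{beta} is the
#' dosage's GLS coefficient at the ML variances; the p-value is the
#' likelihood-ratio test of beta = 0 against chi-square with 1 df.
#' Individuals with missing dosage are dropped for that SNP. The variance
#' basis for \code{varExplainedPct} is the covariate-adjusted trait variance
#' (sigma_a2 + sigma_e2) of the no-SNP model.
#'
#' @param y named trait vector.
#' @param X design matrix aligned to \code{y}.
#' @param twoPhi additive-relationship matrix aligned to \code{y}.
#' @param dosage numeric vector of minor-allele dosages aligned to \code{y}.
#' @param snpId SNP label for the output row.
#' @param decomp,nullFit optional precomputed eigendecomposition of
#'   \code{twoPhi} and no-SNP polygenic fit over the same complete cases
#'   (shared across SNPs by [associationScan()] when no dosages are missing).
#' @return one-row data.frame: snp_id, n, maf, nCopies, beta, betaSE, p,
#'   varExplainedPct.
#' @export
measuredGenotypeFit <- function(y, X, twoPhi, dosage, snpId = "snp",
                                decomp = NULL, nullFit = NULL) {
  stopifnot(length(dosage) == length(y))
  keep <- !is.na(y) & complete.cases(X) & !is.na(dosage)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; g <- dosage[keep]
  G <- twoPhi[keep, keep, drop = FALSE]
  if (diff(range(g)) == 0)
    stop("constant dosage after complete-case filtering for ", snpId)
  maf <- mean(g) / 2
  if (maf > 0.5) { g <- 2 - g; maf <- 1 - maf }   # re-orient within sample
  if (is.null(decomp)) decomp <- .vcDecomp(G)
  null <- if (is.null(nullFit)) fitPolygenic(y, X, G, se = FALSE,
                                             decomp = decomp) else nullFit
  full <- fitPolygenic(y, cbind(X, dosage = g), G, se = FALSE, decomp = decomp)
  lambda <- max(0, 2 * (full@loglik - null@loglik))
  p <- pchisq(lambda, df = 1, lower.tail = FALSE)
  beta <- unname(full@beta["dosage"])
  betaSE <- unname(full@betaSE["dosage"])
  sp2 <- null@sigmaA2 + null@sigmaE2
  data.frame(snp_id = snpId, n = length(y), maf = maf,
             nCopies = sum(g), beta = beta, betaSE = betaSE, p = p,
             varExplainedPct = if (maf > 0) varianceExplained(beta, maf, sp2)
                               else 0)
}

#' Association scan over a genotype table
#'
#' Runs [measuredGenotypeFit()] for every SNP of a (filtered) genotype
#' table and appends the Bonferroni threshold for the number of SNPs
#' actually tested. SNPs whose dosage is constant among the analysed
#' individuals are reported with NA statistics rather than failing the scan.
#'
#' @param gt a filtered \linkS4class{GenotypeTable}.
#' @param y,X,twoPhi trait, design and relationship matrix as in
#'   [measuredGenotypeFit()]; \code{y} names must match the table's ids.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return data.frame, one row per SNP (chrom, posBP, maf, nCopies, beta,
#'   p, varExplainedPct, significant), with attributes \code{nTests} and
#'   \code{threshold}.
#' @export
associationScan <- function(gt, y, X, twoPhi, alpha = 0.05) {
  if (is.null(names(y))) stop("y must be named with member ids")
  idx <- match(names(y), colnames(gt))
  if (anyNA(idx))
    stop("genotype table lacks individuals: ",
         paste(utils::head(names(y)[is.na(idx)], 5), collapse = ", "))
  D <- dosages(gt)[, idx, drop = FALSE]
  info <- snpInfo(gt)
  # with no missing dosages every SNP analyses the same individuals, so one
  # eigendecomposition and one no-SNP fit serve the whole scan
  keep0 <- !is.na(y) & complete.cases(X)
  decomp0 <- nullFit0 <- NULL
  if (!anyNA(D)) {
    G0 <- twoPhi[keep0, keep0, drop = FALSE]
    decomp0 <- .vcDecomp(G0)
    nullFit0 <- fitPolygenic(y[keep0], X[keep0, , drop = FALSE], G0,
                             se = FALSE, decomp = decomp0)
  }
  rows <- vector("list", nrow(info))
  for (k in seq_len(nrow(info))) {
    shared <- !anyNA(D[k, ])
    rows[[k]] <- tryCatch(
      measuredGenotypeFit(y, X, twoPhi, D[k, ], snpId = info$snp_id[k],
                          decomp = if (shared) decomp0 else NULL,
                          nullFit = if (shared) nullFit0 else NULL),
      error = function(e)
        data.frame(snp_id = info$snp_id[k], n = NA_integer_, maf = NA_real_,
                   nCopies = NA_real_, beta = NA_real_, betaSE = NA_real_,
                   p = NA_real_, varExplainedPct = NA_real_))
  }
  out <- do.call(rbind, rows)
  out <- cbind(out[, "snp_id", drop = FALSE],
               chrom = info$chrom, posBP = info$posBP,
               out[, setdiff(names(out), "snp_id")])
  nTests <- sum(!is.na(out$p))
  thr <- if (nTests >= 1) bonferroniThreshold(nTests, alpha) else NA_real_
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "nTests") <- nTests
  attr(out, "threshold") <- thr
  out
}

#' Write / read a genotype file
#'
#' SNP-major tabular format: one row per SNP with columns \code{snp_id
#' chrom pos allele_ref allele_alt} followed by one dosage column per
#' individual (header row carries the ids). Missing dosages read as
#' \code{NA} or \code{.}.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param path file path.
#' @export
writeGenotypeFile <- function(gt, path) {
  info <- snpInfo(gt)
  df <- data.frame(snp_id = info$snp_id, chrom = info$chrom, pos = info$posBP,
                   allele_ref = if ("alleleRef" %in% names(info)) info$alleleRef else "A",
                   allele_alt = if ("alleleAlt" %in% names(info)) info$alleleAlt else "B")
  data.table::fwrite(cbind(df, as.data.frame(dosages(gt))), path, sep = "\t")
  invisible(path)
}

#' @rdname writeGenotypeFile
#' @return \code{readGenotypeFile} returns a \linkS4class{GenotypeTable}.
#' @export
readGenotypeFile <- function(path) {
  dt <- as.data.frame(data.table::fread(path, na.strings = c("NA", ".", "")))
  meta <- c("snp_id", "chrom", "pos", "allele_ref", "allele_alt")
  stopifnot(all(meta %in% names(dt)))
  ids <- setdiff(names(dt), meta)
  d <- as.matrix(dt[, ids, drop = FALSE])
  genotypeTable(d, data.frame(snp_id = as.character(dt$snp_id),
                              chrom = as.character(dt$chrom),
                              posBP = dt$pos,
                              alleleRef = dt$allele_ref,
                              alleleAlt = dt$allele_alt),
                ids = ids)
}

#' Convert an individual-major genotype layout
#'
#' Reads a transposed table (one row per individual: an \code{id} column
#' followed by one column per SNP) plus a SNP annotation table and returns
#' the standard \linkS4class{GenotypeTable}.
#'
#' @param path individual-major file.
#' @param snpInfo data.frame with snp_id, chrom, posBP (and optional allele
#'   labels); order must match or cover the SNP columns.
#' @return a \linkS4class{GenotypeTable}.
#' @export
readGenotypeFileIndividualMajor <- function(path, snpInfo) {
  dt <- as.data.frame(data.table::fread(path, na.strings = c("NA", ".", "")))
  stopifnot("id" %in% names(dt))
  snps <- setdiff(names(dt), "id")
  info <- snpInfo[match(snps, snpInfo$snp_id), , drop = FALSE]
  if (anyNA(info$snp_id)) stop("snpInfo does not annotate every SNP column")
  d <- t(as.matrix(dt[, snps, drop = FALSE]))
  genotypeTable(d, info, ids = as.character(dt$id))
}
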