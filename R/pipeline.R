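## End-to-end analysis pipeline: heritability -> (bivariate) -> linkage ->
## QTL-interval measured-genotype association, mirroring the standard
## family-study analysis plan.

.asPedigree <- function(x) if (is(x, "Pedigree")) x else readPedigreeFile(x)
.asPheno <- function(x) if (is.data.frame(x)) x else readPhenotypeFile(x)
.asGeno <- function(x) if (is(x, "GenotypeTable")) x else readGenotypeFile(x)

#' Run the full pedigree analysis pipeline
#'
#' Executes, in order: trait preparation (optional rank-based inverse normal
#' transform, covariate design), univariate heritability for each trait,
#' bivariate pleiotropy when two traits are given, a multipoint
#' variance-component linkage scan over the supplied MIBD tracks, and
#' measured-genotype association of the SNPs falling inside the 1-LOD
#' support interval of the significant linkage peak (QC and copy filters
#' applied first; the Bonferroni correction uses the number of SNPs actually
#' tested in the interval). Inputs may be in-memory objects or file paths in
#' the package's text formats.
#'
#' @param pedigree \linkS4class{Pedigree} or pedigree file path.
#' @param phenotype phenotype data.frame or CSV path.
#' @param traits one or two trait column names.
#' @param genotypes \linkS4class{GenotypeTable} or genotype file path
#'   (required for the association stage).
#' @param mibd a \linkS4class{MibdTrack}, a list of tracks (one per
#'   chromosome), or NULL to skip linkage.
#' @param stages subset of \code{c("heritability", "bivariate", "linkage",
#'   "association")}.
#' @param applyInverseNormal transform each trait by [inverseNormal()]
#'   before analysis.
#' @param includeStorage include serum storage days in the design.
#' @param alpha family-wise error rate for Bonferroni correction.
#' @param lodSignificant,lodSuggestive LOD classification thresholds.
#' @param interval explicit association interval
#'   \code{c(chrom=..., bpLo=..., bpHi=...)} overriding the linkage peak.
#' @param minCopies minor-allele copy filter threshold.
#' @param outDir optional directory; result tables (CSV) and a JSON log are
#'   written there deterministically.
#' @param seed recorded in the log for provenance (the analysis itself is
#'   deterministic given its inputs).
#' @return list with elements \code{heritability} (named list of
#'   \linkS4class{PolygenicFit}), \code{bivariate}, \code{linkage} (named
#'   list of \linkS4class{LinkageScan} plus \code{peak}), \code{association}
#'   (data.frame with Bonferroni attributes) and \code{log}.
#' @export
runPipeline <- function(pedigree, phenotype, traits,
                        genotypes = NULL, mibd = NULL,
                        stages = c("heritability", "bivariate", "linkage",
                                   "association"),
                        applyInverseNormal = TRUE, includeStorage = TRUE,
                        alpha = 0.05, lodSignificant = 3.0,
                        lodSuggestive = 2.0, interval = NULL,
                        minCopies = 5, outDir = NULL, seed = NULL) {
  stopifnot(length(traits) %in% 1:2, alpha > 0,
            lodSignificant > 0, lodSuggestive > 0)
  ped <- .asPedigree(pedigree)
  pheno <- .asPheno(phenotype)
  miss <- setdiff(traits, names(pheno))
  if (length(miss))
    stop("stage [input]: phenotype table lacks trait column(s): ",
         paste(miss, collapse = ", "))
  G <- twoPhi(kinship(ped))
  result <- list()
  log <- list(package = as.character(packageVersion("pedQTL")),
              seed = seed, traits = traits, alpha = alpha,
              lodSignificant = lodSignificant, lodSuggestive = lodSuggestive,
              applyInverseNormal = applyInverseNormal,
              includeStorage = includeStorage, minCopies = minCopies,
              n_pedigree = length(memberIds(ped)))

  designs <- list()
  for (tr in traits) {
    ph <- pheno
    if (applyInverseNormal) ph[[tr]] <- inverseNormal(ph[[tr]])
    designs[[tr]] <- buildDesign(ph, tr, includeStorage = includeStorage)
  }
  align <- function(des) {
    idx <- match(des$ids, memberIds(ped))
    if (anyNA(idx))
      stop("stage [design]: phenotype ids not in pedigree: ",
           paste(utils::head(des$ids[is.na(idx)], 5), collapse = ", "))
    G[idx, idx, drop = FALSE]
  }

  if ("heritability" %in% stages) {
    result$heritability <- lapply(designs, function(des)
      fitPolygenic(des$y, des$X, align(des)))
    log$h2 <- vapply(result$heritability, function(f) f@h2, 0)
  }

  if ("bivariate" %in% stages && length(traits) == 2) {
    dA <- designs[[1]]; dB <- designs[[2]]
    common <- intersect(dA$ids, dB$ids)
    iA <- match(common, dA$ids); iB <- match(common, dB$ids)
    idx <- match(common, memberIds(ped))
    result$bivariate <- fitBivariate(dA$y[iA], dB$y[iB],
                                     dA$X[iA, , drop = FALSE],
                                     dB$X[iB, , drop = FALSE],
                                     G[idx, idx], traits = traits)
  }

  if ("linkage" %in% stages && !is.null(mibd)) {
    tracks <- if (is(mibd, "MibdTrack")) list(mibd) else mibd
    des <- designs[[1]]
    Gd <- align(des)
    scans <- lapply(tracks, function(trk)
      genomeScan(des$y, des$X, Gd, trk,
                 lodSignificant = lodSignificant,
                 lodSuggestive = lodSuggestive))
    peaks <- vapply(scans, function(s) s@peak$lod, 0)
    best <- scans[[which.max(peaks)]]
    result$linkage <- list(scans = scans, peak = best@peak,
                           classification = best@classification,
                           interval = best@interval)
    log$peakLOD <- best@peak$lod
    log$classification <- best@classification
    if (is.null(interval) && best@classification == "significant")
      interval <- c(chrom = best@peak$chrom,
                    bpLo = unname(best@interval["bpLo"]),
                    bpHi = unname(best@interval["bpHi"]))
  }

  if ("association" %in% stages && !is.null(genotypes)) {
    linkageRan <- "linkage" %in% stages && !is.null(mibd)
    if (is.null(interval) && linkageRan) {
      # linkage ran but produced no significant peak: nothing to interrogate
      log$associationSkipped <- "no significant linkage peak"
      result$log <- log
      if (!is.null(outDir)) .writeReport(result, outDir)
      return(result)
    }
    if (is.null(interval))
      stop("stage [association]: no SNP subset defined -- run the linkage ",
           "stage to a significant peak or supply an explicit interval")
    gt <- .asGeno(genotypes)
    gt <- copyFilter(qcFilter(gt), minCopies = minCopies)
    info <- snpInfo(gt)
    inReg <- as.character(info$chrom) == as.character(interval[["chrom"]]) &
      info$posBP >= as.numeric(interval[["bpLo"]]) &
      info$posBP <= as.numeric(interval[["bpHi"]])
    if (!any(inReg))
      stop("stage [association]: no SNPs inside the interval ",
           interval[["chrom"]], ":", interval[["bpLo"]], "-",
           interval[["bpHi"]])
    des <- designs[[1]]
    ids <- intersect(des$ids, colnames(gt))
    ii <- match(ids, des$ids)
    idx <- match(ids, memberIds(ped))
    result$association <- associationScan(
      gt[inReg, ids], des$y[ii], des$X[ii, , drop = FALSE],
      G[idx, idx], alpha = alpha)
    log$nTestsAssociation <- attr(result$association, "nTests")
    log$bonferroniThreshold <- attr(result$association, "threshold")
    log$interval <- as.list(interval)
  }

  result$log <- log
  if (!is.null(outDir)) .writeReport(result, outDir)
  result
}

.writeReport <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$heritability)) {
    h <- do.call(rbind, lapply(names(result$heritability), function(tr) {
      f <- result$heritability[[tr]]
      data.frame(trait = tr, n = f@nUsed, h2 = f@h2, h2SE = f@h2SE,
                 sigmaA2 = f@sigmaA2, sigmaE2 = f@sigmaE2,
                 loglik = f@loglik, p = f@pH2)
    }))
    data.table::fwrite(h, file.path(outDir, "heritability.csv"))
    cf <- do.call(rbind, lapply(names(result$heritability), function(tr) {
      f <- result$heritability[[tr]]
      data.frame(trait = tr, covariate = names(f@beta), beta = f@beta,
                 se = f@betaSE)
    }))
    data.table::fwrite(cf, file.path(outDir, "covariates.csv"))
  }
  if (!is.null(result$bivariate)) {
    b <- result$bivariate
    data.table::fwrite(data.frame(
      traitA = b@traits[1], traitB = b@traits[2], n = b@nUsed,
      rhoG = b@rhoG, rhoGSE = b@rhoGSE, rhoE = b@rhoE, rhoP = b@rhoP,
      rhoPSE = b@rhoPSE, pRhoG = b@pRhoG, pleiotropy = b@pleiotropy,
      h2A = b@h2A, h2B = b@h2B), file.path(outDir, "bivariate.csv"))
  }
  if (!is.null(result$linkage)) {
    tab <- do.call(rbind, lapply(result$linkage$scans, function(s) s@table))
    data.table::fwrite(tab, file.path(outDir, "linkage.csv"))
  }
  if (!is.null(result$association))
    data.table::fwrite(result$association, file.path(outDir, "association.csv"))
  writeLines(jsonlite::toJSON(result$log, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(outDir, "log.json"))
  invisible(outDir)
}
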