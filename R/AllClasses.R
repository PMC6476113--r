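#' @import methods
#' @importFrom stats complete.cases dnorm median optim optimize pchisq pnorm
#'   qnorm rbinom rnorm rpois runif sd setNames var
#' @importFrom utils packageVersion
NULL

#' Pedigree of a set of related individuals
#'
#' Holds the parent-offspring structure of a (possibly very large)
#' multigenerational pedigree. Founders have both parents missing (\code{NA});
#' all other members have both parents recorded and present in the pedigree.
#' Members are stored in a validated topological order internally so that
#' recursions over the pedigree (kinship, gene dropping) can proceed
#' parents-first without recursion-depth limits.
#'
#' @slot id character vector of unique member identifiers.
#' @slot father,mother character vectors of parent identifiers, \code{NA}
#'   for founders.
#' @slot sex character vector, \code{"male"} or \code{"female"}.
#' @slot topoOrder integer permutation of members such that every parent
#'   precedes all of its offspring.
#'
#' @seealso [loadPedigree()], [kinship()], [simulatePedigree()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    father = "character",
    mother = "character",
    sex = "character",
    topoOrder = "integer"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@father) != n || length(object@mother) != n ||
      length(object@sex) != n || length(object@topoOrder) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@id))
    return(paste("duplicate ids:",
                 paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  if (!all(object@sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  fNA <- is.na(object@father); mNA <- is.na(object@mother)
  mixed <- xor(fNA, mNA)
  if (any(mixed))
    return(paste("half-known parentage (one parent missing) for:",
                 paste(object@id[mixed], collapse = ", ")))
  idx <- seq_len(n)
  fi <- match(object@father, object@id)
  mi <- match(object@mother, object@id)
  badf <- !fNA & is.na(fi); badm <- !mNA & is.na(mi)
  if (any(badf | badm))
    return(paste("unknown parent id for members:",
                 paste(object@id[badf | badm], collapse = ", ")))
  nf <- which(!fNA)
  if (length(nf)) {
    wrongF <- object@sex[fi[nf]] != "male"
    wrongM <- object@sex[mi[nf]] != "female"
    if (any(wrongF))
      return(paste("recorded father is not male for:",
                   paste(object@id[nf[wrongF]], collapse = ", ")))
    if (any(wrongM))
      return(paste("recorded mother is not female for:",
                   paste(object@id[nf[wrongM]], collapse = ", ")))
  }
  # topoOrder must place parents before offspring (also certifies acyclicity)
  pos <- integer(n); pos[object@topoOrder] <- idx
  for (k in nf)
    if (pos[fi[k]] >= pos[k] || pos[mi[k]] >= pos[k])
      return("topoOrder does not place parents before offspring")
  TRUE
})

#' Kinship coefficient matrix
#'
#' Symmetric matrix of pedigree kinship coefficients phi(i, j): the
#' probability that one allele sampled from i and one from j are identical
#' by descent. The additive-relationship structuring matrix used by the
#' variance-component models is \code{2 * phi(x)}.
#'
#' @slot ids ordered member identifiers (row/column names of \code{phi}).
#' @slot phi symmetric numeric matrix; diagonal \eqn{\phi(i,i) = (1+F_i)/2}.
#' @export
setClass("KinshipMatrix",
  representation(ids = "character", phi = "matrix")
)

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  n <- length(object@ids)
  if (!is.numeric(p) || nrow(p) != n || ncol(p) != n)
    return("phi must be a numeric matrix matching ids")
  if (max(abs(p - t(p))) > 1e-12) return("phi must be symmetric")
  if (min(p) < -1e-12 || max(p) > 1 + 1e-12) return("entries must lie in [0, 1]")
  if (any(diag(p) < 0.5 - 1e-12)) return("diagonal must be >= 0.5")
  if (n > 0) {
    ev <- eigen(2 * p, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) return("2*phi must be positive semidefinite")
  }
  TRUE
})

#' Multipoint IBD-sharing track
#'
#' Per-position symmetric matrices of pairwise expected identity-by-descent
#' sharing proportions \eqn{\hat\pi(i,j) \in [0,1]} on a cM grid along one
#' chromosome, the locus-specific structuring matrices of the
#' variance-component linkage scan. Diagonal entries are 1 for non-inbred
#' individuals (up to 2 when autozygous).
#'
#' Large simulated tracks are stored compactly as founder-haplotype label
#' matrices and the per-position matrix is materialised on demand by
#' [pihatAt()]; small tracks (e.g. read from file) store the matrices
#' explicitly.
#'
#' @slot ids member identifiers the matrices are indexed by.
#' @slot chrom chromosome label (scalar).
#' @slot posCM strictly increasing grid positions in centimorgans.
#' @slot posBP base-pair coordinates of the grid positions (\code{NA} if
#'   unknown).
#' @slot pihat list of explicit sharing matrices (may be empty when
#'   \code{labels} is used).
#' @slot labels integer matrix of founder-haplotype labels, \code{n x 2*npos}
#'   (paternal block then maternal block); zero rows when \code{pihat} is
#'   explicit.
#' @export
setClass("MibdTrack",
  representation(
    ids = "character",
    chrom = "character",
    posCM = "numeric",
    posBP = "numeric",
    pihat = "list",
    labels = "matrix"
  )
)

setValidity("MibdTrack", function(object) {
  np <- length(object@posCM)
  if (np == 0) return("empty track")
  if (length(object@chrom) != 1) return("chrom must be a scalar label")
  if (any(diff(object@posCM) <= 0)) return("posCM must be strictly increasing")
  if (length(object@posBP) != np) return("posBP length must match posCM")
  n <- length(object@ids)
  if (length(object@pihat)) {
    if (length(object@pihat) != np) return("pihat list must match positions")
    for (P in object@pihat) {
      if (!is.matrix(P) || nrow(P) != n || ncol(P) != n)
        return("pihat matrices must be n x n")
      if (max(abs(P - t(P))) > 1e-10) return("pihat must be symmetric")
      off <- P[upper.tri(P)]
      # off-diagonal sharing lies in [0, 1] between non-inbred individuals;
      # autozygosity can push the unbiased estimator up to 2
      if (length(off) && (min(off) < -1e-12 || max(off) > 2 + 1e-12))
        return("off-diagonal pihat must lie in [0, 2]")
      if (any(diag(P) < 1 - 1e-12 | diag(P) > 2 + 1e-12))
        return("diagonal pihat must lie in [1, 2]")
    }
  } else {
    if (nrow(object@labels) != n || ncol(object@labels) != 2 * np)
      return("labels must be n x 2*npos when pihat is not stored")
  }
  TRUE
})

#' SNP genotype table
#'
#' Biallelic SNP dosages for a set of individuals, stored as a
#' \linkS4class{SummarizedExperiment} with one \code{"dosage"} assay
#' (SNPs in rows, individuals in columns; values 0/1/2 copies of the
#' designated minor allele, \code{NA} for missing). Row metadata carries
#' \code{chrom}, \code{posBP}, allele labels, minor-allele frequency and
#' minor-allele copy count; column metadata carries the per-person call rate.
#'
#' @seealso [genotypeTable()], [qcFilter()], [copyFilter()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("a 'dosage' assay is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  need <- c("chrom", "posBP", "maf", "nCopies")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (!"callRate" %in% colnames(SummarizedExperiment::colData(object)))
    return("missing colData column: callRate")
  TRUE
})

#' Univariate polygenic variance-component fit
#'
#' Maximum-likelihood fit of the polygenic model
#' \eqn{\Omega = 2\Phi\,\sigma_a^2 + I\,\sigma_e^2} with fixed effects
#' profiled out by generalised least squares. Narrow-sense heritability is
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)} and its p-value comes
#' from the boundary likelihood-ratio test against the
#' \eqn{\tfrac12\chi^2_0 : \tfrac12\chi^2_1} mixture.
#'
#' @export
setClass("PolygenicFit",
  representation(
    sigmaA2 = "numeric", sigmaE2 = "numeric",
    h2 = "numeric", h2SE = "numeric",
    beta = "numeric", betaSE = "numeric",
    loglik = "numeric", loglikNull = "numeric", pH2 = "numeric",
    nUsed = "integer", converged = "logical", degenerate = "logical"
  )
)

#' Bivariate polygenic fit (pleiotropy model)
#'
#' Joint maximum-likelihood fit of two traits with cross-trait covariance
#' \eqn{2\Phi\,\rho_g\sigma_{aA}\sigma_{aB} + I\,\rho_e\sigma_{eA}\sigma_{eB}}.
#' The phenotypic correlation satisfies
#' \eqn{\rho_p = \rho_g\sqrt{h_A^2 h_B^2} +
#'      \rho_e\sqrt{(1-h_A^2)(1-h_B^2)}} by construction.
#'
#' @export
setClass("BivariateFit",
  representation(
    traits = "character",
    h2A = "numeric", h2B = "numeric",
    sigmaP2A = "numeric", sigmaP2B = "numeric",
    rhoG = "numeric", rhoE = "numeric", rhoP = "numeric",
    rhoGSE = "numeric", rhoPSE = "numeric",
    loglik = "numeric", loglikNoRhoG = "numeric", pRhoG = "numeric",
    pleiotropy = "character",
    nUsed = "integer", converged = "logical"
  )
)

#' Single-locus QTL variance-component fit
#'
#' Fit of \eqn{\Omega = \hat\Pi\,\sigma_q^2 + 2\Phi\,\sigma_a^2 +
#' I\,\sigma_e^2} at one genomic position. When the locus matrix is
#' numerically indistinguishable from \eqn{2\Phi} the two genetic components
#' are not separately identifiable; the fit is flagged \code{confounded}
#' and its LOD is defined as zero.
#'
#' @export
setClass("QtlFit",
  representation(
    sigmaQ2 = "numeric", sigmaA2 = "numeric", sigmaE2 = "numeric",
    loglik = "numeric", nUsed = "integer",
    converged = "logical", confounded = "logical"
  )
)

#' Genome/chromosome linkage scan result
#'
#' LOD scores on a cM grid, the peak and its classification against the
#' fixed thresholds (significant: LOD >= 3.0, suggestive: 2.0 <= LOD < 3.0),
#' and the 1-LOD support interval around the peak.
#'
#' @slot table data.frame with columns chrom, posCM, posBP, lod.
#' @slot peak list(chrom, posCM, posBP, lod).
#' @slot classification "significant", "suggestive" or "none".
#' @slot interval named numeric (cmLo, cmHi, bpLo, bpHi); NA when undefined.
#' @slot polygenic the null (polygenic-only) \linkS4class{PolygenicFit}.
#' @export
setClass("LinkageScan",
  representation(
    table = "data.frame",
    peak = "list",
    classification = "character",
    interval = "numeric",
    polygenic = "PolygenicFit"
  )
)

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the gene-dropping simulator: pedigree shape,
#' genetic map, QTL, trait model and covariate effects. Defaults emulate a
#' single extended multigenerational pedigree of roughly a thousand members
#' with a low-heritability trait (h2 = 0.16), a localized QTL explaining 15
#' percent of trait variance, and covariate effects of age, sex, BMI and
#' serum storage time.
#'
#' @seealso [simConfig()] for construction with defaults.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nFoundersPerGen = "integer",
    nGenerations = "integer",
    meanSibship = "numeric",
    chromLengthsCM = "numeric",
    qtlChrom = "character",
    qtlPosCM = "numeric",
    qtlMAF = "numeric",
    qtlVarShare = "numeric",
    nMarkers = "integer",
    h2 = "numeric",
    totalVar = "numeric",
    covEffects = "numeric",
    rhoG = "numeric",
    rhoE = "numeric",
    h2A = "numeric",
    h2B = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nFoundersPerGen < 2) return("need at least 2 founders per generation")
  if (object@nGenerations < 1) return("need at least 1 generation")
  if (object@meanSibship < 0) return("meanSibship must be >= 0")
  if (any(object@chromLengthsCM <= 0)) return("chromosome lengths must be > 0")
  if (is.null(names(object@chromLengthsCM))) return("chromLengthsCM must be named")
  for (x in c(object@qtlMAF, object@h2, object@h2A, object@h2B, object@qtlVarShare))
    if (x < 0 || x > 1) return("frequencies, h2 and variance shares must lie in [0, 1]")
  if (object@h2 + object@qtlVarShare > 1)
    return("h2 + qtlVarShare must not exceed 1")
  if (abs(object@rhoG) > 1 || abs(object@rhoE) > 1)
    return("|rhoG| and |rhoE| must be <= 1")
  if (object@totalVar <= 0) return("totalVar must be > 0")
  TRUE
})
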