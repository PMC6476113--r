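#' Pedigree kinship matrix
#'
#' Computes kinship coefficients by the standard pedigree recursion,
#' evaluated parents-first (Kahn topological order): founders have
#' \eqn{\phi(i,i) = 1/2} and \eqn{\phi = 0} between founders; a non-founder
#' i with parents f, m has \eqn{\phi(i,j) = [\phi(f,j)+\phi(m,j)]/2} for any
#' earlier j and \eqn{\phi(i,i) = [1 + \phi(f,m)]/2}.
#'
#' @param x a \linkS4class{Pedigree}.
#' @return a \linkS4class{KinshipMatrix}.
#' @examples
#' ped <- loadPedigree(data.frame(id = c("f", "m", "c"),
#'                                father = c(NA, NA, "f"),
#'                                mother = c(NA, NA, "m"),
#'                                sex = c("m", "f", "f")))
#' phi(kinship(ped))["f", "c"]   # parent-offspring: 0.25
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' Member identifiers
#' @param x a \linkS4class{Pedigree} or \linkS4class{MibdTrack}.
#' @return character vector of identifiers.
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' Founder indicator
#' @param x a \linkS4class{Pedigree}.
#' @return named logical vector, TRUE where both parents are missing.
#' @export
setGeneric("isFounder", function(x) standardGeneric("isFounder"))

#' Kinship coefficient matrix accessor
#' @param x a \linkS4class{KinshipMatrix}.
#' @return the symmetric numeric matrix of phi values with id dimnames.
#' @export
setGeneric("phi", function(x) standardGeneric("phi"))

#' Additive-relationship structuring matrix
#'
#' Returns \code{2 * phi}, the expected additive relationship matrix that
#' structures the genetic variance component of the polygenic model.
#' @param x a \linkS4class{KinshipMatrix} or \linkS4class{Pedigree}.
#' @return symmetric numeric matrix.
#' @export
setGeneric("twoPhi", function(x) standardGeneric("twoPhi"))

#' Narrow-sense heritability estimate
#' @param x a \linkS4class{PolygenicFit}.
#' @return h2 estimate (numeric scalar).
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' IBD-sharing matrix at a grid position
#' @param x a \linkS4class{MibdTrack}.
#' @param i position index (or cM position via \code{cM =}).
#' @param cM grid position in centimorgans (alternative to \code{i}).
#' @return the symmetric pihat matrix at that position.
#' @export
setGeneric("pihatAt", function(x, i, cM) standardGeneric("pihatAt"))

#' SNP dosage matrix accessor
#' @param x a \linkS4class{GenotypeTable}.
#' @return numeric matrix of minor-allele dosages, SNPs x individuals.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Per-SNP metadata accessor
#' @param x a \linkS4class{GenotypeTable}.
#' @return data.frame of SNP annotation (chrom, posBP, alleles, maf, nCopies).
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
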