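## Trait derivation and the shared covariate design.

#' Glycated albumin percentage from GSP and total serum albumin
#'
#' Converts a glycated serum protein concentration (umol/L) to glycated
#' albumin expressed as a percentage of total serum albumin (g/dL) using the
#' assay manufacturer's conversion:
#' \deqn{\%GA = \frac{GSP \times 0.182 + 1.97}{albumin + 2.9}.}
#' The GSP assay is linear on \[21, 1354\] umol/L; values outside that range
#' trigger a warning (not an error) so flagged measurements remain visible.
#'
#' @param gsp glycated serum protein, umol/L (vectorised).
#' @param albumin total serum albumin, g/dL; must be positive.
#' @param checkRange warn when gsp falls outside the assay linear range.
#' @return \%GA, percent.
#' @examples
#' percentGA(353.5, 4.0)  # 9.61 at the cohort-scale mean GSP
#' @export
percentGA <- function(gsp, albumin, checkRange = TRUE) {
  if (any(albumin <= 0, na.rm = TRUE))
    stop("albumin must be positive (g/dL)")
  if (checkRange) {
    out <- !is.na(gsp) & (gsp < 21.0 | gsp > 1354.0)
    if (any(out))
      warning(sum(out), " GSP value(s) outside the assay linear range [21, 1354] umol/L")
  }
  (gsp * 0.182 + 1.97) / (albumin + 2.9)
}

#' Rank-based inverse normal transformation
#'
#' Replaces each non-missing value by \eqn{\Phi^{-1}[(r - c)/(n - 2c + 1)]}
#' with Blom constant \eqn{c = 3/8}, where r is the value's rank among the
#' n non-missing values (ties receive their average rank, so tied inputs map
#' to identical outputs). Missing values stay missing. The transform is
#' monotone, so trait orderings are preserved while distributional
#' departures from normality are removed before model fitting.
#'
#' @param values numeric vector, possibly with NA.
#' @return transformed vector of the same length.
#' @export
inverseNormal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) stop("all values missing")
  if (n < 2) stop("need at least 2 non-missing values")
  r <- rank(values[ok], ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

.designCols <- c("intercept", "age", "age2", "sex", "ageSex", "age2Sex",
                 "bmi", "storageDays")

#' Build the covariate design shared by all models
#'
#' Constructs the fixed-effect design used throughout: intercept, age, age
#' squared, sex (coded 0 = male, 1 = female), the age-by-sex and
#' age-squared-by-sex interactions, BMI, and (optionally) serum storage
#' days. Age is mean-centered within the retained sample before squaring
#' and interacting, to reduce collinearity; coefficients are therefore
#' reported on the centered-age scale. Individuals missing the trait or any
#' required covariate are dropped (complete case). Columns that are constant
#' within the retained sample (e.g. sex in a single-sex sample) are dropped
#' so the design keeps full column rank.
#'
#' @param pheno data.frame with columns id, age, sex, bmi and (if used)
#'   storage_days, plus the trait column.
#' @param trait name of the trait column.
#' @param includeStorage include the storage-days column.
#' @return list with elements \code{y} (named trait vector), \code{X}
#'   (design matrix with id rownames), \code{ids}, \code{ageMean}, and
#'   \code{dropped} (ids removed as incomplete).
#' @export
buildDesign <- function(pheno, trait, includeStorage = TRUE) {
  pheno <- as.data.frame(pheno)
  need <- c("id", trait, "age", "sex", "bmi")
  if (includeStorage) need <- c(need, "storage_days")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  sex01 <- ifelse(.normalizeSex(pheno$sex) == "female", 1, 0)
  y <- as.numeric(pheno[[trait]])
  cov <- cbind(age = as.numeric(pheno$age), sex = sex01,
               bmi = as.numeric(pheno$bmi))
  if (includeStorage)
    cov <- cbind(cov, storageDays = as.numeric(pheno$storage_days))
  keep <- !is.na(y) & complete.cases(cov)
  if (!any(keep)) stop("empty design: no individual has complete trait and covariates")
  if (any(cov[keep, "age"] < 0)) stop("age must be >= 0")
  if (any(cov[keep, "bmi"] <= 0)) stop("BMI must be > 0")
  if (includeStorage && any(cov[keep, "storageDays"] < 0))
    stop("storage_days must be >= 0")
  ids <- as.character(pheno$id)[keep]
  y <- setNames(y[keep], ids)
  ageMean <- mean(cov[keep, "age"])
  a <- cov[keep, "age"] - ageMean
  s <- cov[keep, "sex"]
  X <- cbind(intercept = 1, age = a, age2 = a^2, sex = s,
             ageSex = a * s, age2Sex = a^2 * s, bmi = cov[keep, "bmi"])
  if (includeStorage) X <- cbind(X, storageDays = cov[keep, "storageDays"])
  rownames(X) <- ids
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  constant["intercept"] <- FALSE
  if (any(constant)) X <- X[, !constant, drop = FALSE]
  # a single-sex sample also makes the interactions duplicate age/age2;
  # pivoted QR drops whatever is left collinear, keeping earlier columns
  q <- qr(X)
  if (q$rank < ncol(X))
    X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
  list(y = y, X = X, ids = ids, ageMean = ageMean,
       dropped = as.character(pheno$id)[!keep])
}

#' Read a phenotype file
#'
#' CSV with a header; one row per individual, an \code{id} column, trait
#' columns in measurement units, and covariate columns \code{age} (years),
#' \code{sex}, \code{bmi} (kg/m2) and \code{storage_days}. Missing values
#' as empty fields or \code{NA}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypeFile <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
}
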