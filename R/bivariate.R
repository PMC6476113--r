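## Bivariate polygenic model: genetic and environmental correlations
## between two traits, pleiotropy classification, LRT for rho_g = 0.
##
## In the eigenbasis of 2*Phi the 2n x 2n covariance factors into one 2x2
## block per eigenvalue d:
##   [ sA2 (hA2 d + 1-hA2)                 c(d)              ]
##   [ c(d)                 sB2 (hB2 d + 1-hB2)              ]
## with c(d) = sqrt(sA2 sB2) [rho_g sqrt(hA2 hB2) d +
##                            rho_e sqrt((1-hA2)(1-hB2))],
## so each likelihood evaluation is O(n) after one decomposition.

# th = (h2A, h2B, rhoG, rhoE, lnsA2, lnsB2); beta profiled by GLS.
.bivProfileLL <- function(th, ysA, ysB, XsA, XsB, d, n) {
  h2A <- th[1]; h2B <- th[2]; rg <- th[3]; re <- th[4]
  sA2 <- exp(th[5]); sB2 <- exp(th[6])
  vA <- sA2 * (h2A * d + (1 - h2A))
  vB <- sB2 * (h2B * d + (1 - h2B))
  cc <- sqrt(sA2 * sB2) *
    (rg * sqrt(h2A * h2B) * d + re * sqrt((1 - h2A) * (1 - h2B)))
  det <- vA * vB - cc^2
  if (min(det) < 1e-300 || min(vA) < 1e-300 || min(vB) < 1e-300) return(-1e300)
  w11 <- vB / det; w22 <- vA / det; w12 <- -cc / det

  pA <- ncol(XsA); pB <- ncol(XsB)
  A11 <- crossprod(XsA * w11, XsA)
  A22 <- crossprod(XsB * w22, XsB)
  A12 <- crossprod(XsA * w12, XsB)
  A <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  b <- c(crossprod(XsA, w11 * ysA + w12 * ysB),
         crossprod(XsB, w12 * ysA + w22 * ysB))
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(-1e300)
  rA <- ysA - as.vector(XsA %*% beta[seq_len(pA)])
  rB <- ysB - as.vector(XsB %*% beta[pA + seq_len(pB)])
  quad <- sum(w11 * rA^2 + 2 * w12 * rA * rB + w22 * rB^2)
  -0.5 * (2 * n * log(2 * pi) + sum(log(det)) + quad)
}

.rhoP <- function(rhoG, rhoE, h2A, h2B)
  rhoG * sqrt(h2A * h2B) + rhoE * sqrt((1 - h2A) * (1 - h2B))

.classifyPleiotropy <- function(rhoG) {
  if (abs(rhoG) >= 1 - 1e-6) "complete"
  else if (abs(rhoG) < 1e-8) "none"
  else "incomplete"
}

#' Fit the bivariate polygenic model
#'
#' Joint maximum-likelihood fit of two traits measured on the same pedigree.
#' Within-trait covariance follows the univariate polygenic model; the
#' cross-trait covariance is
#' \eqn{2\Phi\,\rho_g\sigma_{aA}\sigma_{aB} + I\,\rho_e\sigma_{eA}\sigma_{eB}}.
#' The phenotypic correlation is reported through the identity
#' \eqn{\rho_p = \rho_g\sqrt{h_A^2 h_B^2} +
#'      \rho_e\sqrt{(1-h_A^2)(1-h_B^2)}} evaluated at the fitted components.
#' Individuals missing either trait or any covariate are dropped
#' (complete pairs). \eqn{\rho_g = 0} is tested by a likelihood-ratio test
#' against \eqn{\chi^2_1} (an interior null); when the estimate lies on the
#' boundary \eqn{|\rho_g| = 1} the fit is classified as complete pleiotropy
#' and the half-mixture \eqn{\tfrac12\chi^2_0:\tfrac12\chi^2_1} is used.
#'
#' @param yA,yB trait vectors over the same individuals.
#' @param XA,XB per-trait design matrices (rows aligned with yA/yB).
#' @param twoPhi additive-relationship matrix, same order.
#' @param traits length-2 character, trait labels for reporting.
#' @param se compute standard errors of rho_g and rho_p (delta method on the
#'   observed information).
#' @param decomp optional precomputed eigendecomposition of \code{twoPhi}
#'   restricted to the complete pairs (advanced use inside simulation loops;
#'   must match the rows actually analysed).
#' @return a \linkS4class{BivariateFit}.
#' @export
fitBivariate <- function(yA, yB, XA, XB, twoPhi,
                         traits = c("traitA", "traitB"), se = TRUE,
                         decomp = NULL) {
  stopifnot(length(yA) == length(yB), nrow(XA) == length(yA),
            nrow(XB) == length(yB))
  keep <- !is.na(yA) & !is.na(yB) & complete.cases(XA) & complete.cases(XB)
  yA <- yA[keep]; yB <- yB[keep]
  XA <- XA[keep, , drop = FALSE]; XB <- XB[keep, , drop = FALSE]
  n <- length(yA)
  if (n <= ncol(XA) + ncol(XB) + 5)
    stop("too few complete pairs (", n, ") for the bivariate model")
  if (is.null(decomp)) decomp <- .vcDecomp(twoPhi[keep, keep, drop = FALSE])
  trA <- .transform(decomp, yA, XA)
  trB <- .transform(decomp, yB, XB)
  d <- decomp$d

  # univariate fits seed the starts
  uA <- fitPolygenic(yA, XA, twoPhi[keep, keep], se = FALSE, decomp = decomp)
  uB <- fitPolygenic(yB, XB, twoPhi[keep, keep], se = FALSE, decomp = decomp)
  h2A0 <- min(max(uA@h2, 0.02), 0.9)
  h2B0 <- min(max(uB@h2, 0.02), 0.9)
  lsA0 <- log(uA@sigmaA2 + uA@sigmaE2)
  lsB0 <- log(uB@sigmaA2 + uB@sigmaE2)
  rA <- yA - as.vector(XA %*% qr.solve(XA, yA))
  rB <- yB - as.vector(XB %*% qr.solve(XB, yB))
  r0 <- min(max(stats::cor(rA, rB), -0.9), 0.9)

  lower <- c(0, 0, -1, -0.995, lsA0 - 30, lsB0 - 30)
  upper <- c(1 - 1e-6, 1 - 1e-6, 1, 0.995, lsA0 + 30, lsB0 + 30)
  obj <- function(th) -.bivProfileLL(th, trA$ys, trB$ys, trA$Xs, trB$Xs, d, n)
  runFrom <- function(start, fixRhoG = FALSE) {
    if (fixRhoG) {
      f <- function(th5) obj(c(th5[1:2], 0, th5[3:5]))
      tryCatch(optim(start[-3], f, method = "L-BFGS-B",
                     lower = lower[-3], upper = upper[-3],
                     control = list(factr = 1e7, maxit = 300)),
               error = function(e) NULL)
    } else {
      tryCatch(optim(start, obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = 1e7, maxit = 300)),
               error = function(e) NULL)
    }
  }
  starts <- list(c(h2A0, h2B0, 0, r0, lsA0, lsB0),
                 c(h2A0, h2B0, 0.4, r0 / 2, lsA0, lsB0),
                 c(h2A0, h2B0, -0.4, r0 / 2, lsA0, lsB0))
  best <- NULL
  for (s in starts) {
    fit <- runFrom(s)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("bivariate fit failed from every start")
  th <- best$par
  ll <- -best$value

  # rho_g = 0 submodel for the pleiotropy LRT
  best0 <- NULL
  for (s in starts[1]) {
    fit <- runFrom(s, fixRhoG = TRUE)
    if (!is.null(fit) && (is.null(best0) || fit$value < best0$value)) best0 <- fit
  }
  ll0 <- if (is.null(best0)) NA_real_ else -best0$value
  if (!is.na(ll0) && ll < ll0 - 1e-6) { # constrained fit found a better mode
    refit <- runFrom(c(best0$par[1:2], 0, best0$par[3:5]))
    if (!is.null(refit) && -refit$value > ll) {
      th <- refit$par; ll <- -refit$value
    } else {
      th[3] <- 0; ll <- ll0
    }
  }

  h2A <- th[1]; h2B <- th[2]; rhoG <- th[3]; rhoE <- th[4]
  rhoP <- .rhoP(rhoG, rhoE, h2A, h2B)
  boundary <- abs(rhoG) >= 1 - 1e-6
  lambda <- max(0, 2 * (ll - ll0))
  pRhoG <- if (boundary) 0.5 * pchisq(lambda, 1, lower.tail = FALSE)
           else pchisq(lambda, 1, lower.tail = FALSE)

  rhoGSE <- rhoPSE <- NA_real_
  if (se && !boundary && all(th[1:2] > 1e-4) && all(th[1:2] < 1 - 1e-4)) {
    f <- function(t) .bivProfileLL(t, trA$ys, trB$ys, trA$Xs, trB$Xs, d, n)
    H <- .numHessian(f, th)
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[c(1, 2, 3, 4)] > 0)) {
      rhoGSE <- sqrt(V[3, 3])
      # delta method for rho_p = g(h2A, h2B, rhoG, rhoE)
      gr <- c(
        rhoG * sqrt(h2B / h2A) / 2 - rhoE * sqrt((1 - h2B) / (1 - h2A)) / 2,
        rhoG * sqrt(h2A / h2B) / 2 - rhoE * sqrt((1 - h2A) / (1 - h2B)) / 2,
        sqrt(h2A * h2B),
        sqrt((1 - h2A) * (1 - h2B)), 0, 0)
      v <- as.numeric(t(gr) %*% V %*% gr)
      if (v > 0) rhoPSE <- sqrt(v)
    }
  }

  new("BivariateFit",
      traits = traits, h2A = h2A, h2B = h2B,
      sigmaP2A = exp(th[5]), sigmaP2B = exp(th[6]),
      rhoG = rhoG, rhoE = rhoE, rhoP = rhoP,
      rhoGSE = rhoGSE, rhoPSE = rhoPSE,
      loglik = ll, loglikNoRhoG = ll0, pRhoG = pRhoG,
      pleiotropy = .classifyPleiotropy(rhoG),
      nUsed = as.integer(n), converged = best$convergence == 0)
}

#' @export
setMethod("logLik", "BivariateFit", function(object, ...) object@loglik)

setMethod("show", "BivariateFit", function(object) {
  cat("Bivariate polygenic fit:", paste(object@traits, collapse = " ~ "),
      " (n =", object@nUsed, ")\n")
  cat(sprintf("  rho_g = %.4f (SE %s), p[rho_g=0] = %.3g  [%s pleiotropy]\n",
              object@rhoG,
              ifelse(is.na(object@rhoGSE), "NA", sprintf("%.4f", object@rhoGSE)),
              object@pRhoG, object@pleiotropy))
  cat(sprintf("  rho_e = %.4f, rho_p = %.4f (SE %s)\n", object@rhoE,
              object@rhoP,
              ifelse(is.na(object@rhoPSE), "NA", sprintf("%.4f", object@rhoPSE))))
  cat(sprintf("  h2A = %.3f, h2B = %.3f, logLik = %.3f\n",
              object@h2A, object@h2B, object@loglik))
})
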