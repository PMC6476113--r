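## Univariate polygenic variance-component model: likelihood, ML fit, LRT.
##
## All likelihood evaluations run in the eigenbasis of 2*Phi. With
## 2*Phi = U D U', Omega = sigma_a2 * 2Phi + sigma_e2 * I has the same
## eigenvectors, so after one decomposition every evaluation is O(n * p).

.vcDecomp <- function(twoPhi) {
  e <- eigen(twoPhi, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0))
}

.transform <- function(decomp, y, X) {
  list(ys = as.vector(crossprod(decomp$U, y)),
       Xs = crossprod(decomp$U, X))
}

# GLS with diagonal variance weights w (relative scale): returns beta, the
# weighted residual sum of squares and the information matrix X' W^-1 X.
.gls <- function(ys, Xs, w) {
  iw <- 1 / w
  A <- crossprod(Xs * iw, Xs)
  b <- crossprod(Xs * iw, ys)
  beta <- solve(A, b)
  r <- ys - as.vector(Xs %*% beta)
  list(beta = as.vector(beta), rss = sum(r * r * iw), A = A, resid = r)
}

# Profile log-likelihood at (h2, ln sigma_p2); beta profiled out by GLS.
.polyProfileLL <- function(par, ys, Xs, d, n) {
  h2 <- par[1]; sp2 <- exp(par[2])
  w <- h2 * d + (1 - h2)
  if (min(w) < 1e-12) return(-1e300)
  g <- .gls(ys, Xs, w)
  -0.5 * (n * log(2 * pi) + n * par[2] + sum(log(w)) + g$rss / sp2)
}

.numHessian <- function(f, x, step = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- step; ej[j] <- step
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * step^2)
      }
    }
  }
  H
}

#' Polygenic model log-likelihood
#'
#' Evaluates the multivariate-normal log-likelihood
#' \deqn{-\tfrac12\left[n\log 2\pi + \log|\Omega| +
#'       (y - X\beta)'\Omega^{-1}(y - X\beta)\right],\quad
#'       \Omega = 2\Phi\,\sigma_a^2 + I\,\sigma_e^2}
#' through the eigendecomposition of \code{twoPhi}; a precomputed
#' decomposition can be supplied so one decomposition serves all
#' \eqn{(\sigma_a^2, \sigma_e^2)} evaluations.
#'
#' @param y trait vector.
#' @param X design matrix (see [buildDesign()]).
#' @param twoPhi additive-relationship matrix aligned to \code{y}.
#' @param sigmaA2 additive genetic variance (>= 0).
#' @param sigmaE2 environmental variance (> 0).
#' @param beta fixed-effect coefficient vector.
#' @param decomp optional result of the internal eigendecomposition
#'   (\code{list(U, d)}) of \code{twoPhi}.
#' @return log-likelihood (scalar).
#' @export
polygenicLoglik <- function(y, X, twoPhi, sigmaA2, sigmaE2, beta,
                            decomp = NULL) {
  stopifnot(sigmaA2 >= 0)
  if (sigmaE2 <= 1e-12)
    stop("sigmaE2 below floor: covariance matrix numerically singular")
  n <- length(y)
  stopifnot(nrow(X) == n, length(beta) == ncol(X))
  if (is.null(decomp)) decomp <- .vcDecomp(twoPhi)
  w <- sigmaA2 * decomp$d + sigmaE2
  r <- as.vector(crossprod(decomp$U, y - as.vector(X %*% beta)))
  -0.5 * (n * log(2 * pi) + sum(log(w)) + sum(r * r / w))
}

#' Fit the univariate polygenic model by maximum likelihood
#'
#' Maximises the polygenic likelihood over \eqn{(h^2, \log\sigma_p^2)} with
#' the fixed effects profiled out by generalised least squares at every
#' variance evaluation. Optimisation uses bounded quasi-Newton (L-BFGS-B)
#' from three starting heritabilities (0.05, 0.3, 0.7). The standard error
#' of \eqn{h^2} comes from the observed information (central-difference
#' Hessian, step 1e-4) and is \code{NA} at the boundary; the p-value for
#' \eqn{h^2 = 0} is the boundary likelihood-ratio test of [h2LRT()].
#'
#' @param y named trait vector (NA allowed; complete cases are used).
#' @param X design matrix aligned to \code{y}.
#' @param twoPhi additive-relationship matrix aligned to \code{y}.
#' @param se compute the standard error of h2 (set \code{FALSE} inside
#'   tight simulation loops).
#' @param decomp optional precomputed eigendecomposition of \code{twoPhi}
#'   restricted to the complete cases (advanced use; must match the rows
#'   actually analysed).
#' @return a \linkS4class{PolygenicFit}.
#' @export
fitPolygenic <- function(y, X, twoPhi, se = TRUE, decomp = NULL) {
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  twoPhiK <- twoPhi[keep, keep, drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 2)
    stop("too few complete observations (", n, ") for ", p, " design columns")
  if (is.null(decomp)) decomp <- .vcDecomp(twoPhiK)
  tr <- .transform(decomp, y, X)

  # null model (h2 = 0): ordinary ML regression, closed form
  g0 <- .gls(tr$ys, tr$Xs, rep(1, n))
  sp20 <- g0$rss / n
  ll0 <- -0.5 * (n * log(2 * pi) + n * log(sp20) + n)

  obj <- function(par) -.polyProfileLL(par, tr$ys, tr$Xs, decomp$d, n)
  best <- NULL
  for (h0 in c(0.05, 0.3, 0.7)) {
    fit <- tryCatch(
      optim(c(h0, log(sp20)), obj, method = "L-BFGS-B",
            lower = c(0, log(sp20) - 30), upper = c(1 - 1e-6, log(sp20) + 30),
            control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("polygenic fit failed from every start")
  h2 <- best$par[1]; sp2 <- exp(best$par[2])
  ll <- -best$value
  if (ll < ll0 - 1e-6) { # boundary fit can beat a stalled optimiser
    h2 <- 0; sp2 <- sp20; ll <- ll0
  }
  sigmaA2 <- h2 * sp2; sigmaE2 <- (1 - h2) * sp2
  degenerate <- sigmaE2 < 1e-10 * max(var(y), .Machine$double.eps)
  if (degenerate)
    warning("environmental variance at floor: fit is degenerate (trait is an exact function of the covariates?)")

  w <- h2 * decomp$d + (1 - h2)
  g <- .gls(tr$ys, tr$Xs, w)
  betaSE <- sqrt(diag(solve(g$A)) * sp2)

  h2SE <- NA_real_
  if (se && h2 > 1e-4 && h2 < 1 - 1e-4 && !degenerate) {
    H <- .numHessian(function(par) .polyProfileLL(par, tr$ys, tr$Xs, decomp$d, n),
                     c(h2, log(sp2)))
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && V[1, 1] > 0) h2SE <- sqrt(V[1, 1])
  }

  new("PolygenicFit",
      sigmaA2 = sigmaA2, sigmaE2 = sigmaE2, h2 = h2, h2SE = h2SE,
      beta = setNames(g$beta, colnames(X)),
      betaSE = setNames(as.vector(betaSE), colnames(X)),
      loglik = ll, loglikNull = ll0, pH2 = h2LRT(ll, ll0),
      nUsed = as.integer(n),
      converged = !is.null(best) && best$convergence == 0,
      degenerate = degenerate)
}

#' Boundary likelihood-ratio test for h2 = 0
#'
#' Because \eqn{h^2 = 0} lies on the boundary of the parameter space, the
#' LRT statistic \eqn{\Lambda = 2(\ell_1 - \ell_0)} (clipped at zero) is
#' compared to the half-and-half mixture
#' \eqn{\tfrac12\chi^2_0 : \tfrac12\chi^2_1}, so
#' \eqn{p = \tfrac12 P(\chi^2_1 \ge \Lambda)} and \eqn{\Lambda = 0} gives
#' \eqn{p = 0.5}.
#'
#' @param loglikFull maximised log-likelihood of the full model.
#' @param loglikNull maximised log-likelihood of the h2 = 0 model.
#' @return p-value.
#' @export
h2LRT <- function(loglikFull, loglikNull) {
  if (loglikFull < loglikNull - 1e-6)
    warning("full-model log-likelihood below null: nesting violated, statistic clipped at 0")
  lambda <- max(0, 2 * (loglikFull - loglikNull))
  0.5 * pchisq(lambda, df = 1, lower.tail = FALSE)
}

#' @rdname heritability
#' @export
setMethod("heritability", "PolygenicFit", function(x) x@h2)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "PolygenicFit", function(object, ...) object@loglik)

setMethod("show", "PolygenicFit", function(object) {
  cat("Polygenic variance-component fit (ML), n =", object@nUsed, "\n")
  cat(sprintf("  h2 = %.4f (SE %s), p[h2=0] = %.3g\n", object@h2,
              ifelse(is.na(object@h2SE), "NA", sprintf("%.4f", object@h2SE)),
              object@pH2))
  cat(sprintf("  sigma_a2 = %.4f, sigma_e2 = %.4f, logLik = %.3f\n",
              object@sigmaA2, object@sigmaE2, object@loglik))
  if (object@degenerate) cat("  [degenerate: environmental variance at floor]\n")
  if (!object@converged) cat("  [optimiser did not report convergence]\n")
})
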