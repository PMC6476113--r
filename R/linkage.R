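## Variance-component linkage: single-locus QTL fits, LOD scores,
## chromosome/genome scans and 1-LOD support intervals.

#' Construct an MIBD track
#'
#' @param ids member identifiers.
#' @param chrom chromosome label.
#' @param posCM strictly increasing grid positions (cM).
#' @param pihat list of per-position sharing matrices (one per grid point),
#'   or \code{NULL} when \code{labels} is given.
#' @param posBP optional base-pair coordinates of the grid points.
#' @param labels optional founder-haplotype label matrix (internal compact
#'   storage produced by [geneDrop()]).
#' @return a \linkS4class{MibdTrack}.
#' @export
mibdTrack <- function(ids, chrom, posCM, pihat = NULL, posBP = NULL,
                      labels = NULL) {
  np <- length(posCM)
  if (is.null(posBP)) posBP <- rep(NA_real_, np)
  new("MibdTrack", ids = as.character(ids), chrom = as.character(chrom),
      posCM = as.numeric(posCM), posBP = as.numeric(posBP),
      pihat = if (is.null(pihat)) list() else pihat,
      labels = if (is.null(labels)) matrix(0L, length(ids), 0) else labels)
}

#' @rdname pihatAt
#' @export
setMethod("pihatAt", "MibdTrack", function(x, i, cM) {
  if (missing(i)) {
    i <- which(abs(x@posCM - cM) < 1e-9)
    if (length(i) != 1) stop("no grid position at ", cM, " cM")
  }
  P <- if (length(x@pihat)) x@pihat[[i]]
       else {
         np <- length(x@posCM)
         cpp_pihat(x@labels[, i], x@labels[, np + i])
       }
  dimnames(P) <- list(x@ids, x@ids)
  P
})

#' @rdname memberIds
#' @export
setMethod("memberIds", "MibdTrack", function(x) x@ids)

setMethod("show", "MibdTrack", function(object) {
  cat("MibdTrack: chromosome", object@chrom, "--",
      length(object@posCM), "grid positions (",
      object@posCM[1], "-", object@posCM[length(object@posCM)], "cM ),",
      length(object@ids), "individuals\n")
  cat("  storage:", if (length(object@pihat)) "explicit matrices"
      else "founder-haplotype labels (lazy)", "\n")
})

# profile log-likelihood of the three-component model at u = (hq, u2) with
# ha = (1 - hq) * u2, so the variance-share simplex maps smoothly onto the
# unit box; beta (GLS) and the total variance (rss/n) are profiled out in
# closed form, leaving one Cholesky per evaluation.
.qtlProfileLL <- function(u, y, X, Pi, G, n) {
  nll <- cpp_qtl_nll(u[1], (1 - u[1]) * u[2], Pi, G, as.numeric(y), X)
  if (nll >= 1e300) return(-1e300)
  -nll
}

#' Fit the single-locus QTL variance-component model
#'
#' Maximum-likelihood fit of
#' \eqn{\Omega = \hat\Pi\,\sigma_q^2 + 2\Phi\,\sigma_a^2 + I\,\sigma_e^2}
#' with fixed effects (GLS) and the total variance (rss/n) profiled out in
#' closed form, optimised over the two variance shares
#' \eqn{(\sigma_q^2, \sigma_a^2)/\sigma_p^2} on the simplex. When \eqn{\hat\Pi} coincides with \eqn{2\Phi} the two
#' genetic components are structurally confounded; the fit is flagged and
#' collapses to the polygenic model (LOD defined as 0).
#'
#' @param y trait vector (complete cases used).
#' @param X design matrix.
#' @param twoPhi additive-relationship matrix.
#' @param pihat locus IBD-sharing matrix aligned to \code{y}.
#' @param start optional warm start \code{c(hq, ha, lnSigmaP2)} from a
#'   neighbouring locus.
#' @param polygenic optional \linkS4class{PolygenicFit} on the same data
#'   (supplies the default start and avoids refitting inside scans).
#' @return a \linkS4class{QtlFit}.
#' @export
fitQtlLocus <- function(y, X, twoPhi, pihat, start = NULL, polygenic = NULL) {
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  G <- twoPhi[keep, keep, drop = FALSE]
  Pi <- pihat[keep, keep, drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 3) stop("too few observations for the QTL model")

  if (max(abs(Pi - G)) < 1e-8) {
    pf <- if (is.null(polygenic)) fitPolygenic(y, X, G, se = FALSE) else polygenic
    return(new("QtlFit", sigmaQ2 = 0, sigmaA2 = pf@sigmaA2,
               sigmaE2 = pf@sigmaE2, loglik = pf@loglik,
               nUsed = as.integer(n), converged = TRUE, confounded = TRUE))
  }

  if (is.null(polygenic)) polygenic <- fitPolygenic(y, X, G, se = FALSE)
  sp20 <- polygenic@sigmaA2 + polygenic@sigmaE2
  ha0 <- polygenic@h2
  starts <- list(c(0.05, min(ha0 / 0.95, 1 - 1e-6)),
                 c(0.15, min(max(ha0 - 0.1, 0) / 0.85, 1 - 1e-6)))
  if (!is.null(start)) {
    hq <- min(max(start[1], 0), 1 - 1e-6)
    u2 <- if (hq < 1 - 1e-6) min(max(start[2] / (1 - hq), 0), 1 - 1e-6) else 0
    # warm-started (scan) fits: the neighbouring solution plus one fallback
    starts <- list(c(hq, u2), starts[[1]])
  }
  # value and analytic gradient share one evaluation (optim calls fn and gr
  # at the same point back to back; the cache avoids recomputing)
  yv <- as.numeric(y)
  cache <- new.env(parent = emptyenv())
  evalAt <- function(u) {
    key <- paste(u, collapse = ",")
    if (!identical(cache$key, key)) {
      v <- cpp_qtl_nll_grad(u[1], (1 - u[1]) * u[2], Pi, G, yv, X)
      cache$key <- key
      cache$val <- v
    }
    cache$val
  }
  obj <- function(u) min(evalAt(u)[1], 1e300)
  grad <- function(u) {
    v <- evalAt(u)
    if (v[1] >= 1e300 || anyNA(v[2:3])) return(c(0, 0))
    # chain rule (hq, ha) -> (hq, u2) with ha = (1 - hq) * u2
    c(v[2] - v[3] * u[2], v[3] * (1 - u[1]))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, grad, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(1 - 1e-6, 1 - 1e-6),
            control = list(factr = 1e9, maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (is.null(start) || is.null(best)) next
    # warm-started scans: accept the first start's solution when it already
    # dominates the polygenic fit, and skip the fallback start deep in the
    # null region (previous locus and this fit both at the sigma_q2 = 0
    # boundary, where the likelihood maximum is the polygenic fit itself)
    if (-best$value >= polygenic@loglik + 1e-4) break
    if (start[1] < 1e-4 && best$par[1] < 1e-4) break
  }
  if (is.null(best)) stop("QTL fit failed from every start")
  u <- best$par
  ll <- -best$value
  hq <- u[1]; ha <- (1 - u[1]) * u[2]
  # recover the profiled total variance at the optimum
  V <- hq * Pi + ha * G; diag(V) <- diag(V) + (1 - hq - ha)
  L <- chol(V)
  g <- .gls(backsolve(L, y, transpose = TRUE),
            backsolve(L, X, transpose = TRUE), rep(1, n))
  sp2 <- g$rss / n
  if (ll < polygenic@loglik) { # sigma_q2 = 0 boundary is the polygenic fit
    hq <- 0; ha <- polygenic@h2; sp2 <- sp20; ll <- polygenic@loglik
  }
  new("QtlFit", sigmaQ2 = hq * sp2, sigmaA2 = ha * sp2,
      sigmaE2 = (1 - hq - ha) * sp2, loglik = ll,
      nUsed = as.integer(n), converged = best$convergence == 0,
      confounded = FALSE)
}

#' LOD score from nested log-likelihoods
#'
#' \eqn{LOD = (\ell_{QTL} - \ell_{polygenic}) / \ln 10}, clipped at zero
#' (the QTL model nests the polygenic model, so negative differences are
#' numerical noise).
#'
#' @param loglikQtl maximised log-likelihood with the locus component.
#' @param loglikPoly maximised polygenic log-likelihood.
#' @return LOD score (>= 0).
#' @export
lodScore <- function(loglikQtl, loglikPoly) {
  if (loglikQtl < loglikPoly - 1e-6)
    warning("QTL log-likelihood below polygenic: nesting violated, LOD clipped at 0")
  max(0, (loglikQtl - loglikPoly) / log(10))
}

#' Multipoint variance-component linkage scan
#'
#' Fits the single-locus QTL model at every grid position of an MIBD track,
#' computes LOD scores against the polygenic-only model (fitted once), and
#' classifies the peak against fixed thresholds: significant when peak LOD
#' >= 3.0, suggestive when 2.0 <= peak < 3.0. Ties at the peak are broken by
#' the lowest cM position. Per-locus fits warm-start from the previous
#' locus's variance estimates. The 1-LOD support interval around the peak is
#' attached when the peak exceeds LOD 1 (see [oneLodInterval()]).
#'
#' @param y named trait vector (names are member ids).
#' @param X design matrix aligned to \code{y}.
#' @param twoPhi additive-relationship matrix aligned to \code{y}.
#' @param track a \linkS4class{MibdTrack} covering at least the analysed ids.
#' @param lodSignificant,lodSuggestive classification thresholds.
#' @return a \linkS4class{LinkageScan}.
#' @export
genomeScan <- function(y, X, twoPhi, track,
                       lodSignificant = 3.0, lodSuggestive = 2.0) {
  stopifnot(is(track, "MibdTrack"))
  if (is.null(names(y))) stop("y must be named with member ids")
  keep <- !is.na(y) & complete.cases(X)
  yk <- y[keep]; Xk <- X[keep, , drop = FALSE]
  Gk <- twoPhi[keep, keep, drop = FALSE]
  idx <- match(names(yk), track@ids)
  if (anyNA(idx))
    stop("track lacks individuals: ",
         paste(utils::head(names(yk)[is.na(idx)], 5), collapse = ", "))
  n <- length(yk)
  decomp <- .vcDecomp(Gk)
  poly <- fitPolygenic(yk, Xk, Gk, se = FALSE, decomp = decomp)
  sp20 <- poly@sigmaA2 + poly@sigmaE2

  np <- length(track@posCM)
  lod <- numeric(np)
  warm <- NULL
  for (k in seq_len(np)) {
    Pi <- pihatAt(track, k)[idx, idx, drop = FALSE]
    fit <- fitQtlLocus(yk, Xk, Gk, Pi, start = warm, polygenic = poly)
    lod[k] <- if (fit@confounded) 0 else lodScore(fit@loglik, poly@loglik)
    sp2 <- fit@sigmaQ2 + fit@sigmaA2 + fit@sigmaE2
    warm <- c(fit@sigmaQ2 / sp2, fit@sigmaA2 / sp2, log(sp2))
  }
  tab <- data.frame(chrom = track@chrom, posCM = track@posCM,
                    posBP = track@posBP, lod = lod)
  ipk <- which.max(lod)                 # which.max returns the first maximum
  peak <- list(chrom = track@chrom, posCM = track@posCM[ipk],
               posBP = track@posBP[ipk], lod = lod[ipk])
  cls <- if (peak$lod >= lodSignificant) "significant"
         else if (peak$lod >= lodSuggestive) "suggestive" else "none"
  scan <- new("LinkageScan", table = tab, peak = peak, classification = cls,
              interval = c(cmLo = NA_real_, cmHi = NA_real_,
                           bpLo = NA_real_, bpHi = NA_real_),
              polygenic = poly)
  if (peak$lod > 1) scan@interval <- oneLodInterval(scan)
  scan
}

#' 1-LOD support interval around the scan peak
#'
#' Returns the maximal contiguous run of grid positions around the peak with
#' LOD >= peak - 1, the conventional approximate 95 percent confidence
#' region for QTL location. Base-pair bounds are taken from the grid's bp
#' coordinates at the interval endpoints (linearly interpolated between
#' flanking grid positions when an endpoint's bp is missing but its
#' neighbours' are known). With peak LOD <= 1 the interval is undefined and
#' the whole chromosome is returned with a warning.
#'
#' @param scan a \linkS4class{LinkageScan}.
#' @return named numeric vector \code{(cmLo, cmHi, bpLo, bpHi)}.
#' @export
oneLodInterval <- function(scan) {
  tab <- scan@table
  tab <- tab[tab$chrom == scan@peak$chrom, , drop = FALSE]
  np <- nrow(tab)
  ipk <- which(tab$posCM == scan@peak$posCM)[1]
  if (scan@peak$lod <= 1) {
    warning("peak LOD <= 1: 1-LOD interval undefined, returning whole chromosome")
    return(c(cmLo = tab$posCM[1], cmHi = tab$posCM[np],
             bpLo = tab$posBP[1], bpHi = tab$posBP[np]))
  }
  thr <- scan@peak$lod - 1
  lo <- ipk
  while (lo > 1 && tab$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < np && tab$lod[hi + 1] >= thr) hi <- hi + 1

  bpAt <- function(i) {
    if (!is.na(tab$posBP[i])) return(tab$posBP[i])
    known <- which(!is.na(tab$posBP))
    if (length(known) < 2) return(NA_real_)
    stats::approx(tab$posCM[known], tab$posBP[known], xout = tab$posCM[i],
                  rule = 2)$y
  }
  c(cmLo = tab$posCM[lo], cmHi = tab$posCM[hi],
    bpLo = bpAt(lo), bpHi = bpAt(hi))
}

setMethod("show", "LinkageScan", function(object) {
  cat("Linkage scan: chromosome", object@peak$chrom, "--",
      nrow(object@table), "positions\n")
  cat(sprintf("  peak LOD = %.3f at %.1f cM (%s)\n", object@peak$lod,
              object@peak$posCM, object@classification))
  if (!is.na(object@interval["cmLo"]))
    cat(sprintf("  1-LOD interval: %.1f-%.1f cM\n",
                object@interval["cmLo"], object@interval["cmHi"]))
})

#' Write / read an MIBD track
#'
#' Long-format text file with columns \code{id1 id2 position_cM pihat}
#' (self pairs included; zero-sharing pairs omitted on write), one file per
#' chromosome, plus an optional map file \code{chromosome position_cM
#' position_bp} giving base-pair coordinates of the grid.
#'
#' @param track a \linkS4class{MibdTrack} (materialised on write if stored
#'   as labels).
#' @param path MIBD file path.
#' @param mapPath optional map file path.
#' @return \code{readMibdFile} returns a \linkS4class{MibdTrack}.
#' @export
writeMibdFile <- function(track, path, mapPath = NULL) {
  ids <- track@ids
  n <- length(ids)
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  rows <- lapply(seq_along(track@posCM), function(k) {
    P <- pihatAt(track, k)
    v <- P[ut]
    keep <- v != 0
    data.table::data.table(id1 = ids[ut[keep, 1]], id2 = ids[ut[keep, 2]],
                           position_cM = track@posCM[k], pihat = v[keep])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  if (!is.null(mapPath))
    data.table::fwrite(data.table::data.table(chromosome = track@chrom,
                                              position_cM = track@posCM,
                                              position_bp = track@posBP),
                       mapPath, sep = "\t")
  invisible(path)
}

#' @rdname writeMibdFile
#' @param chrom chromosome label for the track being read.
#' @param ids optional id ordering; defaults to ids seen in the file.
#' @export
readMibdFile <- function(path, chrom, mapPath = NULL, ids = NULL) {
  dt <- data.table::fread(path, colClasses = list(character = c("id1", "id2")))
  if (is.null(ids)) ids <- sort(unique(c(dt$id1, dt$id2)))
  pos <- sort(unique(dt$position_cM))
  n <- length(ids)
  mats <- lapply(pos, function(p) {
    sub <- dt[dt$position_cM == p, ]
    P <- matrix(0, n, n, dimnames = list(ids, ids))
    i <- match(sub$id1, ids); j <- match(sub$id2, ids)
    P[cbind(i, j)] <- sub$pihat
    P[cbind(j, i)] <- sub$pihat
    P
  })
  posBP <- rep(NA_real_, length(pos))
  if (!is.null(mapPath)) {
    mp <- data.table::fread(mapPath)
    m <- match(pos, mp$position_cM[mp$chromosome == chrom])
    posBP <- mp$position_bp[mp$chromosome == chrom][m]
  }
  mibdTrack(ids, chrom, pos, pihat = mats, posBP = posBP)
}
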