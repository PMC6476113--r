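test_that("LOD score definition and clipping", {
  expect_equal(lodScore(-100, -100), 0)
  expect_equal(lodScore(-100 + 2.706 / 2, -100), 2.706 / (2 * log(10)))
  expect_equal(lodScore(-100 + 2.706 / 2, -100), 0.5875, tolerance = 1e-3)
  expect_equal(lodScore(-100 + log(1000), -100), 3)
  expect_warning(lod <- lodScore(-101, -100), "nesting")
  expect_equal(lod, 0)
})

test_that("single-locus QTL fit matches the dense MVN oracle on a toy pedigree", {
  # 5-member pedigree with an explicit locus matrix
  ped <- loadPedigree(data.frame(
    id = c("a", "b", "c", "d", "e"),
    father = c(NA, NA, "a", "a", NA),
    mother = c(NA, NA, "b", "b", NA),
    sex = c("m", "f", "m", "f", "f")))
  G <- twoPhi(kinship(ped))
  Pi <- matrix(c(1, 0, 1, 0, 0,
                 0, 1, 0, 1, 0,
                 1, 0, 1, 0.5, 0,
                 0, 1, 0.5, 1, 0,
                 0, 0, 0, 0, 1), 5, 5)
  Pi <- (Pi + t(Pi)) / 2
  set.seed(3)
  X <- cbind(1, rnorm(5))
  y <- rnorm(5)
  n <- 5
  # profile-likelihood evaluation vs dense oracle at a fixed share point
  for (u in list(c(0.2, 0.4), c(0.01, 0.9))) {
    hq <- u[1]; ha <- (1 - u[1]) * u[2]
    V <- hq * Pi + ha * G + (1 - hq - ha) * diag(n)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    sp2 <- as.numeric(t(r) %*% Vi %*% r) / n
    ref <- denseMvnLoglik(y, as.vector(X %*% beta), sp2 * V)
    got <- pedQTL:::.qtlProfileLL(u, y, X, Pi, G, n)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("locus matrix equal to 2*Phi is flagged confounded with LOD 0", {
  ped <- smallPedigree(seed = 2, founders = 10, gens = 3)
  G <- twoPhi(kinship(ped))
  n <- nrow(G)
  set.seed(5)
  X <- cbind(intercept = rep(1, n))
  y <- rnorm(n)
  fit <- fitQtlLocus(y, X, G, G)
  expect_true(fit@confounded)
  expect_equal(fit@sigmaQ2, 0)
  poly <- fitPolygenic(y, X, G, se = FALSE)
  expect_equal(lodScore(fit@loglik, poly@loglik), 0)
})

test_that("QTL fits detect a strong planted locus and LOD is affine-invariant", {
  cfg <- simConfig(seed = 31, nFoundersPerGen = 40, nGenerations = 4,
                   h2 = 0.1, qtlVarShare = 0.4,
                   chromLengthsCM = c("11" = 10), qtlPosCM = 5)
  cs <- simulatedCase(cfg, withQtl = TRUE)
  des <- buildDesign(cs$ph, "trait")
  idx <- match(des$ids, memberIds(cs$ped))
  Gk <- cs$G[idx, idx]
  Pi <- pihatAt(cs$gd$tracks[["11"]], cM = 5)[idx, idx]
  poly <- fitPolygenic(des$y, des$X, Gk, se = FALSE)
  fit <- fitQtlLocus(des$y, des$X, Gk, Pi, polygenic = poly)
  lod <- lodScore(fit@loglik, poly@loglik)
  expect_gt(lod, 1)
  expect_gt(fit@sigmaQ2, 0)

  poly2 <- fitPolygenic(-3 * des$y + 7, des$X, Gk, se = FALSE)
  fit2 <- fitQtlLocus(-3 * des$y + 7, des$X, Gk, Pi, polygenic = poly2)
  expect_equal(lodScore(fit2@loglik, poly2@loglik), lod, tolerance = 1e-3)
})

test_that("1-LOD interval follows the contiguous-run rule", {
  mkScan <- function(lod, posCM = seq_along(lod) - 1) {
    tab <- data.frame(chrom = "11", posCM = posCM,
                      posBP = posCM * 1e6 + 1, lod = lod)
    ipk <- which.max(lod)
    new("LinkageScan", table = tab,
        peak = list(chrom = "11", posCM = posCM[ipk], posBP = tab$posBP[ipk],
                    lod = lod[ipk]),
        classification = "significant",
        interval = rep(NA_real_, 4),
        polygenic = new("PolygenicFit"))
  }
  # profile (0.5, 1.9, 2.4, 3.2, 2.6, 2.1, ...): the contiguous run with
  # LOD >= 3.2 - 1 = 2.2 around the peak is 2.4, 3.2, 2.6 (2.1 just misses)
  sc <- mkScan(c(0.5, 1.9, 2.4, 3.2, 2.6, 2.1, 1.8, 0.2))
  iv <- oneLodInterval(sc)
  expect_equal(unname(iv["cmLo"]), 2)
  expect_equal(unname(iv["cmHi"]), 4)
  expect_equal(unname(iv["bpLo"]), 2e6 + 1)

  # monotone single-sided profile clips at the chromosome end
  sc2 <- mkScan(c(0.1, 0.8, 1.6, 2.4, 3.4))
  iv2 <- oneLodInterval(sc2)
  expect_equal(unname(iv2["cmHi"]), 4)
  expect_equal(unname(iv2["cmLo"]), 3)

  # peak below 1: whole chromosome with a warning
  sc3 <- mkScan(c(0.2, 0.9, 0.4))
  expect_warning(iv3 <- oneLodInterval(sc3), "undefined")
  expect_equal(unname(iv3[c("cmLo", "cmHi")]), c(0, 2))

  # interval always contains the peak and endpoint LODs >= peak - 1
  set.seed(9)
  for (r in 1:20) {
    prof <- pmax(0, stats::filter(rnorm(30, 1, 1.2), rep(1/3, 3),
                                  circular = TRUE))
    sc <- mkScan(as.numeric(prof))
    if (sc@peak$lod <= 1) next
    iv <- oneLodInterval(sc)
    expect_lte(iv["cmLo"], sc@peak$posCM)
    expect_gte(iv["cmHi"], sc@peak$posCM)
    inside <- sc@table$posCM >= iv["cmLo"] & sc@table$posCM <= iv["cmHi"]
    expect_true(all(sc@table$lod[inside] >= sc@peak$lod - 1))
  }
})

test_that("scan classification uses the fixed thresholds", {
  # classification boundaries mirror the published convention
  cls <- function(peak) if (peak >= 3) "significant"
         else if (peak >= 2) "suggestive" else "none"
  expect_equal(cls(3.18), "significant")
  expect_equal(cls(2.01), "suggestive")
  expect_equal(cls(1.99), "none")

  cfg <- simConfig(seed = 41, nFoundersPerGen = 30, nGenerations = 4,
                   h2 = 0.15, qtlVarShare = 0.5,
                   chromLengthsCM = c("11" = 8), qtlPosCM = 4, nMarkers = 5L)
  cs <- simulatedCase(cfg, withQtl = TRUE)
  des <- buildDesign(cs$ph, "trait")
  idx <- match(des$ids, memberIds(cs$ped))
  scan <- genomeScan(des$y, des$X, cs$G[idx, idx], cs$gd$tracks[["11"]])
  expect_s4_class(scan, "LinkageScan")
  expect_true(all(scan@table$lod >= 0))
  expect_equal(scan@peak$lod, max(scan@table$lod))
  expect_equal(scan@classification, cls(scan@peak$lod))
  # ties broken by lowest cM: peak is the first position attaining the max
  expect_equal(scan@peak$posCM,
               scan@table$posCM[which.max(scan@table$lod)])
})

test_that("MIBD tracks round-trip through the long-format files", {
  cfg <- simConfig(seed = 43, nFoundersPerGen = 10, nGenerations = 3,
                   chromLengthsCM = c("7" = 4), qtlChrom = "7", qtlPosCM = 2,
                   nMarkers = 2L)
  cs <- simulatedCase(cfg, withQtl = TRUE)
  trk <- cs$gd$tracks[["7"]]
  f <- tempfile(fileext = ".mibd"); fm <- tempfile(fileext = ".map")
  writeMibdFile(trk, f, mapPath = fm)
  trk2 <- readMibdFile(f, chrom = "7", mapPath = fm, ids = memberIds(cs$ped))
  expect_true(validObject(trk2))
  expect_equal(trk2@posCM, trk@posCM)
  expect_equal(trk2@posBP, trk@posBP)
  for (k in seq_along(trk@posCM))
    expect_equal(pihatAt(trk2, k), pihatAt(trk, k))
  unlink(c(f, fm))
})
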