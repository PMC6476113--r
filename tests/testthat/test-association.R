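# hand-checkable fixture: 10 SNPs x 6 individuals
fixtureGT <- function() {
  ids <- paste0("i", 1:6)
  d <- rbind(
    c(0, 1, 2, 0, 1, 0),   # autosomal, 4 copies
    c(1, 1, 1, 1, 1, 0),   # autosomal, 5 copies
    c(2, 2, 1, 2, 1, 1),   # autosomal, maf flips: minor copies = 3
    c(0, 0, 0, 0, 0, 0),   # monomorphic
    c(1, 0, NA, 0, 0, 0),  # 1 copy, one missing (at i3)
    c(0, 1, 0, 1, 2, 2),   # autosomal, 6 copies
    c(2, 1, 0, 1, 0, 1),   # autosomal, 5 copies
    c(0, 0, NA, 1, 0, 1),  # missing at i3
    c(1, 2, NA, 0, 1, 0),  # missing at i3
    c(0, 1, 1, 0, 0, 1))   # X chromosome
  info <- data.frame(snp_id = sprintf("s%02d", 1:10),
                     chrom = c(rep("1", 5), rep("2", 4), "X"),
                     posBP = seq(1e6, 1e7, length.out = 10),
                     alleleRef = "A", alleleAlt = "B")
  genotypeTable(d, info, ids = ids)
}

test_that("genotype tables orient to the minor allele", {
  gt <- fixtureGT()
  info <- snpInfo(gt)
  expect_true(all(info$maf <= 0.5))
  # s03 entered with frequency 0.75: dosages flip, 3 minor copies
  expect_equal(info$nCopies[info$snp_id == "s03"], 3)
  expect_equal(unname(dosages(gt)["s03", ]), c(0, 0, 1, 0, 1, 1))
  # alleles swapped alongside
  expect_equal(info$alleleAlt[info$snp_id == "s03"], "A")
})

test_that("QC filter enforces autosomes and the inclusive 95% call rate", {
  gt <- fixtureGT()
  q <- qcFilter(gt)
  # X SNP removed
  expect_false("s10" %in% snpInfo(q)$snp_id)
  # i3 misses 3 of 9 autosomal SNPs (call rate 0.67) and is removed
  expect_false("i3" %in% colnames(q))
  expect_equal(ncol(q), 5)
  expect_equal(nrow(q), 9)
  # counts after filtering match hand enumeration (s01 over i1,i2,i4,i5,i6)
  expect_equal(snpInfo(q)$nCopies[snpInfo(q)$snp_id == "s01"], 2)

  # exact-boundary call rate is retained: 19/20 = 0.95
  d <- matrix(0, 20, 2); d[1, 2] <- NA; d[, 1] <- rep(c(0, 1), 10)
  gt2 <- genotypeTable(d, data.frame(snp_id = sprintf("m%02d", 1:20),
                                     chrom = "1", posBP = 1:20),
                       ids = c("keep95", "alsokeep"))
  q2 <- qcFilter(gt2)
  expect_true(all(c("keep95", "alsokeep") %in% colnames(q2)))
  d[1:2, 2] <- NA   # 18/20 = 0.90 < 0.95: removed
  gt3 <- genotypeTable(d, snpInfo(gt2)[, c("snp_id", "chrom", "posBP")],
                       ids = c("keep", "drop"))
  expect_equal(colnames(qcFilter(gt3)), "keep")
})

test_that("copy filter keeps SNPs with >= 5 minor copies", {
  q <- qcFilter(fixtureGT())
  cf <- copyFilter(q)
  kept <- snpInfo(cf)
  expect_true(all(kept$nCopies >= 5))
  # hand enumeration on the filtered table (individual i3 removed, minor
  # allele re-oriented): only s07 keeps >= 5 minor copies (exactly 5,
  # threshold inclusive)
  expect_equal(kept$snp_id, "s07")
  expect_equal(kept$nCopies, 5)
  expect_false("s04" %in% kept$snp_id)  # monomorphic
  expect_false("s05" %in% kept$snp_id)  # 1 copy
  expect_false("s02" %in% kept$snp_id)  # 4 copies after dropping i3
  expect_false("s06" %in% kept$snp_id)  # flips to minor: 4 copies

  # qcFilter . copyFilter is idempotent
  again <- copyFilter(qcFilter(cf))
  expect_equal(snpInfo(again), snpInfo(cf))
  expect_equal(dosages(again), dosages(cf))
})

test_that("Bonferroni threshold reproduces the published interval criterion", {
  expect_equal(bonferroniThreshold(852), 0.05 / 852)
  expect_equal(signif(bonferroniThreshold(852), 3), 5.87e-5)
  expect_equal(round(-log10(bonferroniThreshold(852)), 2), 4.23)
  expect_equal(bonferroniThreshold(1), 0.05)
  # decreasing in the number of tests, linear in alpha
  n <- c(1, 10, 100, 852, 5000)
  expect_true(all(diff(bonferroniThreshold(n)) < 0))
  expect_equal(bonferroniThreshold(100, alpha = 0.10),
               2 * bonferroniThreshold(100, alpha = 0.05))
})

test_that("variance explained uses the additive HWE formula", {
  expect_equal(varianceExplained(0.2, 0.5, 1), 2.0)
  expect_equal(varianceExplained(0.202, 0.478, 1),
               100 * 2 * 0.478 * 0.522 * 0.202^2)
  expect_equal(varianceExplained(0.202, 0.478, 1), 2.036, tolerance = 1e-3)
  expect_equal(varianceExplained(0, 0.3, 1), 0)
  expect_error(varianceExplained(0.1, 0.6, 1), "maf")
})

test_that("measured-genotype fit matches plain regression when 2Phi = I", {
  set.seed(13)
  n <- 120
  ids <- sprintf("u%03d", 1:n)
  X <- cbind(intercept = 1, cov = rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- setNames(0.5 + 0.25 * g + rnorm(n), ids)
  G <- diag(n); dimnames(G) <- list(ids, ids)
  res <- measuredGenotypeFit(y, X, G, g, snpId = "test")
  # oracle: ML likelihood-ratio test from two plain regressions
  ll <- function(fit) {
    n <- length(fit$residuals)
    -0.5 * n * (log(2 * pi) + log(sum(fit$residuals^2) / n) + 1)
  }
  f0 <- lm(y ~ X - 1); f1 <- lm(y ~ X + g - 1)
  pRef <- pchisq(2 * (ll(f1) - ll(f0)), 1, lower.tail = FALSE)
  expect_equal(res$p, pRef, tolerance = 1e-6)
  expect_equal(res$beta, unname(coef(f1)["g"]), tolerance = 1e-4)

  expect_error(measuredGenotypeFit(y, X, G, rep(0, n)), "constant dosage")
})

test_that("effect recovery inside the polygenic model", {
  cfg <- simConfig(seed = 17, nFoundersPerGen = 40, nGenerations = 4,
                   h2 = 0.2, qtlVarShare = 0.12, qtlMAF = 0.45,
                   chromLengthsCM = c("11" = 6), qtlPosCM = 3, nMarkers = 3L)
  cs <- simulatedCase(cfg, withQtl = TRUE)
  des <- buildDesign(cs$ph, "trait")
  idx <- match(des$ids, memberIds(cs$ped))
  truth <- attr(cs$ph, "truth")
  res <- measuredGenotypeFit(des$y, des$X, cs$G[idx, idx],
                             cs$gd$truth$dosage[des$ids], snpId = "causal")
  expect_lt(abs(res$beta - truth$betaQ), 2.5 * res$betaSE)
  expect_lt(res$p, 0.01)
  expect_gt(res$varExplainedPct, 0)
})

test_that("association scans report per-SNP rows and the Bonferroni attributes", {
  cfg <- simConfig(seed = 27, nFoundersPerGen = 30, nGenerations = 4,
                   h2 = 0.15, qtlVarShare = 0.25,
                   chromLengthsCM = c("11" = 6), qtlPosCM = 3, nMarkers = 6L)
  cs <- simulatedCase(cfg, withQtl = TRUE)
  des <- buildDesign(cs$ph, "trait")
  idx <- match(des$ids, memberIds(cs$ped))
  gt <- copyFilter(qcFilter(cs$gd$genotypes))
  res <- associationScan(gt[, des$ids], des$y, des$X, cs$G[idx, idx])
  expect_equal(nrow(res), nrow(gt))
  expect_equal(attr(res, "nTests"), sum(!is.na(res$p)))
  expect_equal(attr(res, "threshold"),
               bonferroniThreshold(attr(res, "nTests")))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  expect_true(all(res$varExplainedPct >= 0, na.rm = TRUE))
  causal <- res[res$snp_id == cs$gd$truth$snp_id, ]
  expect_equal(which.min(res$p), which(res$snp_id == causal$snp_id))
})

test_that("genotype files round-trip in both layouts", {
  gt <- fixtureGT()
  f <- tempfile(fileext = ".tsv")
  writeGenotypeFile(gt, f)
  gt2 <- readGenotypeFile(f)
  expect_equal(dosages(gt2), dosages(gt))
  expect_equal(snpInfo(gt2)$maf, snpInfo(gt)$maf)

  # individual-major converter
  fi <- tempfile(fileext = ".tsv")
  D <- dosages(gt)
  dtI <- data.frame(id = colnames(D), t(D), check.names = FALSE)
  data.table::fwrite(dtI, fi, sep = "\t")
  gt3 <- readGenotypeFileIndividualMajor(fi, snpInfo(gt))
  expect_equal(dosages(gt3), dosages(gt))
  unlink(c(f, fi))
})
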