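test_that("generators are reproducible and respect the seed streams", {
  cfg <- simConfig(seed = 1, nFoundersPerGen = 20, nGenerations = 3,
                   meanSibship = 3, chromLengthsCM = c("11" = 5),
                   qtlPosCM = 2, nMarkers = 4L)
  p1 <- simulatePedigree(cfg); p2 <- simulatePedigree(cfg)
  expect_identical(memberIds(p1), memberIds(p2))
  expect_identical(p1@father, p2@father)
  g1 <- geneDrop(p1, cfg); g2 <- geneDrop(p1, cfg)
  expect_identical(g1$tracks[["11"]]@labels, g2$tracks[["11"]]@labels)
  expect_identical(dosages(g1$genotypes), dosages(g2$genotypes))
  G <- twoPhi(kinship(p1))
  t1 <- simulateTraits(p1, G, cfg, qtlDosage = g1$truth$dosage)
  t2 <- simulateTraits(p1, G, cfg, qtlDosage = g1$truth$dosage)
  expect_identical(t1$trait, t2$trait)

  # different seed, different pedigree
  p3 <- simulatePedigree(simConfig(seed = 2, nFoundersPerGen = 20,
                                   nGenerations = 3))
  expect_false(identical(p1@father, p3@father))
})

test_that("single-generation configuration yields founders only", {
  cfg <- simConfig(seed = 4, nFoundersPerGen = 12, nGenerations = 1)
  ped <- simulatePedigree(cfg)
  expect_true(all(isFounder(ped)))
  K <- phi(kinship(ped))
  expect_true(all(diag(K) == 0.5))
  expect_true(all(K[upper.tri(K)] == 0))
})

test_that("default configuration produces a cohort-scale pedigree", {
  ped <- simulatePedigree(simConfig(seed = 1))
  n <- length(memberIds(ped))
  expect_gt(n, 800)
  expect_lt(n, 1300)
  # at least 4 generations: maximum ancestor-chain depth >= 4
  depth <- setNames(rep(1L, n), memberIds(ped))
  ord <- ped@topoOrder
  for (k in ord) {
    if (!is.na(ped@father[k]))
      depth[k] <- 1L + max(depth[ped@father[k]], depth[ped@mother[k]])
  }
  expect_gte(max(depth), 4)
  # roughly 55% female
  expect_gt(mean(ped@sex == "female"), 0.48)
  expect_lt(mean(ped@sex == "female"), 0.62)
})

test_that("gene-dropped IBD sharing has the Mendelian structure", {
  cfg <- simConfig(seed = 6, chromLengthsCM = c("1" = 6), qtlChrom = "1",
                   qtlPosCM = 3, nMarkers = 2L)
  trio <- loadPedigree(trioTable())
  gd <- geneDrop(trio, cfg)
  trk <- gd$tracks[["1"]]
  expect_true(validObject(trk))
  # parent-offspring sharing is exactly 0.5 at every locus
  for (k in seq_along(trk@posCM)) {
    P <- pihatAt(trk, k)
    expect_equal(P["F1", "C1"], 0.5)
    expect_equal(P["M1", "C1"], 0.5)
    expect_equal(diag(P), setNames(rep(1, 3), memberIds(trio)))
  }

  # full sibs at one locus: pihat in {0, .5, 1} with probabilities 1/4,1/2,1/4
  sibs <- loadPedigree(data.frame(id = c("F", "M", "s1", "s2"),
                                  father = c(NA, NA, "F", "F"),
                                  mother = c(NA, NA, "M", "M"),
                                  sex = c("m", "f", "m", "f")))
  vals <- vapply(1:600, function(r) {
    gd <- geneDrop(sibs, simConfig(seed = 1000 + r,
                                   chromLengthsCM = c("1" = 1),
                                   qtlChrom = "1", qtlPosCM = 0,
                                   nMarkers = 1L))
    pihatAt(gd$tracks[["1"]], 1)["s1", "s2"]
  }, 0)
  expect_true(all(vals %in% c(0, 0.5, 1)))
  props <- as.numeric(table(factor(vals, levels = c(0, 0.5, 1)))) / 600
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.06)

  # expectation identity: mean pihat over many independent chromosomes
  # approaches 2*phi
  ped <- smallPedigree(seed = 7, founders = 10, gens = 3)
  G <- twoPhi(kinship(ped))
  acc <- 0
  R <- 150
  for (r in 1:R) {
    gd <- geneDrop(ped, simConfig(seed = 5000 + r,
                                  chromLengthsCM = c("1" = 1),
                                  qtlChrom = "1", qtlPosCM = 0,
                                  nMarkers = 1L))
    acc <- acc + pihatAt(gd$tracks[["1"]], 1)
  }
  expect_lt(max(abs(acc / R - G)), 6 * 0.5 / sqrt(R))
})

test_that("simulated traits carry the requested genetic architecture", {
  # null trait: no heritability, no QTL
  cfg0 <- simConfig(seed = 8, nFoundersPerGen = 30, nGenerations = 4,
                    h2 = 0, qtlVarShare = 0)
  cs0 <- simulatedCase(cfg0)
  expect_equal(attr(cs0$ph, "truth")$h2, 0)
  expect_true(all(c("age", "sex", "bmi", "storage_days") %in% names(cs0$ph)))
  expect_true(all(cs0$ph$age >= 18 & cs0$ph$age <= 88))
  expect_true(all(cs0$ph$bmi > 0))
  expect_true(all(cs0$ph$storage_days >= 0))

  # bivariate limit rho_g = 1, h2 = 1 both traits: correlation tends to 1
  cfg1 <- simConfig(seed = 9, nFoundersPerGen = 20, nGenerations = 3,
                    rhoG = 1, rhoE = 0, h2A = 1, h2B = 1,
                    covEffects = c(intercept = 0))
  cs1 <- simulatedCase(cfg1, bivariate = TRUE)
  expect_gt(cor(cs1$ph$traitA, cs1$ph$traitB), 0.99)

  # requested shares must be feasible
  expect_error(simConfig(h2 = 0.7, qtlVarShare = 0.5), "must not exceed 1")
})

test_that("relative-pair trait covariance matches the polygenic model", {
  # empirical covariance of parent-offspring pairs over replicates
  # approaches 2*phi*sigma_a2 = 0.5 * h2 (unit variance, no covariates)
  ped <- loadPedigree(trioTable())
  G <- twoPhi(kinship(ped))
  h2 <- 0.6
  R <- 4000
  po <- matrix(0, R, 2)
  for (r in 1:R) {
    cfg <- simConfig(seed = 20000 + r, h2 = h2, qtlVarShare = 0,
                     covEffects = c(intercept = 0))
    ph <- simulateTraits(ped, G, cfg)
    po[r, ] <- c(ph$trait[1], ph$trait[3])
  }
  expect_lt(abs(cov(po[, 1], po[, 2]) - 0.5 * h2), 0.055)  # ~3 MC SE
  expect_lt(abs(var(po[, 1]) - 1), 0.08)
})
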