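test_that("pedigree loading validates structure and reports offenders", {
  ped <- loadPedigree(trioTable())
  expect_s4_class(ped, "Pedigree")
  expect_equal(sum(isFounder(ped)), 2)
  expect_equal(sum(!isFounder(ped)), 1)

  dup <- trioTable(); dup$id[2] <- "F1"
  expect_error(loadPedigree(dup), "duplicate ids.*F1")

  self <- trioTable(); self$father[3] <- "C1"; self$mother[3] <- "M1"
  expect_error(loadPedigree(self), "cycle.*C1")

  half <- trioTable(); half$mother[3] <- NA
  expect_error(loadPedigree(half), "half-known parentage.*C1")

  unk <- trioTable(); unk$father[3] <- "nobody"
  expect_error(loadPedigree(unk), "unknown parent.*C1")

  wrongSex <- trioTable(); wrongSex$sex[1] <- "f"
  expect_error(loadPedigree(wrongSex), "father is not male.*C1")

  # two-member parent cycle
  cyc <- data.frame(id = c("a", "b", "x", "y"),
                    father = c("b", "a", NA, NA),
                    mother = c("x", "y", NA, NA),
                    sex = c("m", "m", "f", "f"))
  expect_error(loadPedigree(cyc), "cycle")
})

test_that("missing-parent and sex encodings are accepted", {
  tab <- data.frame(id = c("a", "b", "c"), father = c("0", "", "a"),
                    mother = c(NA, "0", "b"), sex = c("1", "2", "female"))
  ped <- loadPedigree(tab)
  expect_equal(unname(isFounder(ped)), c(TRUE, TRUE, FALSE))
  expect_equal(ped@sex, c("male", "female", "female"))
  expect_error(loadPedigree(transform(tab, sex = c("1", "2", "banana"))),
               "unrecognised sex")
})

test_that("kinship recursion reproduces textbook coefficients", {
  K <- phi(kinship(loadPedigree(familyTable())))
  expect_equal(K["f", "c1"], 0.25)        # parent-offspring
  expect_equal(K["c1", "c2"], 0.25)       # full sibs (unrelated parents)
  expect_equal(K["c1", "h"], 0.125)       # half sibs (same father)
  expect_equal(K["c1", "k1"], 0.0625)     # first cousins (f, m are sibs)
  expect_equal(K["gf", "gm"], 0)          # unrelated founders
  expect_equal(K["cc", "cc"], 0.625)      # offspring of full-sib mating
  expect_equal(K["f", "f"], 0.5)          # non-inbred diagonal
})

test_that("2*Phi is positive semidefinite and label-invariant", {
  for (s in 1:4) {
    ped <- smallPedigree(seed = s)
    K <- kinship(ped)
    G <- twoPhi(K)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    # permuting the member rows permutes the matrix consistently
    perm <- sample(length(memberIds(ped)))
    tab <- data.frame(id = ped@id, father = ped@father,
                      mother = ped@mother, sex = ped@sex)[perm, ]
    K2 <- phi(kinship(loadPedigree(tab)))
    expect_equal(K2, phi(K)[perm, perm])
  }
})

test_that("gene-dropping Monte Carlo agrees with the kinship recursion", {
  # parent-offspring pairs share exactly one allele per drop, so the trio
  # estimate is exact
  trio <- loadPedigree(trioTable())
  est <- phi(kinshipMC(trio, nDrops = 10000, seed = 1))
  expect_equal(est["F1", "C1"], 0.25)
  expect_equal(est["M1", "C1"], 0.25)

  # founders only: no shared labels, all off-diagonals exactly zero
  fo <- loadPedigree(data.frame(id = letters[1:6], father = NA, mother = NA,
                                sex = rep(c("m", "f"), 3)))
  estF <- phi(kinshipMC(fo, nDrops = 200, seed = 2))
  expect_true(all(estF[upper.tri(estF)] == 0))
  expect_true(all(diag(estF) == 0.5))

  # random multigeneration pedigrees: max deviation within MC bounds
  # (per-pair SE <= 0.5/sqrt(nDrops); 5.5 sigma covers the max over ~2000
  # pairs with large margin)
  for (s in 1:2) {
    ped <- smallPedigree(seed = s)
    nd <- 50000
    exact <- phi(kinship(ped))
    mc <- phi(kinshipMC(ped, nDrops = nd, seed = s + 10))
    bound <- 5.5 * 0.5 / sqrt(nd)
    expect_lt(max(abs(mc - exact)), bound)
  }
})

test_that("pedigree files round-trip through the readers", {
  ped <- smallPedigree(seed = 3)
  f <- tempfile(fileext = ".csv")
  writePedigreeFile(ped, f)
  ped2 <- readPedigreeFile(f)
  expect_equal(memberIds(ped2), memberIds(ped))
  expect_equal(ped2@father, ped@father)
  expect_equal(ped2@sex, ped@sex)
  expect_equal(phi(kinship(ped2)), phi(kinship(ped)))
  unlink(f)
})
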