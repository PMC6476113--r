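# Small pedigrees and simulation shorthands shared across test files.

trioTable <- function() {
  data.frame(id = c("F1", "M1", "C1"),
             father = c(NA, NA, "F1"),
             mother = c(NA, NA, "M1"),
             sex = c("m", "f", "f"))
}

# two founder couples, full sibs, half sibs, first cousins, and one
# offspring of a full-sib mating (inbred)
familyTable <- function() {
  data.frame(
    id     = c("gf", "gm", "f", "m", "u", "w", "c1", "c2", "h", "k1", "k2", "cc"),
    father = c(NA, NA, "gf", "gf", NA, NA, "f", "f", "f", "m", "m", "c1"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "u", "u", "w", "w", "w", "c2"),
    sex    = c("m", "f", "m", "m", "f", "f", "m", "f", "m", "m", "f", "f"))
}

# random multigeneration pedigree via the package generator, small enough
# for brute-force checks
smallPedigree <- function(seed = 1, founders = 14, gens = 4, sibship = 2.5) {
  simulatePedigree(simConfig(seed = seed, nFoundersPerGen = founders,
                             nGenerations = gens, meanSibship = sibship))
}

# dense multivariate-normal log-density, the brute-force likelihood oracle
denseMvnLoglik <- function(y, mu, Sigma) {
  n <- length(y)
  L <- chol(Sigma)
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# design + trait shorthand for a simulated cohort
simulatedCase <- function(cfg, bivariate = FALSE, withQtl = FALSE) {
  ped <- simulatePedigree(cfg)
  G <- twoPhi(kinship(ped))
  gd <- if (withQtl) geneDrop(ped, cfg) else NULL
  ph <- simulateTraits(ped, G, cfg,
                       qtlDosage = if (withQtl) gd$truth$dosage else NULL,
                       bivariate = bivariate)
  list(ped = ped, G = G, gd = gd, ph = ph)
}
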