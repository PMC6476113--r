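---
title: "Variance-component models for quantitative traits in extended pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component models for quantitative traits in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedQTL)
```

# The problem

Large multigenerational pedigrees — cohorts in which essentially every
participant is connected to every other through genealogy — are among the
most informative designs for dissecting the genetics of quantitative traits.
pedQTL implements the classical variance-component analysis stack for such
cohorts:

1. **Heritability**: how much trait variance is attributable to additive
   genetic effects;
2. **Pleiotropy**: whether two traits share genetic influences, through the
   bivariate genetic correlation;
3. **Linkage**: where in the genome a quantitative trait locus (QTL) lies,
   through a multipoint variance-component scan over identity-by-descent
   (IBD) sharing;
4. **Measured-genotype association**: which SNPs inside the linkage region
   associate with the trait, tested inside the pedigree model so that
   relatedness cannot masquerade as association.

A gene-dropping simulator generates pedigrees, genotypes, exact IBD tracks
and traits with known architecture, so every claim the package makes can be
validated against truth without access to any cohort data.

# Models

## Univariate polygenic model

For a trait vector $y$ over $n$ pedigree members with covariate design $X$,

$$y \sim N(X\beta,\ \Omega), \qquad
  \Omega = 2\Phi\,\sigma_a^2 + I_n\,\sigma_e^2,$$

where $\Phi$ is the pedigree kinship matrix ($\phi_{ij}$ is the probability
that one allele drawn from $i$ and one from $j$ are identical by descent),
$\sigma_a^2$ the additive genetic variance and $\sigma_e^2$ the
individual-specific environmental variance. Narrow-sense heritability is
$h^2 = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$.

Kinship is computed by the standard parents-first recursion (founders
$\phi_{ii} = 1/2$, $\phi_{ij}=\tfrac12[\phi_{fj}+\phi_{mj}]$,
$\phi_{ii}=\tfrac12[1+\phi_{fm}]$), evaluated in Kahn topological order so
deep pedigrees cannot exhaust the call stack. A Monte-Carlo gene-dropping
estimator (`kinshipMC`) serves as an independent oracle in the test suite.

Fitting is by maximum likelihood (ML, the convention of the variance-
component packages this field uses; note ML variance estimates carry a
slight downward bias at small $n$). One eigendecomposition
$2\Phi = U D U'$ reduces every likelihood evaluation to $O(np)$:
in the rotated basis $\Omega$ is diagonal with entries
$\sigma_a^2 d_i + \sigma_e^2$. The optimiser works on
$(h^2, \log\sigma_p^2) \in [0,1]\times\mathbb R$ with $\beta$ profiled out
by generalised least squares at every step (exact given the variances),
bounded quasi-Newton (L-BFGS-B), three starts $h^2_0 \in \{0.05, 0.3, 0.7\}$
and a log-likelihood tolerance of about $10^{-9}$. The standard error of
$h^2$ comes from the observed information (central differences, step
$10^{-4}$) and is reported as `NA` on the boundary.

Because $h^2 = 0$ lies on the boundary of the parameter space, the null
test uses the $\tfrac12\chi^2_0 : \tfrac12\chi^2_1$ mixture:
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$, so a zero statistic gives
$p = 0.5$.

## Covariates and trait preparation

All models share one covariate design: intercept, age, age$^2$, sex
(0 = male, 1 = female), age$\times$sex, age$^2\times$sex, BMI, and
optionally serum storage days (glycation of stored serum proteins drifts
with storage time, so assay-based traits adjust for it). Age is
mean-centred before squaring and interacting — coefficients are reported on
the centred scale — and columns that are constant or collinear within the
analysed sample (e.g. the sex columns in a single-sex subset) are dropped by
pivoted QR so the design keeps full rank. Individuals missing the trait or
any covariate are excluded (complete case).

Traits that depart from normality can be transformed with the rank-based
inverse normal transform before fitting (Blom scores,
$\Phi^{-1}[(r - 3/8)/(n + 1/4)]$, average ranks for ties); the transform is
applied to the raw trait before covariate adjustment. Which traits to
transform is left to the analyst as a per-trait flag, since distributional
diagnostics are data-dependent. For glycated serum protein work the package
also provides the assay conversion
$\%GA = (GSP \times 0.182 + 1.97)/(\text{albumin} + 2.9)$ with a warning
outside the assay's linear range (21–1354 µmol/L).

## Bivariate model and pleiotropy

Two traits $A$ and $B$ are modelled jointly with within-trait covariance as
above and cross-trait covariance
$2\Phi\,\rho_g\sigma_{aA}\sigma_{aB} + I\,\rho_e\sigma_{eA}\sigma_{eB}$.
The phenotypic correlation obeys the identity

$$\rho_p = \rho_g\sqrt{h_A^2 h_B^2} + \rho_e\sqrt{(1-h_A^2)(1-h_B^2)},$$

which the fitted object satisfies exactly by construction. In the
eigenbasis of $2\Phi$ the $2n \times 2n$ covariance factors into one
$2\times2$ block per eigenvalue, so each evaluation is $O(n)$ after one
decomposition. The optimiser works on
$(h_A^2, h_B^2, \rho_g, \rho_e, \log\sigma_A^2, \log\sigma_B^2)$ with
$|\rho_g| \le 1$ permitted (the boundary is *complete pleiotropy*) and
$|\rho_e| \le 0.995$ (an exactly singular environmental block has
likelihood $-\infty$ anyway; the bound only protects the optimiser).
$\rho_g = 0$ (no pleiotropy) is tested by a likelihood-ratio test against
$\chi^2_1$ — an interior null — switching to the half-mixture only when the
estimate sits on the boundary. Individuals missing either trait are
dropped (complete pairs), a deliberately stricter contract than software
that retains half-informative singletons.

## Multipoint linkage

At a genomic position with pairwise expected IBD-sharing matrix $\hat\Pi$
(diagonal 1 for non-inbred individuals), the QTL model adds a
locus-specific component:

$$\Omega = \hat\Pi\,\sigma_q^2 + 2\Phi\,\sigma_a^2 + I\,\sigma_e^2, \qquad
  \mathrm{LOD} = \frac{\ell_{QTL} - \ell_{poly}}{\ln 10}.$$

$\hat\Pi$ varies per locus, so no single decomposition serves the scan;
each evaluation performs one Cholesky factorisation, with $\beta$ (GLS) and
the total variance ($\mathrm{rss}/n$) profiled out in closed form. The
remaining two variance shares are optimised on the simplex via the smooth
reparameterisation $(\sigma_q^2, \sigma_a^2)/\sigma_p^2 =
(u_1, (1-u_1)u_2)$, with an analytic gradient (trace and quadratic-form
terms computed from the same factorisation). Scans warm-start each locus
from its neighbour's solution; deep in the null region (both the warm start
and its solution at the $\sigma_q^2=0$ boundary) the fallback start is
skipped, since the boundary solution *is* the polygenic fit there. When
$\hat\Pi$ is numerically indistinguishable from $2\Phi$ the two genetic
components are structurally confounded; the locus is flagged and its LOD
defined as 0.

Peaks are classified against the conventional fixed thresholds —
significant at LOD $\ge 3.0$, suggestive at $2.0 \le$ LOD $< 3.0$ — with
ties broken toward the lowest cM. The 1-LOD support interval (an
approximate 95% confidence region for QTL location) is the maximal
contiguous run of grid positions around the peak with LOD $\ge$ peak $- 1$;
base-pair bounds are read off the grid's bp coordinates, interpolating
linearly in cM only where an endpoint lacks a bp coordinate. With a peak at
LOD $\le 1$ the interval is undefined and the whole chromosome is returned
with a warning.

The polygenic background retains the pedigree $2\Phi$ at every locus.
(Genotype-derived "empirical" kinship estimators exist, but their exact
construction varies by software; using pedigree kinship throughout is a
documented limitation, not an option toggle.)

## Measured-genotype association

Within a QTL's 1-LOD interval, each SNP's minor-allele dosage (0/1/2) is
appended to the covariate design and the full model — variance components
included — is refitted by ML. The SNP effect $\beta$ is its GLS coefficient
at the ML variances; its p-value is the likelihood-ratio test against
$\chi^2_1$ (the SNP effect is an interior parameter). A fast approximation
that fixes the variance components at the no-SNP fit was considered and
rejected as a default: re-estimation is the classical measured-genotype
likelihood and the per-SNP cost is tamed by sharing the eigendecomposition
across SNPs whenever no dosages are missing.

Before testing, tables pass two filters matching standard practice:
autosomal SNPs only with a per-person call rate of at least 95%
(inclusive), then a minimum of 5 observed minor-allele copies per SNP.
Filters recompute minor-allele orientation and counts, so applying them
twice changes nothing. Multiple testing uses Bonferroni over the SNPs
actually tested in the interval — deliberately the only correction offered.
Variance explained is reported as $100\cdot2\,\mathrm{maf}(1-\mathrm{maf})
\beta^2/\sigma^2$ (additive Hardy–Weinberg approximation) against the
covariate-adjusted trait variance $\sigma^2 = \hat\sigma_a^2 +
\hat\sigma_e^2$ of the no-SNP model; published analyses rarely state their
variance basis, so ours is documented here.

# The synthetic cohort generator

`simConfig()` bundles the generator's knobs; its defaults are the study
conditions the package targets, chosen once:

| parameter | default | rationale |
|---|---|---|
| pedigree | 5 generations × 70 first-generation founders, Poisson(3) sibships | yields a single connected pedigree of roughly 1,000 members, the scale of the motivating cohorts |
| sex ratio | 55% female | typical field-cohort composition |
| age | uniform 18–88 years | adult cohort age span |
| BMI | normal(22.3, 3.7²) kg/m² | lean rural-cohort summary statistics |
| storage | uniform 30–1095 days | archived-serum study span |
| trait | $h^2 = 0.16$, unit variance | low-heritability serum biomarker regime |
| QTL | MAF 0.45, 15% of variance, at 25 cM of a 60 cM chromosome | a common variant of realistic effect; one chromosome keeps scans tractable at a 1 cM grid |
| bivariate | $\rho_g = 0.35$, $\rho_e = 0.10$, $h^2 = 0.30$ each | moderate-pleiotropy regime |

Pedigrees are built generation by generation: founder couples, Poisson
sibships, within-generation marriages that avoid siblings and prefer
crossing family branches (keeping the pedigree connected), and immigrant
founder spouses for the rest; members outside the largest connected
component (stray childless first-generation couples) are dropped. Gene
dropping assigns every founder haplotype a unique label and transmits
labels through meioses under the Haldane map (Poisson crossovers, no
interference — adequate at a 1 cM grid); the recorded labels yield *exact*
realised IBD sharing at every grid position, stored compactly and
materialised per locus on demand. Marker SNPs (and the causal variant) are
created by assigning allele states to founder labels at stated
frequencies; several markers may share a grid position with distinct
assignments, giving imperfect LD. Traits are drawn as
$y = X\beta_{cov} + a + q + e$ with $a \sim N(0, 2\Phi\sigma_a^2)$ via the
eigendecomposition, $q$ either $\beta_q \times$ (centred causal dosage)
with $\beta_q = \sqrt{\sigma_q^2/2p(1-p)}$ — so linkage and association
can both detect the same signal — or, behind a flag, a latent
$N(0, \hat\Pi\sigma_q^2)$ effect. Each stage draws from its own seed
stream (master seed + 1/2/3), so adding traits never perturbs the
pedigree or genotypes.

What the generator does **not** emulate: population LD structure and
demography, genotyping error, sex-specific recombination maps, assortative
mating, shared-household environments. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
those real-data complications.

# Numerical and design notes

* **Identifiers** are exact strings; no case folding. Half-known parentage
  is rejected rather than patched with a dummy founder, because silent
  augmentation changes kinship values.
* **Sex** is validated for parents but unused in the kinship recursion
  (autosomal model only).
* **Degenerate inputs**: a trait that is an exact function of the
  covariates drives $\sigma_e^2$ to its floor; the fit is flagged
  `degenerate` with a warning rather than silently returned.
* **IBD sharing above 1**: between autozygous (inbred) pairs the unbiased
  realised-sharing estimate (IBD allele pairs)/2 can exceed 1 (up to 2);
  containers admit $[0,2]$ off-diagonal, $[1,2]$ diagonal.
* **Boundary-test calibration**: the null distribution of the $h^2$ LRT has
  an atom at 0 whose mass is $\tfrac12$ only asymptotically, and the
  finite-sample mass depends on the spectrum of $2\Phi$: designs dominated
  by one large eigenvalue (deep single-branch pedigrees) skew the score and
  make the test *conservative*. The null-calibration acceptance experiment
  therefore uses a broad three-generation, large-sibship pedigree whose
  information spectrum has many moderate eigenvalues; on deep pedigrees
  users should expect conservative (never anti-conservative) $h^2$
  p-values. This is a property of boundary LRTs, not of the implementation —
  the optimiser was audited against grid search under the null.
* **Problem sizes in the tests**: unit tests run on pedigrees of tens of
  members; statistical acceptance checks use the cohort-default (~1,000
  members, 20 trait replicates for recovery; 500 replicates for null
  calibration; 10 simulated cohorts end to end). These sizes give
  Monte-Carlo error comfortably inside the asserted bounds.
* **Ties and determinism**: scan peaks break ties toward the lowest cM;
  all generators are bit-reproducible given (seed, config); pipeline
  outputs are byte-identical across reruns on the same inputs.

# Known limitations

* Pedigree kinship is used for linkage's polygenic background (not
  genotype-based empirical kinship); with pedigree errors the LOD scores
  inherit the misspecification.
* No dominance, household, or threshold (binary-trait) models.
* Bivariate fits drop individuals observed for only one trait.
* Genome-wide empirical LOD thresholds by gene-dropping null scans are not
  implemented; classification uses the fixed 3.0/2.0 conventions.
* The measured-genotype model is additive (1 df); genotypic 2-df models are
  out of scope.

# A worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
ped <- simulatePedigree(cfg)
gd  <- geneDrop(ped, cfg)
ph  <- simulateTraits(ped, twoPhi(kinship(ped)), cfg,
                      qtlDosage = gd$truth$dosage)
res <- runPipeline(ped, ph, traits = "trait",
                   genotypes = gd$genotypes, mibd = gd$tracks)
res$heritability$trait       # PolygenicFit: h2, SE, boundary-mixture p
res$linkage$peak             # peak LOD and position
res$linkage$interval         # 1-LOD support interval
head(res$association)        # per-SNP beta, LRT p, variance explained
```

The README shows this run with the numbers it prints; the same analysis
(plus oracle comparisons and null calibration) is recomputed from scratch
by `scripts/acceptance.R`.
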