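---
title: "Methods: steepness algorithms, effect sizes, and the phylogenetic multilevel model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steepness algorithms, effect sizes, and the phylogenetic multilevel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodological literature leaves the choice open.
It states no empirical result that the test suite does not itself compute.

## 1. The scientific question

In group-living animals the dominance hierarchy can be *steep* (cardinal
scores fall quickly with rank; despotic) or *shallow* (egalitarian). A
natural comparative hypothesis is that steeper hierarchies should translate
rank more strongly into fitness-related benefits — fecundity, infant
survival, mating success, feeding success. The pipeline operationalizes the
question as a meta-regression: each group contributes an effect size (the
correlation between individual benefit and individual rank, Fisher-Z
transformed) and a steepness value; steepness is the predictor of interest,
with seven control moderators and a three-level random structure (species,
group-in-species, phylogeny).

## 2. Steepness from a sociomatrix

The raw datum is a square count matrix, winners in rows. All four
algorithms reduce it to a slope-like quantity on [0, 1]; they differ in how
they handle sparse data and what uncertainty they attach.

**NormDS (NDS_Dij).** The dyadic index `Dij = Pij - (Pij - 1/2)/(nij + 1)`
shrinks each observed win proportion toward chance by one pseudo-bout, so a
2–0 dyad (Dij = 5/6) is distinguished from a 20–0 dyad (Dij ≈ 0.976).
*Unknown dyads* (`nij = 0`): we set `Dij = Dji = 1/2`, the chance-level
limit of the correction. This choice preserves `Dij + Dji = 1` for every
dyad and hence the identities `sum(DS) = 0` and `mean(NormDS) = (N-1)/2`
that the test suite asserts. How the original implementation treats unknown
dyads is not documented; our convention is stated, not claimed
bit-compatible. Steepness is the absolute OLS slope of sorted NormDS on
ranks 1..N, clamped to [0, 1] (clamping only ever corrects floating-point
overshoot: on the NormDS scale a perfect hierarchy has slope exactly −1).

**Randomization test.** The null keeps every dyad's `nij` fixed and redraws
wins as `Binomial(nij, 1/2)` (default 2000 replicates): "is the hierarchy
steeper than chance, given the observed interaction structure?" The p-value
uses the add-one continuity correction, so it is never exactly 0.

**Elo repeatability (Elo_rpt).** Undated matrices do not identify an
interaction order, so the Elo trajectory is averaged over random orderings
(default 1000). Elo defaults are the classical chess constants (start 1000,
k = 100, logistic width 400); they are configurable, and cross-package
numerical agreement with other Elo implementations is not claimed — the
ICC is scale-free, which is why the constants matter little. Steepness is
ICC(1) across orderings, truncated to [0, 1] (a negative ICC means
"less repeatable than noise", which the steepness scale cannot express).

**Bayesian surrogate (Elo_Bayes, DS_Bayes).** The model is
`s_ij ~ Binomial(n_ij, logistic(a_i - a_j))` with iid N(0, 1) priors on the
latent strengths. We deliberately use a component-wise random-walk
Metropolis sampler (default 4 chains × 2500 kept draws after 1000 burn-in,
proposal SD 0.5) rather than an HMC backend: at sociomatrix scale
(N ≤ a few dozen) it mixes adequately, is dependency-free, and reproduces
the defining outputs — a posterior distribution of steepness with a central
95% credible interval. Draws are mean-centered per iteration, fixing the
translation invariance of the likelihood. Split-chain R-hat > 1.1 raises a
warning, never an error. This surrogate is explicitly *not* numerically
interchangeable with the published HMC implementation it stands in for.

**An identity worth knowing.** With `Dij := logistic(a_i - a_j)` every
dyad satisfies `Dij + Dji = 1` exactly, and David's score collapses
algebraically: `DS_i = N * w_i + const`, so NormDS equals the cumulative
winning probability `w_i = CWP_i`. The DS-flavored and Elo-flavored
posterior steepness are therefore the *same* estimator under this
surrogate, and the pipeline's DS_Bayes and Elo_Bayes rows coincide. With
count-weighted dyadic corrections (as in the raw-data NormDS) the identity
breaks, which is why the distinction is real for the non-Bayesian methods.
We keep both labels because the 8-model report structure treats them as
separate methods.

**Linearity.** The modified Landau index resolves dyads by majority wins,
completes tied/unknown dyads uniformly at random (1000 completions, h' =
mean h), and compares h' to the h distribution of fully random tournaments
(10000 draws, right tail, add-one correction). `is_linear` uses α = 0.05;
the α and the two-step scheme are conventional defaults, the source
literature names the procedure but not its settings.

## 3. Effect sizes

Correlations with |r| = 1 (perfect toy hierarchies produce them) are
winsorized to 1 − 1e−6 with a warning instead of being excluded, so they
survive `atanh`. Ordinal ranks run 1 = top, so the ordinal-basis
correlation is sign-flipped centrally in one function: positive always
means "dominants gain more". Chi-square statistics convert by
`r = ±sqrt(chi2/n)` (the direction is not recoverable from chi-square and
must be supplied); mean±SD pairs via pooled-SD Cohen's d and
`r = d/sqrt(d^2 + a)`, `a = (n1+n2)^2/(n1 n2)`. Literature Spearman
coefficients enter the Fisher pipeline unchanged. Sampling variance is
`1/(n-3)`; groups under 4 individuals are excluded with a logged reason.
Multiple benefit measures in one study period average on the r scale before
transformation; multiple matrices average on the steepness scale.

## 4. The multilevel meta-regression

The model for record *i* in group *g*, species *s* is

    Z_i = x_i' beta + u_s + u_g + u_phylo(s) + e_i,
    u_s ~ N(0, s2_species), u_g ~ N(0, s2_group),
    u_phylo ~ N(0, s2_phylo * A), e_i ~ N(0, v_i) with v_i known,

`A` being the phylogenetic correlation matrix (shared-depth fractions of a
Grafen-calibrated ultrametric tree, ρ = 1 by default). Known `v_i` is what
makes this a meta-analysis: each observation is inverse-variance weighted.

Numerical choices:

* Variance components are maximized on the log scale by L-BFGS-B with
  analytic gradients and five fixed starting points (spanning 1e−4 to 0.1
  and lopsided corners); multi-start guards against the flat ridges this
  likelihood can have when components trade off. The reported optimum is
  additionally required (in the test suite) to dominate a 10×10×10 grid.
* `beta` is profiled out (GLS at the current V), which the envelope theorem
  makes gradient-exact for ML.
* Model comparison across fixed-effect structures uses **ML** likelihoods;
  REML likelihoods are not comparable when X changes, so REML is offered
  only for variance reporting. Degrees of freedom are reported as fixed
  parameters + 3 variance components (full model: 13 + 3 = 16; control:
  12 + 3 = 15), matching the convention of the analyses this mirrors.
* Coding: continuous predictors standardized; categorical predictors
  dummy-coded with the reference level dropped and the retained dummies
  mean-centered (full coding with an intercept is rank-deficient; centering
  keeps the intercept the overall mean and tames interaction collinearity).
  Rank deficiency is an error that names the aliased columns — with few
  species, species-level factors can genuinely alias.
* Q_M is the Wald chi-square over all non-intercept coefficients; Q_E is
  the weighted residual sum of squares of the fixed-effects-only WLS fit,
  df = k − p.
* Phylogenetic signal is the variance share
  `s2_phylo / (s2_species + s2_group + s2_phylo)` (0 when the denominator
  is 0) — a Pagel's-λ analogue for this multilevel setting; its exact
  correspondence to other λ definitions is not asserted. The LRT against
  `s2_phylo = 0` uses a plain χ²(1) reference by default; the 50:50
  boundary mixture is available by flag (the plain reference is the more
  conservative and matches the near-1 p-values such models typically
  print when the signal is absent).
* The LRT between *identical* designs returns χ² = 0 with p = 1 by
  convention.
* Study ID is not a random factor (many studies contribute a single
  record); group and species are, plus the phylogenetic term.

Publication-bias checks run on the published subset only: a meta-regression
of Z on standardized `sqrt(1/n)` (small-study effect) or standardized
publication year (time-lag effect), same random structure, moderator
z-test.

## 5. The synthetic world

The generator is a stated world, not a tuning dial:

* Species tree: Yule (birth 1, no extinction), rescaled to depth 1.
* Abilities in a group of N sit on an equally spaced grid with adjacent gap
  δ, and δ varies across groups as Uniform(0, δ_max), δ_max = 2.5 by
  default — spanning effectively egalitarian (δ = 0 → all win probabilities
  1/2) to near-despotic (δ ≥ 2 → adjacent win probability > 0.88). The
  spread exists so the meta-regression has a real predictor gradient.
* Dyadic interaction counts are Poisson(μ), μ = 10 by default — a
  moderately observed wild group; wins are Binomial with logistic
  probabilities.
* The latent effect of a record is
  `Z = mu_z + beta_steep * steep_std(g) + u_s + u_g + u_phylo`, where
  `steep_std` is the **standardized** NormDS steepness computed from the
  group's *realized* matrix. Two deliberate choices here: (i) using the
  realized (estimated) steepness, and benefits drawn against true
  abilities, keeps estimation noise in both the predictor and the response
  — recovery tests then test the pipeline, not an idealization; (ii)
  `beta_steep` is on the standardized-predictor scale, i.e. the same scale
  the fitted model reports, so "bias of beta-hat" is well defined without a
  scale conversion. (A centered-but-unscaled convention would make the
  recoverable coefficient `beta * sd(steepness)` ≈ 0.06 for beta = 0.3 —
  too small to detect at the stated design sizes, which is how we know the
  standardized reading is the coherent one.)
* Benefits are bivariate-normal with the standardized ability scores at
  correlation `tanh(Z)`; moderators are sampled independently of everything
  (they are pure controls in the generator: their true coefficients are 0).
* The truth ledger stores every latent draw; a test reconstructs each
  record's Z from the ledger exactly.

What the generator does **not** emulate — so a green test does not
establish robustness to it: observation-effort bias (μ independent of group
properties), temporal hierarchy dynamics, non-normal benefit distributions,
moderators correlated with steepness or with each other, unequal group
sizes within a dataset, and digitization error in literature-derived
values.

## 6. Configuration and interfaces

Pipeline settings travel as JSON (blocks `elo:`, `bayes:`, `linearity:`,
`meta:`, `simulate:`) rather than YAML — the offline dependency set has a
JSON parser but no YAML parser, and the structure is identical. The
pipeline defaults are desk-scale (200 Elo randomizations, 2 × 1000 MCMC
draws) so a full 8-model analysis of a ~30-group dataset runs in about a
minute; per-matrix module defaults are the larger values quoted above.
All pipeline randomness derives from one master seed; per-group seeds are
fixed offsets of it, so reports are byte-identical under a repeated run.

## 7. Known limitations

* The Bayesian surrogate's credible intervals inherit random-walk
  Metropolis autocorrelation; at default settings the effective sample size
  is far below the nominal 10000 draws. For N > ~30 individuals, expect to
  raise iterations.
* ML variance components are slightly biased downward at small species
  counts (use REML for reporting when that matters).
* The LRT χ²(1) reference is asymptotic. For the steepness-only model it
  is well calibrated by k ≈ 60 records, but for the full 13-parameter model
  the ML-based test is anticonservative at desk scale (we measure ≈ 14%
  rejection at nominal 5% with k = 60 and ≈ 8% at k = 160, decaying as the
  species count grows). Borderline full-model LRT p-values near 0.05 at
  modest k should therefore be read cautiously; the simple
  (steepness-only) models provide the better-calibrated companion test.
* Landau's h randomization treats dyads as exchangeable; it does not model
  observation effort differences between dyads.
* Pre-computed (non-recomputable) records bypass the steepness and
  linearity machinery entirely and trust their supplied statistics and
  `linear` flag.
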