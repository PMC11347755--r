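# shared small synthetic meta dataset (effect level: z_r drawn directly)
meta_ds <- simulate_dataset(sim_config(S = 10, groups_per_species = 2,
                                       records_per_group = 2, n = 30,
                                       beta_steep = 0.3, seed = 1234),
                            level = "effect")

test_that("build_design produces the documented column structure", {
  d_full <- build_design(meta_ds$records, full_predictors)
  expect_equal(d_full$p, 13)
  d_ctrl <- build_design(meta_ds$records, full_predictors[-1])
  expect_equal(d_ctrl$p, 12)
  # centered dummies sum to zero; continuous columns standardized
  sums <- colSums(d_full$X[, -1])
  expect_equal(unname(sums), rep(0, 12), tolerance = 1e-9)
  expect_equal(sd(d_full$X[, "steepness"]), 1, tolerance = 1e-9)

  dup <- meta_ds$records
  dup$steep2 <- dup$steepness
  expect_error(build_design(dup, c("steepness", "steep2")),
               "aliased.*steep2")
  one_level <- meta_ds$records
  one_level$setting <- "wild"
  expect_error(build_design(one_level, "setting"), "single observed level")
})

test_that("with all variances pinned at 0 the fit is the inverse-variance
           pooled estimate and GLS equals OLS under equal v", {
  rec <- data.frame(record_id = c("a", "b"), group = c("g1", "g2"),
                    species = c("s1", "s2"), z_r = c(0, 1), v = c(1, 1))
  A <- diag(2); dimnames(A) <- list(c("s1", "s2"), c("s1", "s2"))
  f <- meta_fit(build_design(rec), A, "ML",
                fix_zero = c("species", "group", "phylo"))
  expect_equal(unname(f$beta), 0.5)

  set.seed(2)
  rec2 <- meta_ds$records
  rec2$v <- 0.05
  d2 <- build_design(rec2, full_predictors)
  f2 <- meta_fit(d2, meta_ds$A, "ML",
                 fix_zero = c("species", "group", "phylo"))
  ols <- qr.coef(qr(d2$X), d2$y)
  expect_equal(unname(f2$beta), unname(ols), tolerance = 1e-10)
})

test_that("profiled likelihood equals the dense MVN density (k <= 20)", {
  small <- simulate_dataset(sim_config(S = 5, groups_per_species = 2,
                                       records_per_group = 2, n = 20,
                                       seed = 77), level = "effect")
  d <- build_design(small$records, c("steepness", "benefit_category"))
  for (sig in list(c(0.1, 0.05, 0.1), c(0, 0, 0), c(0.3, 0.001, 0.02))) {
    parts <- steeprank:::meta_loglik_parts(
      sig, d, steeprank:::meta_components(d, small$A))
    for (method in c("ML", "REML")) {
      expect_equal(steeprank:::meta_ll_value(parts, d, method),
                   dense_mvn_ll(sig, d, small$A, method), tolerance = 1e-8)
    }
  }
})

test_that("the optimizer's maximum dominates a 10x10x10 variance grid", {
  d <- build_design(meta_ds$records, full_predictors)
  comps <- steeprank:::meta_components(d, meta_ds$A)
  fit <- meta_fit(d, meta_ds$A, "ML")
  grid <- exp(seq(log(1e-4), log(1), length.out = 10))
  best_grid <- -Inf
  for (s1 in grid) for (s2 in grid) for (s3 in grid) {
    parts <- steeprank:::meta_loglik_parts(c(s1, s2, s3), d, comps)
    ll <- steeprank:::meta_ll_value(parts, d, "ML")
    if (ll > best_grid) best_grid <- ll
  }
  expect_gte(fit$loglik + 1e-6, best_grid)
})

test_that("REML and ML agree on beta at fixed variance components", {
  d <- build_design(meta_ds$records, full_predictors)
  comps <- steeprank:::meta_components(d, meta_ds$A)
  parts <- steeprank:::meta_loglik_parts(c(0.08, 0.03, 0.05), d, comps)
  # beta is the same GLS functional regardless of likelihood flavor
  V <- parts$V
  beta_direct <- solve(t(d$X) %*% solve(V, d$X), t(d$X) %*% solve(V, d$y))
  expect_equal(parts$beta, unname(drop(beta_direct)), tolerance = 1e-10)
})

test_that("fit outputs are invariant to record order and LRT to shifts", {
  d <- build_design(meta_ds$records, full_predictors)
  f <- meta_fit(d, meta_ds$A, "ML")
  perm <- sample(nrow(meta_ds$records))
  dp <- build_design(meta_ds$records[perm, ], full_predictors)
  fp <- meta_fit(dp, meta_ds$A, "ML")
  expect_equal(f$loglik, fp$loglik, tolerance = 1e-6)
  expect_equal(f$beta, fp$beta, tolerance = 1e-5)
  expect_equal(f$sigma2, fp$sigma2, tolerance = 1e-4)

  ctrl <- meta_fit(build_design(meta_ds$records, full_predictors[-1]),
                   meta_ds$A, "ML")
  t1 <- lrt(f, ctrl)
  shifted <- meta_ds$records
  shifted$z_r <- shifted$z_r + 5
  f_s <- meta_fit(build_design(shifted, full_predictors), meta_ds$A, "ML")
  c_s <- meta_fit(build_design(shifted, full_predictors[-1]), meta_ds$A,
                  "ML")
  expect_equal(lrt(f_s, c_s)$chi2, t1$chi2, tolerance = 1e-4)
  expect_equal(lrt(f, f)$chi2, 0)
  expect_equal(lrt(f, f)$p_value, 1)
  expect_error(lrt(meta_fit(d, meta_ds$A, "REML"), ctrl), "ML")
})

test_that("omnibus Q_M reduces to the 1-df Wald identity", {
  d <- build_design(meta_ds$records, "steepness")
  f <- meta_fit(d, meta_ds$A, "ML")
  expect_equal(f$qm$statistic,
               unname((f$beta["steepness"] / f$se["steepness"])^2),
               tolerance = 1e-9)
  expect_equal(f$qm$df, 1)
  d0 <- build_design(meta_ds$records)
  expect_error(omnibus_qm(meta_fit(d0, meta_ds$A, "ML")), "intercept-only")
})

test_that("Q_E is zero on exact fits, chi-square-like under homogeneity,
           and inflated under heterogeneity", {
  rec <- meta_ds$records[1:10, ]
  rec$z_r <- 0.4  # constant response, intercept-only design fits exactly
  expect_equal(qe_test(build_design(rec))$statistic, 0, tolerance = 1e-12)

  set.seed(5)
  qe_null <- qe_het <- numeric(120)
  for (i in 1:120) {
    k <- 20; v <- rep(1 / 27, k)
    rec_i <- data.frame(record_id = paste0("r", 1:k),
                        group = paste0("g", 1:k),
                        species = paste0("s", 1:k),
                        z_r = rnorm(k, 0.2, sqrt(v)), v = v)
    qe_null[i] <- qe_test(build_design(rec_i))$statistic
    rec_i$z_r <- rec_i$z_r + rnorm(k, 0, sqrt(0.1))
    qe_het[i] <- qe_test(build_design(rec_i))$statistic
  }
  expect_equal(mean(qe_null), 19, tolerance = 0.15)  # k - p = 19
  expect_gt(mean(qe_het), mean(qe_null))
})

test_that("phylogenetic signal recovers dominant and absent tree variance", {
  set.seed(6)
  lam_null <- lam_strong <- numeric(12)
  p_null <- numeric(12)
  for (i in 1:12) {
    ds0 <- simulate_dataset(sim_config(S = 12, groups_per_species = 2,
                                       records_per_group = 2, n = 30,
                                       sigma2 = c(0.10, 0.05, 0),
                                       seed = 4000 + i), level = "effect")
    s0 <- phylo_signal(build_design(ds0$records, "steepness"), ds0$A)
    lam_null[i] <- s0$lambda
    p_null[i] <- s0$p_value
    ds1 <- simulate_dataset(sim_config(S = 12, groups_per_species = 2,
                                       records_per_group = 2, n = 30,
                                       sigma2 = c(0.03, 0.03, 0.30),
                                       seed = 5000 + i), level = "effect")
    s1 <- phylo_signal(build_design(ds1$records, "steepness"), ds1$A)
    lam_strong[i] <- s1$lambda
  }
  expect_lt(median(lam_null), 0.2)
  expect_gt(mean(p_null > 0.2), 0.5)
  expect_gt(mean(lam_strong > 0.5), 0.5)
  # all-zero-variance convention
  rec <- meta_ds$records[1:8, ]
  d <- build_design(rec)
  f0 <- meta_fit(d, meta_ds$A, "ML", fix_zero = c("species", "group",
                                                  "phylo"))
  tot <- sum(f0$sigma2)
  expect_equal(if (tot > 0) f0$sigma2[["phylo"]] / tot else 0, 0)
})

test_that("bias regressions detect engineered small-study effects", {
  set.seed(9)
  base <- simulate_dataset(sim_config(S = 12, groups_per_species = 2,
                                      records_per_group = 2, n = 30,
                                      seed = 808), level = "effect")
  rec <- base$records
  rec$origin <- "published"
  rec$pub_year <- sample(1990:2020, nrow(rec), replace = TRUE)
  rec$n <- sample(c(5, 10, 20, 40, 80), nrow(rec), replace = TRUE)
  rec$v <- 1 / (rec$n - 3)
  # effect shrinks with n: true r proportional to 1/sqrt(n)
  rec$z_r <- atanh(pmin(0.9, 3 / sqrt(rec$n))) + rnorm(nrow(rec), 0,
                                                       sqrt(rec$v))
  ss <- small_study_test(rec, base$A)
  expect_gt(ss$z, 1.96)

  rec$pub_year <- 2000
  expect_error(time_lag_test(rec, base$A), "constant")
  none <- rec; none$origin <- "unpublished"
  expect_error(small_study_test(none, base$A), "no published")
})

test_that("Q_M p-values are roughly uniform under the null", {
  set.seed(11)
  pvals <- numeric(150)
  for (i in 1:150) {
    k <- 25
    rec <- data.frame(record_id = paste0("r", 1:k),
                      group = paste0("g", 1:k),
                      species = paste0("s", 1:k),
                      z_r = rnorm(k, 0.2, sqrt(1 / 27 + 0.05)),
                      v = rep(1 / 27, k),
                      steepness = runif(k))
    A <- diag(k); dimnames(A) <- list(rec$species, rec$species)
    f <- meta_fit(build_design(rec, "steepness"), A, "ML",
                  fix_zero = c("group", "phylo"))
    pvals[i] <- f$qm$p_value
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
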