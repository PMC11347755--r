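test_that("dyadic dominance indices match the correction formula", {
  s <- rbind(A = c(0, 3), B = c(1, 0))
  colnames(s) <- c("A", "B")
  d <- dyadic_dominance_index(validate_matrix(s))
  expect_equal(d["A", "B"], 0.75 - 0.25 / 5)  # 0.70
  s2 <- rbind(A = c(0, 2), B = c(0, 0))
  colnames(s2) <- c("A", "B")
  d2 <- dyadic_dominance_index(validate_matrix(s2))
  expect_equal(d2["A", "B"], 5 / 6)
  s0 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  d0 <- dyadic_dominance_index(validate_matrix(s0))
  expect_equal(d0["A", "B"], 0.5)
  expect_equal(d0["B", "A"], 0.5)
})

test_that("David's scores reproduce the worked 3-individual example", {
  ds <- davids_scores(worked_example_matrix())
  expect_equal(ds$ds, c(2, 0, -2))
  expect_equal(ds$score, c(5 / 3, 1, 1 / 3))
  st <- steepness_from_scores(ds)
  expect_equal(st$estimate, 2 / 3, tolerance = 1e-12)
  expect_equal(ordinal_from_cardinal(ds)$rank, c(1, 2, 3))
})

test_that("Dij/DS/NormDS invariants hold on random matrices", {
  for (seed in 1:25) {
    m <- random_sociomatrix(sample(3:9, 1), seed = seed)
    n <- nrow(m)
    d <- dyadic_dominance_index(m)
    off <- upper.tri(d)
    expect_equal(d[off] + t(d)[off], rep(1, sum(off)))
    expect_true(all(d >= 0 & d <= 1))
    ds <- davids_scores(m)
    expect_equal(sum(ds$ds), 0, tolerance = 1e-10)
    expect_equal(mean(ds$score), (n - 1) / 2, tolerance = 1e-10)
  }
})

test_that("David's scores match the naive quadruple-loop oracle (N <= 5)", {
  for (seed in 1:20) {
    m <- random_sociomatrix(sample(3:5, 1), mu = 4, seed = 100 + seed)
    oracle <- naive_davids(m)
    got <- davids_scores(m)
    expect_equal(got$ds, oracle$ds, tolerance = 1e-12)
    expect_equal(got$score, oracle$norm_ds, tolerance = 1e-12)
  }
})

test_that("symmetric matrices give flat scores and zero steepness", {
  s <- matrix(3, 4, 4); diag(s) <- 0
  dimnames(s) <- list(paste0("i", 1:4), paste0("i", 1:4))
  ds <- davids_scores(validate_matrix(s))
  expect_equal(ds$ds, rep(0, 4))
  expect_equal(steepness_from_scores(ds)$estimate, 0)
})

test_that("steepness converges to 1 for perfect hierarchies and is invariant
           to relabelling", {
  m <- linear_matrix(8, n_ij = 50)
  expect_gte(steepness_from_scores(davids_scores(m))$estimate, 0.95)
  m2 <- random_sociomatrix(6, seed = 42)
  perm <- sample(6)
  m2p <- validate_matrix(unclass(m2)[perm, perm])
  expect_equal(steepness_from_scores(davids_scores(m2))$estimate,
               steepness_from_scores(davids_scores(m2p))$estimate,
               tolerance = 1e-12)
})

test_that("expected steepness increases with latent ability dispersion", {
  set.seed(99)
  deltas <- c(0, 0.5, 1, 2, 4)
  mean_st <- sapply(deltas, function(d) {
    mean(replicate(8, {
      m <- simulate_matrix(7, d, 12)
      steepness_from_scores(davids_scores(m))$estimate
    }))
  })
  expect_gt(cor(deltas, mean_st, method = "spearman"), 0)
})

test_that("ordinal ranks break ties by id order and ignore input order", {
  cr <- cardinal_ranks(c("A", "B", "C"), c(1, 1, 1), "NDS_Dij")
  expect_equal(ordinal_from_cardinal(cr)$rank, 1:3)
  cr2 <- cardinal_ranks(c("C", "A", "B"), c(0.2, 0.9, 0.5), "NDS_Dij")
  ord <- ordinal_from_cardinal(cr2)
  expect_equal(ord$rank[ord$id == "A"], 1L)
  expect_equal(ord$rank[ord$id == "C"], 3L)
})

test_that("landau_h is 1 for strict orders, 0 for the 3-cycle, and rejects
           unresolved dyads", {
  lin <- matrix(0, 3, 3); lin[upper.tri(lin)] <- 1
  expect_equal(landau_h(lin), 1)
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(landau_h(cyc), 0)
  lin5 <- matrix(0, 5, 5); lin5[upper.tri(lin5)] <- 1
  expect_equal(landau_h(lin5), 1)
  tied <- lin5; tied[1, 5] <- 0; tied[5, 1] <- 1  # bottom beats top: cycle
  expect_lt(landau_h(tied), 1)
  unresolved <- lin; unresolved[1, 2] <- 0
  expect_error(landau_h(unresolved), "unresolved")
})

test_that("linearity_test separates linear from unknown-heavy matrices", {
  lt <- linearity_test(linear_matrix(6, 10), rand_unknown = 100,
                       rand_null = 2000, seed = 1)
  expect_equal(lt$h_prime, 1)
  expect_lt(lt$p_value, 0.05)
  expect_true(lt$is_linear)

  empty <- validate_matrix(matrix(0, 6, 6,
    dimnames = list(paste0("i", 1:6), paste0("i", 1:6))))
  lt0 <- linearity_test(empty, rand_unknown = 300, rand_null = 1000,
                        seed = 2)
  expect_equal(lt0$n_unknown, 15)
  expect_gt(lt0$p_value, 0.1)  # indistinguishable from random tournaments

  # N = 3, one unknown dyad, others linear: completions are one linear
  # order (h = 1) and one cycle (h = 0)
  s <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s["A", "B"] <- 2; s["B", "C"] <- 2
  lt3 <- linearity_test(validate_matrix(s), rand_unknown = 400,
                        rand_null = 200, seed = 3)
  expect_gt(lt3$h_prime, 0)
  expect_lt(lt3$h_prime, 1)
})

test_that("steepness randomization test calibrates against the binomial null", {
  res <- steepness_randomization_test(linear_matrix(6, 20), reps = 1000,
                                      seed = 5)
  expect_lte(res$null_p, 0.01)
  expect_true(all(res$null_steepness >= 0 & res$null_steepness <= 1))
  # continuity correction: p can never be 0 or exceed 1
  res1 <- steepness_randomization_test(linear_matrix(4, 2), reps = 1,
                                       seed = 6)
  expect_gte(res1$null_p, 1 / 2)
  expect_lte(res1$null_p, 1)
})
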