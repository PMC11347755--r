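# Independent oracles and fixture builders. These deliberately use the
# slowest, most literal formulations available so they stay independent of
# the implementation paths they check.

# naive quadruple-loop David's scores straight from the definitional sums
naive_davids <- function(m) {
  s <- unclass(m)
  n <- nrow(s)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      nij <- s[i, j] + s[j, i]
      if (nij == 0) {
        D[i, j] <- 0.5
      } else {
        pij <- s[i, j] / nij
        D[i, j] <- pij - (pij - 0.5) / (nij + 1)
      }
    }
  }
  w <- l <- w2 <- l2 <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) w[i] <- w[i] + D[i, j]
    for (j in seq_len(n)) if (j != i) l[i] <- l[i] + D[j, i]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) w2[i] <- w2[i] + w[j] * D[i, j]
    for (j in seq_len(n)) if (j != i) l2[i] <- l2[i] + l[j] * D[j, i]
  }
  ds <- w + w2 - l - l2
  list(D = D, ds = ds, norm_ds = (ds + n * (n - 1) / 2) / n)
}

# direct dense multivariate-normal log-density of the meta model
dense_mvn_ll <- function(sigma2, design, A, method = "ML") {
  V <- sigma2[1] * outer(design$species, design$species, "==") +
    sigma2[2] * outer(design$group, design$group, "==") +
    sigma2[3] * A[design$species, design$species] +
    diag(design$v, design$k)
  X <- design$X
  Vinv <- solve(V)
  beta <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% design$y)
  r <- design$y - X %*% beta
  quad <- drop(t(r) %*% Vinv %*% r)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (method == "ML") {
    -0.5 * (design$k * log(2 * pi) + ld + quad)
  } else {
    ldM <- as.numeric(determinant(t(X) %*% Vinv %*% X,
                                  logarithm = TRUE)$modulus)
    -0.5 * ((design$k - design$p) * log(2 * pi) + ld + ldM + quad)
  }
}

# random sociomatrix: every dyad interacts Poisson(mu) times, wins split at
# random probabilities
random_sociomatrix <- function(N, mu = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- matrix(0, N, N, dimnames = list(paste0("i", 1:N), paste0("i", 1:N)))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      nij <- rpois(1, mu)
      if (nij == 0) next
      w <- rbinom(1, nij, runif(1))
      s[i, j] <- w
      s[j, i] <- nij - w
    }
  }
  validate_matrix(s)
}

# strict linear-hierarchy matrix: i beats j in every one of n_ij bouts
linear_matrix <- function(N, n_ij = 10) {
  s <- matrix(0, N, N, dimnames = list(paste0("i", 1:N), paste0("i", 1:N)))
  s[upper.tri(s)] <- n_ij
  validate_matrix(s)
}

# worked 3-individual example: A beats B 2-0, A beats C 2-0, B beats C 2-0
worked_example_matrix <- function() {
  s <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s["A", "B"] <- 2; s["A", "C"] <- 2; s["B", "C"] <- 2
  validate_matrix(s)
}

full_predictors <- c("steepness", "benefit_category", "duration_months",
                     "setting", "sex", "dispersal", "social_org", "origin")

# small raw dataset + matching reduced pipeline config for pipeline tests
small_raw_dataset <- function(seed = 7, beta_steep = 0, S = 8) {
  simulate_dataset(sim_config(S = S, groups_per_species = 2,
                              records_per_group = 2, N = 6, delta_max = 2.5,
                              mu = 8, beta_steep = beta_steep, seed = seed),
                   level = "raw")
}

fast_config <- function(seed = 1) {
  pipeline_config(elo = elo_config(n_randomizations = 50),
                  bayes = bayes_config(chains = 1, iter = 300, burn_in = 150),
                  linearity = list(rand_unknown = 100, rand_null = 500),
                  seed = seed)
}
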