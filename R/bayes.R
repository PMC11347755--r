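#' MCMC configuration for the Bayesian steepness surrogates
#'
#' The Bayesian steepness measures model each dyad's wins as
#' `Binomial(n_ij, logistic(a_i - a_j))` with iid standard-normal priors on
#' the latent strengths `a`. Sampling is by component-wise random-walk
#' Metropolis; draws are mean-centered, which fixes the translation
#' invariance of the likelihood. This is a deliberately simple surrogate for
#' heavier HMC-based implementations: it reproduces the defining outputs
#' (posterior steepness with credible intervals) at desk scale but is not
#' numerically interchangeable with them.
#'
#' @param chains Number of independent chains.
#' @param iter Kept draws per chain (post burn-in).
#' @param burn_in Discarded initial sweeps per chain.
#' @param proposal_sd Random-walk proposal standard deviation.
#' @param prob Credible-interval mass (central interval; default 0.95).
#' @param seed Optional integer seed.
#' @export
bayes_config <- function(chains = 4, iter = 2500, burn_in = 1000,
                         proposal_sd = 0.5, prob = 0.95, seed = NULL) {
  stopifnot(chains >= 1, iter >= 10, burn_in >= 0, proposal_sd > 0,
            prob > 0, prob < 1)
  structure(list(chains = chains, iter = iter, burn_in = burn_in,
                 proposal_sd = proposal_sd, prob = prob, seed = seed),
            class = "bayes_config")
}

#' Posterior draws of latent dyadic strengths
#'
#' @param m An `interaction_matrix` with at least one interaction.
#' @param cfg A [bayes_config()].
#' @return A matrix of centered posterior draws (rows = draws, columns =
#'   individuals, named by id), with attributes `rhat` (split-chain, per
#'   individual) and `chains`.
#' @export
fit_latent_strengths <- function(m, cfg = bayes_config()) {
  s <- unclass(m)
  if (nrow(s) < 2) stop("need at least 2 individuals")
  if (sum(s) == 0) stop("matrix has no interactions", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chains <- lapply(seq_len(cfg$chains), function(ch) {
    a0 <- stats::rnorm(nrow(s), 0, 1)
    latent_strength_mcmc_cpp(s, cfg$iter, cfg$burn_in, cfg$proposal_sd, a0)
  })
  draws <- do.call(rbind, chains)
  colnames(draws) <- matrix_ids(m)
  rhat <- split_rhat(chains)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning("split-chain Rhat > 1.1 for ",
            paste(matrix_ids(m)[rhat > 1.1], collapse = ", "),
            "; consider more iterations", call. = FALSE)
  }
  attr(draws, "rhat") <- rhat
  attr(draws, "chains") <- cfg$chains
  draws
}

# split-chain potential scale reduction factor, one value per parameter
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(d) {
    h <- floor(nrow(d) / 2)
    list(d[seq_len(h), , drop = FALSE], d[(h + 1):(2 * h), , drop = FALSE])
  }), recursive = FALSE)
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)                       # p x m
  vars <- sapply(halves, function(d) apply(d, 2, stats::var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  b <- n * apply(means, 1, stats::var)
  w <- rowMeans(vars)
  ifelse(w > 0, sqrt(((n - 1) / n * w + b / n) / w), NA_real_)
}

plogis_mat <- function(a) {
  # logistic of all pairwise differences a_i - a_j
  d <- outer(a, a, "-")
  1 / (1 + exp(-d))
}

steepness_draw_from_sorted <- function(y) {
  n <- length(y)
  r <- seq_len(n)
  slope <- stats::cov(sort(y, decreasing = TRUE), r) / stats::var(r)
  min(max(abs(slope), 0), 1)
}

posterior_steepness <- function(draws_st, ranks, method, prob) {
  qs <- stats::quantile(draws_st, c((1 - prob) / 2, 1 - (1 - prob) / 2),
                        names = FALSE)
  structure(list(draws = draws_st, mean = mean(draws_st),
                 lower = qs[1], upper = qs[2], method = method,
                 scores = ranks),
            class = "posterior_steepness")
}

#' @export
print.posterior_steepness <- function(x, ...) {
  cat(sprintf("steepness [%s]: %.4f (95%% CI %.4f-%.4f, %d draws)\n",
              x$method, x$mean, x$lower, x$upper, length(x$draws)))
  invisible(x)
}

#' Bayesian Elo-flavored steepness
#'
#' For each posterior draw of the latent strengths, the cumulative winning
#' probability of individual i is `CWP_i = sum_{j != i} logistic(a_i - a_j)`.
#' Sorted descending, a perfectly despotic hierarchy gives CWP
#' `(N-1, N-2, ..., 0)` and OLS slope -1 against ranks 1..N, so the absolute
#' slope is a steepness draw on [0, 1]. The posterior mean CWP per individual
#' serves as the Elo_Bayes cardinal rank.
#'
#' @param m An `interaction_matrix`.
#' @param cfg A [bayes_config()].
#' @param draws Optional precomputed draws from [fit_latent_strengths()].
#' @return A `posterior_steepness` (method `"Elo_Bayes"`).
#' @export
bayes_elo_steepness <- function(m, cfg = bayes_config(), draws = NULL) {
  if (is.null(draws)) draws <- fit_latent_strengths(m, cfg)
  cwp <- t(apply(draws, 1, function(a) {
    p <- plogis_mat(a)
    diag(p) <- 0
    rowSums(p)
  }))
  st <- apply(cwp, 1, steepness_draw_from_sorted)
  ranks <- cardinal_ranks(colnames(draws), colMeans(cwp), method = "Elo_Bayes")
  posterior_steepness(st, ranks, "Elo_Bayes", cfg$prob)
}

#' Bayesian David's-score-flavored steepness
#'
#' Each posterior draw defines dyadic dominance indices
#' `Dij = logistic(a_i - a_j)`, from which David's scores and NormDS are
#' computed exactly as in [davids_scores()]; the steepness draw is the
#' absolute OLS slope of sorted NormDS on ranks 1..N. Posterior mean NormDS
#' per individual is the DS_Bayes cardinal rank.
#'
#' @inheritParams bayes_elo_steepness
#' @return A `posterior_steepness` (method `"DS_Bayes"`).
#' @export
bayes_ds_steepness <- function(m, cfg = bayes_config(), draws = NULL) {
  if (is.null(draws)) draws <- fit_latent_strengths(m, cfg)
  n <- ncol(draws)
  nds <- t(apply(draws, 1, function(a) {
    d <- plogis_mat(a)
    diag(d) <- 0
    w <- rowSums(d)
    l <- colSums(d)
    ds <- w + as.vector(d %*% w) - l - as.vector(t(d) %*% l)
    (ds + n * (n - 1) / 2) / n
  }))
  st <- apply(nds, 1, steepness_draw_from_sorted)
  ranks <- cardinal_ranks(colnames(draws), colMeans(nds), method = "DS_Bayes")
  posterior_steepness(st, ranks, "DS_Bayes", cfg$prob)
}
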