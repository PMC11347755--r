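#' Dyadic dominance indices (Dij)
#'
#' The dyadic dominance index corrects the raw win proportion
#' `Pij = s_ij / n_ij` toward chance level for sparsely observed dyads:
#' `Dij = Pij - (Pij - 0.5) / (n_ij + 1)`. Dyads never observed interacting
#' (`n_ij = 0`) are set to the chance value `Dij = Dji = 0.5`, which keeps
#' `Dij + Dji = 1` for every dyad.
#'
#' @param m An `interaction_matrix` (see [validate_matrix()]).
#' @return An N x N numeric matrix of Dij values with zero diagonal.
#' @export
dyadic_dominance_index <- function(m) {
  s <- unclass(m)
  n <- s + t(s)
  p <- ifelse(n > 0, s / ifelse(n > 0, n, 1), 0.5)
  d <- p - (p - 0.5) / (n + 1)
  diag(d) <- 0
  dimnames(d) <- dimnames(s)
  d
}

#' David's scores and normalized David's scores
#'
#' Cardinal dominance scores combining weighted wins and losses:
#' `w_i = sum_j Dij`, `w2_i = sum_j w_j Dij`, `l_i = sum_j Dji`,
#' `l2_i = sum_j l_j Dji`, `DS_i = w_i + w2_i - l_i - l2_i`, and
#' `NormDS_i = (DS_i + N(N-1)/2) / N`. DS sums to zero over individuals and
#' NormDS has mean `(N-1)/2`.
#'
#' @param m An `interaction_matrix`.
#' @return A `cardinal_ranks` object: data frame with columns `id`, `score`
#'   (NormDS), `ds`, `w`, `l`, and attribute `method = "NDS_Dij"`.
#' @export
davids_scores <- function(m) {
  d <- dyadic_dominance_index(m)
  n <- nrow(d)
  w <- rowSums(d)
  l <- colSums(d)
  w2 <- as.vector(d %*% w)
  l2 <- as.vector(t(d) %*% l)
  ds <- w + w2 - l - l2
  norm_ds <- (ds + n * (n - 1) / 2) / n
  cardinal_ranks(matrix_ids(m), norm_ds, method = "NDS_Dij",
                 extra = list(ds = ds, w = w, l = l))
}

#' Construct a cardinal-ranks object
#'
#' @param ids Character vector of individual ids.
#' @param scores Numeric scores, one per id (higher = more dominant).
#' @param method Label of the scoring algorithm.
#' @param extra Optional named list of auxiliary per-individual columns.
#' @return A `cardinal_ranks` data frame.
#' @export
cardinal_ranks <- function(ids, scores, method, extra = NULL) {
  stopifnot(length(ids) == length(scores), all(is.finite(scores)))
  out <- data.frame(id = as.character(ids), score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  attr(out, "method") <- method
  class(out) <- c("cardinal_ranks", "data.frame")
  out
}

#' Ordinal ranks from cardinal scores
#'
#' Rank 1 is the highest score. Ties are broken by the input order of ids so
#' the result is a deterministic permutation of 1..N.
#'
#' @param scores A `cardinal_ranks` object.
#' @return A data frame with columns `id` and `rank`.
#' @export
ordinal_from_cardinal <- function(scores) {
  ord <- order(-scores$score, seq_len(nrow(scores)))
  rk <- integer(nrow(scores))
  rk[ord] <- seq_len(nrow(scores))
  out <- data.frame(id = scores$id, rank = rk, stringsAsFactors = FALSE)
  class(out) <- c("ordinal_ranks", "data.frame")
  out
}

#' Hierarchy steepness from cardinal scores
#'
#' Steepness is the absolute slope of the ordinary least-squares regression
#' of the cardinal scores, sorted in descending order, on the ordinal ranks
#' 1..N. On the NormDS and cumulative-winning-probability scales a perfectly
#' despotic hierarchy gives slope -1, so the estimate lies in [0, 1]; tiny
#' numerical overshoot is clamped.
#'
#' @param scores A `cardinal_ranks` object (or numeric vector of scores).
#' @return A `steepness_result` list with `estimate`, `method`,
#'   `n_individuals`, and the OLS standard error of the slope.
#' @export
steepness_from_scores <- function(scores) {
  method <- if (inherits(scores, "cardinal_ranks")) attr(scores, "method") else "scores"
  x <- if (is.numeric(scores)) scores else scores$score
  n <- length(x)
  stopifnot(n >= 2)
  y <- sort(x, decreasing = TRUE)
  r <- seq_len(n)
  slope <- stats::cov(y, r) / stats::var(r)
  se <- if (n > 2) {
    fit <- stats::lm.fit(cbind(1, r), y)
    sqrt(sum(fit$residuals^2) / (n - 2) / sum((r - mean(r))^2))
  } else NA_real_
  structure(list(estimate = min(max(abs(slope), 0), 1), method = method,
                 n_individuals = n, se = se, null_p = NULL),
            class = "steepness_result")
}

#' @export
print.steepness_result <- function(x, ...) {
  cat(sprintf("steepness [%s]: %.4f (N = %d)\n", x$method, x$estimate,
              x$n_individuals))
  if (!is.null(x$null_p)) cat(sprintf("  randomization p = %.4g\n", x$null_p))
  invisible(x)
}

#' Randomization test for NormDS steepness
#'
#' Keeps each dyad's interaction count `n_ij` fixed and redraws the wins as
#' `Binomial(n_ij, 0.5)` to build a null distribution of steepness under no
#' dominance structure. The right-tail p-value uses the add-one continuity
#' correction `(1 + #{null >= observed}) / (reps + 1)`.
#'
#' @param m An `interaction_matrix`.
#' @param reps Number of null matrices (default 2000).
#' @param seed Optional integer seed.
#' @return A `steepness_result` with `null_p` and the null distribution in
#'   `null_steepness`.
#' @export
steepness_randomization_test <- function(m, reps = 2000, seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- steepness_from_scores(davids_scores(m))
  s <- unclass(m)
  n <- s + t(s)
  N <- nrow(s)
  ut <- upper.tri(n)
  n_dyad <- n[ut]
  null_st <- vapply(seq_len(reps), function(i) {
    wins <- stats::rbinom(length(n_dyad), n_dyad, 0.5)
    full <- matrix(0, N, N, dimnames = dimnames(s))
    full[ut] <- wins
    lower <- matrix(0, N, N)
    lower[ut] <- n_dyad - wins
    full <- full + t(lower)
    steepness_from_scores(davids_scores(structure(full,
      class = c("interaction_matrix", "matrix"))))$estimate
  }, numeric(1))
  obs$null_p <- (1 + sum(null_st >= obs$estimate)) / (reps + 1)
  obs$null_steepness <- null_st
  obs
}

#' Landau's linearity index
#'
#' For a fully resolved dominance relation, `h = 12/(N^3 - N) *
#' sum_i (V_i - (N-1)/2)^2`, with `V_i` the number of individuals dominated
#' by i. `h = 1` for a strict linear order, `h = 0` for maximally circular
#' relations.
#'
#' @param dom N x N binary matrix; `dom[i, j] = 1` iff i dominates j. Every
#'   off-diagonal dyad must be resolved in exactly one direction.
#' @return Landau's h in [0, 1].
#' @export
landau_h <- function(dom) {
  dom <- as.matrix(dom)
  n <- nrow(dom)
  stopifnot(n == ncol(dom), n >= 3)
  resolved <- dom + t(dom)
  diag(resolved) <- 1
  if (any(resolved != 1)) {
    stop("unresolved or doubly-resolved dyad; use linearity_test() for ",
         "matrices with ties or unknowns", call. = FALSE)
  }
  v <- rowSums(dom)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' Linearity test with randomized resolution of unknown dyads
#'
#' Dyads are resolved by majority wins; tied or unobserved dyads are resolved
#' uniformly at random `rand_unknown` times and the modified index `h'` is
#' the mean h over those completions. Significance is the right-tail
#' proportion of `rand_null` fully random tournaments whose h reaches `h'`
#' (add-one continuity correction).
#'
#' @param m An `interaction_matrix` with N >= 3.
#' @param rand_unknown Completions of unknown/tied dyads (default 1000).
#' @param rand_null Null tournaments (default 10000).
#' @param seed Optional seed.
#' @param alpha Significance level for `is_linear` (default 0.05).
#' @return A `linearity_result` list: `h` (index on the majority-resolved
#'   relation with unknowns split half-half), `h_prime`, `p_value`,
#'   `is_linear`, `n_unknown`.
#' @export
linearity_test <- function(m, rand_unknown = 1000, rand_null = 10000,
                           seed = NULL, alpha = 0.05) {
  s <- unclass(m)
  N <- nrow(s)
  stopifnot(N >= 3)
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  wins_ij <- s[upper.tri(s)]
  wins_ji <- t(s)[upper.tri(s)]
  known_dir <- ifelse(wins_ij > wins_ji, 1, ifelse(wins_ji > wins_ij, 0, NA))
  unknown <- is.na(known_dir)

  h_of <- function(dir_upper) {
    dom <- matrix(0, N, N)
    dom[upper.tri(dom)] <- dir_upper
    lower <- matrix(0, N, N)
    lower[upper.tri(lower)] <- 1 - dir_upper
    dom <- dom + t(lower)
    v <- rowSums(dom)
    12 / (N^3 - N) * sum((v - (N - 1) / 2)^2)
  }

  if (any(unknown)) {
    h_draws <- vapply(seq_len(rand_unknown), function(i) {
      d <- known_dir
      d[unknown] <- stats::rbinom(sum(unknown), 1, 0.5)
      h_of(d)
    }, numeric(1))
    h_prime <- mean(h_draws)
  } else {
    h_prime <- h_of(known_dir)
  }
  # h on the deterministic relation; unknown dyads count 0.5 to each side
  dir_exp <- ifelse(unknown, 0.5, known_dir)
  dom <- matrix(0, N, N)
  dom[upper.tri(dom)] <- dir_exp
  lower <- matrix(0, N, N)
  lower[upper.tri(lower)] <- 1 - dir_exp
  dom <- dom + t(lower)
  h_resolved <- 12 / (N^3 - N) * sum((rowSums(dom) - (N - 1) / 2)^2)

  null_h <- vapply(seq_len(rand_null), function(i) {
    h_of(stats::rbinom(length(known_dir), 1, 0.5))
  }, numeric(1))
  p <- (1 + sum(null_h >= h_prime)) / (rand_null + 1)
  structure(list(h = h_resolved, h_prime = h_prime, p_value = p,
                 is_linear = p < alpha, n_unknown = sum(unknown)),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Landau linearity: h = %.4f, h' = %.4f, p = %.4g (%s)\n",
              x$h, x$h_prime, x$p_value,
              if (x$is_linear) "significantly linear" else "not linear"))
  invisible(x)
}
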