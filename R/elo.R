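#' Elo configuration
#'
#' Defaults follow the classical chess parameterization: start rating 1000,
#' update constant k = 100, logistic width 400 rating points.
#'
#' @param k Update constant (> 0).
#' @param start Initial rating for every individual.
#' @param scale Width of the base-10 logistic expected-win curve (> 0).
#' @param n_randomizations Number of randomized interaction sequences used by
#'   [elo_rpt_steepness()] (>= 2).
#' @param seed Optional integer seed.
#' @return A list of class `elo_config`.
#' @export
elo_config <- function(k = 100, start = 1000, scale = 400,
                       n_randomizations = 1000, seed = NULL) {
  stopifnot(k > 0, scale > 0, n_randomizations >= 2)
  structure(list(k = k, start = start, scale = scale,
                 n_randomizations = n_randomizations, seed = seed),
            class = "elo_config")
}

#' Expand a sociomatrix into randomized interaction sequences
#'
#' A sociomatrix aggregates undated interactions, so the Elo trajectory is
#' not identified; each sequence is a uniformly random permutation of the
#' multiset of dyadic win events implied by the matrix.
#'
#' @param m An `interaction_matrix` with at least one interaction.
#' @param n Number of sequences.
#' @param seed Optional integer seed.
#' @return A list of `n` two-column matrices (`winner`, `loser`) of ids.
#' @export
matrix_to_sequences <- function(m, n = 1, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ev <- event_list(m)
  if (nrow(ev) == 0) stop("matrix has no interactions", call. = FALSE)
  ids <- matrix_ids(m)
  lapply(seq_len(n), function(i) {
    p <- sample.int(nrow(ev))
    cbind(winner = ids[ev[p, 1]], loser = ids[ev[p, 2]])
  })
}

# integer event list (winner index, loser index), one row per interaction
event_list <- function(m) {
  s <- unclass(m)
  idx <- which(s > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), 0, 2))
  counts <- s[idx]
  cbind(rep(idx[, 1], counts), rep(idx[, 2], counts))
}

#' Sequential Elo scores for one interaction sequence
#'
#' After each event the winner gains `k * (1 - E_win)` rating points and the
#' loser loses the same amount, where `E_win` is the expected win probability
#' from the current rating difference. The total rating is conserved.
#'
#' @param seq A two-column matrix of (winner id, loser id) events, as
#'   produced by [matrix_to_sequences()].
#' @param cfg An [elo_config()].
#' @param ids Optional id universe (defaults to ids appearing in `seq`).
#' @return A `cardinal_ranks` object with final ratings, method `"Elo"`.
#' @export
elo_scores <- function(seq, cfg = elo_config(), ids = NULL) {
  stopifnot(nrow(seq) >= 1)
  if (is.null(ids)) ids <- sort(unique(c(seq[, 1], seq[, 2])))
  w <- match(seq[, 1], ids)
  l <- match(seq[, 2], ids)
  if (anyNA(w) || anyNA(l)) stop("sequence contains ids outside the universe")
  r <- elo_run_cpp(w - 1L, l - 1L, length(ids), cfg$k, cfg$start, cfg$scale)
  cardinal_ranks(ids, r, method = "Elo")
}

#' Randomized-Elo steepness via repeatability
#'
#' Final Elo scores are computed for many randomized orderings of the
#' interactions; steepness is the one-way intraclass correlation ICC(1) of
#' the scores with individuals as groups and randomizations as replicates.
#' A stable hierarchy reproduces the same ordering regardless of sequence
#' order (ICC near 1); an unresolved one shuffles scores (ICC near 0).
#'
#' @param m An `interaction_matrix`.
#' @param cfg An [elo_config()]; `cfg$n_randomizations` sequences are used.
#' @return A `steepness_result` (method `"Elo_rpt"`) whose `scores` field
#'   holds the per-individual mean ratings (the Elo_rpt cardinal ranks).
#' @export
elo_rpt_steepness <- function(m, cfg = elo_config()) {
  if (nrow(m) < 2) stop("need at least 2 individuals")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ev <- event_list(m)
  if (nrow(ev) == 0) stop("matrix has no interactions", call. = FALSE)
  ids <- matrix_ids(m)
  R <- cfg$n_randomizations
  sc <- matrix(0, nrow(m), R)
  for (j in seq_len(R)) {
    p <- sample.int(nrow(ev))
    sc[, j] <- elo_run_cpp(ev[p, 1] - 1L, ev[p, 2] - 1L, nrow(m),
                           cfg$k, cfg$start, cfg$scale)
  }
  icc <- icc1(sc)
  res <- structure(list(estimate = icc, method = "Elo_rpt",
                        n_individuals = nrow(m), se = NA_real_, null_p = NULL),
                   class = "steepness_result")
  res$scores <- cardinal_ranks(ids, rowMeans(sc), method = "Elo_rpt")
  res
}

# one-way intraclass correlation, rows = groups, columns = replicates,
# truncated to [0, 1]
icc1 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  ms_a <- k * sum((rm_ - gm)^2) / (n - 1)
  ms_w <- sum((x - rm_)^2) / (n * (k - 1))
  if (ms_w == 0 && ms_a == 0) return(0)
  if (ms_w == 0) return(1)
  min(max((ms_a - ms_w) / (ms_a + (k - 1) * ms_w), 0), 1)
}
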