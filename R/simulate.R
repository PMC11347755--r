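#' Simulation configuration
#'
#' Describes a complete synthetic world: a Yule species tree, groups nested
#' in species, win-loss matrices driven by latent abilities, benefits
#' correlated with rank, and effect-size records following the three-level
#' phylogenetic meta-regression model with known parameters.
#'
#' @param S Number of species (>= 2).
#' @param groups_per_species Groups sampled per species.
#' @param records_per_group Effect-size records per group.
#' @param N Individuals per group (>= 4).
#' @param delta_max Upper bound of the per-group ability dispersion
#'   `delta ~ Uniform(0, delta_max)`; adjacent individuals on the latent
#'   ability grid differ by `delta`, so `delta = 0` is an egalitarian group
#'   and `delta >= 3` a near-despotic one.
#' @param mu Per-dyad Poisson mean of the number of observed interactions.
#' @param mu_z True mean Fisher-Z effect.
#' @param beta_steep True coefficient of (centered) group steepness on the
#'   record's latent Z.
#' @param sigma2 Length-3 variances of the species, group-in-species, and
#'   phylogenetic random effects.
#' @param n Benefit sample size for effect-level simulation (raw-level
#'   records use the group size N).
#' @param p_published Probability a record is flagged as published.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(S = 20, groups_per_species = 2, records_per_group = 2,
                       N = 8, delta_max = 2.5, mu = 10, mu_z = 0.2,
                       beta_steep = 0, sigma2 = c(0.10, 0.05, 0.10),
                       n = 30, p_published = 0.5, seed = NULL) {
  stopifnot(S >= 2, groups_per_species >= 1, records_per_group >= 1, N >= 4,
            delta_max >= 0, mu > 0, length(sigma2) == 3, all(sigma2 >= 0),
            n >= 4, p_published >= 0, p_published <= 1)
  structure(list(S = S, groups_per_species = groups_per_species,
                 records_per_group = records_per_group, N = N,
                 delta_max = delta_max, mu = mu, mu_z = mu_z,
                 beta_steep = beta_steep, sigma2 = sigma2, n = n,
                 p_published = p_published, seed = seed),
            class = "sim_config")
}

#' Simulate a pure-birth species tree
#'
#' Yule tree (birth rate 1, no extinction) on `S` extant tips, rescaled to
#' depth 1, with tips relabelled `sp1..spS`.
#'
#' @param S Number of species.
#' @param seed Optional integer seed.
#' @return An ultrametric [ape::phylo] tree.
#' @export
simulate_tree <- function(S, seed = NULL) {
  stopifnot(S >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(S, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("sp", seq_len(S))
  tr
}

#' Simulate a win-loss sociomatrix from latent abilities
#'
#' Abilities sit on an equally spaced grid `a_i = delta * (N + 1 - 2i) / 2`
#' (adjacent gap `delta`, mean 0). Each dyad interacts
#' `n_ij ~ Poisson(mu)` times and the higher-indexed ability wins each bout
#' with probability `logistic(a_i - a_j)`.
#'
#' @param N Group size.
#' @param delta Ability gap between adjacent individuals (>= 0).
#' @param mu Poisson mean of per-dyad interaction counts.
#' @param seed Optional integer seed.
#' @param ids Optional id labels (default `ind1..indN`).
#' @return An `interaction_matrix` with attribute `abilities`.
#' @export
simulate_matrix <- function(N, delta, mu, seed = NULL, ids = NULL) {
  stopifnot(N >= 2, delta >= 0, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- paste0("ind", seq_len(N))
  a <- delta * (N + 1 - 2 * seq_len(N)) / 2
  s <- matrix(0, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      nij <- stats::rpois(1, mu)
      if (nij == 0) next
      wins <- stats::rbinom(1, nij, stats::plogis(a[i] - a[j]))
      s[i, j] <- wins
      s[j, i] <- nij - wins
    }
  }
  m <- structure(s, class = c("interaction_matrix", "matrix"))
  attr(m, "abilities") <- stats::setNames(a, ids)
  m
}

#' Simulate benefits correlated with dominance scores
#'
#' Benefits are drawn so that (scores, benefit) is bivariate normal with the
#' requested correlation: `benefit = true_r * scale(scores) +
#' sqrt(1 - true_r^2) * noise`. The observed sample correlation is then a
#' noisy realization around `true_r`.
#'
#' @param scores Numeric per-individual scores (true abilities or ranks).
#' @param true_r Target correlation, |true_r| < 1.
#' @param seed Optional integer seed.
#' @return A data frame `individual`, `benefit_value`.
#' @export
simulate_benefits <- function(scores, true_r, seed = NULL) {
  stopifnot(abs(true_r) < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  x <- as.vector(scale(scores))
  b <- true_r * x + sqrt(1 - true_r^2) * stats::rnorm(n)
  ids <- if (is.null(names(scores))) paste0("ind", seq_len(n)) else names(scores)
  data.frame(individual = ids, benefit_value = b, stringsAsFactors = FALSE)
}

sample_moderators <- function(n_records, origin_p) {
  list(benefit_type = sample(benefit_types, n_records, replace = TRUE),
       origin = ifelse(stats::runif(n_records) < origin_p, "published",
                       "unpublished"),
       duration_months = round(stats::rgamma(n_records, shape = 2,
                                             scale = 12) + 1),
       pub_year = sample(1985:2023, n_records, replace = TRUE))
}

#' Simulate a complete dataset with known ground truth
#'
#' Structure: `S` species on a Yule tree; per species a dispersal pattern
#' and social organization; per group a setting, sex class, ability
#' dispersion `delta ~ Uniform(0, delta_max)`, and a win-loss matrix; per
#' record a benefit type, origin, duration, and — at `level = "raw"` — a
#' benefit table of the group's individuals. The latent effect of each
#' record is `Z = mu_z + beta_steep * (steepness_g - mean steepness) +
#' u_species + u_group + u_phylo`, with `u_phylo ~ MVN(0, sigma2_p A)`;
#' `steepness_g` is the NormDS steepness computed from the group's realized
#' matrix, so estimation noise in the predictor is part of the generated
#' world. At `level = "raw"`, the record's true correlation is
#' `tanh(Z)` and benefits are drawn at that correlation against the true
#' abilities; at `level = "effect"`, the observed `z_r` is drawn directly as
#' `N(Z, v)` with `v = 1/(n - 3)` (fast path for calibration studies).
#'
#' @param cfg A [sim_config()].
#' @param level `"raw"` (matrices + benefits) or `"effect"` (records only).
#' @return A list of class `sim_dataset`: `records` (data frame), `matrices`
#'   (named list of `interaction_matrix`), `benefits` (named list of benefit
#'   tables, raw level), `tree`, `A`, `truth` (ground-truth ledger),
#'   `config`.
#' @export
simulate_dataset <- function(cfg, level = c("raw", "effect")) {
  level <- match.arg(level)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- simulate_tree(cfg$S)
  A <- correlation_matrix(tree)
  species <- tree$tip.label

  u_s <- stats::rnorm(cfg$S, 0, sqrt(cfg$sigma2[1]))
  u_p <- if (cfg$sigma2[3] > 0) {
    drop(crossprod(chol(A + diag(1e-10, cfg$S)),
                   stats::rnorm(cfg$S))) * sqrt(cfg$sigma2[3])
  } else numeric(cfg$S)
  names(u_s) <- names(u_p) <- species

  dispersal <- sample(moderator_levels$dispersal, cfg$S, replace = TRUE)
  social_org <- sample(moderator_levels$social_org, cfg$S, replace = TRUE)

  groups <- expand.grid(g = seq_len(cfg$groups_per_species),
                        sp = seq_len(cfg$S))
  n_groups <- nrow(groups)
  group_id <- paste0(species[groups$sp], "_g", groups$g)
  u_g <- stats::setNames(stats::rnorm(n_groups, 0, sqrt(cfg$sigma2[2])),
                         group_id)
  delta_g <- stats::runif(n_groups, 0, cfg$delta_max)
  setting_g <- sample(moderator_levels$setting, n_groups, replace = TRUE)
  sex_g <- sample(moderator_levels$sex, n_groups, replace = TRUE)

  matrices <- list()
  steep_g <- numeric(n_groups)
  abilities <- list()
  for (gi in seq_len(n_groups)) {
    m <- simulate_matrix(cfg$N, delta_g[gi], cfg$mu)
    matrices[[group_id[gi]]] <- m
    abilities[[group_id[gi]]] <- attr(m, "abilities")
    steep_g[gi] <- steepness_from_scores(davids_scores(m))$estimate
  }

  rec_rows <- list()
  rid <- 0
  for (gi in seq_len(n_groups)) {
    mods <- sample_moderators(cfg$records_per_group, cfg$p_published)
    for (ri in seq_len(cfg$records_per_group)) {
      rid <- rid + 1
      sp_i <- groups$sp[gi]
      n_rec <- if (level == "raw") cfg$N else cfg$n
      rec_rows[[rid]] <- data.frame(
        record_id = paste0("rec", rid), group = group_id[gi], gi = gi,
        species = species[sp_i], n = n_rec,
        benefit_type = mods$benefit_type[ri],
        benefit_category = benefit_category(mods$benefit_type[ri]),
        duration_months = mods$duration_months[ri],
        setting = setting_g[gi], sex = sex_g[gi],
        dispersal = dispersal[sp_i], social_org = social_org[sp_i],
        origin = mods$origin[ri],
        pub_year = ifelse(mods$origin[ri] == "published",
                          mods$pub_year[ri], NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows)
  # beta_steep is on the standardized-predictor scale (the scale the fitted
  # model reports), so the steepness gradient entering the latent Z is the
  # record-level standardized NormDS steepness
  rec_steep <- steep_g[records$gi]
  steep_sd <- stats::sd(rec_steep)
  steep_std <- if (steep_sd > 0) (rec_steep - mean(rec_steep)) / steep_sd
               else rec_steep * 0
  if (steep_sd == 0 && cfg$beta_steep != 0) {
    warning("all groups have identical steepness: beta_steep unidentifiable",
            call. = FALSE)
  }
  records$true_z <- cfg$mu_z + cfg$beta_steep * steep_std +
    u_s[records$species] + u_g[records$group] + u_p[records$species]
  benefits <- list()
  if (level == "raw") {
    records$true_r <- tanh(records$true_z)
    for (i in seq_len(nrow(records))) {
      benefits[[records$record_id[i]]] <-
        simulate_benefits(abilities[[records$group[i]]], records$true_r[i])
    }
  } else {
    records$v <- 1 / (cfg$n - 3)
    records$z_r <- stats::rnorm(nrow(records), records$true_z,
                                sqrt(records$v))
    records$steepness <- rec_steep
  }
  records$gi <- NULL
  truth <- list(u_species = u_s, u_group = u_g, u_phylo = u_p,
                delta = stats::setNames(delta_g, group_id),
                steepness_nds = stats::setNames(steep_g, group_id),
                mean_steepness = mean(rec_steep),
                sd_steepness = steep_sd,
                abilities = abilities,
                mu_z = cfg$mu_z, beta_steep = cfg$beta_steep,
                sigma2 = cfg$sigma2,
                true_z = stats::setNames(records$true_z, records$record_id))
  structure(list(records = records, matrices = matrices, benefits = benefits,
                 tree = tree, A = A, truth = truth, config = cfg,
                 level = level),
            class = "sim_dataset")
}
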