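steepness_methods <- c("NDS_Dij", "Elo_rpt", "Elo_Bayes", "DS_Bayes")

#' Pipeline configuration
#'
#' Bundles per-module settings. Defaults are desk-scale: they run a full
#' synthetic analysis in about a minute on one CPU. `elo` and `bayes` accept
#' [elo_config()] / [bayes_config()] objects; `linearity` controls the
#' randomized linearity test; `alpha` is the linearity significance level
#' used by the restricted rerun.
#'
#' @param elo An [elo_config()].
#' @param bayes A [bayes_config()].
#' @param linearity List with `rand_unknown`, `rand_null`.
#' @param alpha Linearity significance level (default 0.05).
#' @param seed Master integer seed for the whole analysis.
#' @export
pipeline_config <- function(elo = elo_config(n_randomizations = 200),
                            bayes = bayes_config(chains = 2, iter = 1000,
                                                 burn_in = 500),
                            linearity = list(rand_unknown = 200,
                                             rand_null = 2000),
                            alpha = 0.05, seed = 1L) {
  structure(list(elo = elo, bayes = bayes, linearity = linearity,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized blocks: `elo:`, `bayes:`, `linearity:`, `meta:` (currently
#' `alpha`), `simulate:` (passed to [sim_config()]). Missing blocks fall
#' back to defaults.
#'
#' @param path Path to a JSON config file.
#' @return A list: `pipeline` ([pipeline_config()]) and `simulate`
#'   ([sim_config()] arguments, if present).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (f in intersect(names(raw$elo), names(cfg$elo))) cfg$elo[[f]] <- raw$elo[[f]]
  for (f in intersect(names(raw$bayes), names(cfg$bayes))) {
    cfg$bayes[[f]] <- raw$bayes[[f]]
  }
  for (f in intersect(names(raw$linearity), names(cfg$linearity))) {
    cfg$linearity[[f]] <- raw$linearity[[f]]
  }
  if (!is.null(raw$meta$alpha)) cfg$alpha <- raw$meta$alpha
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  list(pipeline = cfg, simulate = raw$simulate)
}

#' Compute all four steepness measures for one sociomatrix
#'
#' Runs NormDS (with cardinal ranks), randomized-Elo repeatability, and the
#' two Bayesian flavors (sharing one posterior sample of latent strengths).
#'
#' @param m An `interaction_matrix`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for this matrix (defaults to `config$seed`).
#' @return Named list (per method) of lists with `steepness` and `scores`
#'   (a `cardinal_ranks` object).
#' @export
steepness_suite <- function(m, config = pipeline_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  nds_scores <- davids_scores(m)
  nds <- steepness_from_scores(nds_scores)
  elo <- elo_rpt_steepness(m, config$elo)
  draws <- fit_latent_strengths(m, config$bayes)
  eb <- bayes_elo_steepness(m, config$bayes, draws = draws)
  db <- bayes_ds_steepness(m, config$bayes, draws = draws)
  list(
    NDS_Dij = list(steepness = nds$estimate, scores = nds_scores),
    Elo_rpt = list(steepness = elo$estimate, scores = elo$scores),
    Elo_Bayes = list(steepness = eb$mean, scores = eb$scores,
                     ci = c(eb$lower, eb$upper)),
    DS_Bayes = list(steepness = db$mean, scores = db$scores,
                    ci = c(db$lower, db$upper)))
}

#' Write a simulated dataset to a directory
#'
#' Layout: `dataset.csv` (one row per record), `matrices/<group>.csv`
#' sociomatrices, `benefits/<record>.csv` benefit tables, `tree.nwk`, and
#' `truth.json` (ground-truth ledger).
#'
#' @param ds A `sim_dataset` from [simulate_dataset()] at raw level.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"), ds$level == "raw")
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "benefits"), showWarnings = FALSE)
  rec <- ds$records
  rec$matrix_file <- file.path("matrices", paste0(rec$group, ".csv"))
  rec$benefit_file <- file.path("benefits", paste0(rec$record_id, ".csv"))
  rec$true_z <- NULL
  rec$true_r <- NULL
  utils::write.csv(rec, file.path(dir, "dataset.csv"), row.names = FALSE)
  for (g in names(ds$matrices)) {
    write_sociomatrix(ds$matrices[[g]],
                      file.path(dir, "matrices", paste0(g, ".csv")))
  }
  for (r in names(ds$benefits)) {
    utils::write.csv(ds$benefits[[r]],
                     file.path(dir, "benefits", paste0(r, ".csv")),
                     row.names = FALSE)
  }
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  truth <- ds$truth
  truth$abilities <- lapply(truth$abilities, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load and validate a dataset directory
#'
#' Applies the sample-size exclusion rule (n < 4 individuals) with a logged
#' reason per dropped row, checks that every species is a tree tip and every
#' referenced file exists, and reads the sociomatrices, benefit tables, and
#' tree. Rows carrying pre-computed statistics (column `precomputed = TRUE`
#' with `r` and per-method steepness columns) are accepted and flagged as
#' non-recomputable.
#'
#' @param dir Dataset directory (see [write_dataset()] for the layout).
#' @return A list of class `steeprank_dataset`: `records`, `matrices`,
#'   `benefits`, `tree`, `A`, `exclusions` (data frame of dropped rows and
#'   reasons).
#' @export
load_dataset <- function(dir) {
  path <- file.path(dir, "dataset.csv")
  if (!file.exists(path)) stop("no dataset.csv in ", dir, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("record_id", "group", "species", "n", "benefit_type",
                "duration_months", "setting", "sex", "dispersal",
                "social_org", "origin")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop("dataset.csv missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(rec$precomputed)) rec$precomputed <- FALSE
  if (is.null(rec$benefit_category)) {
    rec$benefit_category <- benefit_category(rec$benefit_type)
  }
  tree <- parse_newick(file.path(dir, "tree.nwk"))
  tree <- grafen_if_needed(tree)
  A <- correlation_matrix(tree)
  bad_sp <- setdiff(unique(rec$species), tree$tip.label)
  if (length(bad_sp) > 0) {
    stop("species absent from tree: ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  keep <- rec$n >= 4
  exclusions <- data.frame(record_id = rec$record_id[!keep],
                           reason = sprintf("sample size %d < 4 individuals",
                                            rec$n[!keep]))
  for (i in which(!keep)) {
    message("excluding ", rec$record_id[i], ": ", exclusions$reason[
      exclusions$record_id == rec$record_id[i]])
  }
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records left after exclusions", call. = FALSE)

  matrices <- list()
  benefits <- list()
  for (i in seq_len(nrow(rec))) {
    if (isTRUE(rec$precomputed[i])) next
    mf <- file.path(dir, rec$matrix_file[i])
    bf <- file.path(dir, rec$benefit_file[i])
    if (!file.exists(mf)) stop("missing matrix file: ", mf, call. = FALSE)
    if (!file.exists(bf)) stop("missing benefit file: ", bf, call. = FALSE)
    if (is.null(matrices[[rec$group[i]]])) {
      matrices[[rec$group[i]]] <- read_sociomatrix(mf)
    }
    benefits[[rec$record_id[i]]] <- utils::read.csv(bf,
                                                    stringsAsFactors = FALSE)
  }
  structure(list(records = rec, matrices = matrices, benefits = benefits,
                 tree = tree, A = A, exclusions = exclusions),
            class = "steeprank_dataset")
}

grafen_if_needed <- function(tree) {
  if (is.null(tree$edge.length)) return(grafen_branch_lengths(tree))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (max(depths) - min(depths) > 1e-8 * max(depths)) {
    return(grafen_branch_lengths(tree))
  }
  tree
}

# coerce an in-memory sim_dataset to the loaded-dataset shape
as_steeprank_dataset <- function(ds) {
  if (inherits(ds, "steeprank_dataset")) return(ds)
  stopifnot(inherits(ds, "sim_dataset"), ds$level == "raw")
  rec <- ds$records
  rec$precomputed <- FALSE
  structure(list(records = rec, matrices = ds$matrices,
                 benefits = ds$benefits, tree = ds$tree, A = ds$A,
                 exclusions = data.frame(record_id = character(0),
                                         reason = character(0))),
            class = "steeprank_dataset")
}

# per-group steepness + cardinal ranks for all four methods, seeded
# deterministically from the master seed
group_steepness_table <- function(data, config) {
  groups <- names(data$matrices)
  out <- list()
  for (gi in seq_along(groups)) {
    out[[groups[gi]]] <- steepness_suite(data$matrices[[groups[gi]]], config,
                                         seed = config$seed + 7919L * gi)
  }
  out
}

# assemble effect-size records for one method x rank basis
records_for_model <- function(data, suite, method, basis) {
  rec <- data$records
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    g <- rec$group[i]
    if (isTRUE(rec$precomputed[i])) {
      st_col <- switch(method, NDS_Dij = "steepness_nds",
                       Elo_rpt = "steepness_elo_rpt",
                       Elo_Bayes = "steepness_elo_bayes",
                       DS_Bayes = "steepness_ds_bayes")
      st <- rec[[st_col]][i]
      if (is.null(st) || is.na(st)) {
        stop("precomputed row ", rec$record_id[i], " lacks ", st_col,
             call. = FALSE)
      }
      r <- rec$r[i]
    } else {
      ss <- suite[[g]][[method]]
      st <- ss$steepness
      ben <- data$benefits[[rec$record_id[i]]]
      sc <- ss$scores
      idx <- match(ben$individual, sc$id)
      if (anyNA(idx)) {
        stop("benefit ids not in matrix for record ", rec$record_id[i],
             call. = FALSE)
      }
      r <- if (basis == "cardinal") {
        pearson_r(ben$benefit_value, sc$score[idx])
      } else {
        ord <- ordinal_from_cardinal(sc)
        signed_ordinal_r(ben$benefit_value, ord$rank[idx])
      }
    }
    rows[[i]] <- build_record(
      group = g, species = rec$species[i], r = r, n = rec$n[i],
      rank_basis = basis, method = method, steepness = st,
      moderators = list(benefit_category = rec$benefit_category[i],
                        duration_months = rec$duration_months[i],
                        setting = rec$setting[i], sex = rec$sex[i],
                        dispersal = rec$dispersal[i],
                        social_org = rec$social_org[i],
                        origin = rec$origin[i],
                        pub_year = if (is.na(rec$pub_year[i])) NULL
                                   else rec$pub_year[i]),
      record_id = rec$record_id[i])
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}

control_predictors <- moderator_fields  # the 7 control variables

fit_model_pair <- function(records, A, predictors_full, predictors_control,
                           interaction = NULL) {
  design_full <- build_design(records, predictors_full,
                              interaction = interaction)
  design_control <- build_design(records, predictors_control)
  full <- meta_fit(design_full, A, method = "ML")
  control <- meta_fit(design_control, A, method = "ML")
  full_nophylo <- meta_fit(design_full, A, method = "ML",
                           fix_zero = "phylo")
  test <- lrt(full, control)
  tot <- sum(full$sigma2)
  lambda <- if (tot > 0) unname(full$sigma2["phylo"]) / tot else 0
  sig_chi2 <- max(0, 2 * (full$loglik - full_nophylo$loglik))
  list(full = full, control = control, lrt = test,
       qm = if (design_full$p > 1) omnibus_qm(full) else NULL,
       qe = qe_test(design_full),
       signal = list(lambda = lambda, chi2 = sig_chi2,
                     p_value = stats::pchisq(sig_chi2, 1,
                                             lower.tail = FALSE)))
}

analysis_loop <- function(data, config, predictors_full, predictors_control,
                          interaction = NULL, bias_tests = TRUE) {
  suite <- if (length(data$matrices) > 0) {
    group_steepness_table(data, config)
  } else list()
  rows <- list()
  models <- list()
  for (method in steepness_methods) {
    for (basis in c("cardinal", "ordinal")) {
      recs <- records_for_model(data, suite, method, basis)
      pair <- fit_model_pair(recs, data$A, predictors_full,
                             predictors_control, interaction)
      key <- paste(method, basis, sep = ".")
      models[[key]] <- pair
      row <- data.frame(
        method = method, rank_basis = basis, k = pair$full$k,
        df_full = pair$full$p + 3, df_control = pair$control$p + 3,
        chi2 = pair$lrt$chi2, df = pair$lrt$df, p_value = pair$lrt$p_value,
        beta_steepness = if ("steepness" %in% names(pair$full$beta))
          unname(pair$full$beta["steepness"]) else NA_real_,
        qm = if (is.null(pair$qm)) NA_real_ else pair$qm$statistic,
        qm_p = if (is.null(pair$qm)) NA_real_ else pair$qm$p_value,
        qe = pair$qe$statistic, qe_p = pair$qe$p_value,
        lambda = pair$signal$lambda, lambda_p = pair$signal$p_value,
        stringsAsFactors = FALSE)
      if (bias_tests && any(recs$origin == "published") &&
          sum(recs$origin == "published") > 3) {
        ss <- tryCatch(small_study_test(recs, data$A),
                       error = function(e) NULL)
        tl <- tryCatch(time_lag_test(recs, data$A),
                       error = function(e) NULL)
        row$small_study_z <- if (is.null(ss)) NA_real_ else ss$z
        row$small_study_p <- if (is.null(ss)) NA_real_ else ss$p_value
        row$time_lag_z <- if (is.null(tl)) NA_real_ else tl$z
        row$time_lag_p <- if (is.null(tl)) NA_real_ else tl$p_value
      }
      rows[[key]] <- row
    }
  }
  lrt_table <- do.call(rbind, rows)
  rownames(lrt_table) <- NULL
  list(lrt_table = lrt_table, models = models, suite = suite)
}

#' Run the full meta-analytic pipeline
#'
#' For each of the four steepness algorithms, effect sizes are built against
#' that method's cardinal ranks and against its ordinal ranks (8 models);
#' each full model regresses Fisher-Z on the method's steepness plus the 7
#' control moderators, and is compared to the control model without
#' steepness via an ML likelihood-ratio test. Q_M, Q_E, phylogenetic signal,
#' and (when published records exist) small-study and time-lag bias tests
#' are reported per model.
#'
#' @param dataset A `steeprank_dataset` ([load_dataset()]) or raw-level
#'   `sim_dataset`.
#' @param config A [pipeline_config()].
#' @return An `analysis_report`: `lrt_table` (8 rows), `models`, `n_records`,
#'   `exclusions`, `seed`.
#' @export
run_full_analysis <- function(dataset, config = pipeline_config()) {
  data <- as_steeprank_dataset(dataset)
  res <- analysis_loop(data, config,
                       predictors_full = c("steepness", control_predictors),
                       predictors_control = control_predictors)
  structure(list(lrt_table = res$lrt_table, models = res$models,
                 n_records = nrow(data$records),
                 exclusions = data$exclusions, seed = config$seed,
                 variant = "full"),
            class = "analysis_report")
}

#' Restricted rerun: significantly linear hierarchies only
#'
#' Each group's matrix is screened with [linearity_test()]; groups whose
#' hierarchy is not significantly linear (p >= alpha) are dropped, and the
#' full analysis is repeated on the remainder. Pre-computed rows must carry
#' a logical `linear` column.
#'
#' @inheritParams run_full_analysis
#' @return An `analysis_report` with `linearity` (per-group results) and
#'   `n_removed`.
#' @export
run_restricted <- function(dataset, config = pipeline_config()) {
  data <- as_steeprank_dataset(dataset)
  rec <- data$records
  keep_group <- logical(nrow(rec))
  lin <- list()
  for (g in unique(rec$group)) {
    rows_g <- rec$group == g
    if (all(rec$precomputed[rows_g])) {
      if (is.null(rec$linear)) {
        stop("precomputed rows need a 'linear' flag for the restricted rerun",
             call. = FALSE)
      }
      keep_group[rows_g] <- rec$linear[rows_g]
    } else {
      lt <- linearity_test(data$matrices[[g]],
                           rand_unknown = config$linearity$rand_unknown,
                           rand_null = config$linearity$rand_null,
                           seed = config$seed + 104729L +
                             match(g, unique(rec$group)),
                           alpha = config$alpha)
      lin[[g]] <- lt
      keep_group[rows_g] <- lt$is_linear
    }
  }
  if (!any(keep_group)) {
    stop("no group with a significantly linear hierarchy", call. = FALSE)
  }
  data$records <- rec[keep_group, , drop = FALSE]
  data$matrices <- data$matrices[intersect(names(data$matrices),
                                           unique(data$records$group))]
  data$benefits <- data$benefits[intersect(names(data$benefits),
                                           data$records$record_id)]
  rep_ <- run_full_analysis(data, config)
  rep_$variant <- "restricted"
  rep_$linearity <- lin
  rep_$n_removed <- sum(!keep_group)
  rep_
}

#' Steepness-by-moderator interaction models
#'
#' The full model adds steepness, the factor, and their product columns; the
#' control model drops all three (the remaining 6 moderators stay). The LRT
#' df is the number of added columns: for a 3-level factor, 1 (steepness) +
#' 2 (dummies) + 2 (products) = 5.
#'
#' @inheritParams run_full_analysis
#' @param factor One of `"dispersal"`, `"setting"`, `"sex"`.
#' @return An `analysis_report` (8 rows).
#' @export
run_interaction_models <- function(dataset, config = pipeline_config(),
                                   factor = c("dispersal", "setting", "sex")) {
  factor <- match.arg(factor)
  data <- as_steeprank_dataset(dataset)
  if (length(unique(data$records[[factor]])) < 2) {
    stop("factor ", factor, " has a single observed level", call. = FALSE)
  }
  res <- analysis_loop(
    data, config,
    predictors_full = c("steepness", control_predictors),
    predictors_control = setdiff(control_predictors, factor),
    interaction = c("steepness", factor), bias_tests = FALSE)
  structure(list(lrt_table = res$lrt_table, models = res$models,
                 n_records = nrow(data$records),
                 exclusions = data$exclusions, seed = config$seed,
                 variant = paste0("interaction_", factor)),
            class = "analysis_report")
}

#' Simpler models: steepness only
#'
#' Full models with steepness as the single moderator against intercept-only
#' controls, same random structure.
#'
#' @inheritParams run_full_analysis
#' @export
run_simpler_models <- function(dataset, config = pipeline_config()) {
  data <- as_steeprank_dataset(dataset)
  res <- analysis_loop(data, config,
                       predictors_full = "steepness",
                       predictors_control = character(0),
                       bias_tests = FALSE)
  structure(list(lrt_table = res$lrt_table, models = res$models,
                 n_records = nrow(data$records),
                 exclusions = data$exclusions, seed = config$seed,
                 variant = "simple"),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("steeprank analysis [%s]: %d records, seed %d\n", x$variant,
              x$n_records, x$seed))
  tab <- x$lrt_table
  tab$chi2 <- round(tab$chi2, 3)
  tab$p_value <- round(tab$p_value, 4)
  print(tab[, c("method", "rank_basis", "k", "chi2", "df", "p_value")])
  invisible(x)
}

#' Write an analysis report to files
#'
#' Emits `<prefix>_lrt.csv` (the 8-row LRT table with Q_M, Q_E, signal, and
#' bias columns), `<prefix>.json` (full report), and `<prefix>.txt`
#' (human-readable summary including the exclusion log, seed, and a config
#' hash).
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @param prefix File name prefix (default the report variant).
#' @param config The [pipeline_config()] used (hashed for provenance).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, prefix = report$variant,
                         config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, paste0(prefix, "_lrt.csv"))
  utils::write.csv(report$lrt_table, csv_path, row.names = FALSE)
  cfg_hash <- if (is.null(config)) NA_character_ else {
    sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) %%
      1000000L
  }
  json_path <- file.path(dir, paste0(prefix, ".json"))
  payload <- list(variant = report$variant, seed = report$seed,
                  n_records = report$n_records,
                  config_hash = cfg_hash,
                  version = as.character(utils::packageVersion("steeprank")),
                  lrt_table = report$lrt_table,
                  exclusions = report$exclusions)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  txt_path <- file.path(dir, paste0(prefix, ".txt"))
  con <- file(txt_path, "w")
  on.exit(close(con))
  writeLines(sprintf("steeprank report [%s]  seed=%d  records=%d  config=%s",
                     report$variant, report$seed, report$n_records,
                     as.character(cfg_hash)), con)
  writeLines(utils::capture.output(print(report$lrt_table)), con)
  if (nrow(report$exclusions) > 0) {
    writeLines("exclusions:", con)
    writeLines(sprintf("  %s: %s", report$exclusions$record_id,
                       report$exclusions$reason), con)
  } else {
    writeLines("exclusions: none", con)
  }
  invisible(c(csv_path, json_path, txt_path))
}

#' Dataset composition counts
#'
#' Totals mirroring how compiled effect-size datasets are summarized: data
#' points, published data points, species, groups, and direct-benefit
#' records.
#'
#' @param dataset A `steeprank_dataset` or `sim_dataset`.
#' @return Named list of counts.
#' @export
dataset_counts <- function(dataset) {
  data <- as_steeprank_dataset(dataset)
  rec <- data$records
  list(n_records = nrow(rec),
       n_published = sum(rec$origin == "published"),
       n_species = length(unique(rec$species)),
       n_groups = length(unique(rec$group)),
       n_direct = sum(rec$benefit_category == "direct"))
}
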