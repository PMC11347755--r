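#' Pearson correlation between benefits and dominance scores
#'
#' Perfect correlations are winsorized to `1 - 1e-6` in absolute value (with
#' a warning) so they survive the Fisher transform; groups with fewer than 4
#' individuals are rejected, matching the sample-size exclusion rule applied
#' when assembling effect-size datasets.
#'
#' @param benefits Numeric benefit values.
#' @param scores Numeric cardinal scores, paired with `benefits`.
#' @return Correlation in (-1, 1).
#' @export
pearson_r <- function(benefits, scores) {
  stopifnot(length(benefits) == length(scores))
  if (length(benefits) < 4) {
    stop("sample size of less than 4 individuals", call. = FALSE)
  }
  if (stats::sd(benefits) == 0 || stats::sd(scores) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  winsorize_r(stats::cor(benefits, scores))
}

winsorize_r <- function(r, limit = 1 - 1e-6) {
  if (abs(r) >= limit) {
    warning("|r| >= 1 winsorized to ", format(limit), call. = FALSE)
    r <- sign(r) * limit
  }
  r
}

#' Signed correlation against ordinal ranks
#'
#' Ordinal rank 1 is the most dominant individual, so the raw correlation of
#' benefit with rank number has its sign inverted: a positive return value
#' means dominants obtain more benefits than subordinates.
#'
#' @param benefits Numeric benefit values.
#' @param ordinal An `ordinal_ranks` data frame (or numeric rank vector).
#' @return Correlation in (-1, 1), positive when benefits accrue to dominants.
#' @export
signed_ordinal_r <- function(benefits, ordinal) {
  rk <- if (is.numeric(ordinal)) ordinal else ordinal$rank
  -pearson_r(benefits, rk)
}

#' Correlation coefficient from a chi-square statistic
#'
#' `r = direction * sqrt(chi2 / n)`, the phi-coefficient conversion used by
#' standard effect-size calculators. The direction of the association is not
#' recoverable from chi-square alone and must be supplied.
#'
#' @param chi2 Chi-square statistic (>= 0).
#' @param n Total sample size.
#' @param direction +1 or -1.
#' @export
r_from_chi_square <- function(chi2, n, direction) {
  stopifnot(chi2 >= 0, n > 0, direction %in% c(-1, 1))
  if (chi2 > n) {
    warning("chi2 > n: |r| capped below 1", call. = FALSE)
    return(direction * (1 - 1e-6))
  }
  direction * sqrt(chi2 / n)
}

#' Correlation coefficient from two group means and SDs
#'
#' Pooled-SD Cohen's d converted to r with the unequal-group correction
#' `a = (n1 + n2)^2 / (n1 * n2)` (a = 4 for equal groups):
#' `r = d / sqrt(d^2 + a)`.
#'
#' @param m1,sd1,n1 Mean, SD, and size of group 1.
#' @param m2,sd2,n2 Mean, SD, and size of group 2.
#' @export
r_from_means_sd <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2, n1 + n2 >= 4)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (m1 - m2) / sp
  a <- (n1 + n2)^2 / (n1 * n2)
  d / sqrt(d^2 + a)
}

#' Fisher's Z transform and its sampling variance
#'
#' `z = atanh(r)` stabilizes the variance of a correlation; with n paired
#' observations the sampling variance of z is `1 / (n - 3)`.
#'
#' @param r Correlation with |r| < 1.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| >= 1: winsorize upstream", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @param n Sample size (>= 4).
#' @export
z_variance <- function(n) {
  if (any(n <= 3)) stop("n must exceed 3 for a finite Fisher-Z variance",
                        call. = FALSE)
  1 / (n - 3)
}

#' Aggregate multiple measures or matrices
#'
#' When a group contributes several benefit measures (e.g. two feeding
#' proxies) in the same study period, their correlations are averaged on the
#' r scale before the Fisher transform; when several interaction matrices
#' cover the period, their steepness values are averaged on the steepness
#' scale.
#'
#' @param rs Correlations to average.
#' @export
aggregate_measures <- function(rs) {
  if (length(rs) == 0) stop("empty list of correlations", call. = FALSE)
  mean(rs)
}

#' @rdname aggregate_measures
#' @param values Steepness values to average.
#' @export
aggregate_steepness <- function(values) {
  if (length(values) == 0) stop("empty list of steepness values", call. = FALSE)
  mean(values)
}

benefit_types <- c("fecundity", "infant_survival", "mating_success",
                   "feeding_success")
direct_types <- c("fecundity", "infant_survival")

#' Benefit category from benefit type
#'
#' Fecundity and infant survival are direct fitness benefits; mating and
#' feeding success are indirect.
#' @param benefit_type One of `fecundity`, `infant_survival`,
#'   `mating_success`, `feeding_success`.
#' @export
benefit_category <- function(benefit_type) {
  stopifnot(all(benefit_type %in% benefit_types))
  ifelse(benefit_type %in% direct_types, "direct", "indirect")
}

moderator_fields <- c("benefit_category", "duration_months", "setting",
                      "sex", "dispersal", "social_org", "origin")

moderator_levels <- list(
  benefit_category = c("direct", "indirect"),
  setting = c("wild", "provisioned", "captive"),
  sex = c("female", "male", "both"),
  dispersal = c("female_philopatry", "male_philopatry", "none"),
  social_org = c("OMG", "MMG", "MLS"),
  origin = c("published", "unpublished")
)

#' Build one effect-size record
#'
#' Packs a correlation (possibly aggregated over measures), its Fisher-Z
#' transform, the sampling variance, sample size, identity, and the seven
#' moderators into a single record. Spearman coefficients taken from the
#' literature are accepted as-is on the r scale.
#'
#' @param group Group id.
#' @param species Species id (tree tip label).
#' @param r Correlation(s); averaged via [aggregate_measures()] if several.
#' @param n Sample size (>= 4; smaller groups are an error — exclude them
#'   upstream with a logged reason).
#' @param rank_basis `"cardinal"` or `"ordinal"`.
#' @param method Steepness/rank algorithm label.
#' @param steepness Group hierarchy steepness value(s); averaged if several.
#' @param moderators Named list with `benefit_category`, `duration_months`,
#'   `setting`, `sex`, `dispersal`, `social_org`, `origin`, and `pub_year`
#'   for published records.
#' @param record_id Optional record identifier.
#' @return A one-row data frame of class `effect_size_record`.
#' @export
build_record <- function(group, species, r, n, rank_basis, method, steepness,
                         moderators, record_id = NULL) {
  if (n < 4) stop("sample size of less than 4 individuals (n = ", n, ")",
                  call. = FALSE)
  missing_mod <- setdiff(moderator_fields, names(moderators))
  if (length(missing_mod) > 0) {
    stop("missing moderator field(s): ", paste(missing_mod, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(moderator_levels)) {
    if (!moderators[[f]] %in% moderator_levels[[f]]) {
      stop("invalid level '", moderators[[f]], "' for moderator ", f,
           call. = FALSE)
    }
  }
  if (identical(moderators$origin, "published") &&
      is.null(moderators$pub_year)) {
    stop("published records need pub_year", call. = FALSE)
  }
  r <- winsorize_r(aggregate_measures(r))
  out <- data.frame(
    record_id = if (is.null(record_id)) paste0(group, "_", method, "_", rank_basis)
                else record_id,
    group = group, species = species,
    r = r, z_r = fisher_z(r), v = z_variance(n), n = n,
    rank_basis = rank_basis, method = method,
    steepness = aggregate_steepness(steepness),
    benefit_category = moderators$benefit_category,
    duration_months = moderators$duration_months,
    setting = moderators$setting, sex = moderators$sex,
    dispersal = moderators$dispersal, social_org = moderators$social_org,
    origin = moderators$origin,
    pub_year = if (is.null(moderators$pub_year)) NA_real_
               else moderators$pub_year,
    stringsAsFactors = FALSE)
  class(out) <- c("effect_size_record", "data.frame")
  out
}
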