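#' Build the design for a multilevel meta-regression
#'
#' The response is Fisher's Z (`z_r`) with known sampling variance `v`.
#' Continuous predictors are standardized (mean 0, SD 1); each categorical
#' predictor is expanded to dummy variables with its first (reference) level
#' dropped and the retained dummies mean-centered. Centering keeps the
#' intercept interpretable as the overall mean effect and reduces
#' collinearity with interaction terms. With the steepness predictor and all
#' seven control moderators at their full level sets, the design has 13
#' columns (intercept, steepness, benefit category, duration, setting x2,
#' sex x2, dispersal x2, social organization x2, origin).
#'
#' @param records Data frame of effect-size records ([build_record()] rows or
#'   the `records` element of a simulated dataset).
#' @param predictors Character vector of column names: continuous columns
#'   (e.g. `"steepness"`, `"duration_months"`, `"inv_sqrt_n"`, `"pub_year"`)
#'   and/or categorical moderators (`"benefit_category"`, `"setting"`,
#'   `"sex"`, `"dispersal"`, `"social_org"`, `"origin"`). May be empty for an
#'   intercept-only model.
#' @param interaction Optional `c(continuous, factor)` pair; adds the product
#'   of the standardized continuous column with each centered dummy of the
#'   factor. Both main effects must be in `predictors`.
#' @return A list of class `meta_design`: `y`, `v`, `X`, `species`, `group`,
#'   `k`, `p`, `term_cols` (column names added per predictor).
#' @export
build_design <- function(records, predictors = character(0),
                         interaction = NULL) {
  k <- nrow(records)
  stopifnot(k >= 2, all(records$v > 0))
  X <- matrix(1, k, 1, dimnames = list(NULL, "intercept"))
  term_cols <- list(intercept = "intercept")
  std <- list()  # standardized continuous columns by name
  for (pr in predictors) {
    val <- records[[pr]]
    if (is.null(val)) stop("unknown predictor column: ", pr, call. = FALSE)
    if (is.numeric(val)) {
      if (stats::sd(val) == 0) {
        stop("zero-variance continuous predictor: ", pr, call. = FALSE)
      }
      col <- (val - mean(val)) / stats::sd(val)
      std[[pr]] <- col
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- pr
      term_cols[[pr]] <- pr
    } else {
      levs <- if (pr %in% names(moderator_levels)) {
        intersect(moderator_levels[[pr]], unique(as.character(val)))
      } else sort(unique(as.character(val)))
      if (length(levs) < 2) {
        stop("moderator ", pr, " has a single observed level", call. = FALSE)
      }
      dums <- vapply(levs[-1], function(lv) {
        d <- as.numeric(val == lv)
        d - mean(d)
      }, numeric(k))
      cn <- paste0(pr, "_", levs[-1])
      colnames(dums) <- cn
      X <- cbind(X, dums)
      term_cols[[pr]] <- cn
    }
  }
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2)
    cont <- interaction[1]; fac <- interaction[2]
    if (is.null(std[[cont]])) {
      stop("interaction continuous term '", cont, "' must be in predictors",
           call. = FALSE)
    }
    fac_cols <- term_cols[[fac]]
    if (is.null(fac_cols)) {
      stop("interaction factor '", fac, "' must be in predictors",
           call. = FALSE)
    }
    prod_cols <- X[, fac_cols, drop = FALSE] * std[[cont]]
    colnames(prod_cols) <- paste0(cont, ":", fac_cols)
    X <- cbind(X, prod_cols)
    term_cols[[paste(cont, fac, sep = ":")]] <- colnames(prod_cols)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(y = records$z_r, v = records$v, X = X,
                 species = as.character(records$species),
                 group = as.character(records$group),
                 k = k, p = ncol(X), term_cols = term_cols),
            class = "meta_design")
}

# component covariance matrices for the three random effects
meta_components <- function(design, A) {
  sp <- design$species
  gr <- design$group
  miss <- setdiff(unique(sp), rownames(A))
  if (length(miss) > 0) {
    stop("species missing from phylogenetic correlation matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  list(species = outer(sp, sp, "=="),
       group = outer(gr, gr, "=="),
       phylo = A[sp, sp, drop = FALSE])
}

# Gaussian log-likelihood machinery. sigma2 is length-3 (species, group,
# phylo); `free` marks estimated components, the rest are pinned at 0.
meta_loglik_parts <- function(sigma2, design, comps) {
  V <- diag(design$v, design$k)
  for (c_ in 1:3) {
    if (sigma2[c_] > 0) V <- V + sigma2[c_] * comps[[c_]]
  }
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  logdetV <- 2 * sum(log(diag(L)))
  Vinv <- chol2inv(L)
  X <- design$X
  XtVi <- crossprod(X, Vinv)
  M <- XtVi %*% X                      # X' Vinv X
  Mchol <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Mchol)) return(NULL)
  Minv <- chol2inv(Mchol)
  beta <- drop(Minv %*% (XtVi %*% design$y))
  r <- design$y - drop(X %*% beta)
  Vir <- drop(Vinv %*% r)
  quad <- sum(r * Vir)
  list(V = V, Vinv = Vinv, logdetV = logdetV, beta = beta, r = r, Vir = Vir,
       quad = quad, Minv = Minv, logdetM = 2 * sum(log(diag(Mchol))),
       XtVi = XtVi)
}

meta_ll_value <- function(parts, design, method) {
  k <- design$k; p <- design$p
  if (method == "ML") {
    -0.5 * (k * log(2 * pi) + parts$logdetV + parts$quad)
  } else {
    -0.5 * ((k - p) * log(2 * pi) + parts$logdetV + parts$logdetM +
              parts$quad)
  }
}

#' Fit a phylogenetic multilevel meta-regression
#'
#' Model: `y_i = x_i' beta + u_species + u_group + u_phylo + e_i` with
#' `u_species ~ N(0, sigma2_s I)`, `u_group ~ N(0, sigma2_g I)`,
#' `u_phylo ~ N(0, sigma2_p A)` (A the phylogenetic correlation matrix), and
#' known sampling variances `e_i ~ N(0, v_i)` — so each observation is
#' weighted by the inverse of its effect-size variance. Variance components
#' are maximized over [0, Inf)^3 by multi-start bounded quasi-Newton on the
#' log-variance scale with analytic gradients; `beta` is the GLS solution at
#' the optimum.
#'
#' @param design A [build_design()] result.
#' @param A Phylogenetic correlation matrix (species in rownames).
#' @param method `"ML"` (required for fixed-effect model comparison) or
#'   `"REML"` (variance reporting).
#' @param fix_zero Variance components pinned at 0: any subset of
#'   `c("species", "group", "phylo")` (e.g. `"phylo"` gives the
#'   non-phylogenetic model used by the signal test; all three give the
#'   fixed-effects inverse-variance model).
#' @param n_starts Number of optimizer starts (default 5).
#' @return A `meta_fit` list: `beta`, `se`, `vcov_beta`, `sigma2`, `loglik`,
#'   `method`, `qm` (omnibus moderator test), `k`, `p`, `convergence`.
#' @export
meta_fit <- function(design, A, method = c("ML", "REML"),
                     fix_zero = character(0), n_starts = 5) {
  method <- match.arg(method)
  stopifnot(inherits(design, "meta_design"), design$k > design$p,
            all(fix_zero %in% c("species", "group", "phylo")))
  comps <- meta_components(design, A)
  free <- !(c("species", "group", "phylo") %in% fix_zero)
  nfree <- sum(free)
  if (nfree == 0) {
    parts <- meta_loglik_parts(c(0, 0, 0), design, comps)
    return(finish_meta_fit(parts, numeric(3), design, method, 0L))
  }

  obj_env <- new.env()
  eval_at <- function(eta) {
    key <- paste(format(eta, digits = 17), collapse = ",")
    if (identical(obj_env$key, key)) return(obj_env$parts)
    sigma2 <- numeric(3)
    sigma2[free] <- exp(eta)
    parts <- meta_loglik_parts(sigma2, design, comps)
    obj_env$key <- key
    obj_env$parts <- parts
    obj_env$sigma2 <- sigma2
    parts
  }
  fn <- function(eta) {
    parts <- eval_at(eta)
    if (is.null(parts)) return(1e10)
    -meta_ll_value(parts, design, method)
  }
  gr <- function(eta) {
    parts <- eval_at(eta)
    if (is.null(parts)) return(rep(0, nfree))
    sigma2 <- obj_env$sigma2
    g <- numeric(nfree)
    j <- 0
    for (c_ in 1:3) {
      if (!free[c_]) next
      j <- j + 1
      G <- comps[[c_]]
      tr_term <- sum(parts$Vinv * G)
      if (method == "REML") {
        B <- parts$XtVi %*% G %*% t(parts$XtVi)   # X'Vinv G Vinv X
        tr_term <- tr_term - sum(parts$Minv * B)
      }
      quad_term <- drop(crossprod(parts$Vir, G %*% parts$Vir))
      # d(-ll)/d eta_j = 0.5 * (tr - quad) * sigma2_j
      g[j] <- 0.5 * (tr_term - quad_term) * sigma2[c_]
    }
    g
  }

  starts <- list(rep(log(0.01), nfree), rep(log(1e-4), nfree),
                 rep(log(0.1), nfree))
  if (nfree >= 2) {
    s4 <- rep(log(1e-4), nfree); s4[1] <- log(0.1)
    s5 <- rep(log(1e-4), nfree); s5[nfree] <- log(0.1)
    starts <- c(starts, list(s4, s5))
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = -30, upper = 10,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("variance-component optimization failed to converge", call. = FALSE)
  }
  sigma2 <- numeric(3)
  sigma2[free] <- exp(best$par)
  sigma2[sigma2 < 1e-10] <- 0
  parts <- meta_loglik_parts(sigma2, design, comps)
  finish_meta_fit(parts, sigma2, design, method, best$convergence)
}

finish_meta_fit <- function(parts, sigma2, design, method, convergence) {
  names(sigma2) <- c("species", "group", "phylo")
  ll <- meta_ll_value(parts, design, method)
  beta <- parts$beta
  names(beta) <- colnames(design$X)
  vcov_beta <- parts$Minv
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  se <- sqrt(diag(vcov_beta))
  fit <- structure(list(beta = beta, se = se, vcov_beta = vcov_beta,
                        sigma2 = sigma2, loglik = ll, method = method,
                        k = design$k, p = design$p,
                        term_cols = design$term_cols,
                        convergence = convergence), class = "meta_fit")
  if (design$p > 1) fit$qm <- omnibus_qm(fit)
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("multilevel meta-regression (%s): k = %d, p = %d, logLik = %.4f\n",
              x$method, x$k, x$p, x$loglik))
  coefs <- data.frame(estimate = x$beta, se = x$se,
                      z = x$beta / x$se,
                      p = 2 * stats::pnorm(-abs(x$beta / x$se)))
  print(round(coefs, 4))
  cat("variance components:",
      paste(sprintf("%s = %.4f", names(x$sigma2), x$sigma2), collapse = ", "),
      "\n")
  if (!is.null(x$qm)) {
    cat(sprintf("Q_M(df = %d) = %.3f, p = %.4g\n", x$qm$df, x$qm$statistic,
                x$qm$p_value))
  }
  invisible(x)
}

#' Log-likelihood ratio test between nested meta-regressions
#'
#' Both fits must use ML (REML likelihoods are not comparable across
#' fixed-effect structures). The statistic `2 * (ll_full - ll_control)` is
#' clamped at 0 and referred to a chi-square with df equal to the difference
#' in fixed-parameter count.
#'
#' @param full,control `meta_fit` objects with the same random structure.
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, control) {
  if (full$method != "ML" || control$method != "ML") {
    stop("LRT between fixed-effect structures requires ML fits", call. = FALSE)
  }
  if (full$k != control$k) stop("fits use different data", call. = FALSE)
  df <- full$p - control$p
  if (df < 0) stop("models are not nested (full must add parameters)",
                   call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - control$loglik))
  p <- if (df == 0) as.numeric(chi2 <= 1e-8)  # identical designs
       else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Omnibus moderator test
#'
#' Wald chi-square over all non-intercept coefficients:
#' `Q_M = b' Cov(b)^-1 b` with df equal to the number of moderator
#' coefficients.
#'
#' @param fit A `meta_fit`.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
omnibus_qm <- function(fit) {
  idx <- which(names(fit$beta) != "intercept")
  if (length(idx) == 0) stop("intercept-only model has no moderators",
                             call. = FALSE)
  b <- fit$beta[idx]
  Vb <- fit$vcov_beta[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(Vb, b)))
  list(statistic = stat, df = length(idx),
       p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Residual heterogeneity test
#'
#' Fits the fixed-effects model with weights `1/v_i` only (no random
#' effects); `Q_E` is the weighted residual sum of squares, chi-square with
#' `k - p` df under homogeneity.
#'
#' @param design A [build_design()] result.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
qe_test <- function(design) {
  w <- 1 / design$v
  fit <- stats::lm.wfit(design$X, design$y, w)
  qe <- sum(w * fit$residuals^2)
  df <- design$k - design$p
  list(statistic = qe, df = df,
       p_value = stats::pchisq(qe, df, lower.tail = FALSE))
}

#' Phylogenetic signal of a fitted model
#'
#' Pagel's lambda analogue for the multilevel setting: the share of the total
#' random-effect variance attributable to the tree-structured component,
#' `sigma2_phylo / (sigma2_species + sigma2_group + sigma2_phylo)` (0 when
#' all components are 0). Significance is a likelihood-ratio test against
#' the same model with `sigma2_phylo` pinned at 0, referred to chi-square
#' with 1 df (or, optionally, the 50:50 boundary mixture of chi2_0 and
#' chi2_1).
#'
#' @param design A [build_design()] result.
#' @param A Phylogenetic correlation matrix.
#' @param method Likelihood flavor for both fits (default `"ML"`).
#' @param boundary_mixture Use the boundary null mixture for the p-value.
#' @return A list: `lambda`, `chi2`, `p_value`, `fit`, `fit_nophylo`.
#' @export
phylo_signal <- function(design, A, method = "ML", boundary_mixture = FALSE) {
  fit <- meta_fit(design, A, method = method)
  fit0 <- meta_fit(design, A, method = method, fix_zero = "phylo")
  tot <- sum(fit$sigma2)
  lambda <- if (tot > 0) unname(fit$sigma2["phylo"]) / tot else 0
  chi2 <- max(0, 2 * (fit$loglik - fit0$loglik))
  p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  if (boundary_mixture) p <- if (chi2 == 0) 1 else 0.5 * p
  list(lambda = lambda, chi2 = chi2, p_value = p, fit = fit,
       fit_nophylo = fit0)
}

bias_test <- function(records, A, column, method = "ML") {
  pub <- records[records$origin == "published", , drop = FALSE]
  if (nrow(pub) == 0) stop("no published records", call. = FALSE)
  design <- build_design(pub, predictors = column)
  fit <- meta_fit(design, A, method = method)
  z <- unname(fit$beta[column] / fit$se[column])
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       beta = unname(fit$beta[column]), se = unname(fit$se[column]),
       k = nrow(pub), fit = fit)
}

#' Publication-bias regressions
#'
#' Small-study test: meta-regression of the published effect sizes on the
#' standardized `sqrt(1/n)` as the only fixed factor (random structure
#' unchanged); a positive significant slope means smaller studies report
#' larger effects. Time-lag test: same with the standardized publication
#' year.
#'
#' @param records Effect-size records including an `origin` column.
#' @param A Phylogenetic correlation matrix.
#' @param method Likelihood flavor (default `"ML"`).
#' @return A list: `z`, `p_value`, `beta`, `se`, `k`, `fit`.
#' @export
small_study_test <- function(records, A, method = "ML") {
  records$inv_sqrt_n <- sqrt(1 / records$n)
  bias_test(records, A, "inv_sqrt_n", method)
}

#' @rdname small_study_test
#' @export
time_lag_test <- function(records, A, method = "ML") {
  pub <- records[records$origin == "published", , drop = FALSE]
  if (nrow(pub) > 0 && (anyNA(pub$pub_year) ||
                        stats::sd(pub$pub_year) == 0)) {
    stop("publication year missing or constant in published records",
         call. = FALSE)
  }
  bias_test(records, A, "pub_year", method)
}
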