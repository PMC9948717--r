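#' Add log-scale columns to a pair table
#'
#' The regression stages model natural-log biomass against natural-log
#' Bray-Curtis (and log environmental covariates, matching the usual
#' log-log specification). Pairs with `bray_curtis == 0` have no defined
#' log beta diversity and are dropped with a warning; non-positive
#' covariate values become `NA`.
#'
#' @param pairs pair table from [build_pair_table()].
#' @param log_env also log-transform the environmental covariate means.
#' @return The pair table with `log_summed_biomass`, `log_bray_curtis`
#'   (and `log_<covariate>` columns when `log_env`), zero-dissimilarity
#'   pairs removed.
#' @export
prepare_pairs <- function(pairs, log_env = TRUE) {
  zero <- !is.na(pairs$bray_curtis) & pairs$bray_curtis <= 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with Bray-Curtis 0 dropped from log-scale fits")
    pairs <- pairs[!zero, , drop = FALSE]
  }
  pairs$log_summed_biomass <- log(pairs$summed_biomass)
  pairs$log_bray_curtis <- log(pairs$bray_curtis)
  if (log_env) {
    for (v in intersect(c(.env_vars, "hnf_biomass"), names(pairs))) {
      x <- pairs[[v]]
      x[!is.na(x) & x <= 0] <- NA
      pairs[[paste0("log_", v)]] <- log(x)
    }
  }
  pairs
}

# coefficient table (term, estimate, se, p) from an lm or lmerTest fit
.coef_table <- function(fit) {
  s <- stats::coef(summary(fit))
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], p_value = s[, ncol(s)],
             row.names = NULL)
}

#' Per-cruise beta-diversity effects (GLM stage)
#'
#' For each cruise, ordinary least squares of log summed pair biomass on
#' log pair Bray-Curtis over the cruise's site pairs. The fitted slope is
#' that cruise's beta-diversity effect — the unit of the cross-cruise test.
#'
#' @param pairs pair table; transformed internally via [prepare_pairs()]
#'   if the log columns are absent.
#' @param alpha significance level for flagging slopes (default 0.05).
#' @return A `data.frame` of class `cruise_effects`: `cruise_id`, `slope`,
#'   `se`, `p_value`, `significant`, `n_pairs`, and `mean_beta_mpti`
#'   (cruise mean of the pairs' `beta_mpti`, `NaN` if unfilled). Cruises
#'   with fewer than 3 usable pairs are skipped with a warning; a cruise
#'   whose regressor has zero variance is a fit error.
#' @export
fit_cruise_slopes <- function(pairs, alpha = 0.05) {
  if (!"log_summed_biomass" %in% names(pairs)) pairs <- prepare_pairs(pairs)
  out <- lapply(split(pairs, pairs$cruise_id), function(d) {
    ok <- is.finite(d$log_summed_biomass) & is.finite(d$log_bray_curtis)
    d <- d[ok, , drop = FALSE]
    if (nrow(d) < 3L) {
      warning("cruise ", d$cruise_id[1] %||% "?",
              " skipped: fewer than 3 usable pairs")
      return(NULL)
    }
    if (stats::var(d$log_bray_curtis) == 0) {
      warning("cruise ", d$cruise_id[1],
              ": zero variance in log Bray-Curtis; cruise skipped")
      return(NULL)
    }
    fit <- stats::lm(log_summed_biomass ~ log_bray_curtis, data = d)
    ct <- .coef_table(fit)
    data.frame(cruise_id = d$cruise_id[1],
               slope = ct$estimate[2], se = ct$se[2],
               p_value = ct$p_value[2],
               significant = ct$p_value[2] < alpha,
               n_pairs = nrow(d),
               mean_beta_mpti = mean(d$beta_mpti, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0)
    stop("no cruise could be fitted: zero variance in log Bray-Curtis or ",
         "fewer than 3 usable pairs in every cruise")
  rownames(out) <- NULL
  structure(out, class = c("cruise_effects", "data.frame"))
}

#' @export
print.cruise_effects <- function(x, ...) {
  cat(sprintf("Per-cruise beta-diversity effects (%d cruises, %d significant at the flagged level)\n",
              nrow(x), sum(x$significant)))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

# fit either a random-intercept LMM (lmerTest) or an OLS model on a
# prepared data frame; falls back to OLS when the random effect is
# singular or only one grouping level is present
.fit_engine <- function(data, response, terms, random) {
  rhs <- if (length(terms) > 0) paste(terms, collapse = " + ") else "1"
  keep <- c(response, terms, random)
  data <- data[stats::complete.cases(data[, keep, drop = FALSE]), ,
               drop = FALSE]
  if (nrow(data) < length(terms) + 2L) stop("too few complete observations")
  use_lmm <- !is.null(random) && length(unique(data[[random]])) >= 2L
  if (use_lmm) {
    f <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", random, ")"))
    fit <- suppressMessages(lmerTest::lmer(f, data = data, REML = TRUE))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-effect fit; falling back to a fixed-intercept model")
      use_lmm <- FALSE
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      re_var <- vc$vcov[vc$grp == random]
      resid_var <- vc$vcov[vc$grp == "Residual"]
      X <- stats::model.matrix(fit)
      var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit)))
      marginal_r2 <- var_fixed / (var_fixed + sum(re_var) + resid_var)
      return(list(fit = fit, model_type = "lmm", data = data,
                  random_variance = sum(re_var),
                  residual_variance = resid_var,
                  marginal_r2 = marginal_r2))
    }
  }
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(f, data = data)
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.vector(X %*% stats::coef(fit)))
  resid_var <- summary(fit)$sigma^2
  list(fit = fit, model_type = "lm", data = data, random_variance = 0,
       residual_variance = resid_var,
       marginal_r2 = var_fixed / (var_fixed + resid_var))
}

#' Mixed-effects regression over site pairs
#'
#' Gaussian linear mixed model on the (log) scale with a random intercept
#' per cruise, fitted by REML; fixed-effect p-values use the Satterthwaite
#' approximation. When the random-intercept variance is estimated singular
#' (or only one cruise is present) the model falls back to a
#' fixed-intercept OLS fit with a warning. The marginal R2 reported is the
#' Nakagawa-Schielzeth fixed-effects variance fraction.
#'
#' @param pairs pair table (run through [prepare_pairs()] if the log
#'   columns are absent).
#' @param terms character vector of fixed-effect column names, e.g.
#'   `"log_bray_curtis"`.
#' @param response response column (default `"log_summed_biomass"`).
#' @param random grouping column for the random intercept (default
#'   `"cruise_id"`; `NULL` for plain OLS).
#' @return An object of class `bef_model`: list with `coefficients`
#'   (`data.frame` term/estimate/se/p_value), `model_type`
#'   (`"lmm"`/`"lm"`), `random_variance`, `residual_variance`,
#'   `marginal_r2`, `n`, `formula`, `selection_trace`, `fit`.
#' @export
fit_mixed <- function(pairs, terms = "log_bray_curtis",
                      response = "log_summed_biomass",
                      random = "cruise_id") {
  if (!response %in% names(pairs) && response == "log_summed_biomass")
    pairs <- prepare_pairs(pairs)
  miss <- setdiff(c(response, terms), names(pairs))
  if (length(miss) > 0)
    stop("columns absent from pair table: ", paste(miss, collapse = ", "))
  for (tm in terms) {
    x <- pairs[[tm]][is.finite(pairs[[tm]])]
    if (length(x) > 0 && stats::var(x) == 0)
      stop("degenerate regressor '", tm, "': zero variance")
  }
  eng <- .fit_engine(pairs, response, terms, random)
  structure(list(coefficients = .coef_table(eng$fit),
                 model_type = eng$model_type,
                 random_variance = eng$random_variance,
                 residual_variance = eng$residual_variance,
                 marginal_r2 = eng$marginal_r2,
                 n = nrow(eng$data),
                 formula = paste(trimws(deparse(stats::formula(eng$fit))),
                                 collapse = " "),
                 selection_trace = data.frame(step = integer(0),
                                              dropped = character(0),
                                              p_value = numeric(0)),
                 fit = eng$fit),
            class = "bef_model")
}

#' @export
print.bef_model <- function(x, ...) {
  cat(sprintf("%s fit: %s  (n = %d, marginal R2 = %.3f)\n",
              toupper(x$model_type), x$formula, x$n, x$marginal_r2))
  print(x$coefficients, digits = 3, row.names = FALSE)
  if (x$model_type == "lmm")
    cat(sprintf("Random intercept variance: %.4f; residual: %.4f\n",
                x$random_variance, x$residual_variance))
  if (nrow(x$selection_trace) > 0) {
    cat("Backward-selection removals:\n")
    print(x$selection_trace, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.bef_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.bef_model <- function(object, ...) object

#' Backward covariate selection around protected terms
#'
#' Starts from the full fixed-effect model and repeatedly refits after
#' removing the non-protected term with the largest p-value >= `alpha`,
#' until every remaining non-protected term is significant. Protected
#' terms (the beta-diversity term, and pooled Shannon diversity in the
#' robustness variant) are never candidates for removal. With
#' `alpha = 0` every non-protected term is dropped in turn down to the
#' protected set; with `alpha = 1` the full model is returned (p-values
#' of exactly 1 do not occur in t tests).
#'
#' @param pairs pair table (or cruise-level table for the cross-cruise
#'   stage).
#' @param terms all candidate fixed-effect columns (including protected).
#' @param protect terms never removed.
#' @param alpha removal threshold (drop while max p >= alpha).
#' @param response,random as in [fit_mixed()].
#' @return The final [fit_mixed()] `bef_model`, with `selection_trace`
#'   recording each removal (step, dropped term, its p-value).
#' @export
backward_select <- function(pairs, terms, protect = "log_bray_curtis",
                            alpha = 0.05, response = "log_summed_biomass",
                            random = "cruise_id") {
  if (!all(protect %in% terms)) terms <- union(protect, terms)
  current <- terms
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0))
  step <- 0L
  repeat {
    model <- fit_mixed(pairs, terms = current, response = response,
                       random = random)
    candidates <- setdiff(current, protect)
    if (length(candidates) == 0) break
    ct <- model$coefficients
    p <- stats::setNames(ct$p_value, ct$term)[candidates]
    worst <- names(which.max(p))
    if (length(worst) == 0 || p[[worst]] < alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p_value = as.numeric(p[[worst]])))
    current <- setdiff(current, worst)
  }
  model$selection_trace <- trace
  model
}

#' Cross-cruise test: beta-diversity effects vs. mean betaMPTI
#'
#' Regresses the per-cruise beta-diversity effects (slopes) on the
#' per-cruise mean betaMPTI, optionally with cruise-level environmental
#' covariates subjected to backward selection (the betaMPTI term is
#' protected). A positive betaMPTI coefficient means the beta-diversity
#' effect strengthens when deterministic assembly selects for
#' phylogenetically dissimilar taxa.
#'
#' @param effects a [fit_cruise_slopes()] table with `mean_beta_mpti`
#'   filled (merge in `pairwise_assembly()$cruise` if needed).
#' @param covariates optional `data.frame` with `cruise_id` plus
#'   cruise-level covariate columns to select over.
#' @param alpha backward-selection threshold.
#' @return A `bef_model` (OLS across cruises).
#' @export
cross_cruise_regression <- function(effects, covariates = NULL,
                                    alpha = 0.05) {
  d <- as.data.frame(effects)
  if (!all(c("slope", "mean_beta_mpti") %in% names(d)))
    stop("effects must contain 'slope' and 'mean_beta_mpti'")
  d <- d[is.finite(d$slope) & is.finite(d$mean_beta_mpti), , drop = FALSE]
  if (!is.null(covariates)) d <- merge(d, covariates, by = "cruise_id")
  if (nrow(d) < 3L) stop("need >= 3 cruises with fitted slopes")
  covs <- if (is.null(covariates)) character(0) else
    setdiff(names(covariates), "cruise_id")
  # keep enough residual df to test the protected term: with few cruises,
  # trailing covariates are excluded from the candidate set up front
  max_covs <- max(0L, nrow(d) - 5L)
  if (length(covs) > max_covs) {
    warning(sprintf(
      "only %d cruises: restricting backward selection to %d of %d covariates",
      nrow(d), max_covs, length(covs)))
    covs <- covs[seq_len(max_covs)]
  }
  backward_select(d, terms = c("mean_beta_mpti", covs),
                  protect = "mean_beta_mpti", alpha = alpha,
                  response = "slope", random = NULL)
}

#' Does beta diversity itself track assembly determinism?
#'
#' Mixed model of log Bray-Curtis on betaMPTI with a cruise random
#' intercept: checks that beta diversity increases when assembly processes
#' select for phylogenetically dissimilar taxa (less negative betaMPTI).
#'
#' @param pairs pair table with `beta_mpti` filled.
#' @return A `bef_model`.
#' @export
beta_vs_assembly <- function(pairs) {
  if (!"log_bray_curtis" %in% names(pairs)) pairs <- prepare_pairs(pairs)
  fit_mixed(pairs, terms = "beta_mpti", response = "log_bray_curtis",
            random = "cruise_id")
}
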