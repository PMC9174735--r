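#' Fixed- and random-effects specification for the rank model
#'
#' The full model contains the main predictors of interest — role,
#' configuration, feasibility and time distance — with the
#' role x configuration x feasibility interaction (and all lower-order
#' terms) and the role x time-distance interaction, plus controls. The null
#' model keeps the identical random structure and all controls but drops
#' every term containing a main predictor; under this default the
#' full-vs-null comparison has 13 fixed-effect degrees of freedom.
#'
#' Random structure: crossed random intercepts for male and coalition event,
#' uncorrelated random slopes for time distance (by male and by event) and
#' feasibility (by male). When a structure is not identifiable the slopes
#' are dropped in the order given by `reductions`.
#'
#' @param main character vector of main-predictor formula terms.
#' @param controls character vector of control terms; controls whose
#'   columns are absent, all-missing or single-level are dropped at fit
#'   time.
#' @param random character vector of random-effects terms.
#' @param reductions list of progressively simpler random structures tried
#'   on non-identifiability (first element should equal `random`).
#' @return a `rank_model_spec` list.
#' @export
rank_model_spec <- function(
    main = c("role * configuration * feasibility_z", "role * days_z"),
    controls = c("rank0_z", "age_z", "aggr_z", "stability_z",
                 "competition_z", "ac_z", "group"),
    random = c("(1 + days_z + feasibility_z || male)",
               "(1 + days_z || event_id)"),
    reductions = list(
      c("(1 + days_z + feasibility_z || male)", "(1 + days_z || event_id)"),
      c("(1 + days_z || male)", "(1 + days_z || event_id)"),
      c("(1 + days_z || male)", "(1 | event_id)"),
      c("(1 | male)", "(1 | event_id)"))) {
  structure(list(main = main, controls = controls, random = random,
                 reductions = reductions),
            class = "rank_model_spec")
}

usable_controls <- function(data, controls) {
  keep <- vapply(controls, function(tm) {
    vars <- all.vars(stats::as.formula(paste("~", tm)))
    for (v in vars) {
      if (!v %in% names(data)) return(FALSE)
      x <- data[[v]]
      if (all(is.na(x))) return(FALSE)
      if (length(unique(stats::na.omit(x))) < 2) return(FALSE)
    }
    TRUE
  }, logical(1))
  controls[keep]
}

wrap_fit <- function(fit, role, method, reductions_used = character()) {
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  structure(list(
    fit = fit, role = role, method = method,
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], stat = co[, 3],
                              row.names = NULL),
    n_fixed = length(lme4::fixef(fit)),
    logLik = as.numeric(stats::logLik(fit)),
    varcomp = vc[, c("grp", "var1", "sdcor")],
    singular = lme4::isSingular(fit),
    converged = is.null(conv_msgs) || length(conv_msgs) == 0,
    messages = conv_msgs %||% character(),
    reductions_used = reductions_used,
    formula = deparse1(stats::formula(fit))),
    class = "coalrank_fit")
}

#' @export
print.coalrank_fit <- function(x, ...) {
  cat(sprintf("<coalrank_fit:%s> %s\n  logLik = %.3f, %d fixed effects%s\n",
              x$role, x$formula, x$logLik, x$n_fixed,
              if (x$singular) " (singular random structure)" else ""))
  invisible(x)
}

#' Fit the linear mixed model of future rank
#'
#' Gaussian LMM of future Elo rating on the coalition predictors with
#' crossed random effects for male and event, fitted by maximum likelihood
#' (REML only on request, never for fits entering likelihood-ratio tests).
#' Non-identifiable random-slope structures are simplified along
#' `spec$reductions`, and the reduction used is recorded on the result.
#'
#' @param data rank table from [build_rank_dataset()].
#' @param spec a [rank_model_spec()].
#' @param null fit the informed null (controls and random structure only,
#'   no main-predictor terms)?
#' @param random optional random-structure override (character vector), used
#'   to force the null model onto the structure the full model settled on.
#' @param REML use REML (for variance-component reporting only).
#' @return a `coalrank_fit`.
#' @export
fit_rank_model <- function(data, spec = rank_model_spec(), null = FALSE,
                           random = NULL, REML = FALSE) {
  if (length(unique(data$event_id)) < 2 || length(unique(data$male)) < 2) {
    abort("rank table needs >= 2 events and >= 2 males",
          "coalrank_data_error")
  }
  if (stats::sd(data$response, na.rm = TRUE) == 0) {
    abort("response is constant; the rank model is degenerate",
          "coalrank_data_error")
  }
  controls <- usable_controls(data, spec$controls)
  fixed <- if (null) controls else c(spec$main, controls)
  if (!length(fixed)) fixed <- "1"
  structures <- if (!is.null(random)) list(random) else spec$reductions
  # complete cases over the *full* spec's variables, so full and null fits
  # (and bootstrap refits) always see the same NA-free rows
  all_terms <- c(spec$main, controls, structures[[1]], "response")
  vars <- unique(unlist(lapply(all_terms, function(tm)
    all.vars(stats::as.formula(paste("~", tm))))))
  cc <- stats::complete.cases(data[, intersect(vars, names(data)),
                                   drop = FALSE])
  if (!all(cc)) {
    message(sprintf("dropping %d of %d rows with missing predictor values",
                    sum(!cc), length(cc)))
    data <- data[cc, , drop = FALSE]
  }
  tried <- character()
  for (k in seq_along(structures)) {
    fo <- stats::reformulate(c(fixed, structures[[k]]), response = "response")
    fit <- tryCatch(
      lme4::lmer(fo, data = data, REML = REML,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tried <- c(tried, sprintf("[%d] error: %s", k, conditionMessage(fit)))
      next
    }
    if (lme4::isSingular(fit) && k < length(structures) &&
        is.null(random)) {
      tried <- c(tried, sprintf("[%d] singular", k))
      next
    }
    return(wrap_fit(fit, if (null) "rank-null" else "rank-full",
                    if (REML) "lmer-REML" else "lmer-ML",
                    reductions_used = tried))
  }
  abort(paste0("rank model did not converge under any random structure:\n",
               paste(tried, collapse = "\n")), "coalrank_fit_error")
}

random_structure <- function(fit) {
  fo <- stats::formula(fit$fit)
  bars <- lme4::findbars(fo)
  vapply(bars, function(b) paste0("(", deparse1(b), ")"), character(1))
}

#' Full-vs-null likelihood-ratio test of the rank model
#'
#' Fits the full model (reducing the random structure if needed), refits
#' the informed null with the *same* final random structure, and compares
#' them with [likelihood_ratio_test()].
#'
#' @param data rank table from [build_rank_dataset()].
#' @param spec a [rank_model_spec()].
#' @return list with elements `full`, `null` (both `coalrank_fit`) and
#'   `lrt` (a `coalrank_lrt`).
#' @export
rank_lrt <- function(data, spec = rank_model_spec()) {
  full <- fit_rank_model(data, spec, null = FALSE)
  rs <- random_structure(full)
  # the reduced structure is doubled-bar expanded; refit null on identical terms
  null <- fit_rank_model(data, spec, null = TRUE, random = rs)
  list(full = full, null = null, lrt = likelihood_ratio_test(full, null))
}

#' Likelihood-ratio test of nested mixed-model fits
#'
#' Both fits must be maximum-likelihood fits of the same data with the null
#' model's fixed effects nested in the full model's and identical random
#' structure. The statistic is `2 * (logLik_full - logLik_null)`, floored
#' at zero, on as many degrees of freedom as the difference in fixed-effect
#' parameter counts.
#'
#' @param full,null `coalrank_fit` objects.
#' @return a `coalrank_lrt`: list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  if (!inherits(full, "coalrank_fit") || !inherits(null, "coalrank_fit")) {
    abort("likelihood_ratio_test() expects coalrank_fit objects",
          "coalrank_usage_error")
  }
  if (stats::nobs(full$fit) != stats::nobs(null$fit)) {
    abort("full and null models were fitted to different data",
          "coalrank_usage_error")
  }
  if (!all(names(lme4::fixef(null$fit)) %in% names(lme4::fixef(full$fit)))) {
    abort("null fixed effects are not nested in the full model",
          "coalrank_usage_error")
  }
  df <- full$n_fixed - null$n_fixed
  stat <- max(0, 2 * (full$logLik - null$logLik))
  if (df < 0 || (df == 0 && stat > 1e-6)) {
    abort("full model must have at least as many fixed-effect parameters as the null",
          "coalrank_usage_error")
  }
  # identical specs: no evidence either way
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p),
            class = "coalrank_lrt")
}

#' @export
print.coalrank_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Fit the binomial mixed model of siring probability
#'
#' Logistic GLMM of the per-candidate sire indicator on the window-mean
#' standardized rating (raw \[0, 1\] scale, so the slope is log-odds per
#' unit standardized rating), with a male-ID random intercept and optional
#' group-level and individual controls. The likelihood is maximized with
#' adaptive Gauss-Hermite quadrature (default 10 nodes; 1 gives the Laplace
#' approximation).
#'
#' @param data paternity table from [build_paternity_dataset()] or
#'   [simulate_paternity_cohort()].
#' @param controls character vector of control terms (silently dropped when
#'   absent, all-missing or single-level).
#' @param include_rating set `FALSE` for the null model, which drops only
#'   the rating term.
#' @param nAGQ number of adaptive quadrature nodes.
#' @return a `coalrank_fit`.
#' @export
fit_paternity_model <- function(data,
                                controls = c("age_z", "stability_z",
                                             "competition_z"),
                                include_rating = TRUE, nAGQ = 10) {
  if (length(unique(data$infant)) < 2) {
    abort("paternity table needs >= 2 infants", "coalrank_data_error")
  }
  if (!all(data$sired %in% c(0, 1))) {
    abort("'sired' must be binary", "coalrank_data_error")
  }
  controls <- usable_controls(data, controls)
  fixed <- c(if (include_rating) "rating", controls)
  if (!length(fixed)) fixed <- "1"
  cc <- stats::complete.cases(
    data[, intersect(c("sired", "rating", "male",
                       unlist(lapply(controls, function(tm)
                         all.vars(stats::as.formula(paste("~", tm)))))),
                     names(data)), drop = FALSE])
  if (!all(cc)) {
    message(sprintf("dropping %d of %d rows with missing values",
                    sum(!cc), length(cc)))
    data <- data[cc, , drop = FALSE]
  }
  fo <- stats::reformulate(c(fixed, "(1 | male)"), response = "sired")
  fit <- lme4::glmer(fo, data = data, family = stats::binomial(),
                     nAGQ = nAGQ)
  res <- wrap_fit(fit, if (include_rating) "paternity-full"
                  else "paternity-null",
                  sprintf("glmer-nAGQ%d", nAGQ))
  big <- abs(res$coefficients$estimate) > 15
  if (any(big)) {
    abort(paste0("paternity model shows signs of complete separation ",
                 "(|estimate| > 15 for: ",
                 paste(res$coefficients$term[big], collapse = ", "), ")"),
          "coalrank_separation_error")
  }
  res
}

#' Parametric bootstrap prediction curves
#'
#' Simulates `B` response vectors from the fitted model, refits the model to
#' each, and predicts on `newdata` at the population level (random effects
#' set to zero; numeric z-scored covariates in `newdata` at 0 are
#' predictions at the mean). Failed refits are excluded and counted; more
#' than 20% failures is an error.
#'
#' @param fit a `coalrank_fit`.
#' @param newdata prediction grid (factor columns must use the fitting
#'   levels).
#' @param B number of bootstrap draws (the headline figures use 1000).
#' @param seed integer seed.
#' @param type `"link"` or `"response"` prediction scale.
#' @return list of class `coalrank_bootstrap`: `point` (predictions from
#'   the original fit), `curves` (successful-draw x grid matrix), `band`
#'   (2.5% / 97.5% envelope), `n_failed`.
#' @export
bootstrap_predictions <- function(fit, newdata, B = 1000, seed = 1,
                                  type = c("link", "response")) {
  type <- match.arg(type)
  if (!inherits(fit, "coalrank_fit")) {
    abort("'fit' must be a coalrank_fit", "coalrank_usage_error")
  }
  set.seed(child_seed(seed, "bootstrap"))
  sims <- stats::simulate(fit$fit, nsim = B)
  point <- stats::predict(fit$fit, newdata = newdata, re.form = NA,
                          type = type)
  curves <- matrix(NA_real_, nrow = B, ncol = nrow(newdata))
  ok <- logical(B)
  for (b in seq_len(B)) {
    rf <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(fit$fit, sims[[b]]))),
      error = function(e) NULL)
    if (is.null(rf)) next
    pr <- tryCatch(stats::predict(rf, newdata = newdata, re.form = NA,
                                  type = type),
                   error = function(e) NULL)
    if (is.null(pr)) next
    curves[b, ] <- pr
    ok[b] <- TRUE
  }
  if (mean(!ok) > 0.2) {
    abort(sprintf("bootstrap refits failed for %d of %d draws",
                  sum(!ok), B), "coalrank_bootstrap_error")
  }
  curves <- curves[ok, , drop = FALSE]
  band <- data.frame(newdata,
                     fit = as.numeric(point),
                     lo = apply(curves, 2, stats::quantile, 0.025),
                     hi = apply(curves, 2, stats::quantile, 0.975))
  structure(list(point = as.numeric(point), curves = curves, band = band,
                 n_failed = sum(!ok)),
            class = "coalrank_bootstrap")
}

#' Predicted participant-target gap over time distance
#'
#' Builds the Fig.-2-style prediction: population-level predicted future
#' rating for participants and targets at each time distance, with every
#' numeric covariate at its mean (z-score 0) and categorical covariates at
#' their reference levels, and returns the participant-minus-target gap.
#'
#' @param fit a `coalrank_fit` from [fit_rank_model()].
#' @param data the rank table the model was fitted to (supplies the
#'   z-scaling of `days_since` and factor levels).
#' @param days vector of time distances (days) to predict at.
#' @return data.frame with `days_since`, `participant`, `target`, `gap`.
#' @export
predicted_role_gap <- function(fit, data,
                               days = seq(10, 120, by = 10)) {
  mu <- mean(data$days_since)
  sd_ <- stats::sd(data$days_since)
  grid <- expand.grid(role = levels(data$role), days_since = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$role <- factor(grid$role, levels = levels(data$role))
  grid$days_z <- (grid$days_since - mu) / sd_
  grid$configuration <- factor(levels(data$configuration)[1],
                               levels = levels(data$configuration))
  for (v in c("feasibility_z", "rank0_z", "age_z", "aggr_z", "stability_z",
              "competition_z", "ac_z")) {
    grid[[v]] <- 0
  }
  grid$group <- factor(sort(unique(data$group))[1],
                       levels = sort(unique(as.character(data$group))))
  pr <- stats::predict(fit$fit, newdata = grid, re.form = NA)
  wide <- data.frame(days_since = days,
                     participant = pr[grid$role == "participant"],
                     target = pr[grid$role == "target"])
  wide$gap <- wide$participant - wide$target
  wide
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, standard errors, variance components,
#' log-likelihood and convergence information.
#'
#' @param fit a `coalrank_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  jsonlite::write_json(
    list(role = fit$role, method = fit$method, formula = fit$formula,
         coefficients = fit$coefficients, varcomp = fit$varcomp,
         logLik = fit$logLik, n_fixed = fit$n_fixed,
         singular = fit$singular, converged = fit$converged,
         reductions_used = fit$reductions_used),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
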