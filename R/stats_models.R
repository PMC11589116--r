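# Binomial models for triploidy/aneuploidy incidence: fixed-effect GLMs,
# a random-intercept logistic model fitted by adaptive Gauss-Hermite
# quadrature, drop1 AIC term evaluation, quasi-complete separation
# detection, and stage-interval mortality rates.

#' Specify a binomial incidence model
#'
#' @param response name of the 0/1 response column (e.g. `triploid` or
#'   `aneuploid`).
#' @param fixed_effects character vector of categorical predictors (subset
#'   of treatment / family / stage columns).
#' @param random_intercept optional grouping column for a Gaussian random
#'   intercept (e.g. treatment replicate), or `NULL`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed_effects, random_intercept = NULL) {
  structure(list(response = response, fixed_effects = fixed_effects,
                 random_intercept = random_intercept, link = "logit"),
            class = "model_spec")
}

#' Detect quasi-complete separation in a categorical design
#'
#' Flags every level of every categorical predictor whose response cells
#' are all 0 or all 1 — the configuration that makes logistic maximum
#' likelihood diverge and standard errors blow up. The usual remedy is to
#' refit after dropping the offending level.
#'
#' @param data data frame.
#' @param response 0/1 response column name.
#' @param factors character vector of predictor column names.
#' @return list with `flag` and `levels` (data frame of offending
#'   factor/level/direction rows).
#' @export
detect_separation <- function(data, response, factors) {
  y <- data[[response]]
  rows <- list()
  for (f in factors) {
    g <- as.character(data[[f]])
    for (lv in unique(g)) {
      yy <- y[g == lv]
      if (length(yy) > 0L && (all(yy == 0) || all(yy == 1))) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, level = lv,
          direction = if (all(yy == 1)) "all_one" else "all_zero",
          stringsAsFactors = FALSE)
      }
    }
  }
  levels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = character(0), level = character(0),
               direction = character(0))
  list(flag = nrow(levels) > 0L, levels = levels)
}

prepare_model_frame <- function(data, spec) {
  df <- as.data.frame(data)
  y <- df[[spec$response]]
  if (is.null(y)) tc_stop("tripcheck_config_error",
                          "response column '%s' not found", spec$response)
  if (!all(y %in% c(0, 1)))
    tc_stop("tripcheck_validation_error", "response must be 0/1 (Bernoulli)")
  for (f in spec$fixed_effects) df[[f]] <- factor(df[[f]])
  if (!is.null(spec$random_intercept))
    df[[spec$random_intercept]] <- factor(df[[spec$random_intercept]])
  df
}

fit_formula <- function(spec) {
  rhs <- if (length(spec$fixed_effects) > 0L)
    paste(spec$fixed_effects, collapse = " + ") else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a fixed-effects binomial GLM
#'
#' Logit-link binomial fit by iteratively reweighted least squares
#' (maximum likelihood); deterministic given the data. Quasi-complete
#' separation is detected up front and flagged on the result (standard
#' errors are then unreliable). A rank-deficient design is an error naming
#' the aliased columns.
#'
#' @param data data frame with the response and predictor columns.
#' @param spec a [model_spec()] without random intercept.
#' @return A `tc_fit` object: coefficient table, log-likelihood, AIC
#'   (`2k - 2 logLik`), convergence and separation flags.
#' @export
fit_binomial_glm <- function(data, spec) {
  df <- prepare_model_frame(data, spec)
  sep <- detect_separation(df, spec$response, spec$fixed_effects)
  fit <- stats::glm(fit_formula(spec), family = stats::binomial(), data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    tc_stop("tripcheck_validation_error",
            "rank-deficient design; aliased column(s): %s",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  k <- length(cf)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    kind = "glm",
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], row.names = NULL,
                              stringsAsFactors = FALSE),
    sigma = NA_real_, loglik = ll, k = k, aic = 2 * k - 2 * ll,
    converged = fit$converged, separation_flag = sep$flag,
    separation_levels = sep$levels, spec = spec, data = df, model = fit),
    class = "tc_fit")
}

#' Refit after dropping separation-offending factor levels
#'
#' The remedy for quasi-complete separation: rows belonging to the
#' offending levels are removed and the model refitted; both fits are
#' meant to be reported side by side.
#'
#' @param fit a `tc_fit`.
#' @return A new `tc_fit` on the reduced data (attribute `dropped_levels`).
#' @export
refit_without_separated_levels <- function(fit) {
  sl <- fit$separation_levels
  if (nrow(sl) == 0L) return(fit)
  df <- fit$data
  for (i in seq_len(nrow(sl)))
    df <- df[as.character(df[[sl$factor[i]]]) != sl$level[i], , drop = FALSE]
  for (f in fit$spec$fixed_effects) df[[f]] <- droplevels(factor(df[[f]]))
  refit <- if (fit$kind == "glm") fit_binomial_glm(df, fit$spec) else
    fit_random_intercept_logit(df, fit$spec, nodes = fit$nodes)
  attr(refit, "dropped_levels") <- sl
  refit
}

#' Drop-one-term AIC table
#'
#' Refits the model once per dropped fixed effect (the random intercept,
#' when present, is never dropped) and tabulates AIC; the recommended model
#' is the lowest-AIC candidate, `"<none>"` meaning keep the full model.
#'
#' @param fit a `tc_fit` from [fit_binomial_glm()] or
#'   [fit_random_intercept_logit()].
#' @return Data frame of (term, k, loglik, AIC) with attribute
#'   `recommended`.
#' @export
drop1_aic <- function(fit) {
  if (!fit$converged) tc_stop("tripcheck_validation_error",
                              "drop1 requires a converged full fit")
  rows <- data.frame(term = "<none>", k = fit$k, loglik = fit$loglik,
                     aic = fit$aic, stringsAsFactors = FALSE)
  for (tm in fit$spec$fixed_effects) {
    spec2 <- fit$spec
    spec2$fixed_effects <- setdiff(spec2$fixed_effects, tm)
    sub <- tryCatch({
      if (fit$kind == "glm") fit_binomial_glm(fit$data, spec2)
      else fit_random_intercept_logit(fit$data, spec2, nodes = fit$nodes)
    }, error = function(e) e)
    if (inherits(sub, "error")) {
      rows <- rbind(rows, data.frame(term = paste0("-", tm, " [failed: ",
                                                   conditionMessage(sub), "]"),
                                     k = NA, loglik = NA, aic = NA))
    } else {
      rows <- rbind(rows, data.frame(term = paste0("-", tm), k = sub$k,
                                     loglik = sub$loglik, aic = sub$aic))
    }
  }
  attr(rows, "recommended") <- rows$term[which.min(rows$aic)]
  rows
}

#' Stage-interval mortality rates
#'
#' Rate = deaths / starters per unit and interval. Aggregation over
#' families or treatments must pool the counts before dividing (never
#' average rates); see [aggregate_mortality()].
#'
#' @param counts data frame with `unit_id`, `interval`, `n_start`, `n_dead`.
#' @return The counts with `rate` (NA and flagged when `n_start` is 0).
#' @export
mortality_rates <- function(counts) {
  if (any(counts$n_dead < 0 | counts$n_dead > counts$n_start, na.rm = TRUE))
    tc_stop("tripcheck_validation_error", "n_dead must lie in [0, n_start]")
  counts$rate <- ifelse(counts$n_start > 0, counts$n_dead / counts$n_start,
                        NA_real_)
  counts$flag <- ifelse(counts$n_start > 0, "", "undefined_rate_zero_start")
  counts
}

#' Pool mortality counts over grouping columns
#'
#' @param counts mortality counts table.
#' @param by character vector of grouping columns (plus `interval`).
#' @return Pooled counts with rates recomputed from the pooled counts.
#' @export
aggregate_mortality <- function(counts, by = "interval") {
  dt <- data.table::as.data.table(counts)
  agg <- dt[, .(n_start = sum(n_start), n_dead = sum(n_dead)),
            by = c(by)]
  mortality_rates(as.data.frame(agg))
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("%s binomial fit: %s ~ %s%s\n",
              if (x$kind == "glm") "Fixed-effects" else "Random-intercept",
              x$spec$response,
              paste(x$spec$fixed_effects, collapse = " + "),
              if (!is.null(x$spec$random_intercept))
                paste0(" + (1 | ", x$spec$random_intercept, ")") else ""))
  cat(sprintf("logLik %.3f  AIC %.3f  k %d  converged %s  separation %s\n",
              x$loglik, x$aic, x$k, x$converged, x$separation_flag))
  if (!is.na(x$sigma)) cat(sprintf("random-intercept SD %.4f\n", x$sigma))
  print(x$coefficients, digits = 4)
  invisible(x)
}
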