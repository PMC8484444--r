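#' @title Marginal-effects regression on simulation output
#' @description Ordinary least squares summarizing annual pupal production as
#'   a linear function of weather covariates and pairwise interactions, with
#'   marginal effects evaluated at covariate means.
#' @name analysis_stats
NULL

#' Fit the marginal-analysis regression
#'
#' OLS fit of
#' \deqn{pupae = a + \sum_i b_i x_i + \sum_j b_j x_j + U}
#' where the `x_j` are pairwise products of declared main-effect covariates
#' and `U` is the residual error term. Backed by base R `lm` behind this
#' interface.
#'
#' @param table data.frame holding the response and covariate columns.
#' @param response Name of the response column (default `"pupae"`).
#' @param covariates Character vector of main-effect column names.
#' @param interactions List of length-2 character vectors naming covariate
#'   pairs whose product enters as an interaction (default none).
#' @return A `marginal_regression` object: list with `intercept`,
#'   `coefficients` (main effects), `interaction_coefficients`, `means` (of
#'   the main-effect covariates over the fitted table), `r_squared`,
#'   `residual_variance`, `n`, and the underlying `fit`.
#' @export
fit_marginal_regression <- function(table, response = "pupae",
                                    covariates, interactions = list()) {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (!all(covariates %in% names(table)))
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, names(table)), collapse = ", "), call. = FALSE)
  for (pr in interactions) {
    if (length(pr) != 2 || !all(pr %in% covariates))
      stop("each interaction must name two declared covariates; got: ",
           paste(pr, collapse = ":"), call. = FALSE)
  }
  if (anyDuplicated(covariates))
    stop("duplicate covariate name(s): ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "),
         call. = FALSE)
  zerovar <- covariates[vapply(covariates, function(v)
    stats::var(table[[v]]) == 0, logical(1))]
  if (length(zerovar))
    stop("constant (zero-variance) covariate(s): ",
         paste(zerovar, collapse = ", "), call. = FALSE)

  X <- table[covariates]
  inter_names <- character(0)
  for (pr in interactions) {
    nm <- paste(pr, collapse = ":")
    X[[nm]] <- table[[pr[1]]] * table[[pr[2]]]
    inter_names <- c(inter_names, nm)
  }
  dat <- cbind(stats::setNames(table[response], ".y"), X)
  names(dat) <- c(".y", covariates, inter_names)
  if (nrow(dat) <= ncol(X) + 1)
    stop("need more rows than coefficients (", ncol(X) + 1, ")", call. = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(
    sprintf("`%s`", c(covariates, inter_names)), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear term(s): ",
         paste(gsub("`", "", bad), collapse = ", "), call. = FALSE)
  }
  names(cf) <- gsub("`", "", names(cf))
  s <- suppressWarnings(summary(fit))  # noiseless designs fit perfectly
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    coefficients = cf[covariates],
    interaction_coefficients = if (length(inter_names)) cf[inter_names] else numeric(0),
    interactions = interactions,
    means = vapply(table[covariates], mean, numeric(1)),
    r_squared = s$r.squared,
    residual_variance = s$sigma^2,
    n = nrow(dat),
    fit = fit), class = "marginal_regression")
}

#' Marginal effect of one covariate
#'
#' The partial derivative of the fitted regression with respect to `var`,
#' evaluated at the sample means of the remaining covariates:
#' `b_var + sum over interactions containing var of b_pair * mean(partner)`.
#' With no interactions this is exactly the OLS coefficient.
#'
#' @param model A `marginal_regression`.
#' @param var Name of a main-effect covariate.
#' @return The marginal effect (response units per unit of `var`).
#' @export
marginal_effect <- function(model, var) {
  stopifnot(inherits(model, "marginal_regression"))
  if (!var %in% names(model$coefficients))
    stop("unknown covariate '", var, "'; model covariates: ",
         paste(names(model$coefficients), collapse = ", "), call. = FALSE)
  eff <- unname(model$coefficients[var])
  for (pr in model$interactions) {
    if (var %in% pr) {
      partner <- setdiff(pr, var)
      if (!length(partner)) partner <- var  # self-interaction x*x
      nm <- paste(pr, collapse = ":")
      b <- unname(model$interaction_coefficients[nm])
      eff <- eff + if (identical(partner, var)) 2 * b * model$means[[var]]
                   else b * model$means[[partner]]
    }
  }
  eff
}

#' @export
print.marginal_regression <- function(x, ...) {
  cat("<marginal_regression> n =", x$n, " R^2 =", signif(x$r_squared, 4), "\n")
  cat("  intercept:", signif(x$intercept, 6), "\n")
  for (v in names(x$coefficients))
    cat(sprintf("  %-18s %12.6g  (marginal effect %12.6g)\n",
                v, x$coefficients[[v]], marginal_effect(x, v)))
  if (length(x$interaction_coefficients))
    for (v in names(x$interaction_coefficients))
      cat(sprintf("  %-18s %12.6g\n", v, x$interaction_coefficients[[v]]))
  invisible(x)
}

#' Annual thermal-stress covariates from a weather series
#'
#' Ready-made covariates for the marginal regression: the average over years
#' of the annual sums of daily mortality rates on days with `tmean` below the
#' lower developmental threshold (cold stress) and above the upper inflection
#' temperature (heat stress) of the species' egg-larval stage, plus annual
#' degree-days.
#'
#' @param series A `weather_series`.
#' @param sp A `species_params` object.
#' @param stage_id Stage whose thresholds and mortality are used (default
#'   `"egg_larva"`).
#' @return Named vector `c(cold_mortality =, heat_mortality =, degree_days =)`.
#' @export
thermal_stress_covariates <- function(series, sp, stage_id = "egg_larva") {
  st <- sp$stages[[stage_id]]
  yrs <- format(series$date, "%Y")
  mu <- mortality_rate(series$tmean, stage_id, sp)
  cold <- tapply(ifelse(series$tmean < st$theta_L, mu, 0), yrs, sum)
  heat <- tapply(ifelse(series$tmean > st$theta_U, mu, 0), yrs, sum)
  dd <- tapply(dev_increment(series$tmean, st), yrs, sum)
  c(cold_mortality = mean(cold), heat_mortality = mean(heat),
    degree_days = mean(dd))
}
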