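#' @title Biodemographic functions (BDFs)
#' @description Scalar functions of temperature, relative humidity, and age
#'   that drive development, reproduction, and mortality of each species.
#' @name bdf
NULL

# ascending-power polynomial evaluated by Horner's rule; coefficients are the
# printed digits ("sufficient digits given to ensure accurate replication")
polyval <- function(coef, x) {
  y <- rep(coef[length(coef)], length(x))
  for (i in rev(seq_len(length(coef) - 1L))) y <- y * x + coef[i]
  y
}

#' Temperature-dependent developmental rate R(T)
#'
#' Proportional development per day,
#' \deqn{R(T) = a (T - \theta_L) / (1 + b^{T - \theta_U}),}
#' floored at 0 for `T <= theta_L`. `R` is approximately linear between the
#' thresholds and collapses to 0 above the inflection `theta_U`. Stages without
#' a published rate coefficient use the normalized `a = 1/delta`, which is the
#' form the population dynamics integrate (see [dev_increment()]).
#'
#' @param T Temperature, degrees C (vectorized).
#' @param stage One element of `species_params$stages`.
#' @return Proportional development per day (>= 0).
#' @seealso [dev_increment()]
#' @export
dev_rate <- function(T, stage) {
  a <- stage$a
  if (is.null(a) || is.na(a)) a <- 1 / stage$delta
  pmax(0, a * (T - stage$theta_L)) / (1 + stage$b^(T - stage$theta_U))
}

#' Daily increment of physiological time
#'
#' \deqn{\Delta_x(T) = (T - \theta_L) / (1 + b^{T - \theta_U})}
#' in degree-days per day, floored at 0. Equals `T - theta_L` in the linear
#' range and decays toward 0 above `theta_U`. This is `delta * R(T)` with the
#' rate coefficient normalized to `a = 1/delta`, so that a cohort held at
#' constant favorable `T` accumulates exactly `delta` dd in
#' `delta / (T - theta_L)` days, for every species and stage.
#'
#' @inheritParams dev_rate
#' @return Degree-days accrued per day (>= 0).
#' @export
dev_increment <- function(T, stage) {
  pmax(0, T - stage$theta_L) / (1 + stage$b^(T - stage$theta_U))
}

#' Symmetric unimodal scalar between two limits
#'
#' `F(x, lo, hi)`: 0 at and beyond both limits, exactly 1 at the midpoint,
#' symmetric about it, and continuous. Implemented as the parabola
#' `max(0, 4 (x - lo) (hi - x) / (hi - lo)^2)` — the simplest smooth form with
#' those properties.
#'
#' @param x Value (vectorized).
#' @param lo,hi Lower and upper limits, `lo < hi`.
#' @return Scalar in \[0, 1\].
#' @export
symmetric_window <- function(x, lo, hi) {
  if (lo >= hi) stop("symmetric_window: need lo < hi", call. = FALSE)
  pmax(0, 4 * (x - lo) * (hi - x) / (hi - lo)^2)
}

# sup of the raw (floored) phi_T form over the admissible temperature range,
# used to max-normalize so that max phi_T = 1. Window forms peak at exactly 1.
phi_T_norm_constant <- function(sp) {
  spec <- sp$reproduction$phiT
  if (identical(spec$form, "window")) return(1)
  rng <- if (identical(spec$form, "rational")) {
    c(spec$theta_L, spec$theta_U + 5)
  } else {
    el <- sp$stages$egg_larva
    c(el$theta_L, el$theta_U + 5)
  }
  grid <- seq(rng[1], rng[2], by = 0.01)
  m <- max(phi_T_raw(grid, spec))
  if (m <= 0) stop("phi_T form is non-positive over its admissible range", call. = FALSE)
  m
}

phi_T_raw <- function(T, spec) {
  v <- switch(spec$form,
    window   = symmetric_window(T, spec$lo, spec$hi),
    rational = spec$a * pmax(0, T - spec$theta_L) / (1 + spec$b^(T - spec$theta_U)),
    poly     = polyval(spec$coef, T),
    stop("unknown phiT form '", spec$form, "'", call. = FALSE))
  pmax(0, v)
}

#' Temperature scalar for oviposition
#'
#' Evaluates the species-specific reproduction scalar `phi_T` (a symmetric
#' window for medfly and mexfly, a rate-shaped rational for melon fly, a cubic
#' polynomial for oriental fruit fly), floors negatives at 0, max-normalizes so
#' the supremum over the admissible range is 1, and caps at 1.
#'
#' @param T Temperature, degrees C (vectorized).
#' @param sp A `species_params` object.
#' @return Scalar in \[0, 1\].
#' @export
phi_T <- function(T, sp) {
  spec <- sp$reproduction$phiT
  norm <- sp$reproduction$phiT_norm
  if (is.null(norm)) norm <- phi_T_norm_constant(sp)
  pmin(1, phi_T_raw(T, spec) / norm)
}

#' Relative-humidity scalar for oviposition
#'
#' Evaluates the species form (quartic polynomial for medfly; symmetric
#' windows for melon and oriental fruit fly; mexfly is the medfly value scaled
#' up 36% for its greater desiccation resistance) and clamps to \[0, 1\].
#'
#' @param RH Mean relative humidity, percent, in \[0, 100\] (vectorized).
#' @param sp A `species_params` object.
#' @return Scalar in \[0, 1\].
#' @export
phi_RH <- function(RH, sp) {
  if (any(!is.finite(RH)) || any(RH < 0 | RH > 100))
    stop("phi_RH: RH must be within [0, 100]", call. = FALSE)
  spec <- sp$reproduction$phiRH
  v <- switch(spec$form,
    window = symmetric_window(RH, spec$lo, spec$hi),
    poly   = polyval(spec$coef, RH),
    scaled_medfly = spec$factor * phi_RH(RH, load_species("medfly")),
    stop("unknown phiRH form '", spec$form, "'", call. = FALSE))
  pmin(1, pmax(0, v))
}

#' Temperature-dependent daily mortality rate
#'
#' Proportion dying per day for the stage group the stage belongs to
#' (species-specific polynomial or piecewise exponential, as published),
#' clamped to \[0, 1\]. The curves are convex: low in the favorable interior
#' range and rising steeply toward cold and heat extremes.
#'
#' @param T Temperature, degrees C (vectorized).
#' @param stage_id One of `"egg_larva"`, `"pupa"`, `"adult"`,
#'   `"quiescent_adult"`.
#' @param sp A `species_params` object.
#' @return Proportion dying per day in \[0, 1\].
#' @export
mortality_rate <- function(T, stage_id, sp) {
  stage_id <- match.arg(stage_id, STAGE_IDS)
  g <- sp$mortality$groups[[sp$mortality$stage_group[[stage_id]]]]
  v <- switch(g$form,
    poly = polyval(g$coef, T),
    piecewise_exp = ifelse(T < g$T_break, g$c1 * exp(g$r1 * T), g$c2 * exp(g$r2 * T)))
  pmin(1, pmax(0, v))
}

#' Age-specific oviposition profile at 25 degrees C
#'
#' Eggs per female per day as a function of age `x` in days at the reference
#' temperature of 25 C:
#' \deqn{f(x) = \gamma (x - x_0) / \varphi^{x - x_{ref}}} for `x >= x0`, else
#' 0. `x_ref` equals `x0` for all species except the oriental fruit fly, whose
#' published denominator exponent is offset by 1.5 days. The profile rises
#' after the pre-oviposition period, has a single interior maximum, and decays
#' geometrically to 0.
#'
#' @param x Age in days at 25 C (vectorized, >= 0).
#' @param sp A `species_params` object.
#' @return Eggs per female per day (>= 0).
#' @export
fecundity_profile <- function(x, sp) {
  r <- sp$reproduction
  ifelse(x >= r$x0, r$gamma * (x - r$x0) / r$phi_base^(x - r$x_ref), 0)
}

#' Convert a stage survival proportion to daily rates
#'
#' Given the proportion `p` surviving a `d`-day exposure, the constant daily
#' survivorship is `p^(1/d)` and the daily mortality is `1 - p^(1/d)`.
#'
#' @param p Proportion surviving, in (0, 1\].
#' @param d Duration of exposure, days (> 0).
#' @return Named numeric vector `c(survivorship =, mortality =)`.
#' @examples
#' daily_rate_from_survival(0.079, 14)  # c(0.834, 0.166)
#' @export
daily_rate_from_survival <- function(p, d) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("d must be > 0", call. = FALSE)
  s <- p^(1 / d)
  c(survivorship = s, mortality = 1 - s)
}
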