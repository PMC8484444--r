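#' @title Reproduction: demand and realized oviposition
#' @description Daily oviposition demand by the adult age structure and its
#'   conversion to realized oviposition through a ratio-dependent,
#'   demand-driven functional response.
#' @name reproduction
NULL

#' Proportion of hosts discoverable in one day
#'
#' `alpha = 0.005 * dx_adult`, the assumed proportion of the host pool a
#' searching female population can discover during the day's physiological
#' time increment; capped just below 1.
#'
#' @param dx_adult Adult daily physiological increment, dd (>= 0).
#' @param sp A `species_params` object.
#' @return Search proportion in \[0, 1).
#' @export
search_alpha <- function(dx_adult, sp) {
  if (dx_adult < 0) stop("search_alpha: dx_adult must be >= 0", call. = FALSE)
  min(sp$reproduction$alpha_coeff * dx_adult, 1 - 1e-9)
}

#' Daily oviposition demand of the adult population
#'
#' \deqn{D = \phi_T(T)\,\phi_{RH}(RH)\, sr \sum_i f(x_i)\, N_i}
#' where `f` is the age-specific oviposition profile at 25 C, `x_i` the
#' midpoint age of adult class i converted to days at 25 C, and `sr` the sex
#' ratio (0.5). Demand is 0 when either scalar is 0 or no adults are present.
#'
#' @param adults The adult `stage_state`.
#' @param T Mean temperature, C.
#' @param RH Mean relative humidity, percent.
#' @param sp A `species_params` object.
#' @return List with `phi_T`, `phi_RH`, `fecundity_sum` (eggs/day before
#'   scalars), `sr`, and `D` (eggs/day).
#' @export
oviposition_demand <- function(adults, T, RH, sp) {
  stopifnot(inherits(adults, "stage_state"), identical(adults$stage_id, "adult"))
  pT <- phi_T(T, sp)
  pRH <- phi_RH(RH, sp)
  fx <- fecundity_profile(adult_age_days(sp), sp)
  fsum <- sum(fx * adults$densities)
  sr <- sp$reproduction$sr
  list(phi_T = pT, phi_RH = pRH, fecundity_sum = fsum, sr = sr,
       D = pT * pRH * sr * fsum)
}

#' Realized oviposition (ratio-dependent functional response)
#'
#' The parasitoid form of the demand-driven functional response,
#' \deqn{S = H\left(1 - e^{-\frac{D}{H}\left(1 - e^{-\alpha H / D}\right)}\right),}
#' with the continuous limit `S = 0` at `D = 0`. `S` is demand-limited for
#' small `D` (`S -> D`) and search-limited for large `D`
#' (`S -> H (1 - e^(-alpha))`), and never exceeds `min(D, H)`.
#'
#' @param D Oviposition demand, eggs/day (>= 0).
#' @param H Host level (> 0).
#' @param alpha Proportion of hosts discoverable per day, in \[0, 1).
#' @return Realized oviposition `S`, eggs/day.
#' @export
realized_oviposition <- function(D, H, alpha) {
  if (D < 0 || H <= 0 || alpha < 0 || alpha >= 1)
    stop("realized_oviposition: need D >= 0, H > 0, 0 <= alpha < 1", call. = FALSE)
  if (D == 0) return(0)
  H * (1 - exp(-(D / H) * (1 - exp(-alpha * H / D))))
}
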