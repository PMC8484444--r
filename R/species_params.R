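#' @title Species parameter registry
#' @description Load, validate, and inspect the shipped biodemographic
#'   parameter sets for the four tropical tephritid fruit flies.
#' @name species_params
NULL

STAGE_IDS <- c("egg_larva", "pupa", "adult", "quiescent_adult")

# package-local cache of loaded parameter sets and derived constants
.registry <- new.env(parent = emptyenv())

#' List the species shipped with the package
#'
#' @return Character vector of species identifiers accepted by
#'   [load_species()].
#' @export
list_species <- function() {
  c("medfly", "melon_fly", "oriental_fly", "mexfly")
}

species_param_path <- function(name) {
  system.file("extdata", "species", paste0(name, ".json"),
              package = "tephrisim", mustWork = TRUE)
}

#' Load a frozen species parameter set
#'
#' Reads the shipped parameter file for one species, validates it against the
#' schema (all four life stages present, well-formed functional forms), and
#' returns a `species_params` object. Parameter sets are cached after first
#' load; files are never modified at run time.
#'
#' Stage entries carry the developmental time constant `delta` (degree-days,
#' dd), the lower threshold `theta_L` and upper inflection `theta_U`
#' (degrees C), the nonlinear decay base `b`, the printed rate coefficient `a`
#' (per day per degree C; `NA` where no fitted rate was published for the
#' stage), and the Erlang class count `erlang_k`.
#'
#' @param name One of `"medfly"`, `"melon_fly"`, `"oriental_fly"`, `"mexfly"`.
#' @param path Optional path to an external parameter file obeying the same
#'   schema (registry is extensible); when given, `name` is ignored.
#' @return An object of class `species_params`: a list with elements
#'   `species`, `stages` (named list of stage parameter lists), `reproduction`,
#'   `mortality`, and `rate_fits`.
#' @examples
#' sp <- load_species("medfly")
#' sp$stages$adult$delta      # 772 dd
#' sp$stages$adult$theta_L    # 9.5 degrees C
#' @export
load_species <- function(name, path = NULL) {
  from_registry <- is.null(path)
  if (is.null(path)) {
    if (!is.character(name) || length(name) != 1L || !(name %in% list_species())) {
      stop("unknown species '", paste(name, collapse = ","),
           "'; available species: ", paste(list_species(), collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(.registry[[name]])) return(.registry[[name]])
    path <- species_param_path(name)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- validate_species_params(raw, path)
  # pre-compute the max-normalization constant for phi_T (see phi_T())
  sp$reproduction$phiT_norm <- phi_T_norm_constant(sp)
  class(sp) <- "species_params"
  if (from_registry) .registry[[sp$species]] <- sp
  sp
}

num1 <- function(x) is.numeric(x <- unlist(x)) && length(x) == 1L && is.finite(x)

validate_species_params <- function(raw, path) {
  fail <- function(...) stop("invalid species parameter file '", path, "': ",
                             ..., call. = FALSE)
  for (fld in c("species", "stages", "reproduction", "mortality"))
    if (is.null(raw[[fld]])) fail("missing field '", fld, "'")
  stages <- raw$stages
  missing_st <- setdiff(STAGE_IDS, names(stages))
  if (length(missing_st)) fail("missing stage(s): ", paste(missing_st, collapse = ", "))
  st <- list()
  for (s in STAGE_IDS) {
    p <- stages[[s]]
    for (fld in c("delta", "theta_L", "theta_U", "b", "erlang_k"))
      if (!num1(p[[fld]])) fail("stage '", s, "': field '", fld, "' must be one finite number")
    p <- lapply(p, function(v) if (is.null(v)) NA_real_ else unlist(v))
    if (p$delta <= 0) fail("stage '", s, "': delta must be > 0")
    if (p$theta_L >= p$theta_U) fail("stage '", s, "': need theta_L < theta_U")
    if (p$b <= 1) fail("stage '", s, "': need b > 1")
    if (p$erlang_k < 1 || p$erlang_k != round(p$erlang_k))
      fail("stage '", s, "': erlang_k must be a positive integer")
    p$erlang_k <- as.integer(p$erlang_k)
    p$stage_id <- s
    st[[s]] <- p
  }
  rep <- lapply(raw$reproduction, function(v)
    if (is.list(v)) lapply(v, unlist) else unlist(v))
  for (fld in c("gamma", "phi_base", "x0", "x_ref", "sr", "H", "alpha_coeff", "T_opt"))
    if (!num1(rep[[fld]])) fail("reproduction: field '", fld, "' must be one finite number")
  if (rep$gamma <= 0) fail("reproduction: gamma must be > 0")
  if (rep$phi_base <= 1) fail("reproduction: phi_base must be > 1")
  if (rep$sr <= 0 || rep$sr > 1) fail("reproduction: sr must be in (0, 1]")
  if (rep$H <= 0) fail("reproduction: H must be > 0")
  for (tag in c("phiT", "phiRH")) {
    form <- rep[[tag]]$form
    ok <- switch(tag,
      phiT  = form %in% c("window", "rational", "poly"),
      phiRH = form %in% c("window", "poly", "scaled_medfly"))
    if (is.null(form) || !ok) fail(tag, ": unknown or missing form '", form, "'")
    if (identical(form, "window") && rep[[tag]]$lo >= rep[[tag]]$hi)
      fail(tag, ": window needs lo < hi")
  }
  mort <- raw$mortality
  if (is.null(mort$groups) || is.null(mort$stage_group)) fail("mortality: need 'groups' and 'stage_group'")
  groups <- lapply(mort$groups, function(g) lapply(g, unlist))
  for (gn in names(groups)) {
    g <- groups[[gn]]
    if (!g$form %in% c("poly", "piecewise_exp"))
      fail("mortality group '", gn, "': unknown form '", g$form, "'")
    if (identical(g$form, "poly") && (is.null(g$coef) || !all(is.finite(g$coef))))
      fail("mortality group '", gn, "': malformed coefficient list")
  }
  sg <- lapply(mort$stage_group, unlist)
  for (s in STAGE_IDS) {
    if (is.null(sg[[s]])) fail("mortality: no stage_group mapping for '", s, "'")
    if (!sg[[s]] %in% names(groups))
      fail("mortality: stage '", s, "' maps to undeclared group '", sg[[s]], "'")
  }
  list(species = unlist(raw$species),
       common_name = unlist(raw$common_name),
       latin_name = unlist(raw$latin_name),
       stages = st,
       rate_fits = lapply(raw$rate_fits, function(f) lapply(f, unlist)),
       reproduction = rep,
       mortality = list(groups = groups, stage_group = sg))
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$species, " (", x$latin_name, ")\n", sep = "")
  for (s in STAGE_IDS) {
    p <- x$stages[[s]]
    cat(sprintf("  %-16s delta %6.4g dd > %.5g C  (theta_U %.4g, b %.4g, k %d)\n",
                s, p$delta, p$theta_L, p$theta_U, p$b, p$erlang_k))
  }
  cat("  reproduction: gamma", x$reproduction$gamma,
      "phi", x$reproduction$phi_base, "x0", x$reproduction$x0,
      "sr", x$reproduction$sr, "H", x$reproduction$H, "\n")
  invisible(x)
}
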