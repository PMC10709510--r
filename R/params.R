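#' Species parameter table
#'
#' Validates and normalises a table of per-species parameters: the five
#' Ellenberg site indicator values (L, T, M, R, N; `NA` marks an indifferent
#' species), the three Briemle land-use tolerance values (C, G, TR; never
#' indifferent), the maximum growth rate `g_max` (per year) and the
#' self-regulation factor `f_s`.
#'
#' Indicator values are ordinal preferences on a 1--9 scale; fractional values
#' are allowed.  `f_s` caps the effective growth of a species as its cover
#' approaches `f_s` percent, standing in for fine-scale microsite heterogeneity
#' that the homogeneous cell compartments cannot represent.
#'
#' @param df data.frame with columns `species_id`, `name`, `L`, `T`, `M`, `R`,
#'   `N`, `C`, `G`, `TR`, `g_max`, `f_s` and optionally `inhibits_woody`.
#'   Site columns may contain `NA` (indifferent).
#' @return the validated data.frame with class `"species_table"`.
#' @export
species_table <- function(df) {
  req <- c("species_id", "name", "L", "T", "M", "R", "N",
           "C", "G", "TR", "g_max", "f_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("species table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$species_id <- as.character(df$species_id)
  if (anyDuplicated(df$species_id))
    stop("duplicate species_id: ",
         paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "))
  if (!"inhibits_woody" %in% names(df)) df$inhibits_woody <- FALSE
  for (col in c("L", "T", "M", "R", "N")) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < 1 | v > 9)
    if (any(bad))
      stop("site indicator value out of [1,9] in column ", col,
           ", row(s) ", paste(which(bad), collapse = ", "))
  }
  for (col in c("C", "G", "TR")) {
    v <- df[[col]]
    if (anyNA(v))
      stop("indifferent ('x') value not allowed in land-use column ", col,
           ", row(s) ", paste(which(is.na(v)), collapse = ", "))
    bad <- v < 1 | v > 9
    if (any(bad))
      stop("land-use indicator value out of [1,9] in column ", col,
           ", row(s) ", paste(which(bad), collapse = ", "))
  }
  if (any(df$g_max < 0 | df$g_max > 10))
    stop("g_max out of [0,10], row(s) ",
         paste(which(df$g_max < 0 | df$g_max > 10), collapse = ", "))
  if (any(!is.finite(df$f_s) | df$f_s <= 0 | df$f_s > 15000))
    stop("f_s out of (0,15000], row(s) ",
         paste(which(!is.finite(df$f_s) | df$f_s <= 0 | df$f_s > 15000),
               collapse = ", "))
  class(df) <- c("species_table", "data.frame")
  df
}

#' Global simulation parameters
#'
#' Collects the run-level settings: per-factor slopes for the site control
#' functions, the reduced slope and reduced optimum applied to species that are
#' indifferent for a factor, per-factor weights, the time resolution, the
#' dispersal threshold, the annual mortality rate and the RNG seed.
#'
#' @param slope named numeric of length 5 (L, T, M, R, N) or a single value
#'   recycled; width of the site-condition tolerance curves (>= 0).
#' @param slope_red reduced slope (in `[0,1]`) for indifferent species, per
#'   factor or recycled.
#' @param opt_red reduced optimum (in `[0,1]`) for indifferent species, per
#'   factor or recycled.
#' @param weights named numeric over L, T, M, R, N, C, G, TR (each in
#'   `[1,20]`) or a single value recycled; ecological relevance weights used in
#'   the total environmental dependency.
#' @param steps_per_year 52 (weekly) or 365 (daily).
#' @param n_years positive integer simulation horizon.
#' @param rng_seed integer seed for the single RNG stream.
#' @param dispersal_threshold_pct cover (>, percent) above which a species may
#'   spread vegetatively into the 8-neighbourhood; 1 by default.  Values
#'   >= 100 disable dispersal.
#' @param annual_mortality yearly mortality as a proportion of cover
#'   (default 2, i.e. 200 % per year), divided evenly over the time steps.
#' @param cell_area cell area in square metres (informational; cover is in
#'   percent of the cell).
#' @return list with class `"global_params"`.
#' @export
global_params <- function(slope = 1, slope_red = 0.3, opt_red = 0.6,
                          weights = 1, steps_per_year = 52, n_years = 10,
                          rng_seed = 1L, dispersal_threshold_pct = 1,
                          annual_mortality = 2, cell_area = 100) {
  site_f <- c("L", "T", "M", "R", "N")
  all_f <- c(site_f, "C", "G", "TR")
  expand <- function(x, nm, what, lo, hi) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(nm)), nm)
    if (is.null(names(x))) names(x) <- nm
    x <- x[nm]
    if (anyNA(x)) stop(what, " must cover factors ", paste(nm, collapse = ", "))
    if (any(x < lo | x > hi))
      stop(what, " out of [", lo, ",", hi, "]")
    x
  }
  slope <- expand(slope, site_f, "slope", 0, Inf)
  slope_red <- expand(slope_red, site_f, "slope_red", 0, 1)
  opt_red <- expand(opt_red, site_f, "opt_red", 0, 1)
  weights <- expand(weights, all_f, "weights", 1, 20)
  if (!steps_per_year %in% c(52, 365))
    stop("steps_per_year must be 52 or 365")
  if (n_years < 1) stop("n_years must be >= 1")
  structure(list(slope = slope, slope_red = slope_red, opt_red = opt_red,
                 weights = weights, steps_per_year = as.integer(steps_per_year),
                 n_years = as.integer(n_years), rng_seed = as.integer(rng_seed),
                 dispersal_threshold_pct = dispersal_threshold_pct,
                 annual_mortality = annual_mortality, cell_area = cell_area),
            class = "global_params")
}

#' Vegetation type definitions
#'
#' @param df data.frame with columns `type_id`, `name`, `simulated` (logical;
#'   structural elements such as roads are not dynamically simulated).
#' @param initial_cover named list mapping `type_id` to a named numeric vector
#'   of initial percent cover per species (empty for non-simulated types).
#' @return list with class `"vegtype_table"`.
#' @export
vegtype_table <- function(df, initial_cover = list()) {
  req <- c("type_id", "name", "simulated")
  if (length(setdiff(req, names(df))))
    stop("vegetation type table needs columns ", paste(req, collapse = ", "))
  df$type_id <- as.character(df$type_id)
  if (anyDuplicated(df$type_id)) stop("duplicate vegetation type_id")
  for (id in df$type_id[df$simulated]) {
    cov <- initial_cover[[id]]
    if (is.null(cov))
      stop("simulated vegetation type '", id, "' has no initial cover")
    if (any(cov < 0)) stop("negative initial cover for type '", id, "'")
    # observed community tables can overshoot 100 by rounding (e.g. 100.08)
    if (sum(cov) > 101)
      stop("initial cover of type '", id, "' sums to more than 101 %")
  }
  structure(list(types = df, initial_cover = initial_cover),
            class = "vegtype_table")
}
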