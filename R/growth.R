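#' Per-step mortality
#'
#' A fixed background mortality (default 200 % of cover per year, divided
#' evenly over the time steps) removes cover at the start of every growth
#' cycle.  Mortality is what frees space: plants cannot push each other out,
#' they compete only through regrowth into uncovered area.
#'
#' @param cover_pct current cover in percent (vectorised).
#' @param steps_per_year 52 or 365.
#' @param annual_mortality annual rate (default 2 = 200 % per year).
#' @return list with `cover` (reduced cover) and `freed` (space released, %).
#' @export
mortality_step <- function(cover_pct, steps_per_year, annual_mortality = 2) {
  if (any(cover_pct < 0)) stop("negative cover")
  newc <- cover_pct * (1 - annual_mortality / steps_per_year)
  list(cover = newc, freed = cover_pct - newc)
}

#' Land-use control function
#'
#' Linear sensitivity of a species to a form of land use (cutting, grazing or
#' trampling).  A tolerance value of 9 means the species is unaffected at any
#' intensity (factor 1); at full intensity a maximally sensitive species
#' (value 1) is reduced to 1/9.
#'
#' @param eiv Briemle tolerance value in `[1,9]` (never indifferent).
#' @param intensity land-use intensity in `[0,100]`.
#' @return factor in `[1/9, 1]`; vectorised.
#' @export
landuse_control <- function(eiv, intensity) {
  if (any(is.na(eiv))) stop("land-use tolerance values cannot be indifferent")
  if (any(eiv < 1 | eiv > 9)) stop("land-use tolerance value out of [1,9]")
  if (any(intensity < 0 | intensity > 100)) stop("intensity out of [0,100]")
  (1 - eiv / 9) * (100 - intensity) / 100 + eiv / 9
}

#' Site-condition control function
#'
#' Gaussian ecological tolerance curve: the factor is 1 when the species
#' indicator value equals the site value and decays with the squared mismatch,
#' scaled by 9 (the width of the indicator scale).  `slope` sets the sharpness
#' of the optimum.  For indifferent species (`eiv = NA`) a broader, lower
#' curve is used: `opt_red * exp(-slope_red * (site_value - 5)^2 / 9)`, with
#' the scale midpoint 5 acting as pseudo-optimum, so the factor stays positive
#' everywhere on the scale.
#'
#' @param eiv species indicator value in `[1,9]`, or `NA` for indifferent.
#' @param site_value site indicator value in `[1,9]`.
#' @param slope curve width parameter (>= 0) for regular values.
#' @param slope_red,opt_red reduced slope and optimum for indifferent species.
#' @return factor in `(0, 1]`; vectorised over all arguments.
#' @export
site_control <- function(eiv, site_value, slope, slope_red = 0.3,
                         opt_red = 0.6) {
  if (any(site_value < 1 | site_value > 9)) stop("site value out of [1,9]")
  n <- max(length(eiv), length(site_value), length(slope))
  eiv <- rep_len(eiv, n); site_value <- rep_len(site_value, n)
  slope <- rep_len(slope, n)
  slope_red <- rep_len(slope_red, n); opt_red <- rep_len(opt_red, n)
  ind <- is.na(eiv)
  out <- numeric(n)
  out[!ind] <- exp(-slope[!ind] * (site_value[!ind] - eiv[!ind])^2 / 9)
  out[ind] <- opt_red[ind] * exp(-slope_red[ind] * (site_value[ind] - 5)^2 / 9)
  out
}

#' Weight of a control function
#'
#' Suboptimal factors gain influence on the weighted mean: the weight of a
#' control value f is `(2 - f)^w`, which is 1 at the optimum (f = 1) and grows
#' to `2^w` as f approaches 0.  `w` is the per-factor ecological relevance
#' weight.
#'
#' @param f control value in `(0, 1]`.
#' @param w factor weight in `[1, 20]`.
#' @return weight in `[1, 2^w]`; vectorised.
#' @export
factor_weight <- function(f, w) (2 - f)^w

#' Total environmental dependency
#'
#' Weighted mean of the eight control values, with weights from
#' [factor_weight()].  Using a mean instead of a product avoids the collapse
#' of multiplying many suboptimal factors (0.7^8 < 0.1); the result always
#' lies between the worst and the best individual factor.
#'
#' @param factors named numeric of control values in `(0,1]`.
#' @param weights numeric of per-factor weights (same length/names).
#' @return the total dependency f_total.
#' @export
total_dependency <- function(factors, weights) {
  if (!length(factors)) stop("empty factor set")
  if (length(weights) == 1L) weights <- rep(weights, length(factors))
  W <- factor_weight(factors, weights)
  sum(W * factors) / sum(W)
}

#' Growth rate
#'
#' Per-year growth rate of a species compartment:
#' `g = g_max * (f_s - cover) / f_s * f_total`, floored at 0.  The
#' self-regulation term reduces growth linearly as cover approaches `f_s`,
#' preventing the best-adapted species from monopolising all space; decline
#' beyond `f_s` is driven by mortality and competition only.
#'
#' @param cover_pct current cover in percent.
#' @param g_max maximum growth rate (per year).
#' @param f_s self-regulation factor (> 0), percent-cover units.
#' @param f_total total environmental dependency in `(0,1]`.
#' @return growth rate per year, >= 0; vectorised.
#' @export
growth_rate <- function(cover_pct, g_max, f_s, f_total) {
  if (any(f_s <= 0)) stop("f_s must be positive")
  pmax(0, g_max * (f_s - cover_pct) / f_s * f_total)
}

#' Potential growth per time step
#'
#' `delta_c = g * cover / steps_per_year`: the annual growth rate applied to
#' the current cover and scaled to the step length, so that yearly
#' trajectories are (quasi-)invariant to the choice of 52 vs 365 steps.
#'
#' @param g growth rate per year (>= 0).
#' @param cover_pct current cover in percent.
#' @param steps_per_year 52 or 365.
#' @return potential cover increment for this step, in percent.
#' @export
potential_growth <- function(g, cover_pct, steps_per_year) {
  g * cover_pct / steps_per_year
}

#' Lottery allocation of free space
#'
#' If the summed potential growth (local potential plus stored ingrowth from
#' neighbours) fits into the available space, every species realises its
#' potential; otherwise the available space is divided proportionally to
#' potential growth.
#'
#' @param potentials named numeric (>= 0) of per-species potential growth.
#' @param available_space free space in the cell, percent (>= 0).
#' @return named numeric of realised growth; sums to
#'   `min(sum(potentials), available_space)`.
#' @export
allocate_space <- function(potentials, available_space) {
  if (any(potentials < 0)) stop("negative potential growth")
  if (available_space < 0) stop("negative available space")
  tot <- sum(potentials)
  if (tot <= available_space || tot == 0) return(potentials)
  potentials * (available_space / tot)
}

# Precompute the (cells x species) matrix of total environmental dependency.
# Site values and land-use intensities are constant within a run, so f_total
# per cell and species does not change between steps.
compute_f_total <- function(site, landuse, species, globals) {
  n_cells <- nrow(site)
  n_sp <- nrow(species)
  site_f <- c("L", "T", "M", "R", "N")
  lu_f <- c("C", "G", "TR")
  wts <- globals$weights
  num <- matrix(0, n_cells, n_sp)
  den <- matrix(0, n_cells, n_sp)
  for (j in seq_len(n_sp)) {
    for (k in seq_along(site_f)) {
      fc <- site_f[k]
      f <- site_control(species[[fc]][j], site[, k],
                        slope = globals$slope[[fc]],
                        slope_red = globals$slope_red[[fc]],
                        opt_red = globals$opt_red[[fc]])
      W <- factor_weight(f, wts[[fc]])
      num[, j] <- num[, j] + W * f
      den[, j] <- den[, j] + W
    }
    for (k in seq_along(lu_f)) {
      fc <- lu_f[k]
      f <- landuse_control(species[[fc]][j], landuse[, k])
      W <- factor_weight(f, wts[[fc]])
      num[, j] <- num[, j] + W * f
      den[, j] <- den[, j] + W
    }
  }
  num / den
}
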