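# Independent reference computations used to validate the engine.  These are
# deliberately plain scalar recursions with no code shared with the growth or
# scheduler internals.

#' Single-species, single-cell reference trajectory
#'
#' Direct scalar iteration of mortality, growth and space allocation for one
#' species in one cell with a constant total environmental dependency and no
#' dispersal:
#' `c <- c * (1 - M/spy); c <- c + min(gmax * (fs - c)/fs * ftot * c / spy,
#' 100 - c)`.
#' Used as an independent check of the full scheduler.
#'
#' The positive fixed point of this recursion (growth balancing mortality) is
#' `c* = fs * (1 - M / (gmax * ftot))` when `gmax * ftot > M` (clipped by the
#' 100 % space limit), and 0 otherwise.
#'
#' @param g_max maximum growth rate (per year).
#' @param f_s self-regulation factor.
#' @param f_total constant environmental dependency in `(0,1]`.
#' @param c0 initial cover (%).
#' @param steps number of steps to iterate.
#' @param steps_per_year 52 or 365.
#' @param annual_mortality annual mortality rate (default 2).
#' @return numeric vector of length `steps + 1` (cover after each step,
#'   starting with `c0`).
#' @export
single_species_trajectory <- function(g_max, f_s, f_total, c0, steps,
                                      steps_per_year,
                                      annual_mortality = 2) {
  out <- numeric(steps + 1)
  out[1] <- c0
  cc <- c0
  for (t in seq_len(steps)) {
    cc <- cc * (1 - annual_mortality / steps_per_year)
    g <- g_max * (f_s - cc) / f_s * f_total
    if (g < 0) g <- 0
    grow <- g * cc / steps_per_year
    avail <- 100 - cc
    if (grow > avail) grow <- avail
    cc <- cc + grow
    if (cc < 1e-6) cc <- 0
    out[t + 1] <- cc
  }
  out
}

#' Random synthetic community
#'
#' Reproducible random species tables and matching site values for property
#' tests (conservation, symmetry, calibration recovery).  With
#' `eiv_spread = 0` all species share the site's indicator values and are
#' ecologically identical.
#'
#' @param seed integer seed (restores the RNG state afterwards).
#' @param n_species number of species (>= 1).
#' @param eiv_spread maximal absolute deviation of species indicator values
#'   from the site values (integer steps, clipped to `[1,9]`).
#' @return list with `species` (a [species_table()]), `site` (named L..N) and
#'   `landuse` (named C, G, TR intensities, all zero).
#' @export
random_community <- function(seed, n_species, eiv_spread = 2) {
  if (n_species < 1) stop("n_species must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  site <- c(L = 7, T = 5, M = 5, R = 6, N = 5)
  draw <- function(center) {
    v <- center + sample(seq(-eiv_spread, eiv_spread), n_species,
                         replace = TRUE)
    pmin(9, pmax(1, v))
  }
  df <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    name = sprintf("Synthetic species %d", seq_len(n_species)),
    L = draw(site["L"]), T = draw(site["T"]), M = draw(site["M"]),
    R = draw(site["R"]), N = draw(site["N"]),
    C = 5, G = 5, TR = 5,
    g_max = stats::runif(n_species, 3.5, 5.5),
    f_s = stats::runif(n_species, 80, 1000),
    stringsAsFactors = FALSE)
  if (eiv_spread == 0)
    for (col in c("L", "T", "M", "R", "N")) df[[col]] <- site[[col]]
  list(species = species_table(df), site = site,
       landuse = c(C = 0, G = 0, TR = 0))
}

# Build a small homogeneous grid from a site/landuse vector and initial
# covers; shared by calibration targets and tests.
homogeneous_grid <- function(species, site, landuse, initial, globals,
                             n_rows = 1, n_cols = 1) {
  init <- stats::setNames(as.numeric(initial), names(initial))
  vt <- vegtype_table(
    data.frame(type_id = "plot", name = "plot", simulated = TRUE,
               stringsAsFactors = FALSE),
    initial_cover = list(plot = init))
  type_map <- matrix("plot", n_rows, n_cols)
  site_maps <- lapply(site[c("L", "T", "M", "R", "N")],
                      function(v) matrix(v, n_rows, n_cols))
  landuse_maps <- lapply(landuse[c("C", "G", "TR")],
                         function(v) matrix(v, n_rows, n_cols))
  build_grid(type_map, site_maps, landuse_maps, vt, species, globals)
}
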