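#' Start a simulation run
#'
#' Wraps a built grid into a run object holding the year/step counters, the
#' recorder and (optionally) a classification ruleset used to refresh the
#' vegetation types twice per simulated year (at the first and the mid-year
#' step).
#'
#' @param grid a `veg_grid`.
#' @param ruleset optional `veg_ruleset` for vegetation typing.
#' @param record_every recording cadence in steps; default
#'   `steps_per_year / 2` (twice yearly, matching the typing updates).
#' @return object of class `veg_run`.
#' @export
simulation_run <- function(grid, ruleset = NULL, record_every = NULL) {
  spy <- grid$globals$steps_per_year
  if (is.null(record_every)) record_every <- spy %/% 2
  structure(list(grid = grid, ruleset = ruleset,
                 year = 1L, step = 0L,
                 record_every = as.integer(record_every),
                 records = list()), class = "veg_run")
}

#' Advance one time step
#'
#' Executes one full scheduling cycle in the documented order.  Cycle 1, over
#' all modeled cells in row-major order: optional vegetation-type update (only
#' at the two designated steps of the year), mortality, recomputation of
#' available space, growth rate and potential growth per species, the
#' stochastic dispersal split (events accumulate for the next step), and the
#' lottery allocation of available space over local potentials plus the
#' ingrowth delivered from the previous step.  Cycle 2 commits the ingrowth
#' buffer.  After every step each modeled cell satisfies
#' `sum(cover) + available_space = 100`.
#'
#' @param run a `veg_run`.
#' @return the advanced run.
#' @export
simulation_step <- function(run) {
  grid <- run$grid
  g <- grid$globals
  spy <- g$steps_per_year
  run$step <- run$step + 1L
  if (run$step > spy) { run$step <- 1L; run$year <- run$year + 1L }

  typing_steps <- c(1L, spy %/% 2L + 1L)
  if (!is.null(run$ruleset) && run$step %in% typing_steps)
    grid <- classify_grid(grid, run$ruleset)

  m <- grid$modeled
  cov <- grid$cover

  # cycle 1: mortality frees space before growth
  mort <- mortality_step(cov[m, , drop = FALSE], spy, g$annual_mortality)
  cov[m, ] <- mort$cover
  avail <- 100 - rowSums(cov)

  # dynamic growth: rate and per-step potential
  fs <- grid$species$f_s
  gmax <- grid$species$g_max
  gr <- pmax(0, sweep(1 - sweep(cov, 2, fs, "/"), 2, gmax, "*")) * grid$f_total
  pot <- gr * cov / spy
  pot[!m, ] <- 0

  # stochastic split of potential growth towards neighbours
  grid$cover <- cov          # disperse_all reads post-mortality cover for p
  disp <- disperse_all(grid, pot)
  pot <- disp$pot
  grid$ingrowth_next <- disp$ingrowth_next

  # lottery competition over local potential + delivered ingrowth
  tot_pot <- pot + grid$ingrowth_current
  s <- rowSums(tot_pot)
  scale <- ifelse(s > avail & s > 0, avail / s, 1)
  cov <- cov + tot_pot * scale
  cov[cov < 1e-6] <- 0       # extinction threshold against denormal drift
  cov[!m, ] <- 0
  grid$cover <- cov
  grid$ingrowth_current[] <- 0

  # cycle 2
  grid <- commit_ingrowth(grid)
  run$grid <- grid

  if (run$record_every > 0 && run$step %% run$record_every == 0)
    run$records[[length(run$records) + 1L]] <-
      list(year = run$year, step = run$step, cover = grid$cover,
           veg_type = grid$veg_type)
  run
}

#' Run a simulation for a number of years
#'
#' Seeds the single RNG stream from the globals, then executes
#' `years * steps_per_year` steps.
#'
#' @param grid a `veg_grid`.
#' @param years number of simulated years (default `globals$n_years`).
#' @param ruleset optional classification ruleset (see [parse_ruleset()]).
#' @param record_every recording cadence in steps (default twice yearly).
#' @param seed optional override of `globals$rng_seed`.
#' @return a completed `veg_run`.
#' @export
run_simulation <- function(grid, years = NULL, ruleset = NULL,
                           record_every = NULL, seed = NULL) {
  if (is.null(years)) years <- grid$globals$n_years
  if (is.null(seed)) seed <- grid$globals$rng_seed
  set.seed(seed)
  run <- simulation_run(grid, ruleset, record_every)
  n_steps <- years * grid$globals$steps_per_year
  for (i in seq_len(n_steps)) run <- simulation_step(run)
  run
}

#' Landscape-mean cover per record
#'
#' @param run a completed `veg_run`.
#' @return data.frame: one row per record (`year`, `step`) and one column per
#'   species with its mean cover over all modeled cells.
#' @export
landscape_mean_cover <- function(run) {
  m <- run$grid$modeled
  if (!length(run$records)) {
    out <- as.data.frame(matrix(numeric(0), 0, 2 + ncol(run$grid$cover)))
    names(out) <- c("year", "step", colnames(run$grid$cover))
    return(out)
  }
  rows <- lapply(run$records, function(r)
    c(year = r$year, step = r$step, colMeans(r$cover[m, , drop = FALSE])))
  out <- as.data.frame(do.call(rbind, rows))
  out
}

#' Per-cell cover of one species across records
#'
#' @param run a completed `veg_run`.
#' @param species_id one species ID.
#' @param years optional year range filter `c(from, to)`.
#' @return matrix records x modeled cells of percent cover.
#' @export
cell_cover_series <- function(run, species_id, years = NULL) {
  recs <- run$records
  if (!is.null(years))
    recs <- Filter(function(r) r$year >= years[1] && r$year <= years[2], recs)
  m <- run$grid$modeled
  do.call(rbind, lapply(recs, function(r) r$cover[m, species_id]))
}

#' @export
print.veg_run <- function(x, ...) {
  cat("<veg_run> year ", x$year, ", step ", x$step, ", ",
      length(x$records), " records\n", sep = "")
  invisible(x)
}

#' @export
summary.veg_run <- function(object, ...) {
  lm <- landscape_mean_cover(object)
  if (nrow(lm)) {
    last <- lm[nrow(lm), -(1:2), drop = FALSE]
    cat("Final landscape-mean cover (%):\n")
    print(round(unlist(last), 2))
  } else cat("No records.\n")
  invisible(lm)
}

#' Trajectories of landscape-mean cover
#'
#' Line plot of the recorded landscape-mean cover per species over simulated
#' time, the standard way to inspect whether a community has reached its
#' dynamic equilibrium.
#'
#' @param x a `veg_run`.
#' @param species optional character vector of species IDs to show.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.veg_run <- function(x, species = NULL, ...) {
  lm <- landscape_mean_cover(x)
  if (!nrow(lm)) { warning("no records to plot"); return(invisible(NULL)) }
  tt <- lm$year + (lm$step - 1) / x$grid$globals$steps_per_year
  y <- as.matrix(lm[, -(1:2), drop = FALSE])
  if (!is.null(species)) y <- y[, species, drop = FALSE]
  graphics::matplot(tt, y, type = "l", lty = 1, xlab = "year",
                    ylab = "mean cover [%]", ...)
  graphics::legend("topright", legend = colnames(y), col = seq_len(ncol(y)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(lm)
}
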