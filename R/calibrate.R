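#' Start values for species calibration
#'
#' Exemplary start values for the two free species parameters, derived from
#' the dominance and abundance patterns observed in the calibration
#' scenarios: dominant species get a high self-regulation factor (they may
#' reach high cover before growth saturates), abundant species a high maximum
#' growth rate.
#'
#' @param dominance_class `"dominant"`, `"less dominant"` or
#'   `"least dominant"`.
#' @param abundance_class `"high"`, `"medium"` or `"low"`.
#' @return named numeric `c(g_max =, f_s =)`.
#' @export
start_values <- function(dominance_class = c("dominant", "less dominant",
                                             "least dominant"),
                         abundance_class = c("high", "medium", "low")) {
  dominance_class <- match.arg(dominance_class)
  abundance_class <- match.arg(abundance_class)
  fs <- c("dominant" = 1000, "less dominant" = 500, "least dominant" = 100)
  gm <- c("high" = 5.0, "medium" = 4.5, "low" = 3.5)
  c(g_max = unname(gm[abundance_class]), f_s = unname(fs[dominance_class]))
}

#' Define a calibration target
#'
#' One calibration scenario: site and land-use conditions, the initial covers,
#' and the target cover vector the community should settle at.
#'
#' @param site named numeric (L, T, M, R, N) site indicator values.
#' @param landuse named numeric (C, G, TR) intensities.
#' @param initial named numeric of initial percent cover per species.
#' @param target named numeric of target percent cover per species.
#' @param years simulation horizon per evaluation (default 15).
#' @param window evaluation window: mean over the last `window` years
#'   (default 5).
#' @param n_rows,n_cols grid size of the calibration plot (default 1 x 1).
#' @return list of class `calibration_target`.
#' @export
calibration_target <- function(site, landuse, initial, target, years = 15,
                               window = 5, n_rows = 1, n_cols = 1) {
  if (any(target < 0) || sum(target) > 101)
    stop("targets must be >= 0 and sum to at most ~101")
  if (window > years) stop("evaluation window exceeds the horizon")
  structure(list(site = site, landuse = landuse, initial = initial,
                 target = target, years = years, window = window,
                 n_rows = n_rows, n_cols = n_cols),
            class = "calibration_target")
}

# Mean absolute error of landscape-mean covers (last `window` years) against
# one target.
target_error <- function(target, species, globals, seed) {
  grid <- homogeneous_grid(species, target$site, target$landuse,
                           target$initial, globals,
                           target$n_rows, target$n_cols)
  run <- run_simulation(grid, years = target$years, seed = seed)
  lm <- landscape_mean_cover(run)
  keep <- lm$year > target$years - target$window
  sim <- colMeans(lm[keep, names(target$target), drop = FALSE])
  mean(abs(sim - target$target))
}

#' Calibrate species growth parameters against target communities
#'
#' Iterative coordinate search over (g_max, f_s) per species, minimising the
#' maximum over scenarios of the mean absolute cover error in the evaluation
#' window.  Because the objective always spans all scenarios, every accepted
#' move is implicitly re-checked against previously satisfied scenarios (the
#' backward check).  Steps are multiplicative and shrink when a full sweep
#' yields no improvement.
#'
#' @param targets list of [calibration_target()]s (at least one).
#' @param species a [species_table()] with start values for g_max and f_s.
#' @param globals a [global_params()].
#' @param budget maximum number of full parameter sweeps (default 30).
#' @param tolerance stop when the objective falls below this mean absolute
#'   cover error in percent (default 2).
#' @param step initial multiplicative step (default 0.5, i.e. try x1.5 and
#'   /1.5).
#' @param seed seed for the evaluation runs (one deterministic stream).
#' @return list with `species` (fitted table), `error` (final objective),
#'   `converged`, `history` (best objective per sweep, non-increasing) and
#'   `report` (per-scenario residuals of the fitted table).
#' @export
calibrate <- function(targets, species, globals, budget = 30, tolerance = 2,
                      step = 0.5, seed = 1L) {
  if (!length(targets)) stop("no calibration targets")
  if (inherits(targets, "calibration_target")) targets <- list(targets)
  objective <- function(sp) {
    max(vapply(targets, target_error, numeric(1), species = sp,
               globals = globals, seed = seed))
  }
  best <- objective(species)
  history <- best
  cur <- species
  for (sweep in seq_len(budget)) {
    if (best <= tolerance) break
    improved <- FALSE
    for (j in seq_len(nrow(cur))) {
      for (par in c("g_max", "f_s")) {
        for (fac in c(1 + step, 1 / (1 + step))) {
          cand <- cur
          val <- cand[[par]][j] * fac
          if (par == "g_max") val <- min(10, max(0.1, val))
          if (par == "f_s") val <- min(15000, max(1, val))
          cand[[par]][j] <- val
          err <- objective(cand)
          if (err < best) {
            best <- err
            cur <- cand
            improved <- TRUE
          }
        }
      }
    }
    history <- c(history, best)
    if (!improved) step <- step / 2
    if (step < 0.01) break
  }
  report <- do.call(rbind, lapply(seq_along(targets), function(i)
    data.frame(scenario = i,
               error = target_error(targets[[i]], cur, globals, seed))))
  list(species = cur, error = best, converged = best <= tolerance,
       history = history, report = report)
}
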