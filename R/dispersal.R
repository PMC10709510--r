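#' Stochastic vegetative spread of potential growth
#'
#' A species whose cover exceeds the dispersal threshold may redirect part of
#' its potential growth into one of its eight (virtual) neighbour cells:
#' with probability `cover_pct / 100` an event occurs and a direction is drawn
#' uniformly among the eight virtual neighbour positions.  If the drawn
#' position lies inside the closed boundary, a uniform fraction `u ~ U(0,1)`
#' of the step's potential growth is transferred there and the remainder
#' stays local; a draw pointing off-grid transfers nothing (no flux across
#' the closed boundary — the growth stays in the cell).  Events aimed at
#' unmodeled cells are created and then discarded (growth is lost at
#' structural boundaries).  Draws come from the run's single seeded RNG
#' stream.
#'
#' @param cover_pct current cover of the species in this cell (%).
#' @param pot_growth the species' potential growth this step (%).
#' @param neighbors integer vector of length 8: neighbour cell indices of the
#'   eight virtual positions, `NA` where off-grid (a row of
#'   `grid$neighbors`).
#' @param threshold dispersal threshold in percent cover (default 1).
#' @return list with `local` (potential growth staying in the cell) and
#'   `event` (`NULL`, or a list with `target` cell index and `amount`;
#'   discarding events into unmodeled targets is the caller's concern).
#'   `local + amount` always equals `pot_growth` exactly.
#' @export
maybe_disperse <- function(cover_pct, pot_growth, neighbors, threshold = 1) {
  if (pot_growth < 0) stop("negative potential growth")
  if (cover_pct <= threshold)
    return(list(local = pot_growth, event = NULL))
  if (stats::runif(1) >= cover_pct / 100)
    return(list(local = pot_growth, event = NULL))
  k <- min(8L, floor(stats::runif(1) * 8) + 1L)
  if (is.na(neighbors[k]))
    return(list(local = pot_growth, event = NULL))
  u <- stats::runif(1)
  list(local = (1 - u) * pot_growth,
       event = list(target = neighbors[k], amount = u * pot_growth))
}

# Vectorised dispersal pass over the whole grid.  The RNG stream is consumed
# in deterministic order: first the event-decision uniforms for all eligible
# (cell, species) pairs in row-major cell order (species-table order within a
# cell), then neighbour and fraction draws for the realised events in the
# same order.  Returns the reduced local potentials and accumulates the
# transferred amounts into ingrowth_next (discarding boundary/unmodeled
# targets).
disperse_all <- function(grid, pot) {
  thr <- grid$globals$dispersal_threshold_pct
  n_sp <- ncol(pot)
  elig_t <- t(grid$cover > thr & pot > 0)   # species x cells
  idx <- which(elig_t)                      # cell-major, species within cell
  if (!length(idx)) return(list(pot = pot, ingrowth_next = grid$ingrowth_next))
  sp <- (idx - 1L) %% n_sp + 1L
  cell <- (idx - 1L) %/% n_sp + 1L
  p <- grid$cover[cbind(cell, sp)] / 100
  ev <- stats::runif(length(idx)) < p
  if (!any(ev)) return(list(pot = pot, ingrowth_next = grid$ingrowth_next))
  cell <- cell[ev]; sp <- sp[ev]
  k <- pmin(8L, floor(stats::runif(sum(ev)) * 8) + 1L)
  target <- grid$neighbors[cbind(cell, k)]
  inb <- !is.na(target)   # off-grid draws transfer nothing (closed boundary)
  cell <- cell[inb]; sp <- sp[inb]; target <- target[inb]
  if (!length(cell))
    return(list(pot = pot, ingrowth_next = grid$ingrowth_next))
  u <- stats::runif(length(cell))
  moved <- u * pot[cbind(cell, sp)]
  pot[cbind(cell, sp)] <- pot[cbind(cell, sp)] - moved
  keep <- grid$modeled[target]
  if (any(keep)) {
    key <- (target[keep] - 1L) * n_sp + sp[keep]
    agg <- rowsum(moved[keep], key)
    kk <- as.integer(rownames(agg))
    tcell <- (kk - 1L) %/% n_sp + 1L
    tsp <- (kk - 1L) %% n_sp + 1L
    ing <- grid$ingrowth_next
    ing[cbind(tcell, tsp)] <- ing[cbind(tcell, tsp)] + agg[, 1]
    return(list(pot = pot, ingrowth_next = ing))
  }
  list(pot = pot, ingrowth_next = grid$ingrowth_next)
}

#' Commit neighbour ingrowth for the next time step
#'
#' Second cell cycle of a step: the potential growth accumulated for
#' neighbours during this step becomes the ingrowth that competes for space
#' in the next step (one-step-delayed delivery); the accumulator is zeroed.
#' A species arriving in a cell where it is absent is created there with zero
#' cover and competes for space like any resident.
#'
#' @param grid a `veg_grid`.
#' @return the updated grid.
#' @export
commit_ingrowth <- function(grid) {
  grid$ingrowth_current <- grid$ingrowth_next
  grid$ingrowth_current[!grid$modeled, ] <- 0
  grid$ingrowth_next[] <- 0
  grid
}
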