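#' Build a landscape grid
#'
#' Assembles the simulation state from a vegetation-type map, five site
#' indicator value layers, three land-use intensity layers, the vegetation
#' type definitions, the species table and the global parameters.  Cells whose
#' type is `NA` or whose type is not simulated (roads, structural elements)
#' are unmodeled: they carry no vegetation and are never updated, but act as a
#' closed buffer around the modeled area.
#'
#' Internally cells are stored row-major (origin upper-left, sweeping to the
#' lower right), covers in percent of cell area, with per-cell/per-species
#' accumulators for potential ingrowth from neighbours (delivered one step
#' delayed).
#'
#' @param type_map matrix of vegetation type IDs (`NA` = unmodeled).
#' @param site_maps list of five matrices (L, T, M, R, N), values in `[1,9]`.
#' @param landuse_maps list of three matrices (C, G, TR), values in `[0,100]`.
#' @param vegtypes a [vegtype_table()].
#' @param species a [species_table()].
#' @param globals a [global_params()].
#' @return object of class `veg_grid`.
#' @export
build_grid <- function(type_map, site_maps, landuse_maps, vegtypes, species,
                       globals) {
  species <- species_table(species)
  stopifnot(inherits(vegtypes, "vegtype_table"),
            inherits(globals, "global_params"))
  type_map <- as.matrix(type_map)
  nr <- nrow(type_map); nc <- ncol(type_map)
  dims_ok <- function(m) identical(dim(as.matrix(m)), c(nr, nc))
  if (!all(vapply(site_maps, dims_ok, logical(1))) ||
      !all(vapply(landuse_maps, dims_ok, logical(1))))
    stop("all raster layers must share the dimensions of the type map")
  if (length(site_maps) != 5 || length(landuse_maps) != 3)
    stop("need 5 site layers (L,T,M,R,N) and 3 land-use layers (C,G,TR)")

  # row-major cell index: cell = (row-1)*ncol + col
  as_cells <- function(m) as.vector(t(as.matrix(m)))
  type_vec <- as.character(as_cells(type_map))
  known <- c(vegtypes$types$type_id, NA)
  if (!all(type_vec %in% known))
    stop("unknown vegetation type ID(s): ",
         paste(unique(setdiff(type_vec, known)), collapse = ", "))
  sim_types <- vegtypes$types$type_id[vegtypes$types$simulated]
  modeled <- !is.na(type_vec) & type_vec %in% sim_types

  site <- matrix(unlist(lapply(site_maps, as_cells)), nr * nc, 5,
                 dimnames = list(NULL, c("L", "T", "M", "R", "N")))
  landuse <- matrix(unlist(lapply(landuse_maps, as_cells)), nr * nc, 3,
                    dimnames = list(NULL, c("C", "G", "TR")))
  if (any(site[modeled, ] < 1 | site[modeled, ] > 9, na.rm = FALSE))
    stop("site indicator value out of [1,9]")
  if (any(landuse[modeled, ] < 0 | landuse[modeled, ] > 100))
    stop("land-use intensity out of [0,100]")

  n_cells <- nr * nc
  n_sp <- nrow(species)
  cover <- matrix(0, n_cells, n_sp, dimnames = list(NULL, species$species_id))
  for (id in unique(type_vec[modeled])) {
    init <- vegtypes$initial_cover[[id]]
    unknown_sp <- setdiff(names(init), species$species_id)
    if (length(unknown_sp))
      stop("initial cover of type '", id, "' names unknown species: ",
           paste(unknown_sp, collapse = ", "))
    rows <- which(modeled & type_vec == id)
    for (sp in names(init)) cover[rows, sp] <- init[[sp]]
  }

  grid <- structure(list(
    n_rows = nr, n_cols = nc, n_cells = n_cells,
    species = species, globals = globals, vegtypes = vegtypes,
    modeled = modeled, veg_type = type_vec,
    site = site, landuse = landuse, cover = cover,
    ingrowth_current = matrix(0, n_cells, n_sp),
    ingrowth_next = matrix(0, n_cells, n_sp),
    neighbors = neighbor_index(nr, nc),
    f_total = NULL), class = "veg_grid")
  grid$f_total <- compute_f_total(grid$site, grid$landuse, species, globals)
  grid
}

# n_cells x 8 matrix over the eight virtual Moore positions: the neighbouring
# cell index, or NA where the position lies outside the closed boundary.
neighbor_index <- function(nr, nc) {
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  cell <- seq_len(nr * nc)
  r <- (cell - 1) %/% nc + 1
  c_ <- (cell - 1) %% nc + 1
  out <- matrix(NA_integer_, nr * nc, 8)
  for (k in 1:8) {
    rr <- r + off[k, 1]; cc <- c_ + off[k, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[ok, k] <- (rr[ok] - 1) * nc + cc[ok]
  }
  out
}

#' Moore neighbourhood of a cell
#'
#' In-bounds neighbours of cell (row, col): 8 in the interior, 5 on an edge,
#' 3 at a corner (closed boundary, no wraparound).
#'
#' @param grid a `veg_grid`.
#' @param row,col 1-based cell coordinates (origin upper-left).
#' @return two-column matrix of neighbour (row, col) coordinates.
#' @export
neighbors8 <- function(grid, row, col) {
  if (row < 1 || row > grid$n_rows || col < 1 || col > grid$n_cols)
    stop("cell (", row, ",", col, ") out of bounds")
  idx <- (row - 1) * grid$n_cols + col
  nb <- grid$neighbors[idx, ]
  nb <- nb[!is.na(nb)]
  cbind(row = (nb - 1) %/% grid$n_cols + 1, col = (nb - 1) %% grid$n_cols + 1)
}

#' Initialise a soil seed bank
#'
#' For primary-succession scenarios every species in the species table is
#' given at least `cover_pct` percent cover in every modeled cell, mimicking a
#' ubiquitous seed bank on raw soil.
#'
#' @param grid a `veg_grid`.
#' @param cover_pct low initial cover per species, e.g. 0.1 or 1.
#' @return the updated grid.
#' @export
seed_bank_initialize <- function(grid, cover_pct) {
  if (cover_pct <= 0) stop("cover_pct must be positive")
  newcov <- pmax(grid$cover, cover_pct)
  tot <- rowSums(newcov)
  if (any(tot[grid$modeled] > 100))
    stop("seed bank would push total cover above 100 %")
  grid$cover[grid$modeled, ] <- newcov[grid$modeled, ]
  grid
}

#' @export
print.veg_grid <- function(x, ...) {
  cat("<veg_grid> ", x$n_rows, "x", x$n_cols, " cells (",
      sum(x$modeled), " modeled), ", nrow(x$species), " species\n", sep = "")
  cat("  steps/year: ", x$globals$steps_per_year,
      ", mean total cover (modeled): ",
      round(mean(rowSums(x$cover)[x$modeled]), 2), " %\n", sep = "")
  invisible(x)
}
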