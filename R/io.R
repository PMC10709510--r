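#' Read a species parameter table
#'
#' Delimited text (tab, comma or semicolon; auto-detected) with header
#' `species_id, name, L, T, M, R, N, C, G, TR, g_max, f_s` and optionally
#' `inhibits_woody`.  The literal `x` marks an indifferent value and is only
#' allowed in the five site columns; fractional indicator values are accepted.
#'
#' @param path file path.
#' @return a validated [species_table()].
#' @export
read_species_table <- function(path) {
  df <- read_delim_auto(path)
  site_cols <- c("L", "T", "M", "R", "N")
  lu_cols <- c("C", "G", "TR")
  for (col in intersect(c(site_cols, lu_cols), names(df))) {
    v <- trimws(as.character(df[[col]]))
    isx <- tolower(v) == "x"
    if (col %in% lu_cols && any(isx))
      stop("'x' (indifferent) is not allowed in land-use column ", col,
           ", row(s) ", paste(which(isx), collapse = ", "))
    v[isx] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) & !isx
    if (any(bad))
      stop("non-numeric value in column ", col, ", row(s) ",
           paste(which(bad), collapse = ", "))
    df[[col]] <- num
  }
  species_table(df)
}

#' Write a species parameter table
#'
#' Inverse of [read_species_table()]; indifferent values are written as `x`.
#'
#' @param species a [species_table()].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @export
write_species_table <- function(species, path, sep = "\t") {
  out <- as.data.frame(species)
  for (col in c("L", "T", "M", "R", "N"))
    out[[col]] <- ifelse(is.na(out[[col]]), "x",
                         format(out[[col]], trim = TRUE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Delimiter auto-detection among tab / semicolon / comma on the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";"
    else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read an ESRI ASCII grid
#'
#' Reads the standard header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by the value matrix (first
#' data row = northernmost row, matching the simulator's upper-left origin).
#' Alternatively accepts a headerless delimited grid of values.  `NODATA`
#' cells become `NA` (unmodeled when used as a type map).
#'
#' @param path file path.
#' @return numeric matrix with attributes `xllcorner`, `yllcorner`,
#'   `cellsize` when an ESRI header was present.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  has_hdr <- length(hdr) > 0
  if (has_hdr) {
    for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
      if (is.null(hdr[[f]])) stop("ESRI ASCII header is missing '", f, "'")
  }
  body <- lines[i:length(lines)]
  rows <- lapply(body, function(l) {
    v <- strsplit(trimws(l), "[\\s,;]+", perl = TRUE)[[1]]
    suppressWarnings(as.numeric(v))
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    stop("ragged raster rows (widths ", paste(unique(widths), collapse = "/"),
         ")")
  m <- do.call(rbind, rows)
  if (has_hdr) {
    if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
      stop("raster body is ", nrow(m), "x", ncol(m),
           " but the header declares ", hdr$nrows, "x", hdr$ncols)
    if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
    attr(m, "xllcorner") <- hdr$xllcorner
    attr(m, "yllcorner") <- hdr$yllcorner
    attr(m, "cellsize") <- hdr$cellsize
  }
  m
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param path output path.
#' @param cellsize cell edge length in map units (default 10).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata value written for `NA` cells (default -9999).
#' @export
write_raster <- function(values, path, cellsize = 10, xllcorner = 0,
                         yllcorner = 0, nodata = -9999) {
  values <- as.matrix(values)
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  vals <- values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulation outputs
#'
#' Exports, per recorded step: (a) one long-format cover table
#' (`cover.csv`: year, step, row, col, species, cover), (b) a vegetation-type
#' grid per record (`vegtype_y<year>_s<step>.asc`, ESRI ASCII, type IDs coded
#' by their position in the type table), and (c) a landscape summary
#' (`summary.csv`: per-record mean cover per species and vegetation-type
#' percentages).
#'
#' @param run a completed `veg_run`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(run, outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  grid <- run$grid
  m <- grid$modeled
  cellrow <- (seq_len(grid$n_cells) - 1) %/% grid$n_cols + 1
  cellcol <- (seq_len(grid$n_cells) - 1) %% grid$n_cols + 1
  sp <- colnames(grid$cover)
  paths <- character(0)

  long <- do.call(rbind, lapply(run$records, function(r) {
    idx <- which(m)
    data.frame(year = r$year, step = r$step,
               row = rep(cellrow[idx], times = length(sp)),
               col = rep(cellcol[idx], times = length(sp)),
               species = rep(sp, each = length(idx)),
               cover = as.vector(r$cover[idx, ]))
  }))
  if (is.null(long))
    long <- data.frame(year = integer(0), step = integer(0),
                       row = integer(0), col = integer(0),
                       species = character(0), cover = numeric(0))
  p <- file.path(outdir, "cover.csv")
  utils::write.csv(long, p, row.names = FALSE)
  paths <- c(paths, p)

  type_ids <- grid$vegtypes$types$type_id
  for (r in run$records) {
    code <- match(r$veg_type, type_ids)
    mat <- matrix(code, grid$n_rows, grid$n_cols, byrow = TRUE)
    p <- file.path(outdir, sprintf("vegtype_y%03d_s%03d.asc", r$year, r$step))
    write_raster(mat, p)
    paths <- c(paths, p)
  }

  summ <- do.call(rbind, lapply(run$records, function(r) {
    mc <- colMeans(r$cover[m, , drop = FALSE])
    vt <- table(factor(r$veg_type[m], levels = type_ids))
    pct <- 100 * as.numeric(vt) / sum(m)
    cbind(data.frame(year = r$year, step = r$step),
          as.data.frame(t(mc)),
          stats::setNames(as.data.frame(t(pct)),
                          paste0("type_pct_", type_ids)))
  }))
  p <- file.path(outdir, "summary.csv")
  utils::write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a run configuration
#'
#' YAML file describing a run: file paths for the species table, vegetation
#' type tables, raster layers, plus global parameter fields (see
#' [global_params()]), output directory and recording cadence.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
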