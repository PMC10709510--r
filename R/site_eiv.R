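#' Aggregate species indicator values of a releve into a site value
#'
#' A site's indicator value for one factor can be estimated from the species
#' observed in a vegetation releve: either the median, the unweighted mean or
#' the cover-weighted mean of the species' indicator values.  Species that are
#' indifferent for the factor are excluded (standard practice in indicator
#' value averaging).
#'
#' @param releve data.frame with columns `species_id` and `cover`
#'   (abundance weight, >= 0).
#' @param species a [species_table()] providing the indicator values.
#' @param factor one of `"L"`, `"T"`, `"M"`, `"R"`, `"N"`.
#' @param method `"median"`, `"mean"` or `"cover_weighted_mean"`.
#' @return a site value in `[1,9]`.
#' @export
mean_site_eiv <- function(releve, species, factor = c("L", "T", "M", "R", "N"),
                          method = c("mean", "median",
                                     "cover_weighted_mean")) {
  factor <- match.arg(factor)
  method <- match.arg(method)
  if (any(releve$cover < 0)) stop("negative abundance")
  idx <- match(releve$species_id, species$species_id)
  if (anyNA(idx))
    stop("releve names species not in the species table: ",
         paste(releve$species_id[is.na(idx)], collapse = ", "))
  vals <- species[[factor]][idx]
  keep <- !is.na(vals)
  if (!any(keep))
    stop("no species with a non-indifferent ", factor, " value in the releve")
  vals <- vals[keep]
  w <- releve$cover[keep]
  switch(method,
         median = stats::median(vals),
         mean = mean(vals),
         cover_weighted_mean = {
           if (sum(w) <= 0) stop("cover weights sum to zero")
           sum(vals * w) / sum(w)
         })
}

#' Derive a site indicator value from soil-map attributes
#'
#' Decision rules mapping soil-map attributes (as provided by German soil
#' maps, e.g. the NRW BK50) to the five site indicator values.  Where the
#' source aggregates several scale points into a class, the class proxy value
#' is returned with the range attached as attributes; combinations that the
#' rules cannot resolve without further field information (shaded sites for
#' L, exceptionally warm sites for T) return `NA` with
#' `attr(, "undetermined") = TRUE`.
#'
#' Attribute vocabulary (all optional unless required by the factor):
#' * `open_area_m2` — numeric site size; < 5000 counts as a small site.
#' * `covered` — logical; TRUE for sites under canopy (forest etc.).
#' * `aspect` — `"WSW-ESE"`, `"SE-SW"` or `"unspecified"`.
#' * `hillslope` — `"<5"`, `"5-20"`, `">20"` or `"unspecified"` (degrees).
#' * `altitude_m` — numeric altitude.
#' * `moisture_class` — `"very dry"`, `"dry"`, `"moderately dry - slightly
#'   moist"`, `"moist"`, `"wet"`.
#' * `cec_class` — `"<40"`, `"40-80"`, `"80-160"`, `"160-320"`, `"320-640"`,
#'   `">640"` (cation exchange capacity, mol+/m2).
#' * `soil_type` — code among P, Q, E, O, N, R, Z, B, L, K, S, SG, G, GN.
#' * `texture_class` — integer 1..9 (1 = loamy clay ... 9 = low on fines).
#' * `topsoil_thickness` — `"<60"`, `"60-200"`, `">200"` (cm).
#'
#' @param attrs named list of soil attributes.
#' @param factor one of `"L"`, `"T"`, `"M"`, `"R"`, `"N"`.
#' @return numeric site value (possibly a class proxy with attributes
#'   `range` and `flagged`), or `NA` with attribute `undetermined`.
#' @export
soil_to_site_eiv <- function(attrs, factor = c("L", "T", "M", "R", "N")) {
  factor <- match.arg(factor)
  need <- function(nm) {
    if (is.null(attrs[[nm]])) stop("missing soil attribute '", nm,
                                   "' for factor ", factor)
    attrs[[nm]]
  }
  undetermined <- function() structure(NA_real_, undetermined = TRUE)
  proxy <- function(value, range = NULL, flagged = FALSE) {
    if (!is.null(range)) attr(value, "range") <- range
    if (flagged) attr(value, "flagged") <- TRUE
    value
  }
  switch(factor,
    L = {
      if (isTRUE(attrs$covered)) return(undetermined())
      size <- need("open_area_m2")
      aspect <- match.arg(need("aspect"), c("WSW-ESE", "SE-SW", "unspecified"))
      slope <- match.arg(need("hillslope"), c("<5", "5-20", ">20",
                                              "unspecified"))
      if (size < 5000) {
        # small sites: peripheral shading lowers the value
        if (aspect == "WSW-ESE" && slope == ">20") return(6)
        if (aspect == "WSW-ESE" && slope == "5-20") return(7)
        if (aspect == "SE-SW" && slope %in% c("5-20", ">20")) return(7.5)
        if (slope %in% c("<5", "unspecified")) return(6.5)
        # remaining combination (unshaded but steep, aspect unspecified)
        proxy(8.5, range = c(8, 9), flagged = TRUE)
      } else {
        if (aspect == "WSW-ESE" && slope == ">20") return(6.5)
        if (aspect == "WSW-ESE" && slope == "5-20") return(7.5)
        if (aspect == "SE-SW" && slope %in% c("5-20", ">20")) return(9)
        8   # any aspect, flat or unspecified slope
      }
    },
    T = {
      alt <- need("altitude_m")
      if (alt > 1500) return(proxy(2, range = c(1, 3), flagged = TRUE))
      if (alt > 800) return(4)
      if (alt > 650) return(4.5)
      if (alt > 450) return(5)
      if (alt > 300) return(6)
      if (alt >= 0) return(7)
      # values 8-9 are reserved for exceptionally warm sites and need
      # further information (aspect, exposure)
      undetermined()
    },
    M = {
      mc <- match.arg(need("moisture_class"),
                      c("very dry", "dry", "moderately dry - slightly moist",
                        "moist", "wet"))
      switch(mc,
             "very dry" = proxy(1.5, range = c(1, 2)),
             "dry" = 3,
             "moderately dry - slightly moist" = proxy(5, range = c(4, 6)),
             "moist" = 7,
             "wet" = proxy(8.5, range = c(8, 9)))
    },
    R = {
      cc <- match.arg(need("cec_class"),
                      c("<40", "40-80", "80-160", "160-320", "320-640",
                        ">640"))
      switch(cc,
             "<40" = proxy(2, range = c(1, 2)),
             "40-80" = 3,
             "80-160" = 4,
             "160-320" = proxy(5.5, range = c(5, 6)),
             "320-640" = proxy(7.5, range = c(7, 8)),
             ">640" = 9)
    },
    N = {
      st <- toupper(need("soil_type"))
      poor <- c("P", "Q", "E", "O", "N")
      rendzina <- c("R", "Z")
      rich <- c("B", "L", "K", "S", "SG", "G", "GN")
      if (st %in% poor) return(proxy(2, range = c(1, 3)))
      if (st %in% rendzina) return(3)
      if (!st %in% rich) stop("unknown soil type code '", st, "'")
      tex <- need("texture_class")
      if (!tex %in% 1:9) stop("texture class must be 1..9")
      if (tex >= 4) return(proxy(3.5, range = c(3, 4)))
      th <- match.arg(need("topsoil_thickness"), c("<60", "60-200", ">200"))
      if (tex == 3 && th == "<60") return(proxy(5, range = c(4, 6)))
      if (tex %in% c(2, 3) && th == "60-200")
        return(proxy(6.5, range = c(6, 7)))
      if (tex %in% c(1, 2, 3) && th == ">200")
        return(proxy(8.5, range = c(8, 9)))
      # fine-textured shallow profiles not covered by the source rules
      undetermined()
    })
}

#' Land-use scenario catalogue
#'
#' Named management scenarios with their cutting / grazing / trampling
#' intensity triples.
#'
#' @param name scenario name; one of `"Hay-meadow"`, `"Mown pasture"`,
#'   `"Extensive pasture"`, `"Intensive pasture"`, `"Sheep pen"`, `"Fallow"`.
#' @return list with `name` and `intensities` (named numeric C, G, TR).
#' @export
scenario_intensities <- function(name) {
  catalogue <- list(
    "Hay-meadow" = c(C = 75, G = 1, TR = 1),
    "Mown pasture" = c(C = 75, G = 20, TR = 10),
    "Extensive pasture" = c(C = 0, G = 35, TR = 20),
    "Intensive pasture" = c(C = 0, G = 50, TR = 50),
    "Sheep pen" = c(C = 0, G = 85, TR = 85),
    "Fallow" = c(C = 0, G = 1, TR = 1))
  if (!name %in% names(catalogue))
    stop("unknown land-use scenario '", name, "'; known: ",
         paste(names(catalogue), collapse = ", "))
  list(name = name, intensities = catalogue[[name]])
}
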