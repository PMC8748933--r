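#' Land-cover grid on the study lattice
#'
#' @param class_matrix character matrix of land-cover classes
#'   (`natural_vegetated`, `agriculture`, `urban`, `water`, `other`),
#'   rows = y, columns = x.
#' @param ecoregion_matrix character matrix of ecoregion ids, same shape.
#' @param cell_size_m cell edge length in metres.
#' @param origin (x, y) of the lower-left corner in metres.
#' @return An object of class `landcover_grid`.
#' @export
landcover_grid <- function(class_matrix, ecoregion_matrix, cell_size_m = 1000,
                           origin = c(0, 0)) {
  class_matrix <- as.matrix(class_matrix)
  ecoregion_matrix <- as.matrix(ecoregion_matrix)
  if (!all(dim(class_matrix) == dim(ecoregion_matrix)))
    stop("class and ecoregion matrices must have the same shape")
  ok <- c("natural_vegetated", "agriculture", "urban", "water", "other")
  if (!all(class_matrix %in% ok))
    stop("unknown land-cover class(es): ",
         paste(setdiff(unique(class_matrix), ok), collapse = ", "))
  structure(list(class = class_matrix, ecoregion = ecoregion_matrix,
                 cell_size = cell_size_m, origin = origin),
            class = "landcover_grid")
}

# centre coordinates of every grid cell (metres)
grid_centres <- function(grid) {
  nr <- nrow(grid$class); nc <- ncol(grid$class)
  list(x = grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size,
       y = grid$origin[2] + (seq_len(nr) - 0.5) * grid$cell_size)
}

# (row, col) of the cell containing a point; NA outside the extent
locate_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  col[col < 1 | col > ncol(grid$class)] <- NA
  row[row < 1 | row > nrow(grid$class)] <- NA
  cbind(row = row, col = col)
}

#' Wildfire hotspot filter
#'
#' Retains hotspots with detection confidence at or above `conf_min`, dated
#' within the study window, and whose surrounding land cover (cell centres
#' within `buffer_m` of the hotspot centroid) is at most `max_anthro_frac`
#' agriculture + urban + water. Hotspots outside the land-cover extent are
#' dropped with a warning.
#'
#' @param hotspots data.frame with `x`, `y` (metres), `date` (Date or
#'   ISO-8601 string), `confidence` (percent), `frp` (MW).
#' @param landcover a [landcover_grid()].
#' @param buffer_m buffer radius in metres.
#' @param conf_min minimum detection confidence (percent).
#' @param date_window length-2 Date/character vector, inclusive.
#' @param max_anthro_frac maximum tolerated anthropogenic + water fraction.
#' @return The retained subset of `hotspots`, with an added
#'   `ecoregion_id` column.
#' @export
filter_wildfires <- function(hotspots, landcover, buffer_m = 1000,
                             conf_min = 95,
                             date_window = c("2000-11-01", "2019-12-31"),
                             max_anthro_frac = 0.10) {
  if (nrow(hotspots) == 0) {
    hotspots$ecoregion_id <- character(0)
    return(hotspots)
  }
  dates <- as.Date(hotspots$date)
  win <- as.Date(date_window)
  keep <- hotspots$confidence >= conf_min & dates >= win[1] & dates <= win[2]
  cells <- locate_cell(landcover, hotspots$x, hotspots$y)
  outside <- is.na(cells[, 1]) | is.na(cells[, 2])
  if (any(outside & keep))
    warning(sum(outside & keep), " hotspot(s) outside land-cover extent dropped")
  keep <- keep & !outside
  ctr <- grid_centres(landcover)
  anthro <- landcover$class %in% c("agriculture", "urban", "water")
  dim(anthro) <- dim(landcover$class)
  for (i in which(keep)) {
    # only cells within buffer_m of the hotspot point count
    dx <- ctr$x - hotspots$x[i]
    dy <- ctr$y - hotspots$y[i]
    near_c <- which(abs(dx) <= buffer_m)
    near_r <- which(abs(dy) <= buffer_m)
    d2 <- outer(dy[near_r]^2, dx[near_c]^2, `+`)
    inb <- d2 <= buffer_m^2
    if (!any(inb)) next
    frac <- mean(anthro[near_r, near_c, drop = FALSE][inb])
    if (frac > max_anthro_frac) keep[i] <- FALSE
  }
  out <- hotspots[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  out$ecoregion_id <- landcover$ecoregion[cbind(cells[, 1], cells[, 2])]
  rownames(out) <- NULL
  out
}

#' Ecoregion fire frequency and intensity
#'
#' Fire frequency is the retained hotspot count divided by ecoregion area
#' and multiplied by the ecoregion's vegetated land-cover proportion; fire
#' intensity (FI) is the mean radiative power of the retained hotspots.
#' Ecoregions whose vegetated proportion falls below `min_vegetated` are
#' flagged `excluded` (no large preserved vegetated area).
#'
#' @param retained output of [filter_wildfires()].
#' @param landcover a [landcover_grid()].
#' @param area_km2 optional named vector of ecoregion areas; defaults to
#'   cell counts times cell area.
#' @param min_vegetated exclusion threshold on the vegetated proportion.
#' @return data.frame with `ecoregion_id`, `fire_count`,
#'   `fire_count_per_area`, `FI`, `vegetated_prop`, `excluded`.
#' @export
fire_metrics <- function(retained, landcover, area_km2 = NULL,
                         min_vegetated = 0.5) {
  ids <- sort(unique(as.vector(landcover$ecoregion)))
  ncell <- table(factor(as.vector(landcover$ecoregion), levels = ids))
  if (is.null(area_km2))
    area_km2 <- as.vector(ncell) * (landcover$cell_size / 1000)^2
  else area_km2 <- unname(area_km2[ids])
  if (any(area_km2 <= 0)) stop("zero-area ecoregion")
  veg <- tapply(as.vector(landcover$class) == "natural_vegetated",
                factor(as.vector(landcover$ecoregion), levels = ids), mean)
  cnt <- table(factor(retained$ecoregion_id, levels = ids))
  fi <- tapply(retained$frp, factor(retained$ecoregion_id, levels = ids),
               mean)
  data.frame(ecoregion_id = ids,
             fire_count = as.integer(cnt),
             fire_count_per_area = as.vector(cnt) / area_km2 * as.vector(veg),
             FI = as.vector(fi),
             vegetated_prop = as.vector(veg),
             excluded = as.vector(veg) < min_vegetated,
             row.names = NULL)
}

#' Hurricane activity per ecoregion
#'
#' Six-hourly track points are counted per ecoregion and divided by area.
#'
#' @param tracks data.frame with `x`, `y` (metres); points outside the grid
#'   are ignored.
#' @param landcover a [landcover_grid()] providing the ecoregion raster.
#' @param area_km2 optional named vector of ecoregion areas (km2).
#' @return data.frame with `ecoregion_id`, `HUR` (points per km2).
#' @export
hurricane_rate <- function(tracks, landcover, area_km2 = NULL) {
  ids <- sort(unique(as.vector(landcover$ecoregion)))
  ncell <- table(factor(as.vector(landcover$ecoregion), levels = ids))
  if (is.null(area_km2))
    area_km2 <- as.vector(ncell) * (landcover$cell_size / 1000)^2
  else area_km2 <- unname(area_km2[ids])
  if (nrow(tracks) == 0) {
    return(data.frame(ecoregion_id = ids, HUR = 0, row.names = NULL))
  }
  cells <- locate_cell(landcover, tracks$x, tracks$y)
  inside <- !is.na(cells[, 1])
  eco <- landcover$ecoregion[cbind(cells[inside, 1], cells[inside, 2])]
  cnt <- table(factor(eco, levels = ids))
  data.frame(ecoregion_id = ids, HUR = as.vector(cnt) / area_km2,
             row.names = NULL)
}
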