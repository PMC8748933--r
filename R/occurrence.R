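#' Species occurrence counts on a cell lattice
#'
#' Container for integer occurrence-record counts of species, resolved per
#' grid cell, with each cell assigned to an ecoregion. When abundance is only
#' known at ecoregion resolution, use one cell per ecoregion; all downstream
#' aggregation gives identical results in that case.
#'
#' @param counts integer matrix, cells in rows, species in columns; column
#'   names are species ids.
#' @param cell_ecoregion character vector of length `nrow(counts)` mapping
#'   each cell to its ecoregion id.
#' @return An object of class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(counts, cell_ecoregion) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have species column names")
  if (length(cell_ecoregion) != nrow(counts))
    stop("cell_ecoregion must have one entry per row of counts")
  if (any(counts < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(colnames(counts)))
    stop("species ids must be unique")
  structure(
    list(counts = counts, cell_ecoregion = as.character(cell_ecoregion)),
    class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("<occurrence_matrix> ", ncol(x$counts), " species x ",
      nrow(x$counts), " cells in ", length(unique(x$cell_ecoregion)),
      " ecoregions; total records ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Collapse an occurrence matrix to ecoregion totals
#'
#' @param occ an [occurrence_matrix()].
#' @return integer matrix, ecoregions in rows (named), species in columns.
#' @export
ecoregion_totals <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  rowsum(occ$counts, group = occ$cell_ecoregion, reorder = TRUE)
}

#' Ecoregion ids of an occurrence matrix
#' @param occ an [occurrence_matrix()].
#' @return character vector of unique ecoregion ids, sorted.
#' @export
ecoregion_ids <- function(occ) sort(unique(occ$cell_ecoregion))

# named value vector for one trait; species with missing value are dropped
# (per-trait exclusion, never imputation)
trait_values <- function(traits, trait) {
  rows <- traits$trait_name == trait & !is.na(traits$value)
  stats::setNames(traits$value[rows], traits$species_id[rows])
}

CONTINUOUS_TRAITS <- c("WD", "LeafSize")
BINARY_TRAITS <- c("StemSpines", "LeafSpines", "Latex")
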