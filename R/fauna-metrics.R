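#' Mammal assemblage with per-cell presence maps
#'
#' @param species data.frame with columns `species_id`, `body_mass` (kg),
#'   `diet` (one of browser/grazer/mixed/other), `herbivory_fraction`,
#'   `status` (`"EP_extinct"` or `"extant"`),
#'   `feeds_mainly_on_vegetative` (logical).
#' @param presence 0/1 matrix, cells in rows, species in columns (column
#'   names matching `species$species_id`).
#' @param cell_ecoregion character vector mapping cells to ecoregion ids.
#' @return An object of class `fauna_assemblage`.
#' @export
fauna_assemblage <- function(species, presence, cell_ecoregion) {
  need <- c("species_id", "body_mass", "diet", "herbivory_fraction",
            "status", "feeds_mainly_on_vegetative")
  stopifnot(all(need %in% names(species)))
  presence <- as.matrix(presence)
  if (!setequal(colnames(presence), species$species_id))
    stop("presence columns must match species ids")
  if (nrow(presence) != length(cell_ecoregion))
    stop("grid mismatch: presence has ", nrow(presence),
         " cells but cell_ecoregion has ", length(cell_ecoregion))
  if (any(species$body_mass <= 0)) stop("body_mass must be positive")
  if (any(species$herbivory_fraction < 0 | species$herbivory_fraction > 1))
    stop("herbivory_fraction must be in [0, 1]")
  presence <- presence[, species$species_id, drop = FALSE]
  structure(list(species = species, presence = presence,
                 cell_ecoregion = as.character(cell_ecoregion)),
            class = "fauna_assemblage")
}

#' @export
print.fauna_assemblage <- function(x, ...) {
  cat("<fauna_assemblage> ", nrow(x$species), " species (",
      sum(x$species$status == "EP_extinct"), " extinct) on ",
      nrow(x$presence), " cells\n", sep = "")
  invisible(x)
}

subset_assemblage <- function(assemblage, keep) {
  fauna_assemblage(assemblage$species[keep, , drop = FALSE],
                   assemblage$presence[, keep, drop = FALSE],
                   assemblage$cell_ecoregion)
}

#' Extinct megafauna filter
#'
#' Keeps prehistoric-extinct species with body mass strictly above 50 kg
#' whose diet is at least 90% plants.
#'
#' @param assemblage a [fauna_assemblage()].
#' @return The filtered assemblage (possibly with zero species).
#' @export
filter_megafauna <- function(assemblage) {
  s <- assemblage$species
  subset_assemblage(assemblage, s$status == "EP_extinct" &
                      s$body_mass > 50 & s$herbivory_fraction >= 0.9)
}

#' Extant herbivore filter
#'
#' Keeps extant species that are at least 90% herbivorous and feed mainly on
#' aboveground vegetative tissues (frugivores, granivores and root feeders
#' drop out). No body-size threshold is applied.
#'
#' @inheritParams filter_megafauna
#' @return The filtered assemblage.
#' @export
filter_extant <- function(assemblage) {
  s <- assemblage$species
  subset_assemblage(assemblage, s$status == "extant" &
                      s$herbivory_fraction >= 0.9 &
                      s$feeds_mainly_on_vegetative)
}

#' Mean species richness per ecoregion
#'
#' Cell-level richness is the number of species present in the cell
#' (optionally restricted to one diet guild); the ecoregion value is the
#' mean across all of its cells.
#'
#' @inheritParams filter_megafauna
#' @param diet_filter optional diet guild (`"browser"`, `"grazer"`,
#'   `"mixed"`); `NULL` counts every species.
#' @return data.frame with `ecoregion_id`, `richness`.
#' @export
ecoregion_richness <- function(assemblage, diet_filter = NULL) {
  P <- assemblage$presence
  if (!is.null(diet_filter)) {
    keep <- assemblage$species$diet == diet_filter
    P <- P[, keep, drop = FALSE]
  }
  rich <- if (ncol(P) == 0) rep(0, nrow(P)) else rowSums(P)
  m <- tapply(rich, assemblage$cell_ecoregion, mean)
  data.frame(ecoregion_id = names(m), richness = as.vector(m),
             row.names = NULL)
}

#' Mean body mass per ecoregion
#'
#' Each occupied cell contributes the mean mass of the species present in
#' it; cells with no species are excluded, and ecoregions with no occupied
#' cell get `NA` (a mean of masses is undefined on an empty set).
#'
#' @inheritParams filter_megafauna
#' @return data.frame with `ecoregion_id`, `body_mass` (kg).
#' @export
ecoregion_body_mass <- function(assemblage) {
  P <- assemblage$presence
  mass <- assemblage$species$body_mass
  n <- rowSums(P)
  cellmass <- ifelse(n > 0, as.vector(P %*% mass) / n, NA_real_)
  ids <- sort(unique(assemblage$cell_ecoregion))
  val <- vapply(ids, function(e) {
    v <- cellmass[assemblage$cell_ecoregion == e]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(ecoregion_id = ids, body_mass = as.vector(val),
             row.names = NULL)
}

#' Grazer-minus-browser richness difference
#'
#' @param grazer,browser data.frames from [ecoregion_richness()] for the
#'   grazer and browser guilds (mixed feeders excluded by construction).
#' @return data.frame with `ecoregion_id`, `diff`.
#' @export
diet_difference <- function(grazer, browser) {
  m <- merge(grazer, browser, by = "ecoregion_id",
             suffixes = c("_g", "_b"))
  data.frame(ecoregion_id = m$ecoregion_id,
             diff = m$richness_g - m$richness_b, row.names = NULL)
}

#' Allometric density index per ecoregion
#'
#' Per-species density is `c_coef * mass^b_exp` (Damuth-type scaling by
#' default), summed over the species present in each cell and averaged per
#' ecoregion. Reported alongside its Spearman correlation with richness,
#' which is the diagnostic this index exists for.
#'
#' @inheritParams filter_megafauna
#' @param c_coef,b_exp allometric coefficients; `b_exp` is normally
#'   negative (density declines with mass).
#' @return data.frame with `ecoregion_id`, `density`; the Spearman
#'   correlation with ecoregion richness is attached as attribute
#'   `cor_with_richness`.
#' @export
allometric_density <- function(assemblage, c_coef = 1, b_exp = -0.75) {
  if (b_exp >= 0)
    warning("b_exp >= 0: densities normally decline with body mass")
  d <- c_coef * assemblage$species$body_mass^b_exp
  cellden <- as.vector(assemblage$presence %*% d)
  m <- tapply(cellden, assemblage$cell_ecoregion, mean)
  out <- data.frame(ecoregion_id = names(m), density = as.vector(m),
                    row.names = NULL)
  rich <- ecoregion_richness(assemblage)
  attr(out, "cor_with_richness") <-
    if (stats::sd(out$density) == 0 || stats::sd(rich$richness) == 0) NA_real_
    else stats::cor(out$density, rich$richness, method = "spearman")
  out
}

#' All ecoregion-level fauna metrics for one assemblage pair
#'
#' Convenience wrapper computing, per ecoregion: extinct megafauna richness
#' (M_rich), mean body mass (M_bm), per-guild richness (MG_rich, MB_rich,
#' MMf_rich), grazer-browser difference (MGB_dif), and the extant analogues
#' (H_rich, H_bm, HGB_dif).
#'
#' @param assemblage an unfiltered [fauna_assemblage()]; the megafauna and
#'   extant filters are applied internally.
#' @return data.frame keyed by `ecoregion_id`.
#' @export
fauna_summary <- function(assemblage) {
  mega <- filter_megafauna(assemblage)
  ext <- filter_extant(assemblage)
  out <- ecoregion_richness(mega)
  names(out)[2] <- "M_rich"
  out$M_bm <- ecoregion_body_mass(mega)$body_mass
  mg <- ecoregion_richness(mega, "grazer")
  mb <- ecoregion_richness(mega, "browser")
  out$MG_rich <- mg$richness
  out$MB_rich <- mb$richness
  out$MMf_rich <- ecoregion_richness(mega, "mixed")$richness
  out$MGB_dif <- diet_difference(mg, mb)$diff
  out$H_rich <- ecoregion_richness(ext)$richness
  out$H_bm <- ecoregion_body_mass(ext)$body_mass
  out$HGB_dif <- diet_difference(ecoregion_richness(ext, "grazer"),
                                 ecoregion_richness(ext, "browser"))$diff
  out
}
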