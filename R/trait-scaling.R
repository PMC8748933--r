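#' Summarize raw trait records to one value per species and trait
#'
#' Continuous traits (wood density, leaf size) are averaged across records.
#' Binary traits (stem spines, leaf spines, latex) take the maximum across
#' records, on the assumption that omitting a presence is more likely than
#' reporting a spurious one.
#'
#' @param records data.frame with columns `species_id`, `trait_name`,
#'   `value`. Additional columns are ignored.
#' @return A trait table: data.frame with `species_id`, `trait_name`,
#'   `value`, `n_records`.
#' @export
summarize_species <- function(records) {
  stopifnot(all(c("species_id", "trait_name", "value") %in% names(records)))
  bad <- records$trait_name %in% CONTINUOUS_TRAITS & !is.na(records$value) &
    records$value < 0
  if (any(bad)) {
    warning(sum(bad), " negative continuous trait record(s) rejected")
    records <- records[!bad, , drop = FALSE]
  }
  binv <- records$value[records$trait_name %in% BINARY_TRAITS]
  if (any(!is.na(binv) & !binv %in% c(0, 1)))
    stop("binary trait values must be 0 or 1")
  records <- records[!is.na(records$value), , drop = FALSE]
  key <- interaction(records$species_id, records$trait_name, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    v <- if (d$trait_name[1] %in% BINARY_TRAITS) max(d$value) else mean(d$value)
    data.frame(species_id = d$species_id[1], trait_name = d$trait_name[1],
               value = v, n_records = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$species_id, out$trait_name), , drop = FALSE]
}

#' Abundance-weighted ecoregion means of a continuous trait
#'
#' Within each grid cell the community-weighted mean is
#' sum(abundance x species value) / sum(abundance), restricted to species
#' with a trait value; the ecoregion value is the unweighted mean across its
#' cells (cells with no covered abundance are skipped). Ecoregions with no
#' covered abundance at all get `NA`.
#'
#' @param occ an [occurrence_matrix()].
#' @param traits a trait table as returned by [summarize_species()].
#' @param trait one of `"WD"`, `"LeafSize"`.
#' @param cell_weighting `"unweighted"` (default) averages cell values
#'   equally; `"abundance"` weights cells by their covered abundance.
#' @return data.frame with `ecoregion_id`, `mean`, `n_cells`,
#'   `species_coverage` (number of contributing species in the ecoregion).
#' @export
ecoregion_weighted_mean <- function(occ, traits, trait,
                                    cell_weighting = c("unweighted", "abundance")) {
  cell_weighting <- match.arg(cell_weighting)
  if (!trait %in% c(CONTINUOUS_TRAITS, BINARY_TRAITS))
    stop("unknown trait: ", trait)
  if (trait %in% BINARY_TRAITS)
    stop(trait, " is binary; use ecoregion_binary_counts()")
  vals <- trait_values(traits, trait)
  sp <- intersect(colnames(occ$counts), names(vals))
  A <- occ$counts[, sp, drop = FALSE]
  v <- vals[sp]
  num <- as.vector(A %*% v)
  den <- rowSums(A)
  cwm <- ifelse(den > 0, num / den, NA_real_)
  eco <- occ$cell_ecoregion
  ids <- ecoregion_ids(occ)
  res <- lapply(ids, function(e) {
    i <- which(eco == e & den > 0)
    m <- if (length(i) == 0) NA_real_
         else if (cell_weighting == "unweighted") mean(cwm[i])
         else sum(cwm[i] * den[i]) / sum(den[i])
    cov <- sum(colSums(A[eco == e, , drop = FALSE]) > 0)
    data.frame(ecoregion_id = e, mean = m, n_cells = length(i),
               species_coverage = cov)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Presence/absence record counts of a binary trait per ecoregion
#'
#' Presences are the total abundance of species carrying the trait;
#' absences are the remaining covered abundance (species without a trait
#' value contribute to neither).
#'
#' @inheritParams ecoregion_weighted_mean
#' @param trait `"StemSpines"` or `"Latex"`.
#' @return data.frame with `ecoregion_id`, `presences`, `absences`,
#'   `species_coverage`.
#' @export
ecoregion_binary_counts <- function(occ, traits, trait) {
  if (!trait %in% c(CONTINUOUS_TRAITS, BINARY_TRAITS))
    stop("unknown trait: ", trait)
  if (trait %in% CONTINUOUS_TRAITS)
    stop(trait, " is continuous; use ecoregion_weighted_mean()")
  vals <- trait_values(traits, trait)
  sp <- intersect(colnames(occ$counts), names(vals))
  A <- ecoregion_totals(occ)[, sp, drop = FALSE]
  pres <- as.vector(A %*% vals[sp])
  tot <- rowSums(A)
  data.frame(ecoregion_id = rownames(A),
             presences = as.integer(round(pres)),
             absences = as.integer(round(tot - pres)),
             species_coverage = as.integer(rowSums(A > 0)),
             row.names = NULL)
}

#' Species-level leaf-spine presence counts per ecoregion
#'
#' Leaf spinescence is scored on palms only, and ecoregion abundance is
#' collapsed to presence/absence before counting, so the result is the
#' number of distinct palm species with and without leaf spines present in
#' the ecoregion. Ecoregions without palms get `NA` counts and are flagged.
#'
#' @inheritParams ecoregion_weighted_mean
#' @param palm_species character vector of palm species ids; non-palm
#'   species present in the trait table are excluded with a message.
#' @return data.frame with `ecoregion_id`, `present_species`,
#'   `absent_species`, `no_palms` (logical flag).
#' @export
ecoregion_presence_fraction <- function(occ, traits, palm_species) {
  vals <- trait_values(traits, "LeafSpines")
  nonpalm <- setdiff(names(vals), palm_species)
  if (length(nonpalm) > 0) {
    message(length(nonpalm), " non-palm species excluded from leaf-spine scoring")
    vals <- vals[setdiff(names(vals), nonpalm)]
  }
  sp <- intersect(colnames(occ$counts), names(vals))
  P <- (ecoregion_totals(occ)[, sp, drop = FALSE] > 0) * 1L
  pres <- as.vector(P %*% vals[sp])
  tot <- rowSums(P)
  out <- data.frame(ecoregion_id = rownames(P),
                    present_species = as.integer(pres),
                    absent_species = as.integer(tot - pres),
                    no_palms = tot == 0, row.names = NULL)
  out$present_species[out$no_palms] <- NA_integer_
  out$absent_species[out$no_palms] <- NA_integer_
  out
}
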