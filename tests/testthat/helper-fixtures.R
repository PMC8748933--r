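# random occurrence/trait fixtures and record-level brute-force oracles

random_fixture <- function(n_eco = 5, n_sp = 8, n_cells = 2, seed = 1,
                           coverage = 0.8) {
  set.seed(seed)
  eco_ids <- sprintf("E%02d", seq_len(n_eco))
  sp_ids <- sprintf("S%02d", seq_len(n_sp))
  cells <- rep(eco_ids, each = n_cells)
  counts <- matrix(rpois(length(cells) * n_sp, 3), length(cells), n_sp,
                   dimnames = list(NULL, sp_ids))
  covered <- runif(n_sp) < coverage
  if (!any(covered)) covered[1] <- TRUE
  traits <- rbind(
    data.frame(species_id = sp_ids[covered], trait_name = "WD",
               value = runif(sum(covered), 0.3, 0.9), n_records = 1L),
    data.frame(species_id = sp_ids[covered], trait_name = "StemSpines",
               value = rbinom(sum(covered), 1, 0.4), n_records = 1L),
    data.frame(species_id = sp_ids[covered], trait_name = "LeafSpines",
               value = rbinom(sum(covered), 1, 0.4), n_records = 1L))
  list(occ = occurrence_matrix(counts, cells), traits = traits,
       eco_ids = eco_ids, sp_ids = sp_ids, covered = sp_ids[covered])
}

# record-level loop oracle for the abundance-weighted continuous mean
oracle_weighted_mean <- function(occ, traits, trait) {
  vals <- with(subset(traits, trait_name == trait & !is.na(value)),
               setNames(value, species_id))
  out <- numeric(0)
  for (e in sort(unique(occ$cell_ecoregion))) {
    cells <- which(occ$cell_ecoregion == e)
    cwms <- c()
    for (ci in cells) {
      num <- 0; den <- 0
      for (s in colnames(occ$counts)) {
        if (!s %in% names(vals)) next
        a <- occ$counts[ci, s]
        num <- num + a * vals[[s]]
        den <- den + a
      }
      if (den > 0) cwms <- c(cwms, num / den)
    }
    out[e] <- if (length(cwms)) mean(cwms) else NA_real_
  }
  out
}

oracle_binary_counts <- function(occ, traits, trait) {
  vals <- with(subset(traits, trait_name == trait & !is.na(value)),
               setNames(value, species_id))
  pres <- abs_ <- numeric(0)
  for (e in sort(unique(occ$cell_ecoregion))) {
    cells <- which(occ$cell_ecoregion == e)
    p <- 0; tot <- 0
    for (ci in cells) for (s in colnames(occ$counts)) {
      if (!s %in% names(vals)) next
      a <- occ$counts[ci, s]
      tot <- tot + a
      if (vals[[s]] == 1) p <- p + a
    }
    pres[e] <- p; abs_[e] <- tot - p
  }
  list(presences = pres, absences = abs_)
}

oracle_presence_counts <- function(occ, traits, palm_species) {
  vals <- with(subset(traits, trait_name == "LeafSpines" & !is.na(value)),
               setNames(value, species_id))
  vals <- vals[names(vals) %in% palm_species]
  pres <- abs_ <- numeric(0)
  for (e in sort(unique(occ$cell_ecoregion))) {
    cells <- which(occ$cell_ecoregion == e)
    p <- 0; a <- 0
    for (s in names(vals)) {
      present <- sum(occ$counts[cells, s]) > 0
      if (present && vals[[s]] == 1) p <- p + 1
      if (present && vals[[s]] == 0) a <- a + 1
    }
    pres[e] <- p; abs_[e] <- a
  }
  list(present = pres, absent = abs_)
}

# small fauna fixture with hand-settable masses/diets
small_fauna <- function(species, presence, cell_eco) {
  fauna_assemblage(species, presence, cell_eco)
}

fauna_species_row <- function(id, mass = 100, diet = "browser",
                              herb = 0.95, status = "EP_extinct",
                              veg = TRUE) {
  data.frame(species_id = id, body_mass = mass, diet = diet,
             herbivory_fraction = herb, status = status,
             feeds_mainly_on_vegetative = veg, stringsAsFactors = FALSE)
}
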