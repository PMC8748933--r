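KNOWN_PREDICTORS <- c("M_rich", "M_bm", "M_bm_sq", "MG_rich", "MB_rich",
                      "MMf_rich", "MGB_dif", "H_rich", "H_bm", "H_bm_sq",
                      "HGB_dif", "MAT", "MAR", "RS", "CEC", "pH", "SND",
                      "FI", "fire_count", "HUR", "insular")

#' Configuration of a synthetic study system
#'
#' Defines a self-consistent synthetic world: a lattice of ecoregions with
#' climate/soil/disturbance covariates, a diet-structured mammal assemblage
#' with planted richness geography, plant species whose abundances tilt
#' community trait means along planted linear effects, land cover, fire
#' hotspots, hurricane tracks, and fossil sites with known ground truth.
#'
#' @param n_ecoregions number of ecoregions (>= 10 for covariate
#'   generation).
#' @param n_cells_per_ecoregion occurrence/presence grid cells per
#'   ecoregion.
#' @param n_plant_species,n_fauna_species pool sizes (fauna includes both
#'   extinct and extant species).
#' @param island_fraction fraction of ecoregions that are insular.
#' @param effect_sizes named list per trait (WD, LeafSize, StemSpines,
#'   Latex, LeafSpines) of named numeric vectors of standardized slopes on
#'   ecoregion predictors; these are the planted trait effects.
#' @param target_corr_map_ph sample correlation planted between mean
#'   annual rainfall and soil pH (|r| < 1).
#' @param quantile_rule richness quantile used by the shift rule.
#' @param seed master seed; each component draws from its own derived
#'   stream, so regenerating one component leaves the others unchanged.
#' @param n_extinct number of extinct (EP) megafauna species.
#' @param diet_counts_extinct named counts of classifiable extinct diets
#'   (browser, grazer, mixed); the remainder have unknown diet.
#' @param dispersion negative-binomial size of occurrence counts.
#' @param records_per_cell expected occurrence records per grid cell.
#' @param palm_fraction fraction of plant species that are palms (the
#'   leaf-spine pool).
#' @param trait_coverage fraction of species with data, per trait.
#' @param cluster_separation strength (in community-mean SD units) of the
#'   planted antiherbiome trait centroids; 0 plants no cluster structure.
#' @param residual_trait_sd SD of the ecoregion-level residual trait
#'   geography (the noise term of `D = X beta + noise`); `NULL` uses
#'   `sqrt(max(0.15, 1 - sum(beta^2)))` per trait so that planted slopes
#'   are standardized. Set to 0 (with zero effects and separation) for a
#'   fully exchangeable null world with no trait geography at all.
#' @param savanna_fraction fraction of ecoregions given a savanna biome.
#' @param fossil_composition named counts of fossil sites placed inside
#'   shift ecoregions, adjacent to them, and in stable savannas.
#' @param sites_per_ecoregion_cap maximum fossil sites in one ecoregion.
#' @param landcover_res land-cover pixels per ecoregion edge.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(n_ecoregions = 150, n_cells_per_ecoregion = 4,
                         n_plant_species = 300, n_fauna_species = 126,
                         island_fraction = 0.047,
                         effect_sizes = default_effect_sizes(),
                         target_corr_map_ph = -0.78, quantile_rule = 0.75,
                         seed = 1L, n_extinct = 66,
                         diet_counts_extinct = c(browser = 22, grazer = 16,
                                                 mixed = 15),
                         dispersion = 5, records_per_cell = 400,
                         palm_fraction = 0.15, trait_coverage = 0.85,
                         cluster_separation = 4,
                         residual_trait_sd = NULL,
                         savanna_fraction = 0.08,
                         fossil_composition = c(inside = 13, adjacent = 3,
                                                stable = 6),
                         sites_per_ecoregion_cap = 5,
                         landcover_res = 6) {
  assert_count(n_ecoregions, "n_ecoregions")
  assert_count(n_cells_per_ecoregion, "n_cells_per_ecoregion")
  assert_count(n_plant_species, "n_plant_species")
  assert_count(n_fauna_species, "n_fauna_species")
  if (island_fraction < 0 || island_fraction > 1)
    stop("island_fraction must be in [0, 1]")
  if (abs(target_corr_map_ph) >= 1)
    stop("|target_corr_map_ph| must be < 1")
  if (quantile_rule <= 0 || quantile_rule >= 1)
    stop("quantile_rule must be in (0, 1)")
  if (n_extinct > n_fauna_species)
    stop("n_extinct cannot exceed n_fauna_species")
  if (sum(diet_counts_extinct) > n_extinct)
    stop("diet counts exceed the number of extinct species")
  unknown <- setdiff(unique(unlist(lapply(effect_sizes, names))),
                     KNOWN_PREDICTORS)
  if (length(unknown) > 0)
    stop("effect_sizes name unknown predictor(s): ",
         paste(unknown, collapse = ", "))
  bad <- setdiff(names(effect_sizes),
                 c(CONTINUOUS_TRAITS, BINARY_TRAITS))
  if (length(bad) > 0)
    stop("effect_sizes name unknown trait(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "world_config")
}

#' Default planted trait effects
#'
#' Moderate standardized slopes echoing the qualitative geography the
#' pipeline is built to detect: wood density and leaf spines increase and
#' leaf size decreases with megafauna richness, stem spines respond to soil
#' pH and (quadratically) to megafauna body mass, latex tracks soil
#' chemistry and small extant herbivores.
#'
#' @return named list of named numeric vectors.
#' @export
default_effect_sizes <- function() {
  list(
    WD = c(M_rich = 0.40, MGB_dif = 0.20, CEC = -0.20, HUR = 0.15),
    LeafSize = c(M_rich = -0.40, MAR = 0.30),
    StemSpines = c(pH = 0.40, M_bm = 0.20, M_bm_sq = -0.25, MGB_dif = 0.20),
    Latex = c(H_bm = -0.30, pH = -0.30, CEC = 0.25),
    LeafSpines = c(M_rich = 0.35))
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", x$n_ecoregions, " ecoregions x ",
      x$n_cells_per_ecoregion, " cells, ", x$n_plant_species,
      " plant species, ", x$n_fauna_species, " mammals (", x$n_extinct,
      " extinct), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

BIOME_MOIST <- "Tropical & Subtropical Moist Broadleaf Forests"
BIOME_DRY <- "Tropical & Subtropical Dry Broadleaf Forests"
BIOME_TROP_SAV <- "Tropical & Subtropical Grasslands, Savannas & Shrublands"
BIOME_TEMP_SAV <- "Temperate Grasslands, Savannas & Shrublands"

#' Generate ecoregion covariates
#'
#' Climate, soil, fire, hurricane and insularity covariates on a lattice of
#' ecoregions. Rainfall and soil pH are built from empirically
#' orthonormalized Gaussian factors so their sample correlation equals the
#' configured target exactly (a Gaussian-copula construction; only this one
#' pairwise correlation is constrained). Biomes are assigned from the
#' rainfall gradient: the driest ecoregions become savannas, then dry
#' forests, and the remainder moist forests.
#'
#' @param config a [world_config()].
#' @return data.frame with one row per ecoregion: lattice position, MAT,
#'   MAR, RS, CEC, pH, SND, FI, fire_count, HUR, insular, biome, area_km2.
#' @export
generate_covariates <- function(config) {
  n <- config$n_ecoregions
  if (n < 10)
    stop("need at least 10 ecoregions to enforce the rainfall-pH correlation")
  set.seed(component_seed(config$seed, "covariates"))
  r <- config$target_corr_map_ph
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  z1s <- as.vector(scale(z1))
  e2 <- z2 - z1s * sum(z1s * z2) / sum(z1s^2)
  e2s <- as.vector(scale(e2))
  mar_z <- z1s
  ph_z <- r * z1s + sqrt(1 - r^2) * e2s
  ids <- sprintf("E%03d", seq_len(n))
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  MAR <- pmax(10, 1400 + 600 * mar_z)
  MAT <- stats::rnorm(n, 24, 3)
  n_isl <- round(n * config$island_fraction)
  insular <- rep(FALSE, n)
  insular[sample.int(n, n_isl)] <- TRUE
  # biome from the rainfall gradient
  biome <- rep(BIOME_MOIST, n)
  ord <- order(MAR)
  n_sav <- round(config$savanna_fraction * n)
  n_dry <- round(0.22 * n)
  sav <- ord[seq_len(n_sav)]
  biome[sav] <- ifelse(MAT[sav] < stats::median(MAT), BIOME_TEMP_SAV,
                       BIOME_TROP_SAV)
  biome[ord[n_sav + seq_len(n_dry)]] <- BIOME_DRY
  fire_z <- -0.5 * mar_z + stats::rnorm(n, 0, sqrt(0.75))
  hur <- numeric(n)
  coastal <- sample.int(n, round(0.2 * n))
  hur[coastal] <- stats::rexp(length(coastal), rate = 20)
  data.frame(
    ecoregion_id = ids,
    row = rep(seq_len(nr), each = nc)[seq_len(n)],
    col = rep(seq_len(nc), times = nr)[seq_len(n)],
    MAT = MAT,
    MAR = MAR,
    RS = pmin(95, pmax(5, stats::rnorm(n, 45, 15))),
    CEC = pmax(1, stats::rnorm(n, 16, 6)),
    pH = 5.8 + 0.7 * ph_z,
    SND = pmin(95, pmax(5, stats::rnorm(n, 50, 15))),
    FI = pmax(5, 40 + 18 * fire_z),
    fire_count = stats::rpois(n, exp(1.6 - 0.8 * mar_z)),
    HUR = hur,
    insular = insular,
    biome = biome,
    area_km2 = config$n_cells_per_ecoregion * 1.0,
    stringsAsFactors = FALSE)
}

#' Rook adjacency of the ecoregion lattice
#'
#' @param covariates output of [generate_covariates()] (uses `row`/`col`).
#' @return two-column data.frame of adjacent ecoregion id pairs.
#' @export
world_adjacency <- function(covariates) {
  key <- paste(covariates$row, covariates$col)
  idx <- stats::setNames(covariates$ecoregion_id, key)
  edges <- list()
  for (i in seq_len(nrow(covariates))) {
    right <- idx[paste(covariates$row[i], covariates$col[i] + 1)]
    down <- idx[paste(covariates$row[i] + 1, covariates$col[i])]
    if (!is.na(right))
      edges[[length(edges) + 1]] <- c(covariates$ecoregion_id[i], right)
    if (!is.na(down))
      edges[[length(edges) + 1]] <- c(covariates$ecoregion_id[i], down)
  }
  out <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(out) <- c("from", "to")
  out
}

# planted per-ecoregion guild richness targets; the megafauna-rich set R is
# sized so that the nearest-rank quantile threshold over mainland
# ecoregions exactly separates the two bands
plan_fauna_targets <- function(config, covariates) {
  mainland <- covariates$ecoregion_id[!covariates$insular]
  n_m <- length(mainland)
  h <- n_m - ceiling(config$quantile_rule * n_m) + 1
  sav <- mainland[is_savanna_biome(
    covariates$biome[match(mainland, covariates$ecoregion_id)])]
  if (length(sav) >= h) {
    rich <- sample(sav, h)
  } else {
    forest <- setdiff(mainland, sav)
    rich <- c(sav, sample(forest, h - length(sav)))
  }
  n <- nrow(covariates)
  in_rich <- covariates$ecoregion_id %in% rich
  tg <- data.frame(
    ecoregion_id = covariates$ecoregion_id,
    MG = ifelse(in_rich, sample(3:6, n, TRUE), sample(0:2, n, TRUE)),
    MB = ifelse(in_rich, sample(5:8, n, TRUE), sample(1:4, n, TRUE)),
    MMf = ifelse(in_rich, sample(3:5, n, TRUE), sample(0:3, n, TRUE)),
    Moth = ifelse(in_rich, sample(3:5, n, TRUE), sample(0:3, n, TRUE)))
  isl <- covariates$insular
  tg[isl, c("MG", "MB", "MMf", "Moth")] <-
    lapply(tg[isl, c("MG", "MB", "MMf", "Moth")], function(v) pmax(0, v %/% 2))
  list(targets = tg, rich_set = rich,
       shift_set = setdiff(rich, sav), stable_savanna_set = intersect(rich, sav))
}

#' Generate the mammal assemblage
#'
#' Extinct (EP) megafauna species all exceed 50 kg with >= 90% plant diet;
#' diet guilds follow the configured counts, the remainder having unknown
#' diet. Extant species carry no size threshold and include a share of
#' frugivores that the extant filter is meant to remove. Presence maps
#' follow planted per-ecoregion guild richness targets: a megafauna-rich
#' band (savanna ecoregions plus the planted shift set) against a poorer
#' background, with islands halved.
#'
#' @param config a [world_config()].
#' @param covariates output of [generate_covariates()].
#' @return list with `assemblage` (a [fauna_assemblage()]) and `truth`
#'   (rich/shift/stable-savanna ecoregion sets and the richness targets).
#' @export
generate_fauna <- function(config, covariates) {
  set.seed(component_seed(config$seed, "fauna"))
  n_ext <- config$n_extinct
  dc <- config$diet_counts_extinct
  diet_ext <- sample(c(rep("browser", dc["browser"]),
                       rep("grazer", dc["grazer"]),
                       rep("mixed", dc["mixed"]),
                       rep("other", n_ext - sum(dc))))
  ext <- data.frame(
    species_id = sprintf("X%03d", seq_len(n_ext)),
    body_mass = 50 * (1 + stats::rlnorm(n_ext, meanlog = 0, sdlog = 1)),
    diet = diet_ext,
    herbivory_fraction = stats::runif(n_ext, 0.9, 1),
    status = "EP_extinct",
    feeds_mainly_on_vegetative = TRUE,
    stringsAsFactors = FALSE)
  n_liv <- config$n_fauna_species - n_ext
  frug <- stats::runif(n_liv) < 0.2
  liv <- data.frame(
    species_id = sprintf("L%03d", seq_len(n_liv)),
    body_mass = stats::rlnorm(n_liv, meanlog = 1.5, sdlog = 1.5),
    diet = sample(c("browser", "grazer", "mixed"), n_liv, TRUE,
                  prob = c(0.45, 0.3, 0.25)),
    herbivory_fraction = ifelse(frug, stats::runif(n_liv, 0.3, 0.89),
                                stats::runif(n_liv, 0.9, 1)),
    status = "extant",
    feeds_mainly_on_vegetative = !frug,
    stringsAsFactors = FALSE)
  species <- rbind(ext, liv)
  plan <- plan_fauna_targets(config, covariates)
  tg <- plan$targets
  ncell <- config$n_cells_per_ecoregion
  cell_eco <- rep(covariates$ecoregion_id, each = ncell)
  P <- matrix(0L, length(cell_eco), nrow(species),
              dimnames = list(NULL, species$species_id))
  pools <- list(
    grazer = ext$species_id[ext$diet == "grazer"],
    browser = ext$species_id[ext$diet == "browser"],
    mixed = ext$species_id[ext$diet == "mixed"],
    other = ext$species_id[ext$diet == "other"])
  tgcols <- c(grazer = "MG", browser = "MB", mixed = "MMf", other = "Moth")
  # extant richness gradient follows rainfall, with an island penalty
  mar_z <- zscore(covariates$MAR)
  h_base <- pmax(1, round(8 + 5 * stats::plogis(mar_z) -
                            4 * covariates$insular + stats::rnorm(
                              nrow(covariates), 0, 1)))
  liv_pool <- liv$species_id
  for (i in seq_len(nrow(covariates))) {
    rows <- which(cell_eco == covariates$ecoregion_id[i])
    for (g in names(pools)) {
      k <- tg[i, tgcols[g]]
      if (k <= 0) next
      ord <- sample(pools[[g]])
      for (j in seq_along(rows)) {
        # grazer counts are exact (they sit right on the threshold band);
        # other guilds jitter by one species across cells
        kk <- if (g == "grazer") min(k, length(ord))
              else max(0, min(length(ord), k + sample(-1:1, 1)))
        if (kk > 0) P[rows[j], ord[seq_len(kk)]] <- 1L
      }
    }
    ordl <- sample(liv_pool)
    for (j in seq_along(rows)) {
      kk <- max(1, min(length(ordl), h_base[i] + sample(-1:1, 1)))
      P[rows[j], ordl[seq_len(kk)]] <- 1L
    }
  }
  list(assemblage = fauna_assemblage(species, P, cell_eco),
       truth = plan)
}

# planted antiherbiome labels: megafauna-rich ecoregions split into SLT
# (arid half) and ILW (moist half); elsewhere moist forest is BCL, drier
# biomes SLT, with ILW for the wetter dry forests
plan_antiherbiomes <- function(covariates, rich_set) {
  lab <- rep(NA_character_, nrow(covariates))
  in_rich <- covariates$ecoregion_id %in% rich_set
  med <- stats::median(covariates$MAR[in_rich])
  lab[in_rich] <- ifelse(covariates$MAR[in_rich] <= med, "SLT", "ILW")
  moist <- is_moist_biome(covariates$biome)
  lab[!in_rich & moist] <- "BCL"
  dry <- !in_rich & !moist
  medd <- stats::median(covariates$MAR[dry])
  lab[dry] <- ifelse(covariates$MAR[dry] <= medd, "SLT", "ILW")
  stats::setNames(lab, covariates$ecoregion_id)
}

ANTIHERBIOME_CENTROIDS <- rbind(
  SLT = c(WD = -0.2, LeafSize = -1.2, StemSpines = 1.2,
          LeafSpines = 0.8, Latex = -0.5),
  ILW = c(WD = 1.2, LeafSize = 0.0, StemSpines = -0.3,
          LeafSpines = -0.3, Latex = 0.0),
  BCL = c(WD = -0.5, LeafSize = 1.2, StemSpines = -1.0,
          LeafSpines = -0.5, Latex = 1.0))

#' Generate plant occurrences and traits with planted effects
#'
#' Species carry latent standard-normal trait scores (independent per
#' trait) mapped to wood density, leaf size and the binary defences.
#' Per-ecoregion species weights are exponentially tilted along each
#' trait's planted linear predictor `D = X beta + noise` (plus the
#' antiherbiome centroid offsets), so the expected community-weighted
#' trait mean is linear in `D` and the standardized slope of the
#' aggregated trait on each predictor approaches the planted beta.
#' Occurrence counts are negative-binomial around the tilted weights
#' (occurrence-record counts are overdispersed).
#'
#' @param config a [world_config()].
#' @param covariates ecoregion table carrying every predictor named in
#'   `config$effect_sizes` (i.e. including fauna metrics).
#' @param antiherbiome_labels optional named label vector for the planted
#'   cluster offsets; omitted (or `cluster_separation = 0`) plants none.
#' @return list with `occurrences` (an [occurrence_matrix()]), `traits`
#'   (trait table), `palm_species`, `planted` (the per-trait `D` vectors).
#' @export
generate_occurrences_and_traits <- function(config, covariates,
                                            antiherbiome_labels = NULL) {
  set.seed(component_seed(config$seed, "occurrences"))
  n <- nrow(covariates)
  ns <- config$n_plant_species
  traits_all <- c(CONTINUOUS_TRAITS, BINARY_TRAITS)
  es <- config$effect_sizes
  used <- unique(unlist(lapply(es, names)))
  missing_pred <- setdiff(used, names(covariates))
  if (length(missing_pred) > 0)
    stop("covariate table lacks predictor(s) named in effect_sizes: ",
         paste(missing_pred, collapse = ", "))
  sp_ids <- sprintf("P%03d", seq_len(ns))
  n_palm <- max(1, round(config$palm_fraction * ns))
  palms <- sp_ids[(ns - n_palm + 1):ns]
  U <- matrix(stats::rnorm(ns * length(traits_all)), ns,
              dimnames = list(sp_ids, traits_all))
  D <- matrix(0, n, length(traits_all),
              dimnames = list(covariates$ecoregion_id, traits_all))
  for (tr in traits_all) {
    beta <- es[[tr]]
    beta <- beta[beta != 0]
    d <- numeric(n)
    if (length(beta) > 0) {
      X <- vapply(names(beta), function(p) zscore(covariates[[p]]),
                  numeric(n))
      X[is.na(X)] <- 0      # islands can lack body-mass metrics
      d <- as.vector(X %*% beta)
    }
    sig <- config$residual_trait_sd %||%
      sqrt(max(0.15, 1 - sum(beta^2)))
    if (sig > 0) d <- d + stats::rnorm(n, 0, sig)
    if (!is.null(antiherbiome_labels) && config$cluster_separation > 0) {
      lab <- antiherbiome_labels[covariates$ecoregion_id]
      off <- ANTIHERBIOME_CENTROIDS[lab, tr]
      off[is.na(off)] <- 0
      d <- d + config$cluster_separation * off
    }
    D[, tr] <- d
  }
  # exponential tilt: weight of species s in ecoregion e proportional to
  # exp(alpha_s + gamma * sum_t u_st * D_et); for unit-normal u this shifts
  # the weighted mean of u by gamma * D exactly, per trait, in expectation
  gamma <- 0.6
  alpha <- stats::rnorm(ns, 0, 0.5)
  L <- matrix(rep(alpha, each = n), n, ns) + gamma * (D %*% t(U))
  W <- exp(L - apply(L, 1, max))
  W <- W / rowSums(W)
  ncell <- config$n_cells_per_ecoregion
  cell_eco <- rep(covariates$ecoregion_id, each = ncell)
  mu <- config$records_per_cell * W[rep(seq_len(n), each = ncell), ,
                                    drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = config$dispersion),
                   nrow(mu), ncol(mu), dimnames = list(NULL, sp_ids))
  occ <- occurrence_matrix(counts, cell_eco)
  # species trait values from the latent scores
  val <- list(
    WD = pmax(0.15, 0.58 + 0.12 * U[, "WD"]),
    LeafSize = exp(2.2 + 0.7 * U[, "LeafSize"]),
    StemSpines = as.numeric(U[, "StemSpines"] > stats::qnorm(0.70)),
    Latex = as.numeric(U[, "Latex"] > stats::qnorm(0.65)),
    LeafSpines = as.numeric(U[, "LeafSpines"] > stats::qnorm(0.70)))
  rows <- list()
  for (tr in traits_all) {
    covered <- if (tr == "LeafSpines") sp_ids %in% palms
               else stats::runif(ns) < config$trait_coverage
    rows[[tr]] <- data.frame(species_id = sp_ids[covered], trait_name = tr,
                             value = unname(val[[tr]][covered]),
                             n_records = 1L, stringsAsFactors = FALSE)
  }
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL
  list(occurrences = occ, traits = traits, palm_species = palms,
       planted = D)
}

#' Generate the land-cover grid, fire hotspots and hurricane tracks
#'
#' Each ecoregion is a square block of land-cover pixels, mostly natural
#' vegetation with scattered agriculture, water and urban pixels. Hotspot
#' counts follow the covariate fire counts, with a share of low-confidence
#' and out-of-window detections for the filter to remove; radiative power
#' tracks the covariate fire intensity. Track points are laid in
#' ecoregions with non-zero hurricane activity.
#'
#' @param config a [world_config()].
#' @param covariates output of [generate_covariates()].
#' @return list with `landcover` (a [landcover_grid()]), `hotspots`,
#'   `tracks` (data.frames).
#' @export
generate_disturbance_inputs <- function(config, covariates) {
  set.seed(component_seed(config$seed, "landcover"))
  n <- nrow(covariates)
  res <- config$landcover_res
  nr_e <- max(covariates$row); nc_e <- max(covariates$col)
  cls <- matrix("natural_vegetated", nr_e * res, nc_e * res)
  eco <- matrix(NA_character_, nr_e * res, nc_e * res)
  for (i in seq_len(n)) {
    rr <- (covariates$row[i] - 1) * res + seq_len(res)
    cc <- (covariates$col[i] - 1) * res + seq_len(res)
    eco[rr, cc] <- covariates$ecoregion_id[i]
    block <- sample(c("natural_vegetated", "agriculture", "water", "urban"),
                    res * res, TRUE, prob = c(0.86, 0.08, 0.04, 0.02))
    cls[rr, cc] <- block
  }
  keep <- !is.na(eco)
  cls[!keep] <- "other"
  eco[!keep] <- "none"
  grid <- landcover_grid(cls, eco, cell_size_m = 1000)
  set.seed(component_seed(config$seed, "hotspots"))
  hs <- list()
  for (i in seq_len(n)) {
    k <- stats::rpois(1, covariates$fire_count[i] + 1)
    if (k == 0) next
    x0 <- (covariates$col[i] - 1) * res * 1000
    y0 <- (covariates$row[i] - 1) * res * 1000
    hs[[i]] <- data.frame(
      x = x0 + stats::runif(k, 0, res * 1000),
      y = y0 + stats::runif(k, 0, res * 1000),
      date = as.Date("2000-11-01") +
        ifelse(stats::runif(k) < 0.9,
               sample.int(6900, k, TRUE) - 1, -sample.int(300, k, TRUE)),
      confidence = ifelse(stats::runif(k) < 0.8, stats::runif(k, 95, 100),
                          stats::runif(k, 50, 95)),
      frp = stats::rlnorm(k, log(covariates$FI[i]), 0.4))
  }
  hotspots <- do.call(rbind, hs)
  rownames(hotspots) <- NULL
  set.seed(component_seed(config$seed, "tracks"))
  tk <- list()
  for (i in which(covariates$HUR > 0)) {
    k <- stats::rpois(1, covariates$HUR[i] * covariates$area_km2[i] *
                        res * res)
    if (k == 0) next
    x0 <- (covariates$col[i] - 1) * res * 1000
    y0 <- (covariates$row[i] - 1) * res * 1000
    tk[[length(tk) + 1]] <- data.frame(
      x = x0 + stats::runif(k, 0, res * 1000),
      y = y0 + stats::runif(k, 0, res * 1000))
  }
  tracks <- if (length(tk)) do.call(rbind, tk)
            else data.frame(x = numeric(), y = numeric())
  list(landcover = grid, hotspots = hotspots, tracks = tracks)
}

#' Generate fossil sites with known ground truth
#'
#' Sites with evidence of past savanna dominance are placed inside the
#' true shift ecoregions (locally forest today), in ecoregions adjacent to
#' them (locally forest), and in stable savannas (locally savanna; a third
#' of these are placed as relict savanna patches inside shift ecoregions).
#'
#' @param config a [world_config()].
#' @param truth list with `shift_set` and `stable_savanna_set`.
#' @param adjacency edge list from [world_adjacency()].
#' @return data.frame of fossil sites.
#' @export
generate_fossil_sites <- function(config, truth, adjacency) {
  set.seed(component_seed(config$seed, "sites"))
  comp <- config$fossil_composition
  n_sites <- sum(comp)
  if (n_sites == 0)
    return(data.frame(site_id = character(), ecoregion_id = character(),
                      epoch = character(), past_vegetation = character(),
                      current_local_vegetation = character()))
  cap <- config$sites_per_ecoregion_cap
  shift <- truth$shift_set
  sav <- truth$stable_savanna_set
  a <- adjacency$from; b <- adjacency$to
  adj_cand <- setdiff(unique(c(b[a %in% shift], a[b %in% shift])), shift)
  n_rel <- floor(comp["stable"] / 3)
  need <- c(inside = unname(comp["inside"]) + n_rel,
            adjacent = unname(comp["adjacent"]),
            stable = unname(comp["stable"]) - n_rel)
  avail <- c(inside = length(shift) * cap,
             adjacent = length(adj_cand) * cap,
             stable = length(sav) * cap)
  if (any(need > avail))
    stop("requested fossil sites exceed available ecoregions x cap for: ",
         paste(names(need)[need > avail], collapse = ", "))
  pick <- function(pool, k) sample(rep(pool, cap))[seq_len(k)]
  eco <- c(pick(shift, comp["inside"]), pick(adj_cand, comp["adjacent"]),
           pick(shift, n_rel), pick(sav, comp["stable"] - n_rel))
  local <- c(rep("forest", comp["inside"] + comp["adjacent"]),
             rep("savanna", comp["stable"]))
  data.frame(
    site_id = sprintf("F%02d", seq_len(n_sites)),
    ecoregion_id = eco,
    epoch = sample(c("LGM", "mid-Holocene", "both"), n_sites, TRUE,
                   prob = c(0.45, 0.35, 0.2)),
    past_vegetation = "savanna",
    current_local_vegetation = local,
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study system
#'
#' Runs all component generators in order, computes the fauna metrics that
#' serve as model predictors, and assembles the ground-truth record. Each
#' component uses its own RNG stream derived from the master seed, so the
#' same configuration is bit-identical across runs.
#'
#' @param config a [world_config()].
#' @return An object of class `synthetic_world`: list with `config`,
#'   `covariates` (ecoregion table including fauna metrics), `fauna`,
#'   `occurrences`, `traits`, `palm_species`, `landcover`, `hotspots`,
#'   `tracks`, `fossil_sites`, `adjacency`, `truth`.
#' @export
synthetic_world <- function(config = world_config()) {
  cov <- generate_covariates(config)
  adj <- world_adjacency(cov)
  fa <- generate_fauna(config, cov)
  fs <- fauna_summary(fa$assemblage)
  cov <- merge(cov, fs, by = "ecoregion_id", sort = TRUE)
  cov$M_bm_sq <- zscore(cov$M_bm)^2
  cov$H_bm_sq <- zscore(cov$H_bm)^2
  labels <- plan_antiherbiomes(cov, fa$truth$rich_set)
  ot <- generate_occurrences_and_traits(config, cov, labels)
  dist_in <- generate_disturbance_inputs(config, cov)
  truth <- list(effect_sizes = config$effect_sizes,
                rich_set = fa$truth$rich_set,
                shift_set = fa$truth$shift_set,
                stable_savanna_set = fa$truth$stable_savanna_set,
                antiherbiome = labels,
                planted_D = ot$planted,
                seed = config$seed)
  sites <- generate_fossil_sites(config, truth, adj)
  structure(list(config = config, covariates = cov,
                 fauna = fa$assemblage, occurrences = ot$occurrences,
                 traits = ot$traits, palm_species = ot$palm_species,
                 landcover = dist_in$landcover, hotspots = dist_in$hotspots,
                 tracks = dist_in$tracks, fossil_sites = sites,
                 adjacency = adj, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed ", x$config$seed, ": ",
      nrow(x$covariates), " ecoregions (",
      sum(x$covariates$insular), " insular), ",
      x$config$n_plant_species, " plant species, ",
      nrow(x$fauna$species), " mammals, ",
      length(x$truth$shift_set), " true shift ecoregions, ",
      nrow(x$fossil_sites), " fossil sites\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Occurrences, traits, the ecoregion table, fossil sites and adjacency as
#' CSV; land cover as two character grids with a JSON sidecar; a manifest
#' (config, seed, component checksums) as JSON.
#'
#' @param world a [synthetic_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  occ <- data.frame(cell = seq_len(nrow(world$occurrences$counts)),
                    ecoregion_id = world$occurrences$cell_ecoregion,
                    world$occurrences$counts, check.names = FALSE)
  utils::write.csv(occ, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(world$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(world$covariates, file.path(dir, "ecoregions.csv"),
                   row.names = FALSE)
  utils::write.csv(world$fossil_sites, file.path(dir, "fossil_sites.csv"),
                   row.names = FALSE)
  utils::write.csv(world$adjacency, file.path(dir, "adjacency.csv"),
                   row.names = FALSE)
  utils::write.csv(world$hotspots, file.path(dir, "hotspots.csv"),
                   row.names = FALSE)
  write(apply(world$landcover$class, 1, paste, collapse = ","),
        file.path(dir, "landcover_class.txt"))
  write(apply(world$landcover$ecoregion, 1, paste, collapse = ","),
        file.path(dir, "landcover_ecoregion.txt"))
  sidecar <- list(cell_size_m = world$landcover$cell_size,
                  origin = world$landcover$origin,
                  nrow = nrow(world$landcover$class),
                  ncol = ncol(world$landcover$class))
  jsonlite::write_json(sidecar, file.path(dir, "landcover.json"),
                       auto_unbox = TRUE)
  cfg <- world$config
  cfg$effect_sizes <- lapply(cfg$effect_sizes, as.list)
  manifest <- list(config = cfg[!vapply(cfg, is.function, logical(1))],
                   seed = world$config$seed,
                   checksums = list(
                     occurrences = sum(world$occurrences$counts),
                     traits = nrow(world$traits),
                     sites = nrow(world$fossil_sites)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
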