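small_cfg <- function(seed = 1,
                      fossil_composition = c(inside = 3, adjacent = 1,
                                             stable = 2), ...) {
  world_config(n_ecoregions = 30, n_cells_per_ecoregion = 2,
               n_plant_species = 60, n_fauna_species = 50, n_extinct = 30,
               diet_counts_extinct = c(browser = 10, grazer = 8, mixed = 6),
               fossil_composition = fossil_composition,
               seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(world_config(n_ecoregions = 0), "integer")
  expect_error(world_config(target_corr_map_ph = -1), "< 1")
  expect_error(world_config(island_fraction = 1.2), "island_fraction")
  expect_error(world_config(effect_sizes = list(WD = c(bogus = 0.3))),
               "bogus")
  expect_error(world_config(effect_sizes = list(Height = c(M_rich = 1))),
               "unknown trait")
  expect_error(world_config(n_extinct = 200, n_fauna_species = 100),
               "exceed")
})

test_that("covariates hit the planted rainfall-pH correlation", {
  cfg <- world_config(seed = 1)
  cov <- generate_covariates(cfg)
  expect_gt(cor(cov$MAR, cov$pH), -0.83)
  expect_lt(cor(cov$MAR, cov$pH), -0.73)
  cfg0 <- world_config(seed = 2, target_corr_map_ph = 0)
  cov0 <- generate_covariates(cfg0)
  expect_lt(abs(cor(cov0$MAR, cov0$pH)), 0.2)
  expect_error(generate_covariates(world_config(n_ecoregions = 9)),
               "at least 10")
})

test_that("the same seed reproduces the world bit-exactly", {
  w1 <- synthetic_world(small_cfg(seed = 5))
  w2 <- synthetic_world(small_cfg(seed = 5))
  expect_identical(w1$occurrences$counts, w2$occurrences$counts)
  expect_identical(w1$covariates, w2$covariates)
  expect_identical(w1$fossil_sites, w2$fossil_sites)
  expect_identical(w1$fauna$presence, w2$fauna$presence)
  w3 <- synthetic_world(small_cfg(seed = 6))
  expect_false(identical(w1$occurrences$counts, w3$occurrences$counts))
})

test_that("component RNG streams are independent of one another", {
  cfg <- small_cfg(seed = 7)
  cov1 <- generate_covariates(cfg)
  # drawing fauna in between must not change a regenerated covariate table
  invisible(generate_fauna(cfg, cov1))
  cov2 <- generate_covariates(cfg)
  expect_identical(cov1, cov2)
})

test_that("the configured extinct pool and diet counts are realized", {
  w <- synthetic_world(world_config(
    n_ecoregions = 20, n_cells_per_ecoregion = 1, n_plant_species = 40,
    n_fauna_species = 90, n_extinct = 66,
    diet_counts_extinct = c(browser = 22, grazer = 16, mixed = 15),
    fossil_composition = c(inside = 2, adjacent = 1, stable = 1),
    seed = 3))
  sp <- w$fauna$species
  expect_equal(sum(sp$status == "EP_extinct"), 66)
  ext <- sp[sp$status == "EP_extinct", ]
  expect_equal(unname(table(ext$diet)[c("browser", "grazer", "mixed")]),
               c(22, 16, 15), ignore_attr = TRUE)
  expect_true(all(ext$body_mass > 50))
  expect_true(all(ext$herbivory_fraction >= 0.9))
})

test_that("island ecoregions carry planted lower megafauna richness", {
  w <- synthetic_world(world_config(seed = 8, island_fraction = 0.2,
                                    fossil_composition = c(inside = 3,
                                                           adjacent = 1,
                                                           stable = 2)))
  fs <- fauna_summary(w$fauna)
  isl <- w$covariates$insular[match(fs$ecoregion_id,
                                    w$covariates$ecoregion_id)]
  expect_lt(mean(fs$M_rich[isl]), mean(fs$M_rich[!isl]))
})

test_that("planted positive effects drive the aggregated trait upward", {
  signs <- 0
  for (s in 1:12) {
    w <- synthetic_world(world_config(
      seed = s, n_ecoregions = 60, n_cells_per_ecoregion = 1,
      n_plant_species = 100, n_fauna_species = 70,
      effect_sizes = list(WD = c(M_rich = 0.5)), cluster_separation = 0,
      fossil_composition = c(inside = 2, adjacent = 1, stable = 1)))
    agg <- ecoregion_weighted_mean(w$occurrences, w$traits, "WD")
    d <- merge(agg, w$covariates, by = "ecoregion_id")
    signs <- signs + (coef(lm(mean ~ M_rich, d))["M_rich"] > 0)
  }
  expect_gte(signs, 12 * 0.95 - 1e-9)
})

test_that("a null world leaves aggregated trait-predictor correlations near zero", {
  null_es <- lapply(default_effect_sizes(), function(v) v * 0)
  cors <- vapply(1:10, function(s) {
    w <- synthetic_world(world_config(
      seed = s, n_ecoregions = 60, n_cells_per_ecoregion = 1,
      n_plant_species = 100, n_fauna_species = 70, effect_sizes = null_es,
      cluster_separation = 0,
      fossil_composition = c(inside = 2, adjacent = 1, stable = 1)))
    agg <- ecoregion_weighted_mean(w$occurrences, w$traits, "WD")
    d <- merge(agg, w$covariates, by = "ecoregion_id")
    cor(d$mean, d$M_rich)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("a single plant species makes every ecoregion mean its value", {
  w <- synthetic_world(world_config(
    n_ecoregions = 15, n_cells_per_ecoregion = 1, n_plant_species = 1,
    n_fauna_species = 30, n_extinct = 20,
    diet_counts_extinct = c(browser = 6, grazer = 5, mixed = 4),
    trait_coverage = 1,
    fossil_composition = c(inside = 1, adjacent = 1, stable = 1),
    seed = 9))
  agg <- ecoregion_weighted_mean(w$occurrences, w$traits, "WD")
  v <- w$traits$value[w$traits$trait_name == "WD"]
  expect_true(all(abs(agg$mean[!is.na(agg$mean)] - v) < 1e-12))
})

test_that("fossil sites follow the requested composition and capacity errors fire", {
  w <- synthetic_world(small_cfg(seed = 10))
  sites <- w$fossil_sites
  expect_equal(nrow(sites), 6)
  expect_true(all(sites$past_vegetation == "savanna"))
  inside <- sites$ecoregion_id %in% w$truth$shift_set
  expect_true(all(sites$current_local_vegetation[!inside %in% TRUE |
                                                   sites$current_local_vegetation == "savanna"] %in%
                    c("forest", "savanna")))
  cfg_much <- world_config(
    n_ecoregions = 30, n_cells_per_ecoregion = 2, n_plant_species = 60,
    n_fauna_species = 50, n_extinct = 30,
    diet_counts_extinct = c(browser = 10, grazer = 8, mixed = 6),
    fossil_composition = c(inside = 500, adjacent = 1, stable = 1),
    seed = 10)
  expect_error(synthetic_world(cfg_much), "exceed")
  # zero sites is a valid world
  w0 <- synthetic_world(small_cfg(
    seed = 11, fossil_composition = c(inside = 0, adjacent = 0, stable = 0)))
  expect_equal(nrow(w0$fossil_sites), 0)
})

test_that("world export writes the plain-text bundle with a manifest", {
  w <- synthetic_world(small_cfg(seed = 12))
  dir <- tempfile("world")
  write_world(w, dir)
  files <- list.files(dir)
  expect_true(all(c("occurrences.csv", "traits.csv", "ecoregions.csv",
                    "fossil_sites.csv", "adjacency.csv", "manifest.json",
                    "landcover.json") %in% files))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$checksums$occurrences, sum(w$occurrences$counts))
  unlink(dir, recursive = TRUE)
})
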