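test_that("megafauna filter applies the strict 50 kg, diet and status rules", {
  sp <- rbind(fauna_species_row("a", mass = 60, herb = 0.95),
              fauna_species_row("b", mass = 50, herb = 0.95),
              fauna_species_row("c", mass = 500, herb = 1,
                                status = "extant"),
              fauna_species_row("d", mass = 300, herb = 0.85))
  P <- matrix(1L, 2, 4, dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, c("E1", "E2"))
  kept <- filter_megafauna(fa)$species$species_id
  expect_equal(kept, "a")                  # 50 kg exactly is dropped
})

test_that("extant filter keeps small folivores and drops frugivores", {
  sp <- rbind(fauna_species_row("f1", mass = 2, status = "extant",
                                herb = 0.95, veg = TRUE),
              fauna_species_row("f2", mass = 20, status = "extant",
                                herb = 0.95, veg = FALSE),
              fauna_species_row("f3", mass = 100, status = "EP_extinct"))
  P <- matrix(1L, 1, 3, dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, "E1")
  expect_equal(filter_extant(fa)$species$species_id, "f1")
})

test_that("ecoregion richness is the mean of cell richness", {
  sp <- do.call(rbind, lapply(1:5, function(i)
    fauna_species_row(paste0("s", i))))
  P <- matrix(0L, 2, 5, dimnames = list(NULL, sp$species_id))
  P[1, 1:3] <- 1L
  P[2, 1:5] <- 1L
  fa <- fauna_assemblage(sp, P, c("E1", "E1"))
  expect_equal(ecoregion_richness(fa)$richness, 4.0)
})

test_that("diet-filtered richness is zero for an absent guild", {
  sp <- do.call(rbind, lapply(1:3, function(i)
    fauna_species_row(paste0("s", i), diet = "browser")))
  P <- matrix(1L, 2, 3, dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, c("E1", "E2"))
  expect_true(all(ecoregion_richness(fa, "grazer")$richness == 0))
})

test_that("body mass averages only occupied cells", {
  sp <- rbind(fauna_species_row("a", mass = 100),
              fauna_species_row("b", mass = 300))
  P <- matrix(c(1L, 0L, 1L, 0L), 2, 2, dimnames = list(NULL, c("a", "b")))
  fa <- fauna_assemblage(sp, P, c("E1", "E1"))
  expect_equal(ecoregion_body_mass(fa)$body_mass, 200)  # empty cell excluded
  P0 <- matrix(0L, 1, 2, dimnames = list(NULL, c("a", "b")))
  fa0 <- fauna_assemblage(sp, P0, "E1")
  expect_true(is.na(ecoregion_body_mass(fa0)$body_mass))
})

test_that("single-species world returns its mass everywhere occupied", {
  sp <- fauna_species_row("solo", mass = 77)
  P <- matrix(1L, 3, 1, dimnames = list(NULL, "solo"))
  fa <- fauna_assemblage(sp, P, c("E1", "E2", "E2"))
  expect_true(all(ecoregion_body_mass(fa)$body_mass == 77))
})

test_that("grid mismatch is rejected with dimensions named", {
  sp <- fauna_species_row("a")
  P <- matrix(1L, 3, 1, dimnames = list(NULL, "a"))
  expect_error(fauna_assemblage(sp, P, c("E1", "E2")), "grid mismatch")
})

test_that("diet difference and guild bounds match a brute-force loop", {
  set.seed(5)
  n_sp <- 12
  sp <- do.call(rbind, lapply(1:n_sp, function(i)
    fauna_species_row(paste0("s", i),
                      mass = runif(1, 60, 900),
                      diet = sample(c("browser", "grazer", "mixed",
                                      "other"), 1))))
  P <- matrix(rbinom(6 * n_sp, 1, 0.5), 6,
              dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, rep(c("E1", "E2", "E3"), each = 2))
  mg <- ecoregion_richness(fa, "grazer")
  mb <- ecoregion_richness(fa, "browser")
  dd <- diet_difference(mg, mb)
  expect_equal(dd$diff, mg$richness - mb$richness)
  # brute force per-cell loop for overall richness
  all_r <- ecoregion_richness(fa)
  for (e in unique(fa$cell_ecoregion)) {
    cells <- which(fa$cell_ecoregion == e)
    expect_equal(all_r$richness[all_r$ecoregion_id == e],
                 mean(vapply(cells, function(ci) sum(P[ci, ]), numeric(1))))
  }
  # guild richness can never exceed overall richness
  expect_true(all(mg$richness <= all_r$richness))
  expect_true(all(mg$richness + mb$richness +
                    ecoregion_richness(fa, "mixed")$richness <=
                    all_r$richness))
})

test_that("one cell per ecoregion makes ecoregion metrics equal cell metrics", {
  set.seed(9)
  sp <- do.call(rbind, lapply(1:6, function(i)
    fauna_species_row(paste0("s", i), mass = runif(1, 60, 500))))
  P <- matrix(rbinom(4 * 6, 1, 0.6), 4, dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, paste0("E", 1:4))
  r <- ecoregion_richness(fa)
  expect_equal(r$richness, as.numeric(rowSums(P)[order(paste0("E", 1:4))]))
})

test_that("allometric density reduces to richness at b = 0 and reports the correlation diagnostic", {
  set.seed(2)
  sp <- do.call(rbind, lapply(1:8, function(i)
    fauna_species_row(paste0("s", i), mass = runif(1, 60, 2000))))
  P <- matrix(rbinom(8 * 8, 1, 0.5), 8, dimnames = list(NULL, sp$species_id))
  fa <- fauna_assemblage(sp, P, paste0("E", rep(1:4, each = 2)))
  expect_warning(d0 <- allometric_density(fa, c_coef = 1, b_exp = 0),
                 "decline")
  expect_equal(d0$density, ecoregion_richness(fa)$richness)
  d <- allometric_density(fa)              # Damuth default b = -0.75
  expect_true(is.finite(attr(d, "cor_with_richness")))
  empty <- fauna_assemblage(sp[0, ], P[, 0, drop = FALSE],
                            paste0("E", rep(1:4, each = 2)))
  expect_true(all(allometric_density(empty)$density == 0))
})

test_that("fauna summary computes the guild difference exactly", {
  w <- synthetic_world(world_config(n_ecoregions = 12,
                                    n_cells_per_ecoregion = 2,
                                    n_plant_species = 30,
                                    n_fauna_species = 40, n_extinct = 25,
                                    diet_counts_extinct = c(browser = 8,
                                                            grazer = 7,
                                                            mixed = 5),
                                    fossil_composition = c(inside = 2,
                                                           adjacent = 1,
                                                           stable = 1),
                                    seed = 4))
  fs <- fauna_summary(w$fauna)
  expect_equal(fs$MGB_dif, fs$MG_rich - fs$MB_rich)
  expect_true(all(fs$MG_rich + fs$MB_rich + fs$MMf_rich <= fs$M_rich + 1e-9))
})
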