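TRAIT_FAMILY <- c(WD = "gaussian", LeafSize = "gaussian",
                  StemSpines = "binomial_counts", Latex = "binomial_counts",
                  LeafSpines = "binomial_counts")

# candidate predictors per trait, mirroring the trait-model design:
# hurricane counts enter only for wood density, body-mass quadratics are
# forced for stem spines
trait_candidates <- function(trait) {
  base <- c("M_rich", "M_bm", "MGB_dif", "H_rich", "H_bm", "HGB_dif",
            "MAT", "MAR", "pH", "RS", "CEC", "SND", "FI")
  if (trait == "WD") base <- c(base, "HUR")
  base
}

#' Aggregate all five traits to ecoregion level
#'
#' @param occ an [occurrence_matrix()].
#' @param traits a trait table.
#' @param palm_species palm species ids for the leaf-spine path.
#' @return data.frame keyed by `ecoregion_id` with the trait summary
#'   columns used by the defence matrix and the trait models.
#' @export
scale_traits <- function(occ, traits, palm_species) {
  wd <- ecoregion_weighted_mean(occ, traits, "WD")
  ls_ <- ecoregion_weighted_mean(occ, traits, "LeafSize")
  ss <- ecoregion_binary_counts(occ, traits, "StemSpines")
  lt <- ecoregion_binary_counts(occ, traits, "Latex")
  lsp <- ecoregion_presence_fraction(occ, traits, palm_species)
  out <- data.frame(
    ecoregion_id = wd$ecoregion_id,
    WD_mean = wd$mean, WD_coverage = wd$species_coverage,
    LeafSize_mean = ls_$mean,
    StemSpines_presences = ss$presences, StemSpines_absences = ss$absences,
    Latex_presences = lt$presences, Latex_absences = lt$absences,
    LeafSpines_present_species = lsp$present_species,
    LeafSpines_absent_species = lsp$absent_species,
    no_palms = lsp$no_palms)
  out
}

trait_response <- function(trait, table) {
  switch(trait,
         WD = "WD_mean", LeafSize = "LeafSize_mean",
         StemSpines = c("StemSpines_presences", "StemSpines_absences"),
         Latex = c("Latex_presences", "Latex_absences"),
         LeafSpines = c("LeafSpines_present_species",
                        "LeafSpines_absent_species"))
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes, in order: trait scaling, fauna metrics, disturbance metrics,
#' the per-trait regression protocol, the matrix-randomization null test,
#' the defence matrix / PCA / antiherbiome clustering with group
#' contrasts, and the biome-shift classification validated against the
#' fossil sites. Islands are excluded from the models, the clustering and
#' the shift rule. Stages can be toggled; a stage whose inputs were
#' toggled off refuses with a clear message.
#'
#' @param world a [synthetic_world()] (or a list with the same
#'   components read from files).
#' @param n_reps randomizations for the null test.
#' @param run_models,run_null,run_cluster,run_shift stage toggles.
#' @param traits_to_fit traits to model (default all five).
#' @param seed seed for the randomization stage.
#' @return list of class `pipeline_result` with `ecoregions` (the merged
#'   ecoregion table), `fits`, `nulls`, `defence`, `pca`, `clusters`,
#'   `contrasts`, `thresholds`, `classification`, `fossil_validation`,
#'   and `resolved_config`.
#' @export
run_pipeline <- function(world, n_reps = 200, run_models = TRUE,
                         run_null = TRUE, run_cluster = TRUE,
                         run_shift = TRUE,
                         traits_to_fit = names(TRAIT_FAMILY),
                         seed = world$config$seed) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tl <- stage("trait_scaling",
              scale_traits(world$occurrences, world$traits,
                           world$palm_species))
  fm <- stage("fauna_metrics", fauna_summary(world$fauna))
  dist_fire <- stage("disturbance", {
    kept <- filter_wildfires(world$hotspots, world$landcover)
    fm2 <- fire_metrics(kept, world$landcover)
    hr <- hurricane_rate(world$tracks, world$landcover)
    merge(fm2[c("ecoregion_id", "fire_count_per_area", "FI",
                "vegetated_prop", "excluded")],
          hr, by = "ecoregion_id")
  })
  eco <- world$covariates
  eco <- eco[!names(eco) %in% c("FI", "HUR")]         # recomputed below
  eco <- merge(eco, tl, by = "ecoregion_id")
  eco <- merge(eco, dist_fire, by = "ecoregion_id", all.x = TRUE)
  # ecoregions lacking a retained hotspot keep the covariate intensity
  eco$FI[is.na(eco$FI)] <- mean(eco$FI, na.rm = TRUE)
  mainland <- eco[!eco$insular, , drop = FALSE]
  Mtot <- ecoregion_totals(world$occurrences)
  fits <- nulls <- NULL
  if (run_models) {
    fits <- lapply(traits_to_fit, function(tr) {
      stage(paste0("fit_", tr), fit_trait_model(
        data = mainland,
        response = trait_response(tr, mainland),
        candidates = trait_candidates(tr),
        family = TRAIT_FAMILY[[tr]],
        forced_quadratics = if (tr == "StemSpines")
          c("M_bm_sq", "H_bm_sq") else character(),
        defence_sign = if (tr == "LeafSize") -1 else 1,
        adjacency = world$adjacency))
    })
    names(fits) <- traits_to_fit
  }
  if (run_null) {
    if (!run_models)
      stop("the randomization stage needs the model stage: ",
           "enable run_models")
    nulls <- lapply(traits_to_fit, function(tr) {
      f <- fits[[tr]]
      if (f$empty) return(NULL)
      stage(paste0("null_", tr), coefficient_null_test(
        f, Mtot[f$eco_ids, , drop = FALSE], world$traits, tr,
        n_reps = n_reps, seed = seed,
        palm_species = world$palm_species))
    })
    names(nulls) <- traits_to_fit
  }
  defence <- pca <- clusters <- contrasts <- NULL
  if (run_cluster) {
    defence <- stage("defence_matrix", {
      fill <- NULL
      if (run_models && !is.null(fits$LeafSpines) &&
          !fits$LeafSpines$empty) {
        need <- mainland$ecoregion_id[mainland$no_palms]
        if (length(need) > 0) {
          nd <- mainland[mainland$ecoregion_id %in% need, , drop = FALSE]
          fill <- stats::setNames(
            as.vector(predict(fits$LeafSpines, newdata = nd,
                              type = "response")), nd$ecoregion_id)
        }
      }
      build_defence_matrix(mainland, spine_fill = fill)
    })
    pca <- stage("pca", pca_axes(defence))
    clusters <- stage("clustering",
                      cluster_antiherbiomes(pca$scores, defence))
    contrasts <- stage("contrasts", {
      lab <- clusters$labels
      vars <- c("Dim1", "Dim2", "Dim3")
      sc <- lapply(vars, function(v)
        contrast_groups(pca$scores[, v], lab[rownames(pca$scores)]))
      names(sc) <- vars
      env_vars <- c("M_rich", "M_bm", "MG_rich", "MB_rich", "MGB_dif",
                    "H_rich", "H_bm", "MAT", "MAR", "pH", "CEC", "SND",
                    "RS", "FI", "HUR")
      ev <- lapply(env_vars, function(v) {
        idx <- match(names(lab), mainland$ecoregion_id)
        tryCatch(contrast_groups(mainland[[v]][idx], lab),
                 error = function(e) NULL)
      })
      names(ev) <- env_vars
      c(sc, ev[!vapply(ev, is.null, logical(1))])
    })
  }
  thresholds <- classification <- fossil_validation <- NULL
  if (run_shift) {
    if (!run_cluster)
      stop("the shift stage needs antiherbiome labels: enable run_cluster")
    rule <- shift_rule(quantile = world$config$quantile_rule)
    thresholds <- stage("thresholds", derive_thresholds(mainland, rule))
    classification <- stage("classify_shift",
                            classify_shift(mainland, clusters$labels, rule,
                                           thresholds))
    fossil_validation <- stage("validate_fossils",
                               validate_fossils(world$fossil_sites,
                                                classification,
                                                world$adjacency))
  }
  structure(list(ecoregions = eco, fits = fits, nulls = nulls,
                 defence = defence, pca = pca, clusters = clusters,
                 contrasts = contrasts, thresholds = thresholds,
                 classification = classification,
                 fossil_validation = fossil_validation,
                 resolved_config = list(
                   seed = seed, n_reps = n_reps,
                   r_screen = 0.60, p_cut = 0.05, vif_max = 3.33,
                   quantile = world$config$quantile_rule,
                   confidence_min = 95, buffer_m = 1000,
                   anthropogenic_fraction = 0.10)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$fits))
    for (tr in names(x$fits))
      cat(sprintf("  %-10s selected: %s\n", tr,
                  paste(x$fits[[tr]]$selected, collapse = ", ")))
  if (!is.null(x$clusters))
    cat("  antiherbiomes: k =", x$clusters$k, "(",
        paste(names(table(x$clusters$labels)), collapse = ", "), ")\n")
  if (!is.null(x$fossil_validation)) {
    s <- x$fossil_validation$summary
    cat("  fossil support:", s$n_supporting, "of", s$n_sites, "sites\n")
  }
  invisible(x)
}

#' Write pipeline reports
#'
#' Per-trait model tables (predictor, effect size r, CI, average
#' contribution), the antiherbiome characterization table (per-label area
#' proportions by biome), the shift classification table, the null-test
#' ensemble summaries, and a resolved-config snapshot.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$fits)) {
    tabs <- lapply(names(result$fits), function(tr) {
      f <- result$fits[[tr]]
      if (f$empty) return(NULL)
      es <- f$effect_sizes
      dm <- f$dominance
      data.frame(trait = tr, predictor = es$term, r = es$r,
                 r_low = es$r_low, r_high = es$r_high,
                 avg_contribution = dm$avg_contribution[
                   match(es$term, dm$term)],
                 fitstat = unname(f$fitstat[1]))
    })
    utils::write.csv(do.call(rbind, tabs),
                     file.path(dir, "model_tables.csv"), row.names = FALSE)
  }
  if (!is.null(result$nulls)) {
    ns <- lapply(names(result$nulls), function(tr) {
      n <- result$nulls[[tr]]
      if (is.null(n)) return(NULL)
      cbind(trait = tr, n$summary)
    })
    utils::write.csv(do.call(rbind, ns), file.path(dir, "null_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$clusters)) {
    eco <- result$ecoregions
    lab <- result$clusters$labels
    idx <- match(names(lab), eco$ecoregion_id)
    area <- tapply(eco$area_km2[idx], list(lab, eco$biome[idx]), sum)
    area[is.na(area)] <- 0
    tot <- sum(eco$area_km2[!eco$insular])
    prop <- area / tot
    ct <- data.frame(antiherbiome = rownames(prop), prop,
                     check.names = FALSE)
    utils::write.csv(ct, file.path(dir, "antiherbiome_areas.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(ecoregion_id = names(lab), antiherbiome = unname(lab)),
      file.path(dir, "antiherbiome_labels.csv"), row.names = FALSE)
  }
  if (!is.null(result$classification)) {
    utils::write.csv(result$classification,
                     file.path(dir, "shift_classification.csv"),
                     row.names = FALSE)
    n_shift <- sum(grepl("^ShiftTo", result$classification$class))
    if (n_shift == 0)
      writeLines("none detected",
                 file.path(dir, "shift_none_detected.txt"))
  }
  if (!is.null(result$fossil_validation) &&
      nrow(result$fossil_validation$verdicts) > 0) {
    utils::write.csv(result$fossil_validation$verdicts,
                     file.path(dir, "fossil_validation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$fossil_validation$summary,
                         file.path(dir, "fossil_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$resolved_config,
                       file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
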