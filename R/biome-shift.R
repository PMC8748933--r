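#' Shift-detection rule settings
#'
#' @param quantile the richness quantile defining "megafauna-rich".
#' @param antiherbiomes_eligible antiherbiome labels analogous to African
#'   arid nutrient-rich / mesic nutrient-poor savannas.
#' @param manual_overrides data.frame with columns `ecoregion_id`,
#'   `class` (the class to force), `reason`; applied last and logged
#'   verbatim in the rule trace.
#' @return list of class `shift_rule`.
#' @export
shift_rule <- function(quantile = 0.75,
                       antiherbiomes_eligible = c("SLT", "ILW"),
                       manual_overrides = NULL) {
  stopifnot(quantile > 0, quantile < 1)
  structure(list(quantile = quantile,
                 antiherbiomes_eligible = antiherbiomes_eligible,
                 manual_overrides = manual_overrides),
            class = "shift_rule")
}

#' Derive megafauna richness thresholds
#'
#' Nearest-rank (type-1) empirical quantiles of overall and grazer
#' megafauna richness across the supplied ecoregions; the quantile method
#' is recorded so the thresholds are reproducible.
#'
#' @param fauna data.frame with `M_rich` and `MG_rich` columns over the
#'   non-excluded ecoregions.
#' @param rule a [shift_rule()].
#' @return list with `M_rich`, `MG_rich`, `quantile`, `method`.
#' @export
derive_thresholds <- function(fauna, rule = shift_rule()) {
  if (nrow(fauna) < 4) stop("need at least 4 ecoregions to derive thresholds")
  list(M_rich = nearest_rank_quantile(fauna$M_rich, rule$quantile),
       MG_rich = nearest_rank_quantile(fauna$MG_rich, rule$quantile),
       quantile = rule$quantile, method = "nearest-rank (type 1)")
}

is_forest_biome <- function(b) grepl("Forest", b, ignore.case = TRUE)
is_moist_biome <- function(b) grepl("Moist", b, ignore.case = TRUE)
is_savanna_biome <- function(b) grepl("Savanna|Grassland", b,
                                      ignore.case = TRUE)

#' Classify ecoregions as stable savannas or savanna-to-forest shifts
#'
#' An ecoregion is classified `ShiftToMoistForest` / `ShiftToDryForest`
#' when it (1) is currently forest-dominated, (2) carries an eligible
#' antiherbiome label, and (3) has both overall and grazer megafauna
#' richness at or above the derived quantile thresholds. A currently
#' savanna-dominated ecoregion meeting the fauna criteria is a
#' `StableSavanna`. Everything else (including ecoregions without an
#' antiherbiome label) is `NotApplicable`. Manual overrides are applied
#' last and recorded in the trace.
#'
#' @param ecoregions data.frame with `ecoregion_id`, `biome`, `M_rich`,
#'   `MG_rich`.
#' @param labels named character vector (or data.frame with
#'   `ecoregion_id`, `antiherbiome`) of antiherbiome labels.
#' @param rule a [shift_rule()].
#' @param thresholds from [derive_thresholds()]; derived from `ecoregions`
#'   when `NULL`.
#' @return data.frame with `ecoregion_id`, `class` and rule-trace columns
#'   (`forest`, `savanna`, `eligible_antiherbiome`, `m_rich_ok`,
#'   `mg_rich_ok`, `override`).
#' @export
classify_shift <- function(ecoregions, labels, rule = shift_rule(),
                           thresholds = NULL) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$antiherbiome, labels$ecoregion_id)
  if (is.null(thresholds)) thresholds <- derive_thresholds(ecoregions, rule)
  lab <- unname(labels[as.character(ecoregions$ecoregion_id)])
  tr <- data.frame(
    ecoregion_id = ecoregions$ecoregion_id,
    antiherbiome = as.vector(lab),
    forest = is_forest_biome(ecoregions$biome),
    savanna = is_savanna_biome(ecoregions$biome),
    eligible_antiherbiome = !is.na(lab) &
      lab %in% rule$antiherbiomes_eligible,
    m_rich_ok = ecoregions$M_rich >= thresholds$M_rich,
    mg_rich_ok = ecoregions$MG_rich >= thresholds$MG_rich,
    override = NA_character_)
  fauna_ok <- tr$m_rich_ok & tr$mg_rich_ok
  cls <- rep("NotApplicable", nrow(tr))
  shift <- tr$forest & tr$eligible_antiherbiome & fauna_ok
  cls[shift & is_moist_biome(ecoregions$biome)] <- "ShiftToMoistForest"
  cls[shift & !is_moist_biome(ecoregions$biome)] <- "ShiftToDryForest"
  cls[tr$savanna & fauna_ok] <- "StableSavanna"
  cls[is.na(lab) & tr$forest] <- "NotApplicable"
  ov <- rule$manual_overrides
  if (!is.null(ov)) {
    for (i in seq_len(nrow(ov))) {
      j <- which(tr$ecoregion_id == ov$ecoregion_id[i])
      if (length(j) == 1) {
        cls[j] <- ov$class[i]
        tr$override[j] <- ov$reason[i]
      }
    }
  }
  tr$class <- cls
  tr[c("ecoregion_id", "class", "antiherbiome", "forest", "savanna",
       "eligible_antiherbiome", "m_rich_ok", "mg_rich_ok", "override")]
}

#' Validate the shift classification against fossil sites
#'
#' A site with evidence of past savanna dominance supports a
#' savanna-to-forest shift when its present local vegetation is forest and
#' it lies inside a shift-classified ecoregion, or inside any other
#' ecoregion adjacent to one. Sites whose ecoregion is unknown are
#' excluded and counted.
#'
#' @param sites data.frame with `site_id`, `ecoregion_id`, `epoch`,
#'   `past_vegetation`, `current_local_vegetation`.
#' @param classification output of [classify_shift()].
#' @param adjacency two-column data.frame of adjacent ecoregion id pairs.
#' @return list with per-site `verdicts` (data.frame) and `summary`
#'   (n_sites, n_supporting, n_inside, n_nearby, n_nonsupporting,
#'   n_excluded, support_fraction; the fraction is `NA` for zero sites).
#' @export
validate_fossils <- function(sites, classification, adjacency) {
  shift_ids <- classification$ecoregion_id[
    grepl("^ShiftTo", classification$class)]
  if (nrow(sites) == 0) {
    return(list(verdicts = data.frame(),
                summary = list(n_sites = 0L, n_supporting = 0L,
                               n_inside = 0L, n_nearby = 0L,
                               n_nonsupporting = 0L, n_excluded = 0L,
                               support_fraction = NA_real_)))
  }
  known <- sites$ecoregion_id %in% classification$ecoregion_id
  excluded <- sum(!known)
  s <- sites[known, , drop = FALSE]
  a <- as.character(adjacency[[1]]); b <- as.character(adjacency[[2]])
  neighbours <- function(e) c(b[a == e], a[b == e])
  inside <- s$ecoregion_id %in% shift_ids
  nearby <- !inside & vapply(as.character(s$ecoregion_id), function(e)
    any(neighbours(e) %in% shift_ids), logical(1))
  forest_local <- s$current_local_vegetation == "forest"
  supports <- forest_local & (inside | nearby)
  verdicts <- data.frame(
    site_id = s$site_id, ecoregion_id = s$ecoregion_id,
    local_forest = forest_local, inside_shift = inside,
    near_shift = nearby, supports_shift = supports,
    reason = ifelse(supports & inside, "forest locally, inside shift ecoregion",
             ifelse(supports, "forest locally, adjacent to shift ecoregion",
             ifelse(!forest_local, "local vegetation still savanna",
                    "forest locally but away from any shift ecoregion"))),
    row.names = NULL)
  list(verdicts = verdicts,
       summary = list(
         n_sites = nrow(s),
         n_supporting = sum(supports),
         n_inside = sum(supports & inside),
         n_nearby = sum(supports & nearby),
         n_nonsupporting = sum(!supports),
         n_excluded = excluded,
         support_fraction = if (nrow(s) == 0) NA_real_
                            else sum(supports) / nrow(s)))
}
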