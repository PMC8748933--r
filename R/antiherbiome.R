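DEFENCE_COLS <- c("WD", "LeafSize", "StemSpines_prop", "LeafSpines_prop",
                  "Latex_prop")

#' Build the five-trait ecoregion defence matrix
#'
#' Assembles one row per ecoregion with wood density, leaf size, and the
#' proportions of spiny-stemmed, spiny-leaved and latex-bearing plants,
#' then standardizes each column to zero mean and unit variance. Binary
#' traits enter as proportions (presences over presences + absences; for
#' leaf spines, species with over species without). Ecoregions lacking
#' palms have their leaf-spine proportion filled from supplied predicted
#' probabilities (the fitted leaf-spine model); ecoregions missing any
#' other trait are excluded and logged.
#'
#' @param summaries data.frame keyed by `ecoregion_id` with columns
#'   `WD_mean`, `LeafSize_mean`, `StemSpines_presences`,
#'   `StemSpines_absences`, `Latex_presences`, `Latex_absences`,
#'   `LeafSpines_present_species`, `LeafSpines_absent_species`.
#' @param spine_fill named numeric vector of predicted leaf-spine
#'   probabilities used to fill ecoregions without palms (names are
#'   ecoregion ids); `NULL` leaves them excluded.
#' @return An object of class `defence_matrix`: list with `raw` and `std`
#'   matrices (rownames = ecoregion ids), `filled` (ids whose leaf-spine
#'   value was model-filled), `excluded` (ids dropped for missing traits).
#' @export
build_defence_matrix <- function(summaries, spine_fill = NULL) {
  raw <- data.frame(
    WD = summaries$WD_mean,
    LeafSize = summaries$LeafSize_mean,
    StemSpines_prop = summaries$StemSpines_presences /
      (summaries$StemSpines_presences + summaries$StemSpines_absences),
    LeafSpines_prop = summaries$LeafSpines_present_species /
      (summaries$LeafSpines_present_species +
         summaries$LeafSpines_absent_species),
    Latex_prop = summaries$Latex_presences /
      (summaries$Latex_presences + summaries$Latex_absences),
    row.names = summaries$ecoregion_id)
  filled <- character()
  if (!is.null(spine_fill)) {
    need <- rownames(raw)[is.na(raw$LeafSpines_prop)]
    can <- intersect(need, names(spine_fill))
    raw[can, "LeafSpines_prop"] <- spine_fill[can]
    filled <- can
  }
  ok <- stats::complete.cases(raw)
  excluded <- rownames(raw)[!ok]
  if (length(excluded) > 0)
    message(length(excluded), " ecoregion(s) excluded for missing traits")
  raw <- raw[ok, , drop = FALSE]
  sds <- vapply(raw, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  std <- scale(as.matrix(raw))
  structure(list(raw = as.matrix(raw), std = std, filled = filled,
                 excluded = excluded), class = "defence_matrix")
}

#' @export
print.defence_matrix <- function(x, ...) {
  cat("<defence_matrix> ", nrow(x$std), " ecoregions x ", ncol(x$std),
      " traits (", length(x$filled), " leaf-spine cells model-filled, ",
      length(x$excluded), " ecoregions excluded)\n", sep = "")
  invisible(x)
}

#' Principal component axes of the defence matrix
#'
#' Eigendecomposition of the standardized trait matrix (equivalently of the
#' trait correlation matrix). The sign convention fixes the first axis to
#' correlate positively with the stem-spine proportion, so that positive
#' Dim1 is the physical-defence pole of the physical-chemical axis.
#'
#' @param dm a [build_defence_matrix()] result.
#' @return list with `scores` (ecoregions x axes), `loadings`,
#'   `var_frac` (variance fraction per axis).
#' @export
pca_axes <- function(dm) {
  X <- dm$std
  if (qr(X)$rank < 3) stop("defence matrix has rank < 3")
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- p$x
  loadings <- p$rotation
  colnames(scores) <- colnames(loadings) <-
    paste0("Dim", seq_len(ncol(scores)))
  # sign convention: Dim1 positively loaded on stem spines
  if (loadings["StemSpines_prop", 1] < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  list(scores = scores, loadings = loadings,
       var_frac = p$sdev^2 / sum(p$sdev^2))
}

# within-group sum of squares for a labelled score matrix
within_inertia <- function(S, labels) {
  sum(vapply(split(seq_len(nrow(S)), labels), function(i) {
    Si <- S[i, , drop = FALSE]
    sum(scale(Si, scale = FALSE)^2)
  }, numeric(1)))
}

#' Cluster ecoregions into antiherbiomes
#'
#' Ward-linkage hierarchical clustering on the retained principal-component
#' scores. The number of clusters is where partitioning stops paying:
#' splitting continues while each further split still removes far more
#' within-group inertia than a structureless split would (at least six
#' times the noise floor, estimated as the median inertia loss of the
#' deepest splits considered), and k is the last such split. The raw
#' inertia loss alone cannot choose k — the first split always removes the
#' most — hence the comparison against the noise floor. When even the
#' first split fails the bar, k = 2 is returned with a weak-structure
#' warning. Cluster labels are mapped to antiherbiome names by trait
#' profile: small leaves + stem spines = SLT, highest wood density = ILW,
#' large leaves + latex = BCL; when more clusters than syndromes are found,
#' the extras map to their nearest syndrome (two spatial clusters may share
#' a defence strategy).
#'
#' @param scores score matrix from [pca_axes()].
#' @param dm the [build_defence_matrix()] used for the scores (for the
#'   profile-based label mapping).
#' @param k_max largest number of clusters considered (must be < n).
#' @param axes which score columns to cluster on (default all).
#' @return list with `labels` (named character vector of antiherbiome
#'   names), `k`, `inertia` (within-group inertia by k), `ratio` (the
#'   selection criterion by k), `hclust`, `weak_structure` (TRUE when the
#'   criterion is nearly flat).
#' @export
cluster_antiherbiomes <- function(scores, dm, k_max = 8,
                                  axes = seq_len(ncol(scores))) {
  S <- scores[, axes, drop = FALSE]
  n <- nrow(S)
  if (k_max >= n) stop("k_max must be smaller than the number of ecoregions")
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  ks <- 1:(min(k_max, n - 1) + 1)
  W <- vapply(ks, function(k) within_inertia(S, stats::cutree(hc, k)),
              numeric(1))
  gain <- -diff(W)                       # inertia removed by moving to k+1
  names(gain) <- ks[-1]
  kk <- 2:min(k_max, length(gain))
  ratio <- gain[as.character(kk)] / pmax(gain[as.character(kk + 1)], 1e-12)
  # noise floor: the inertia a split harvests once no structure is left,
  # estimated from the deepest splits considered. Partitioning continues
  # while every split still removes well above that floor; k is the last
  # such split (ties toward fewer clusters by construction).
  noise <- stats::median(gain[as.character(utils::tail(ks[-1], 4))])
  qual <- gain[as.character(kk)] >= 6 * noise
  weak <- !qual[1]
  if (weak) {
    warning("weak cluster structure: no split clears the inertia noise floor")
    k <- 2L
  } else {
    k <- if (all(qual)) max(kk) else kk[which.min(qual) - 1L]
  }
  cl <- stats::cutree(hc, k)
  labels <- map_antiherbiome_names(dm$std[rownames(S), , drop = FALSE], cl)
  list(labels = labels, k = k, inertia = stats::setNames(W, ks),
       ratio = ratio, hclust = hc, weak_structure = weak)
}

# assign SLT / ILW / BCL by standardized cluster trait profiles
map_antiherbiome_names <- function(std, cl) {
  ks <- sort(unique(cl))
  prof <- t(vapply(ks, function(k) colMeans(std[cl == k, , drop = FALSE]),
                   numeric(ncol(std))))
  rownames(prof) <- ks
  score <- cbind(
    SLT = prof[, "StemSpines_prop"] - prof[, "LeafSize"],
    ILW = prof[, "WD"],
    BCL = prof[, "LeafSize"] + prof[, "Latex_prop"])
  names_out <- stats::setNames(rep(NA_character_, length(ks)), ks)
  pool <- colnames(score)
  left <- as.character(ks)
  while (length(pool) > 0 && length(left) > 0) {
    best <- which(score[left, pool, drop = FALSE] ==
                    max(score[left, pool, drop = FALSE]), arr.ind = TRUE)[1, ]
    names_out[left[best[1]]] <- pool[best[2]]
    left <- left[-best[1]]
    pool <- pool[-best[2]]
  }
  # more clusters than syndromes: the extras are spatial sub-clusters of a
  # strategy, so they take their nearest syndrome (duplicates allowed)
  left_over <- names(names_out)[is.na(names_out)]
  if (length(left_over) > 0)
    names_out[left_over] <- colnames(score)[
      apply(score[left_over, , drop = FALSE], 1, which.max)]
  out <- names_out[as.character(cl)]
  names(out) <- names(cl)
  out
}

# Dunn's pairwise rank-based z tests following a Kruskal-Wallis test,
# with the usual tie correction
dunn_pairs <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  gs <- names(rbar)
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ns[p[1]] + 1 / ns[p[2]]))
    z <- (rbar[p[1]] - rbar[p[2]]) / se
    data.frame(group1 = p[1], group2 = p[2], z = as.vector(z),
               p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }))
}

#' Kruskal-Wallis and Dunn post-hoc contrasts among antiherbiomes
#'
#' Global Kruskal-Wallis test followed by pairwise Dunn z tests with
#' Benjamini-Hochberg correction. Groups with fewer than 2 members are
#' excluded from the pairwise stage and flagged.
#'
#' @param values numeric vector (e.g. an axis score or an environment
#'   variable per ecoregion).
#' @param labels group labels aligned with `values`.
#' @return list with `kw` (statistic, df, p), `pairwise` (data.frame with
#'   z, raw and BH-adjusted p), `excluded_groups`.
#' @export
contrast_groups <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(labels[ok])
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    keep <- !labels %in% small
    values <- values[keep]; labels <- droplevels(labels[keep])
  }
  if (nlevels(labels) < 2)
    stop("need at least 2 groups with at least 2 members")
  kw <- stats::kruskal.test(values, labels)
  pw <- dunn_pairs(values, labels)
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(kw = list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw, excluded_groups = small)
}

#' Synthetic defence-trait clusters with controlled separation
#'
#' Generates `n` ecoregion trait rows in `k` compact clusters whose
#' centroids are at least `separation` pooled within-cluster profile
#' standard deviations apart. Within-cluster noise is an isotropic
#' Gaussian on the 5-trait profile, scaled to unit profile SD and
#' truncated at radius 1.35, so clusters separated by 3 or more profile
#' SDs are geometrically disjoint and recovery is unambiguous.
#'
#' @param n rows; split as evenly as possible across clusters.
#' @param k number of clusters.
#' @param separation minimum centroid distance in profile-SD units.
#' @param seed integer seed.
#' @return list with `matrix` (n x 5 trait matrix) and `truth` (integer
#'   cluster labels).
#' @export
simulate_defence_clusters <- function(n = 150, k = 3, separation = 3,
                                      seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(k), length.out = n)
  # centroid directions chosen to straddle the origin
  dirs <- matrix(stats::rnorm(k * 5), k, 5)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs <- scale(dirs, scale = FALSE)
  dd <- as.matrix(stats::dist(dirs))
  mind <- min(dd[dd > 0])
  cent <- dirs * (separation / mind)
  # isotropic profile noise: unit profile SD, truncated at radius 1.35
  E <- matrix(stats::rnorm(n * 5, 0, sqrt(1 / 5)), n, 5)
  r <- sqrt(rowSums(E^2))
  over <- r > 1.35
  E[over, ] <- E[over, , drop = FALSE] * (1.35 / r[over])
  X <- cent[cl, ] + E
  colnames(X) <- DEFENCE_COLS
  rownames(X) <- sprintf("E%03d", seq_len(n))
  list(matrix = X, truth = stats::setNames(cl, rownames(X)))
}
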