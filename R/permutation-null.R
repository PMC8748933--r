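#' Randomize a species-abundance-by-ecoregion matrix
#'
#' Randomization operates at ecoregion resolution (rows = ecoregions,
#' columns = species). Available schemes and their conserved quantities:
#' `shuffle_species_columns` permutes each species' abundances across
#' ecoregions independently (per-species totals conserved; decouples traits
#' from geography while preserving species prevalence),
#' `shuffle_ecoregion_rows` permutes whole ecoregion rows (row composition
#' conserved), and `fixed_marginals_swap` performs diagonal unit swaps on
#' random 2x2 submatrices (both row and column sums conserved).
#'
#' @param M integer matrix, ecoregions in rows, species in columns.
#' @param scheme randomization scheme id.
#' @param n_swaps number of attempted swaps for `fixed_marginals_swap`
#'   (default 10 x number of non-zero entries).
#' @return A randomized matrix with the same dimnames.
#' @export
randomize_matrix <- function(M, scheme = c("shuffle_species_columns",
                                           "shuffle_ecoregion_rows",
                                           "fixed_marginals_swap"),
                             n_swaps = NULL) {
  if (is.character(scheme) && length(scheme) == 1 &&
      !scheme %in% c("shuffle_species_columns", "shuffle_ecoregion_rows",
                     "fixed_marginals_swap"))
    stop("unknown scheme '", scheme, "'; options: shuffle_species_columns, ",
         "shuffle_ecoregion_rows, fixed_marginals_swap")
  scheme <- match.arg(scheme)
  n <- nrow(M); s <- ncol(M)
  if (n < 2) return(M)
  switch(scheme,
    shuffle_species_columns = {
      idx <- vapply(seq_len(s), function(j) sample.int(n), integer(n))
      out <- M
      out[] <- M[cbind(as.vector(idx), rep(seq_len(s), each = n))]
      out
    },
    shuffle_ecoregion_rows = {
      out <- M[sample.int(n), , drop = FALSE]
      rownames(out) <- rownames(M)
      out
    },
    fixed_marginals_swap = {
      if (s < 2) return(M)
      out <- M
      k <- n_swaps %||% (10L * sum(M > 0))
      r1 <- sample.int(n, k, replace = TRUE)
      r2 <- sample.int(n, k, replace = TRUE)
      c1 <- sample.int(s, k, replace = TRUE)
      c2 <- sample.int(s, k, replace = TRUE)
      for (i in seq_len(k)) {
        if (r1[i] == r2[i] || c1[i] == c2[i]) next
        a <- out[r1[i], c1[i]]; d <- out[r2[i], c2[i]]
        if (a > 0 && d > 0) {
          out[r1[i], c1[i]] <- a - 1L
          out[r2[i], c2[i]] <- d - 1L
          out[r1[i], c2[i]] <- out[r1[i], c2[i]] + 1L
          out[r2[i], c1[i]] <- out[r2[i], c1[i]] + 1L
        }
      }
      out
    })
}

# recompute the model response from a (possibly randomized) ecoregion x
# species matrix; returns a vector (gaussian CWM) or 2-col count matrix.
# This is the one-cell-per-ecoregion aggregation path expressed as direct
# matrix algebra; its equality with the cell-level operations is tested.
response_from_matrix <- function(M, traits, trait,
                                 palm_species = NULL) {
  if (trait %in% CONTINUOUS_TRAITS) {
    vals <- trait_values(traits, trait)
    sp <- intersect(colnames(M), names(vals))
    A <- M[, sp, drop = FALSE]
    den <- rowSums(A)
    stats::setNames(ifelse(den > 0, as.vector(A %*% vals[sp]) / den,
                           NA_real_), rownames(M))
  } else if (trait == "LeafSpines") {
    vals <- trait_values(traits, trait)
    keep <- intersect(names(vals), palm_species %||% names(vals))
    sp <- intersect(colnames(M), keep)
    P <- (M[, sp, drop = FALSE] > 0) * 1L
    pres <- as.vector(P %*% vals[sp])
    out <- cbind(present_species = pres, absent_species = rowSums(P) - pres)
    rownames(out) <- rownames(M)
    out
  } else {
    vals <- trait_values(traits, trait)
    sp <- intersect(colnames(M), names(vals))
    A <- M[, sp, drop = FALSE]
    pres <- as.vector(A %*% vals[sp])
    out <- cbind(presences = pres, absences = rowSums(A) - pres)
    rownames(out) <- rownames(M)
    out
  }
}

#' Randomization test of model coefficients
#'
#' Re-estimates the selected model on trait values derived from `n_reps`
#' randomizations of the species-abundance-by-ecoregion matrix and compares
#' each observed coefficient to the 0.05-0.95 quantile band of its null
#' distribution. The selected predictor set is held fixed across replicates
#' (the comparison is between the original coefficients and their
#' re-estimates under a decoupled trait geography).
#'
#' @param fit a [fit_trait_model()] result (or a list with `selected`,
#'   `family`, `data`, `y`, `eco_ids`).
#' @param M ecoregion-by-species abundance matrix for the response trait
#'   (rows named by ecoregion id).
#' @param traits trait table covering the response trait.
#' @param trait the response trait name.
#' @param n_reps number of randomizations (>= 1; >= 100 recommended for
#'   quantile stability).
#' @param scheme randomization scheme, see [randomize_matrix()].
#' @param seed optional integer seed for the ensemble.
#' @param band two-sided quantile band (defaults to 0.05 and 0.95).
#' @param palm_species palm species ids (leaf spines only).
#' @param max_fail_frac abort when more than this fraction of replicate
#'   fits fail.
#' @return An object of class `null_ensemble`: data.frame `summary` with
#'   one row per coefficient (observed, q05, q95, outside-band verdict),
#'   plus the per-replicate coefficient matrix.
#' @export
coefficient_null_test <- function(fit, M, traits, trait, n_reps = 1000,
                                  scheme = "shuffle_species_columns",
                                  seed = NULL, band = c(0.05, 0.95),
                                  palm_species = NULL,
                                  max_fail_frac = 0.05) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  terms <- fit$selected
  if (length(terms) == 0) stop("the selected model is empty")
  data <- fit$data
  eco <- fit$eco_ids
  observed <- fit$coefficients[setdiff(names(fit$coefficients),
                                       "(Intercept)")]
  reps <- matrix(NA_real_, n_reps, length(observed),
                 dimnames = list(NULL, names(observed)))
  fails <- 0L
  # fixed design across replicates: factor the model matrix once
  Xd <- cbind(`(Intercept)` = 1, as.matrix(data[terms]))
  qrX <- if (fit$family == "gaussian") qr(Xd) else NULL
  for (i in seq_len(n_reps)) {
    Mi <- randomize_matrix(M, scheme)
    resp <- response_from_matrix(Mi, traits, trait, palm_species)
    co <- tryCatch({
      if (fit$family == "gaussian") {
        yv <- resp[eco]
        if (anyNA(yv)) {
          ok <- !is.na(yv)
          f <- fit_terms(yv[ok], data[ok, , drop = FALSE], terms, "gaussian")
          stats::coef(f$fit)[names(observed)]
        } else {
          qr.coef(qrX, yv)[names(observed)]
        }
      } else {
        ym <- resp[eco, , drop = FALSE]
        ok <- stats::complete.cases(ym) & rowSums(ym) > 0
        f <- fit_terms(ym[ok, , drop = FALSE], data[ok, , drop = FALSE],
                       terms, "binomial_counts")
        stats::coef(f$fit)[names(observed)]
      }
    }, error = function(e) NULL)
    if (is.null(co) || anyNA(co)) fails <- fails + 1L else reps[i, ] <- co
    if (fails > max_fail_frac * n_reps)
      stop("more than ", 100 * max_fail_frac,
           "% of replicate fits failed (", fails, " of ", i, ")")
  }
  # order-statistic band: with N replicates and k = floor(alpha * (N + 1)),
  # (X_(k), X_(N+1-k)) gives exact finite-sample coverage 2k/(N+1) under
  # exchangeability (the standard permutation-test construction)
  q <- apply(reps, 2, function(v) {
    v <- sort(v[!is.na(v)])
    N <- length(v)
    k <- max(1L, floor(band[1] * (N + 1)))
    c(v[k], v[N + 1L - k])
  })
  summ <- data.frame(
    coefficient = names(observed), observed = as.vector(observed),
    q05 = q[1, ], q95 = q[2, ],
    outside_band = as.vector(observed) < q[1, ] |
      as.vector(observed) > q[2, ],
    n_effective_reps = colSums(!is.na(reps)),
    scheme = scheme, row.names = NULL)
  structure(list(summary = summ, reps = reps, scheme = scheme,
                 n_reps = n_reps, band = band, failed = fails),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", x$n_reps, " randomizations (", x$scheme, ")\n",
      sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
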