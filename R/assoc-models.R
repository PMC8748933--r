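HERBIVORY_VARS <- c("M_rich", "M_bm", "M_bm_sq", "MGB_dif",
                    "H_rich", "H_bm", "H_bm_sq", "HGB_dif")

#' Predictor correlation screen and branch structure
#'
#' Flags predictor pairs correlated at `|r| >= threshold`. When the
#' designated branch pair (mean annual rainfall vs soil pH by default) is
#' among them, two candidate sets are emitted and model selection is run
#' once per branch; other flagged pairs are reported for the analyst.
#' Constant predictors are dropped with a warning.
#'
#' @param data data.frame of candidate predictors (ecoregions in rows).
#' @param candidates character vector of predictor column names.
#' @param threshold absolute correlation above which a pair is flagged.
#' @param branch_pair length-2 character vector naming the pair that splits
#'   model selection into two branches when flagged.
#' @return list with `branches` (list of candidate vectors, named by the
#'   branch variable retained or `"single"`), `flagged` (data.frame of
#'   flagged pairs with their correlation), `dropped` (constant predictors).
#' @export
correlation_screen <- function(data, candidates, threshold = 0.60,
                               branch_pair = c("MAR", "pH")) {
  candidates <- intersect(candidates, names(data))
  X <- data[candidates]
  const <- vapply(X, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warning("constant predictor(s) dropped: ",
            paste(candidates[const], collapse = ", "))
    candidates <- candidates[!const]
    X <- X[candidates]
  }
  flagged <- data.frame(var1 = character(), var2 = character(), r = numeric())
  if (length(candidates) > 1) {
    C <- stats::cor(X, use = "pairwise.complete.obs")
    idx <- which(abs(C) >= threshold & upper.tri(C), arr.ind = TRUE)
    if (nrow(idx) > 0)
      flagged <- data.frame(var1 = rownames(C)[idx[, 1]],
                            var2 = colnames(C)[idx[, 2]],
                            r = C[idx])
  }
  pair_in <- all(branch_pair %in% candidates)
  pair_flagged <- pair_in && any(
    (flagged$var1 %in% branch_pair) & (flagged$var2 %in% branch_pair))
  if (pair_flagged) {
    branches <- list(setdiff(candidates, branch_pair[2]),
                     setdiff(candidates, branch_pair[1]))
    names(branches) <- branch_pair
  } else {
    branches <- list(single = candidates)
  }
  list(branches = branches, flagged = flagged,
       dropped = names(const)[const])
}

# formula from predictor names ("x_sq" columns are plain columns in data);
# the environment must be the caller's so that step()/update() can refit
make_formula <- function(lhs, terms, env = parent.frame()) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(lhs, "~", rhs), env = env)
}

# binomial fits under heterogeneity weights make the successes non-integer
# by construction; that glm warning is expected and uninformative here
quiet_binomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# enforce quadratic-with-linear hierarchy on a term set
hierarchy_ok <- function(terms) {
  sq <- grep("_sq$", terms, value = TRUE)
  all(sub("_sq$", "", sq) %in% terms)
}

drop_orphan_quadratics <- function(terms) {
  sq <- grep("_sq$", terms, value = TRUE)
  orphan <- sq[!sub("_sq$", "", sq) %in% terms]
  setdiff(terms, orphan)
}

#' Overdispersed binomial fit with Williams-type iterative weights
#'
#' Fits a binomial logit model to (presence, absence) counts. If the plain
#' fit's residual deviance is at or above its residual degrees of freedom,
#' overdispersion is handled by Williams-type heterogeneity weights
#' `1 / (1 + phi * (m - 1))`, with `phi` updated from the Pearson statistic
#' until the residual deviance drops below the residual df (or `max_iter`
#' is hit, in which case the last iterate is returned flagged). When no
#' overdispersion is detected the plain fit is returned unchanged.
#'
#' @param presences,absences integer vectors of trait presence/absence
#'   counts per ecoregion.
#' @param data data.frame of predictors.
#' @param terms character vector of predictor columns.
#' @param max_iter maximum number of weight updates.
#' @return list with `fit` (a `glm`), `phi`, `weights` (heterogeneity
#'   weights, 1 when no overdispersion), `overdispersed`, `converged`,
#'   `iterations`.
#' @export
overdispersed_binomial_fit <- function(presences, absences, data, terms,
                                       max_iter = 100) {
  m <- presences + absences
  if (any(m <= 0)) stop("each observation needs presences + absences > 0")
  n <- length(m)
  y <- presences / m
  df_fit <- data
  df_fit$.y <- y
  fml <- make_formula(".y", terms)
  fit <- quiet_binomial(stats::glm(fml, family = stats::binomial(),
                                   data = df_fit, weights = m))
  k <- length(stats::coef(fit))
  if (n - k <= 0) stop("residual degrees of freedom is zero")
  if (fit$deviance < fit$df.residual) {
    return(list(fit = fit, phi = 0, weights = rep(1, n),
                overdispersed = FALSE, converged = TRUE, iterations = 0L))
  }
  phi <- 0
  w <- rep(1, n)
  it <- 0L
  repeat {
    it <- it + 1L
    X2 <- sum(stats::residuals(fit, type = "pearson")^2)
    if (abs(X2 - fit$df.residual) < 0.1 || it >= max_iter / 2) break
    h <- stats::hatvalues(fit)
    denom <- sum(w * (1 - h) * (m - 1))
    if (denom <= 0) break
    phi <- max(0, phi + (X2 - fit$df.residual) / denom)
    w <- 1 / (1 + phi * (m - 1))
    fit <- quiet_binomial(stats::glm(fml, family = stats::binomial(),
                                     data = df_fit, weights = w * m))
  }
  # the weights exist to keep the deviance below the residual df; push phi
  # up from the Pearson solution until that holds
  extra <- 0L
  while (fit$deviance >= fit$df.residual && extra < max_iter) {
    extra <- extra + 1L
    phi <- phi * 1.1 + 1e-6
    w <- 1 / (1 + phi * (m - 1))
    fit <- quiet_binomial(stats::glm(fml, family = stats::binomial(),
                                     data = df_fit, weights = w * m))
  }
  it <- it + extra
  list(fit = fit, phi = phi, weights = w, overdispersed = TRUE,
       converged = fit$deviance < fit$df.residual, iterations = it)
}

# fit helper: gaussian lm or (williams-weighted) binomial glm on a term set
fit_terms <- function(response, data, terms, family, williams = TRUE) {
  if (family == "gaussian") {
    df_fit <- data
    df_fit$.y <- response
    list(fit = stats::lm(make_formula(".y", terms), data = df_fit),
         weights = NULL, phi = 0)
  } else {
    if (williams) {
      w <- overdispersed_binomial_fit(response[, 1], response[, 2], data,
                                      terms)
      list(fit = w$fit, weights = w$weights, phi = w$phi,
           overdispersed = w$overdispersed, converged = w$converged)
    } else {
      m <- response[, 1] + response[, 2]
      df_fit <- data
      df_fit$.y <- response[, 1] / m
      list(fit = quiet_binomial(stats::glm(make_formula(".y", terms),
                            family = stats::binomial(), data = df_fit,
                            weights = m)),
           weights = rep(1, length(m)), phi = 0)
    }
  }
}

coef_pvalues <- function(fit, vcov. = NULL) {
  ct <- if (is.null(vcov.)) stats::coef(summary(fit))
        else lmtest::coeftest(fit, vcov. = vcov.)
  p <- ct[, 4]
  p[names(p) != "(Intercept)"]
}

#' Bidirectional stepwise AIC selection with significance pruning
#'
#' Starts from the full model over the candidate set, runs both-direction
#' stepwise AIC search, then iteratively drops the least significant
#' remaining predictor until all have `p <= p_cut`. A quadratic term
#' (`<var>_sq` column) is only retained together with its linear term, and
#' the linear term is never pruned while its quadratic survives. For
#' binomial count responses, AIC search uses the plain binomial likelihood
#' and the pruning stage uses the Williams-weighted fit.
#'
#' @param response numeric vector (gaussian) or two-column matrix of
#'   (presences, absences) counts (binomial).
#' @param data data.frame holding all candidate predictor columns.
#' @param candidates character vector of candidate predictors.
#' @param family `"gaussian"` or `"binomial_counts"`.
#' @param forced_quadratics quadratic terms that must enter the full model;
#'   each requires its linear term among the candidates.
#' @param p_cut significance level for the pruning stage.
#' @return list with `terms`, `fit`, `aic`, `weights`, `phi`, `empty`
#'   (TRUE when no predictor survives), `pruned` (terms removed by
#'   significance pruning).
#' @export
stepwise_select <- function(response, data, candidates,
                            family = c("gaussian", "binomial_counts"),
                            forced_quadratics = character(), p_cut = 0.05) {
  family <- match.arg(family)
  candidates <- unique(c(candidates, forced_quadratics))
  if (!hierarchy_ok(candidates))
    stop("quadratic term(s) without their linear term: ",
         paste(grep("_sq$", candidates[!candidates %in%
           drop_orphan_quadratics(candidates)], value = TRUE), collapse = ", "))
  n <- if (is.matrix(response)) nrow(response) else length(response)
  if (n < length(candidates) + 2)
    stop("need n >= number of candidates + 2")
  df_fit <- data
  if (family == "gaussian") {
    df_fit$.y <- response
    full <- stats::lm(make_formula(".y", candidates), data = df_fit)
    scope <- list(lower = stats::as.formula(".y ~ 1"),
                  upper = make_formula(".y", candidates))
    sel <- stats::step(full, scope = scope, direction = "both", trace = 0)
  } else {
    m <- response[, 1] + response[, 2]
    df_fit$.y <- response[, 1] / m
    df_fit$.m <- m
    full <- stats::glm(make_formula(".y", candidates),
                       family = stats::binomial(), data = df_fit,
                       weights = .m)
    scope <- list(lower = stats::as.formula(".y ~ 1"),
                  upper = make_formula(".y", candidates))
    sel <- stats::step(full, scope = scope, direction = "both", trace = 0)
  }
  terms <- attr(stats::terms(sel), "term.labels")
  terms <- drop_orphan_quadratics(terms)
  pruned <- character()
  repeat {
    f <- fit_terms(response, data, terms, family)
    if (length(terms) == 0) break
    p <- coef_pvalues(f$fit)
    # never drop a linear term whose quadratic is still in the model
    protected <- sub("_sq$", "", grep("_sq$", terms, value = TRUE))
    droppable <- setdiff(names(p), protected)
    if (length(droppable) == 0 || max(p[droppable]) <= p_cut) break
    worst <- droppable[which.max(p[droppable])]
    pruned <- c(pruned, worst)
    terms <- drop_orphan_quadratics(setdiff(terms, worst))
  }
  f <- fit_terms(response, data, terms, family)
  aic <- if (family == "gaussian") stats::AIC(f$fit)
         else stats::AIC(fit_terms(response, data, terms, family,
                                   williams = FALSE)$fit)
  list(terms = terms, fit = f$fit, aic = aic, weights = f$weights,
       phi = f$phi, empty = length(terms) == 0, pruned = pruned)
}

#' Effect sizes (Pearson r) with confidence intervals per coefficient
#'
#' Converts each coefficient's test statistic into a partial correlation,
#' `r = t / sqrt(t^2 + df)`, whose sign matches the coefficient. Intervals
#' come from the Fisher z transform with the model's residual df.
#'
#' @param fit a fitted `lm` or `glm`.
#' @param vcov. optional covariance matrix (e.g. HC) used for the test
#'   statistics.
#' @param level confidence level.
#' @return data.frame with `term`, `estimate`, `statistic`, `p`, `r`,
#'   `r_low`, `r_high`.
#' @export
effect_sizes <- function(fit, vcov. = NULL, level = 0.95) {
  ct <- if (is.null(vcov.)) stats::coef(summary(fit))
        else lmtest::coeftest(fit, vcov. = vcov.)
  keep <- rownames(ct) != "(Intercept)"
  ct <- ct[keep, , drop = FALSE]
  df <- stats::df.residual(fit)
  t <- ct[, 3]
  r <- t / sqrt(t^2 + df)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(max(df - 1, 1))
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = rownames(ct), estimate = ct[, 1], statistic = t,
             p = ct[, 4], r = r,
             r_low = tanh(z - q * se), r_high = tanh(z + q * se),
             row.names = NULL)
}

# fit statistic for a predictor subset: plain R2 (gaussian) or McFadden
# pseudo-R2 (binomial at fixed prior weights)
subset_fitstat <- function(response, data, terms, family, prior_w = NULL) {
  if (family == "gaussian") {
    df_fit <- data
    df_fit$.y <- response
    fit <- stats::lm(make_formula(".y", terms), data = df_fit)
    summary(fit)$r.squared
  } else {
    m <- response[, 1] + response[, 2]
    w <- if (is.null(prior_w)) rep(1, length(m)) else prior_w
    df_fit <- data
    df_fit$.y <- response[, 1] / m
    fit <- quiet_binomial(stats::glm(make_formula(".y", terms),
                      family = stats::binomial(), data = df_fit,
                      weights = w * m))
    null <- quiet_binomial(stats::glm(.y ~ 1, family = stats::binomial(),
                       data = df_fit, weights = w * m))
    1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(null))
  }
}

#' Dominance analysis: average R-squared contribution per predictor
#'
#' General dominance: for each predictor, the increment in fit when it is
#' added is averaged first over all subsets of the other predictors of a
#' given size, then over sizes. Gaussian models use plain R-squared (so
#' contributions sum exactly to the model R-squared), binomial models use
#' McFadden's pseudo-R-squared at the supplied prior weights.
#'
#' @inheritParams stepwise_select
#' @param terms the selected predictors (at most 12; the enumeration is
#'   over all `2^k` subsets).
#' @param prior_w optional heterogeneity weights from the Williams fit,
#'   held fixed across subsets.
#' @return data.frame with `term`, `avg_contribution`, plus attribute
#'   `total` (full-model fit statistic).
#' @export
dominance_contributions <- function(response, data, terms,
                                    family = c("gaussian", "binomial_counts"),
                                    prior_w = NULL) {
  family <- match.arg(family)
  k <- length(terms)
  if (k > 12) stop("more than 12 predictors; reduce the model first")
  if (k == 0) return(data.frame(term = character(), avg_contribution = numeric()))
  stat <- new.env(parent = emptyenv())
  key <- function(s) paste0("s|", paste(sort(s), collapse = "|"))
  getstat <- function(s) {
    kk <- key(s)
    if (is.null(stat[[kk]]))
      stat[[kk]] <- subset_fitstat(response, data, s, family, prior_w)
    stat[[kk]]
  }
  contrib <- stats::setNames(numeric(k), terms)
  for (j in terms) {
    others <- setdiff(terms, j)
    by_size <- vapply(0:length(others), function(sz) {
      subs <- if (sz == 0) list(character(0))
              else utils::combn(others, sz, simplify = FALSE)
      mean(vapply(subs, function(s) getstat(c(s, j)) - getstat(s),
                  numeric(1)))
    }, numeric(1))
    contrib[j] <- mean(by_size)
  }
  out <- data.frame(term = terms, avg_contribution = as.vector(contrib),
                    row.names = NULL)
  attr(out, "total") <- getstat(terms)
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` regresses predictor j on all the
#' others (columns of the model matrix, intercept excluded).
#'
#' @param fit a fitted `lm` or `glm`.
#' @return named numeric vector of VIFs (all 1 for a single predictor).
#' @export
vif_values <- function(fit) {
  X <- stats::model.matrix(fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

# connected components of an adjacency edge list over the given ids
adjacency_components <- function(ids, adjacency) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(adjacency))) {
      a <- as.character(adjacency[i, 1]); b <- as.character(adjacency[i, 2])
      if (!a %in% ids || !b %in% ids) next
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == max(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Residual diagnostics for an ecoregion-level model
#'
#' Kolmogorov-Smirnov normality check on standardized residuals (note the
#' estimated-parameters caveat), Breusch-Pagan homoscedasticity test (lm
#' only), and Moran's I spatial autocorrelation over the ecoregion
#' adjacency (analytic normal approximation). When the adjacency graph is
#' disconnected, Moran's I is computed on the largest component and
#' flagged.
#'
#' @param fit a fitted `lm` or `glm`.
#' @param adjacency optional two-column data.frame of adjacent ecoregion id
#'   pairs; row order of the model data must carry ecoregion ids in
#'   `eco_ids`.
#' @param eco_ids character vector of ecoregion ids, one per model row.
#' @return list with `ks_p`, `bp_p`, `moran_p`, `moran_flag`, `max_vif`,
#'   `vif`.
#' @export
fit_diagnostics <- function(fit, adjacency = NULL, eco_ids = NULL) {
  res <- stats::residuals(fit)
  ks_p <- tryCatch(
    suppressWarnings(stats::ks.test(res / stats::sd(res), "pnorm")$p.value),
    error = function(e) NA_real_)
  has_regressor <- length(stats::coef(fit)) > 1
  bp_p <- if (inherits(fit, "lm") && !inherits(fit, "glm") && has_regressor)
    lmtest::bptest(fit)$p.value else NA_real_
  moran_p <- NA_real_
  moran_flag <- NA_character_
  if (!is.null(adjacency) && !is.null(eco_ids) && nrow(adjacency) > 0) {
    comp <- adjacency_components(eco_ids, adjacency)
    if (length(unique(comp)) > 1) {
      big <- names(which.max(table(comp)))
      keep <- comp == as.integer(big)
      moran_flag <- sprintf(
        "disconnected adjacency: Moran's I on largest component (%d of %d)",
        sum(keep), length(keep))
    } else keep <- rep(TRUE, length(eco_ids))
    ids <- eco_ids[keep]
    W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    a <- as.character(adjacency[[1]]); b <- as.character(adjacency[[2]])
    ok <- a %in% ids & b %in% ids
    W[cbind(a[ok], b[ok])] <- 1
    W[cbind(b[ok], a[ok])] <- 1
    if (sum(W) > 0)
      moran_p <- ape::Moran.I(res[keep], W)$p.value
  }
  v <- vif_values(fit)
  list(ks_p = unname(ks_p), bp_p = unname(bp_p), moran_p = moran_p,
       moran_flag = moran_flag, max_vif = if (length(v)) max(v) else NA_real_,
       vif = v)
}

#' Fit the ecoregion trait model with the full selection protocol
#'
#' Runs the complete regression protocol for one response: correlation
#' screen with the rainfall/pH branch split, bidirectional stepwise AIC
#' with significance pruning per branch, branch choice by AIC, the
#' herbivory sign rule (a significant herbivory coefficient whose sign
#' implies less defence under more herbivory is discarded together with its
#' related diet term, and selection is re-run), residual diagnostics with a
#' heteroskedasticity-consistent refit of the coefficient tests when
#' Breusch-Pagan rejects, effect sizes, dominance contributions, and VIFs.
#'
#' @param data data.frame with one row per ecoregion, holding the response
#'   and every candidate predictor (quadratic columns named `<var>_sq`).
#' @param response for `family = "gaussian"` the response column name; for
#'   `"binomial_counts"` a length-2 vector naming the presence and absence
#'   count columns.
#' @param candidates candidate predictor columns.
#' @param family `"gaussian"` or `"binomial_counts"`.
#' @param forced_quadratics quadratic terms forced into the full model
#'   (e.g. body-mass squared for stem spines).
#' @param defence_sign expected sign of herbivory effects on this response:
#'   `+1` when more defence means a larger response (wood density, spines,
#'   latex), `-1` when it means a smaller one (leaf size).
#' @param adjacency optional ecoregion adjacency edge list for Moran's I.
#' @param eco_ids ecoregion ids per row of `data` (defaults to the
#'   `ecoregion_id` column when present).
#' @param branch_pair,r_threshold,p_cut,vif_max protocol constants; the
#'   defaults are the standard settings.
#' @return An object of class `trait_fit`.
#' @export
fit_trait_model <- function(data, response, candidates,
                            family = c("gaussian", "binomial_counts"),
                            forced_quadratics = character(),
                            defence_sign = 1, adjacency = NULL,
                            eco_ids = NULL, branch_pair = c("MAR", "pH"),
                            r_threshold = 0.60, p_cut = 0.05,
                            vif_max = 3.33) {
  family <- match.arg(family)
  cl <- match.call()
  if (is.null(eco_ids) && "ecoregion_id" %in% names(data))
    eco_ids <- as.character(data$ecoregion_id)
  y <- if (family == "gaussian") data[[response]]
       else as.matrix(data[response])
  keep <- if (family == "gaussian") !is.na(y)
          else stats::complete.cases(y) & rowSums(y) > 0
  keep <- keep & stats::complete.cases(data[intersect(candidates, names(data))])
  data <- data[keep, , drop = FALSE]
  y <- if (family == "gaussian") y[keep] else y[keep, , drop = FALSE]
  eco_ids <- eco_ids[keep]
  scr <- correlation_screen(data, candidates, threshold = r_threshold,
                            branch_pair = branch_pair)
  active <- unique(unlist(scr$branches))
  discarded <- character()
  repeat {
    branches <- lapply(scr$branches, function(b)
      setdiff(intersect(b, active), character(0)))
    sels <- lapply(branches, function(cand)
      stepwise_select(y, data, cand, family,
                      forced_quadratics = intersect(forced_quadratics, cand),
                      p_cut = p_cut))
    aics <- vapply(sels, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    sel <- sels[[best]]
    delta_aic <- if (length(aics) > 1) abs(diff(sort(aics))[1]) else NA_real_
    # herbivory sign rule: drop effects implying less defence under more
    # herbivory, together with the related diet-difference term
    bad <- character()
    if (!sel$empty) {
      co <- stats::coef(sel$fit)
      p <- coef_pvalues(sel$fit)
      herb <- intersect(names(p),
                        setdiff(HERBIVORY_VARS, grep("_sq$", HERBIVORY_VARS,
                                                     value = TRUE)))
      for (v in herb) {
        if (p[v] <= p_cut && sign(co[v]) != sign(defence_sign)) {
          bad <- c(bad, v)
          if (v %in% c("M_rich", "MGB_dif")) bad <- c(bad, "MGB_dif")
          if (v %in% c("H_rich", "HGB_dif")) bad <- c(bad, "HGB_dif")
          if (v == "M_bm") bad <- c(bad, "M_bm_sq")
          if (v == "H_bm") bad <- c(bad, "H_bm_sq")
        }
      }
      bad <- intersect(unique(bad), active)
    }
    if (length(bad) == 0) break
    discarded <- c(discarded, bad)
    active <- setdiff(active, bad)
  }
  branch <- names(sels)[best]
  fit <- sel$fit
  diag <- fit_diagnostics(fit, adjacency, eco_ids)
  hc_used <- FALSE
  vc <- NULL
  if (!is.na(diag$bp_p) && diag$bp_p <= p_cut && !sel$empty) {
    # heteroskedasticity: redo coefficient tests under HC covariance and
    # re-enter the pruning loop
    hc_used <- TRUE
    terms <- sel$terms
    repeat {
      f <- fit_terms(y, data, terms, family)
      if (length(terms) == 0) break
      vc <- sandwich::vcovHC(f$fit, type = "HC3")
      p <- coef_pvalues(f$fit, vcov. = vc)
      protected <- sub("_sq$", "", grep("_sq$", terms, value = TRUE))
      droppable <- setdiff(names(p), protected)
      if (length(droppable) == 0 || max(p[droppable]) <= p_cut) break
      terms <- drop_orphan_quadratics(
        setdiff(terms, droppable[which.max(p[droppable])]))
    }
    sel$terms <- terms
    sel$empty <- length(terms) == 0
    f <- fit_terms(y, data, terms, family)
    fit <- f$fit
    sel$fit <- fit
    sel$weights <- f$weights
    vc <- if (!sel$empty) sandwich::vcovHC(fit, type = "HC3") else NULL
    diag <- fit_diagnostics(fit, adjacency, eco_ids)
  }
  es <- if (sel$empty) NULL else effect_sizes(fit, vcov. = vc)
  dom <- if (sel$empty) NULL
         else dominance_contributions(y, data, sel$terms, family,
                                      prior_w = sel$weights)
  fitstat <- if (family == "gaussian") {
    c(r_squared = summary(fit)$r.squared,
      adj_r_squared = summary(fit)$adj.r.squared)
  } else {
    c(mcfadden = if (is.null(dom)) 0 else attr(dom, "total"))
  }
  structure(list(
    response = response, family = family, call = cl,
    branch = branch, delta_aic = delta_aic, branch_aics = aics,
    selected = sel$terms, fit = fit, coefficients = stats::coef(fit),
    effect_sizes = es, dominance = dom, fitstat = fitstat,
    diagnostics = diag, hc_used = hc_used, vcov_hc = vc,
    weights = sel$weights, phi = sel$phi %||% 0,
    discarded = discarded, empty = sel$empty,
    vif_max_allowed = vif_max,
    vif_ok = is.na(diag$max_vif) || diag$max_vif <= vif_max,
    eco_ids = eco_ids, data = data, y = y,
    screen = scr), class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  resp <- paste(x$response, collapse = "/")
  cat("<trait_fit> ", resp, " (", x$family, "), branch: ", x$branch,
      if (!is.na(x$delta_aic)) sprintf(" (dAIC %.2f)", x$delta_aic), "\n",
      sep = "")
  if (x$empty) {
    cat("  no predictor survived selection\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    cat("  fit:", paste(sprintf("%s = %.3f", names(x$fitstat), x$fitstat),
                        collapse = ", "), "\n")
    if (x$hc_used) cat("  coefficient tests under HC covariance\n")
    if (length(x$discarded))
      cat("  discarded by sign rule:", paste(x$discarded, collapse = ", "),
          "\n")
  }
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) {
  print(object)
  if (!object$empty) {
    cat("\nEffect sizes (Pearson r, 95% CI):\n")
    print(object$effect_sizes, digits = 3)
    cat("\nAverage contribution (dominance analysis):\n")
    print(object$dominance, digits = 3)
    cat(sprintf("\nmax VIF: %.2f (limit %.2f)\n",
                object$diagnostics$max_vif, object$vif_max_allowed))
  }
  invisible(object)
}

#' @export
coef.trait_fit <- function(object, ...) object$coefficients

#' @export
predict.trait_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.trait_fit <- function(object, ...) stats::residuals(object$fit, ...)
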