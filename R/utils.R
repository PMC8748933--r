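#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent RNG stream per world component: deterministic sub-seed derived
# from the master seed, kept inside 32-bit integer range.
component_seed <- function(seed, component) {
  offs <- c(covariates = 101L, fauna = 211L, occurrences = 307L,
            sites = 401L, hotspots = 503L, landcover = 601L,
            tracks = 701L)
  if (!component %in% names(offs)) stop("unknown RNG component: ", component)
  as.integer((as.numeric(seed) * 48271 + offs[[component]]) %% 2147483587)
}

# z-scores; constant vectors map to 0 rather than NaN; NAs pass through
zscore <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

# Nearest-rank (type 1) empirical quantile, the convention used for the
# megafauna richness thresholds.
nearest_rank_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 1, names = FALSE, na.rm = TRUE)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}
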