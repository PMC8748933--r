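sim_predictors <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(M_rich = rnorm(n), M_bm = rnorm(n), MGB_dif = rnorm(n),
                  MAT = rnorm(n), RS = rnorm(n), CEC = rnorm(n),
                  SND = rnorm(n))
  z <- rnorm(n)
  d$MAR <- as.vector(scale(z))
  e <- rnorm(n)
  e <- as.vector(scale(e - d$MAR * sum(d$MAR * e) / sum(d$MAR^2)))
  d$pH <- -0.78 * d$MAR + sqrt(1 - 0.78^2) * e
  d$M_bm_sq <- d$M_bm^2
  d
}

test_that("correlation screen splits the rainfall/pH branch and flags pairs", {
  d <- sim_predictors(150)
  scr <- correlation_screen(d, names(d))
  expect_length(scr$branches, 2)
  expect_false("pH" %in% scr$branches$MAR)
  expect_false("MAR" %in% scr$branches$pH)
  expect_true(any(scr$flagged$r < -0.6))
  # all-weak correlations give a single branch
  scr1 <- correlation_screen(d, c("M_rich", "MAT", "RS"))
  expect_named(scr1$branches, "single")
  # a duplicated column (r = 1) is flagged
  d$dup <- d$MAT
  scr2 <- correlation_screen(d, c("MAT", "dup", "RS"))
  expect_true(any(abs(scr2$flagged$r) == 1))
  # constant predictors are dropped with a warning
  d$const <- 1
  expect_warning(correlation_screen(d, c("MAT", "const")), "constant")
})

test_that("stepwise selection recovers a planted single predictor and prunes noise", {
  hits <- 0
  for (seed in 1:20) {
    d <- sim_predictors(143, seed)
    y <- 0.5 * d$M_rich + rnorm(143, 0, sqrt(1 - 0.25))
    sel <- stepwise_select(y, d, c("M_rich", "MAT", "RS", "CEC", "SND"),
                           "gaussian")
    if (identical(sel$terms, "M_rich") ||
        ("M_rich" %in% sel$terms && length(sel$terms) <= 2)) hits <- hits + 1
    expect_true("M_rich" %in% sel$terms)
    expect_true(all(coef_pvalues(sel$fit) <= 0.05))
  }
  expect_gte(hits, 18)
})

test_that("quadratic terms obey the hierarchy rule", {
  d <- sim_predictors(100)
  expect_error(stepwise_select(rnorm(100), d, c("MAT", "RS"),
                               "gaussian", forced_quadratics = "M_bm_sq"),
               "quadratic")
  # a surviving quadratic keeps its linear term even when the linear term
  # alone would be pruned
  set.seed(42)
  y <- 0.6 * d$M_bm_sq + rnorm(100, 0, 0.5)
  sel <- stepwise_select(y, d, c("M_bm", "MAT"), "gaussian",
                         forced_quadratics = "M_bm_sq")
  if ("M_bm_sq" %in% sel$terms) expect_true("M_bm" %in% sel$terms)
})

test_that("a null world rarely lets any given predictor through selection", {
  cands <- c("M_rich", "MAT", "RS", "CEC", "SND", "MGB_dif")
  hit <- 0
  for (seed in 1:40) {
    d <- sim_predictors(143, seed + 500)
    y <- rnorm(143)
    sel <- stepwise_select(y, d, cands, "gaussian")
    if ("M_rich" %in% sel$terms) hit <- hit + 1
  }
  expect_lte(hit / 40, 0.15)
})

test_that("Williams weighting reduces exactly to plain logit without overdispersion", {
  # an exactly binomial draw whose plain fit shows no overdispersion
  found <- FALSE
  for (seed in 1:10) {
    set.seed(seed)
    n <- 100
    x <- rnorm(n)
    m <- rep(40, n)
    p <- plogis(-0.3 + 0.6 * x)
    pres <- rbinom(n, m, p)
    d <- data.frame(x = x)
    plain <- glm(cbind(pres, m - pres) ~ x, family = binomial())
    if (plain$deviance < plain$df.residual) {
      found <- TRUE
      w <- overdispersed_binomial_fit(pres, m - pres, d, "x")
      expect_false(w$overdispersed)
      expect_lt(max(abs(coef(w$fit) - coef(plain))), 1e-6)
      expect_true(all(w$weights == 1))
      break
    }
  }
  expect_true(found)
})

test_that("Williams weighting drives deviance below df on beta-binomial data", {
  for (rho in c(0.05, 0.1, 0.2)) {
    set.seed(round(100 * rho))
    n <- 120
    x <- rnorm(n)
    m <- rpois(n, 45) + 5
    mu <- plogis(-0.2 + 0.5 * x)
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    pres <- rbinom(n, m, rbeta(n, a, b))
    w <- overdispersed_binomial_fit(pres, m - pres, data.frame(x = x), "x")
    expect_true(w$overdispersed)
    expect_true(w$converged)
    expect_lt(w$fit$deviance, w$fit$df.residual)
    expect_gt(w$phi, 0)
  }
})

test_that("degenerate binomial inputs are rejected", {
  expect_error(overdispersed_binomial_fit(3, 2, data.frame(x = 1), "x"),
               "degrees of freedom")
  expect_error(overdispersed_binomial_fit(c(0, 1), c(0, 4),
                                          data.frame(x = 1:2), "x"),
               "> 0")
})

test_that("effect-size r reduces to known identities", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  f <- lm(y ~ x)
  es <- effect_sizes(f)
  expect_equal(es$r, cor(x, y), tolerance = 1e-12)   # simple-regression identity
  # an exactly orthogonal response gives t = 0 hence r = 0
  y0 <- residuals(lm(rnorm(n) ~ x))
  es0 <- effect_sizes(lm(y0 ~ x))
  expect_equal(es0$r, 0, tolerance = 1e-10)
  expect_equal(sign(es$r), sign(coef(f)["x"]), ignore_attr = TRUE)
})

test_that("multi-predictor effect sizes equal brute-force partial correlations", {
  set.seed(8)
  n <- 80
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.5 * d$a - 0.3 * d$b + rnorm(n)
  f <- lm(y ~ a + b + c, data = d)
  es <- effect_sizes(f)
  for (v in c("a", "b", "c")) {
    others <- setdiff(c("a", "b", "c"), v)
    ry <- residuals(lm(reformulate(others, "y"), data = cbind(d, y = y)))
    rx <- residuals(lm(reformulate(others, v), data = d))
    expect_equal(es$r[es$term == v], cor(ry, rx), tolerance = 1e-8)
  }
})

test_that("dominance contributions match the hand-enumerated 2-predictor case", {
  set.seed(9)
  n <- 50
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 0.6 * d$a + 0.3 * d$b + rnorm(n)
  dom <- dominance_contributions(y, d, c("a", "b"), "gaussian")
  r2 <- function(f) summary(f)$r.squared
  ra <- r2(lm(y ~ a, d)); rb <- r2(lm(y ~ b, d)); rab <- r2(lm(y ~ a + b, d))
  expect_equal(dom$avg_contribution[dom$term == "a"],
               mean(c(ra, rab - rb)), tolerance = 1e-12)
  expect_equal(dom$avg_contribution[dom$term == "b"],
               mean(c(rb, rab - ra)), tolerance = 1e-12)
  expect_equal(sum(dom$avg_contribution), rab, tolerance = 1e-12)
})

test_that("contributions sum to R2 under an orthonormal design", {
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 3), n)))       # exactly orthonormal columns
  d <- as.data.frame(X)
  names(d) <- c("p1", "p2", "p3")
  set.seed(10)
  y <- 0.7 * d$p1 - 0.4 * d$p2 + 0.2 * d$p3 + rnorm(n, 0, 0.5)
  dom <- dominance_contributions(y, d, names(d), "gaussian")
  r2 <- summary(lm(y ~ p1 + p2 + p3, d))$r.squared
  expect_equal(sum(dom$avg_contribution), r2, tolerance = 1e-8)
  # single predictor: contribution equals the model R2
  dom1 <- dominance_contributions(y, d, "p1", "gaussian")
  expect_equal(dom1$avg_contribution,
               summary(lm(y ~ p1, d))$r.squared)
  expect_error(dominance_contributions(y, d[rep(1:3, 5)],
                                       paste0("V", 1:13), "gaussian"),
               "12")
})

test_that("VIF matches its definition and explodes for duplicated predictors", {
  set.seed(11)
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- rnorm(50)
  f <- lm(y ~ a + b + c, data = d)
  v <- vif_values(f)
  skip_if_not_installed("car")
  expect_equal(unname(v), unname(car::vif(f)), tolerance = 1e-8)
  d$a2 <- d$a + rnorm(50, 0, 1e-4)
  v2 <- vif_values(lm(y ~ a + a2 + b, data = d))
  expect_gt(max(v2), 1000)
})

test_that("diagnostics report KS, BP and Moran p-values with adjacency handling", {
  set.seed(12)
  n <- 60
  ids <- sprintf("E%02d", 1:n)
  adj <- data.frame(from = ids[-n], to = ids[-1])   # a chain
  d <- data.frame(x = rnorm(n))
  y <- 0.5 * d$x + rnorm(n)
  f <- lm(y ~ x, data = d)
  dg <- fit_diagnostics(f, adj, ids)
  expect_true(all(is.finite(c(dg$ks_p, dg$bp_p, dg$moran_p))))
  expect_true(is.na(dg$moran_flag))
  # disconnected adjacency: computed on the largest component, flagged
  adj2 <- adj[-30, ]
  dg2 <- fit_diagnostics(f, adj2, ids)
  expect_match(dg2$moran_flag, "largest component")
})

test_that("heteroscedastic data triggers the HC refit path", {
  set.seed(13)
  n <- 160
  d <- data.frame(M_rich = rnorm(n), MAT = rnorm(n), RS = rnorm(n))
  mu <- 1 + 0.8 * d$M_rich
  y <- mu + rnorm(n, 0, 0.3 + abs(mu))     # variance grows with the mean
  d$WD_mean <- y
  fit <- fit_trait_model(d, "WD_mean", c("M_rich", "MAT", "RS"),
                         family = "gaussian")
  expect_true(fit$hc_used)
  expect_s3_class(fit, "trait_fit")
})

test_that("the rainfall and pH branches are the same code path parameterized by the swap", {
  set.seed(14)
  d <- sim_predictors(150, 14)
  y <- 0.6 * d$MAR + rnorm(150, 0, 0.7)
  d$WD_mean <- y
  fit <- fit_trait_model(d, "WD_mean", c("M_rich", "MAR", "pH", "MAT"),
                         family = "gaussian")
  expect_true(fit$branch %in% c("MAR", "pH"))
  expect_length(fit$branch_aics, 2)
  # swapping the branch-pair order must not change the winning model terms
  fit2 <- fit_trait_model(d, "WD_mean", c("M_rich", "MAR", "pH", "MAT"),
                          family = "gaussian", branch_pair = c("pH", "MAR"))
  expect_setequal(fit$selected, fit2$selected)
})

test_that("the herbivory sign rule discards backwards defence effects", {
  set.seed(15)
  n <- 150
  d <- data.frame(M_rich = rnorm(n), MGB_dif = rnorm(n), MAT = rnorm(n))
  # leaf size *increasing* with megafauna richness contradicts defence
  y <- 0.6 * d$M_rich + rnorm(n, 0, 0.6)
  d$LeafSize_mean <- y
  fit <- fit_trait_model(d, "LeafSize_mean", c("M_rich", "MGB_dif", "MAT"),
                         family = "gaussian", defence_sign = -1)
  expect_true("M_rich" %in% fit$discarded)
  expect_false("M_rich" %in% fit$selected)
})
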