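test_that("Box-Cox transform has the right special cases and limit", {
  y <- c(0.5, 1, 2, 5)
  expect_equal(boxcox_transform(y, 1), y - 1)
  expect_equal(boxcox_transform(y, 0), log(y))
  expect_lt(max(abs(boxcox_transform(y, 1e-8) - log(y))), 1e-6)
  expect_error(boxcox_transform(c(1, -1), 0.5), "positive")
  # monotone in y for any lambda (rank preservation)
  set.seed(3)
  yy <- sort(stats::rlnorm(50))
  for (l in c(-1, -0.3, 0, 0.22, 1, 2)) {
    expect_false(is.unsorted(boxcox_transform(yy, l)))
  }
})

test_that("lambda-hat maximizes a directly coded profile log-likelihood", {
  set.seed(57)
  y <- stats::rlnorm(200, 1, 0.5)
  grid <- seq(-2, 2, by = 0.01)
  # independent oracle: profile log-likelihood of the intercept-only
  # normal model on the transformed scale, with the Jacobian term
  ll <- vapply(grid, function(l) {
    z <- if (l == 0) log(y) else (y^l - 1) / l
    n <- length(y)
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * sum(log(y))
  }, numeric(1))
  expect_equal(boxcox_lambda(y, grid = grid), grid[which.max(ll)])
})

test_that("profile-likelihood lambda recovers generative powers", {
  # single draws of lambda-hat are noisy (the power is weakly identified
  # when the response's coefficient of variation is small), so recovery is
  # judged on the mean over replicate simulations
  set.seed(61)
  # lognormal response -> lambda near 0
  l0 <- replicate(30, boxcox_lambda(stats::rlnorm(500, 1, 0.6)))
  expect_lt(abs(mean(l0)), 0.05)
  # already-normal positive response -> lambda near 1
  l1 <- replicate(30, boxcox_lambda(stats::rnorm(500, 10, 2)))
  expect_lt(abs(mean(l1) - 1), 0.25)
  # invert-transform recovery at lambda = 0.25
  lam <- 0.25
  l25 <- replicate(20, {
    z <- stats::rnorm(1000, 5, 1)
    boxcox_lambda((lam * z + 1)^(1 / lam))
  })
  expect_lt(abs(mean(l25) - lam), 0.1)
})

test_that("OLS bookkeeping records fit, parameters and scale equivariance", {
  set.seed(67)
  d <- data.frame(x = stats::rnorm(30))
  d$y <- 2 + 3 * d$x
  f <- suppressWarnings(fit_ols(d, "y", "x"))  # exact fit by construction
  expect_equal(f$r2, 1)
  expect_equal(f$k, 3)  # intercept + slope + error variance
  null <- fit_ols(d, "y")
  expect_equal(null$r2, 0)
  expect_equal(null$k, 2)
  d$x2 <- d$x
  expect_error(fit_ols(d, "y", c("x", "x2")), "rank-deficient")
  # standardized slope equals unstandardized slope times sd(x)
  d2 <- data.frame(x = stats::rnorm(40))
  d2$y <- 1 + 0.5 * d2$x + stats::rnorm(40, 0, 0.2)
  raw <- fit_ols(d2, "y", "x")$coefficients["x", 1]
  z <- d2; z$x <- as.vector(scale(z$x))
  std <- fit_ols(z, "y", "x")$coefficients["x", 1]
  expect_equal(std, raw * stats::sd(d2$x), tolerance = 1e-10)
  # null simulation: E[R^2] = 1/(n-1)
  set.seed(71)
  n <- 25
  r2s <- replicate(400, {
    dd <- data.frame(x = stats::rnorm(n), y = stats::rnorm(n))
    fit_ols(dd, "y", "x")$r2
  })
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 0.01)
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-10, 3, 24), 20 + 6 + 2 * 3 * 4 / 20)
  # hand-computed difference for equal log-likelihoods, k 3 vs 4, n = 12
  d34 <- aicc(0, 4, 12) - aicc(0, 3, 12)
  expect_equal(d34, (8 + 40 / 7) - (6 + 3))
  # n -> infinity: correction vanishes
  expect_equal(aicc(-10, 3, 1e8), -2 * -10 + 6, tolerance = 1e-5)
  expect_error(aicc(0, 5, 6), "undefined")
})

test_that("model selection ranks by AICc with normalized Akaike weights", {
  set.seed(73)
  d <- data.frame(x1 = stats::rnorm(30), x2 = stats::rnorm(30))
  d$y <- 1 + 2 * d$x1 + stats::rnorm(30, 0, 0.5)
  fits <- list(fit_ols(d, "y"), fit_ols(d, "y", "x1"), fit_ols(d, "y", "x2"),
               fit_ols(d, "y", c("x1", "x2")))
  tab <- select_models(fits)
  expect_equal(tab$delta[1], 0)
  expect_equal(sum(tab$weight), 1)
  expect_false(is.unsorted(tab$aicc))
  expect_true(grepl("x1", tab$model[1]))
  single <- select_models(fits[2])
  expect_equal(single$weight, 1)
  expect_equal(single$delta, 0)
  # two models at delta {0, 2}: weights e^0 : e^-1
  w <- exp(c(0, -1)); w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))
})

test_that("model averaging handles degenerate weight configurations", {
  set.seed(79)
  d <- data.frame(x1 = stats::rnorm(40), x2 = stats::rnorm(40))
  d$y <- 1 + 2 * d$x1 + stats::rnorm(40, 0, 0.3)
  fits <- list(fit_ols(d, "y"), fit_ols(d, "y", "x1"), fit_ols(d, "y", "x2"))
  avg <- model_average(fits)
  # each variable appears in exactly one model: averaged beta is that beta
  expect_equal(avg$estimate[avg$variable == "x1"],
               fits[[2]]$coefficients["x1", 1])
  expect_equal(avg$estimate[avg$variable == "x2"],
               fits[[3]]$coefficients["x2", 1])
  expect_true(all(avg$importance >= 0 & avg$importance <= 1))
  # symmetric two-model case with equal weights and opposite betas
  d2 <- data.frame(xp = c(1, -1, 2, -2, 0.5, -0.5),
                   xm = -c(1, -1, 2, -2, 0.5, -0.5))
  d2$y <- c(1.1, -0.9, 2.05, -2.1, 0.45, -0.55)
  f2 <- list(fit_ols(d2, "y", "xp"), fit_ols(d2, "y", "xm"))
  # identical fits, equal weights; betas are +b and -b
  avg2 <- model_average(f2, variables = c("xp", "xm"))
  expect_equal(avg2$estimate[1], -avg2$estimate[2])
  expect_error(model_average(fits, variables = "zz"), "no model")
})

test_that("the permutation F test is deterministic and detects strong signal", {
  set.seed(83)
  x <- stats::rnorm(20)
  y <- x * sqrt(0.8) + stats::rnorm(20, 0, sqrt(0.2))  # R^2 near 0.8
  p1 <- permutation_F(y, data.frame(x = x), n_perm = 499, seed = 7)
  p2 <- permutation_F(y, data.frame(x = x), n_perm = 499, seed = 7)
  expect_identical(p1$permuted_F, p2$permuted_F)
  expect_true(p1$significant)
  expect_lt(p1$p_value, 0.05)
  # observed F agrees with lm's
  lmF <- unname(summary(stats::lm(y ~ x))$fstatistic[1])
  expect_equal(p1$observed_F, lmF, tolerance = 1e-10)
  expect_error(permutation_F(y, data.frame(x = x), n_perm = 10), "at least")
})

test_that("correlation screening flags only collinear pairs", {
  set.seed(89)
  x <- stats::rnorm(100)
  d <- data.frame(a = x, b = 2 * x, c = stats::rnorm(100))
  flags <- correlation_screen(d)
  expect_true(any(flags$var_a == "a" & flags$var_b == "b"))
  expect_equal(flags$r[flags$var_a == "a" & flags$var_b == "b"], 1)
  # threshold 1: nothing but perfect collinearity
  expect_equal(nrow(correlation_screen(d, r_threshold = 1 - 1e-12)), 1L)
  # independent columns at n = 1000: no flags at 0.5
  big <- as.data.frame(matrix(stats::rnorm(5000), 1000, 5))
  expect_equal(nrow(correlation_screen(big)), 0L)
  d$k <- 1
  expect_error(correlation_screen(d), "constant")
})

test_that("global univariate regressions rank landscape predictors by R^2", {
  set.seed(97)
  land <- data.frame(ag = stats::rnorm(7), forest = stats::rnorm(7))
  y <- 2 + 0.5 * as.vector(scale(land$ag))
  tab <- suppressWarnings(global_univariate(y, land))  # exact fit
  expect_equal(tab$variable[1], "ag")
  expect_equal(tab$r2[1], 1)
  expect_equal(tab$coefficient[1], 0.5, tolerance = 1e-10)
  # consistent relabeling of networks changes nothing
  perm <- sample(7)
  tab2 <- suppressWarnings(global_univariate(y[perm], land[perm, ]))
  expect_equal(tab2$r2, tab$r2, tolerance = 1e-10)
  expect_error(global_univariate(y[1:2], land[1:2, ]), "at least 3")
  # parameter recovery across simulated network sets
  set.seed(101)
  hits <- replicate(200, {
    x <- stats::rnorm(7)
    yy <- 1 + 0.4 * as.vector(scale(x)) + stats::rnorm(7, 0, 0.2)
    t <- global_univariate(yy, data.frame(v = x))
    abs(t$coefficient - 0.4) < 2 * t$se
  })
  expect_gt(mean(hits), 0.85)
})

test_that("the local candidate set has the canonical fourteen models", {
  landscape <- c("forest_prop", "ag_prop", "edge_prop",
                 "forest_conn", "ag_conn", "edge_conn")
  specs <- local_candidate_set(landscape)
  expect_length(specs, 14L)
  expect_equal(sum(vapply(specs, length, integer(1)) == 0), 1L)  # null
  # at most one landscape variable per model
  n_land <- vapply(specs, function(p) sum(p %in% landscape), integer(1))
  expect_true(all(n_land <= 1))
  # overlap appears alone and with every landscape variable
  has_ov <- vapply(specs, function(p) "hr_overlap" %in% p, logical(1))
  expect_equal(sum(has_ov), 7L)

  set.seed(103)
  d <- as.data.frame(matrix(stats::runif(24 * 6, 0.1, 1), 24, 6))
  names(d) <- landscape
  d$hr_overlap <- stats::runif(24, 0.05, 0.8)
  d$soc <- exp(-4 + 2 * d$hr_overlap + stats::rnorm(24, 0, 0.3))
  out <- fit_local_models(d, "soc", landscape)
  expect_equal(nrow(out$table), 14L)
  expect_equal(sum(out$table$weight), 1)
  expect_true(all(out$table$delta >= 0))
  expect_equal(nrow(out$averaged), 7L)
})
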