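test_that("Box-Cox transform matches its closed forms and recovers lambda", {
  x <- c(exp(1), 1, 4)
  expect_equal(boxcox_transform(x, pseudocount = 0, lambda = 0)$transformed,
               log(x))
  expect_equal(boxcox_transform(x, pseudocount = 0, lambda = 1)$transformed,
               x - 1)
  expect_error(boxcox_transform(c(-1, 2), pseudocount = 0.5), "domain-error")

  # lognormal data: the profile likelihood picks lambda near 0
  set.seed(20)
  bc <- boxcox_transform(stats::rlnorm(5000), pseudocount = 0)
  expect_lt(abs(bc$lambda), 0.1)

  # and near 1 for already-Gaussian data
  bc1 <- boxcox_transform(stats::rnorm(5000, mean = 50, sd = 2), pseudocount = 0)
  expect_lt(abs(bc1$lambda - 1), 0.25)
})

test_that("Box-Cox profile likelihood agrees with the MASS reference", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- stats::rlnorm(800, 1, 0.8)
  bc <- boxcox_transform(x, pseudocount = 0)
  mb <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(bc$lambda - mb$x[which.max(mb$y)]), 0.02)
})

test_that("predictor matrix builds downstream lags and drops incomplete rows", {
  X <- build_predictor_matrix(c(1, 2, 3, 4, 5))
  expect_equal(X$codon_index, c(0L, 1L))
  expect_equal(X$Lag1, c(2, 3))
  expect_equal(X$Lag2, c(3, 4))
  expect_equal(X$Lag3, c(4, 5))
  expect_equal(attr(X, "n_dropped"), 3L)

  # constant feature retained but flagged
  Xc <- build_predictor_matrix(rnorm(50), features = list(const = rep(2, 50)))
  expect_true("const" %in% names(Xc))
  expect_equal(attr(Xc, "zero_variance"), "const")

  # all-missing feature dropped with a warning
  expect_warning(
    Xm <- build_predictor_matrix(rnorm(20), features = list(gone = rep(NA_real_, 20))),
    "all-missing")
  expect_false("gone" %in% names(Xm))

  # rows with a masked feature value are dropped
  f <- c(NA, rnorm(19))
  Xd <- build_predictor_matrix(rnorm(20), features = list(f = f), n_lags = 1)
  expect_false(0L %in% Xd$codon_index)

  expect_error(build_predictor_matrix(c(1, 2, 3), n_lags = 3),
               "empty-design-error")
})

test_that("OLS reproduces closed forms and reports the classic columns", {
  x <- 1:20
  X <- build_predictor_matrix(2 * x, features = list(x = as.numeric(x)), n_lags = 0)
  fit <- ols_fit(X, "x")
  td <- suppressWarnings(tidy(fit))  # exact fit: zero residual variance
  expect_equal(td$estimate[td$term == "x"], 2, tolerance = 1e-10)
  expect_named(td, c("term", "estimate", "std_error", "t_value", "p_value"))

  # intercept-only fit estimates the mean
  y <- rnorm(30)
  X0 <- build_predictor_matrix(y, n_lags = 0)
  f0 <- ols_fit(X0, character(0))
  expect_equal(tidy(f0)$estimate, mean(y))

  # closed-form simple-regression slope on random designs
  set.seed(22)
  for (i in 1:5) {
    xx <- rnorm(40); yy <- rnorm(40)
    Xi <- build_predictor_matrix(yy, features = list(x = xx), n_lags = 0)
    sl <- tidy(ols_fit(Xi, "x"))$estimate[2]
    expect_equal(sl, stats::cov(xx, yy) / stats::var(xx), tolerance = 1e-10)
  }

  # AIC matches the mainstream Gaussian definition
  set.seed(23)
  yy <- rnorm(50); xx <- rnorm(50)
  Xi <- build_predictor_matrix(yy, features = list(x = xx), n_lags = 0)
  expect_equal(ols_fit(Xi, "x")$aic, stats::AIC(stats::lm(yy ~ xx)))

  expect_error(ols_fit(build_predictor_matrix(rnorm(4), n_lags = 1),
                       c("Lag1")), NA)
  # duplicated predictor columns are rank deficient
  Xr <- build_predictor_matrix(rnorm(30),
                               features = list(a = xx[1:30], b = xx[1:30]),
                               n_lags = 0)
  expect_error(ols_fit(Xr), "singular-design-error")

  g <- glance(ols_fit(Xi, "x"))
  expect_equal(g$n, 50)
  expect_true(g$r_squared >= 0 && g$r_squared <= 1)
})

test_that("stepwise AIC selects greedily, deterministically, and sanely", {
  # a real Lag1 signal is found and the spurious bulk is not
  set.seed(24)
  truth <- simulation_truth(beta = c(intercept = 0, lag1 = 0.5), sigma = 0.2,
                            depth = 500, seed = 91)
  prof <- simulate_profiles(400, truth, replicates = 1)
  y <- boxcox_transform(prof$count, lambda = 0)$transformed
  X <- build_predictor_matrix(y, features = list(junk = rnorm(length(y))))
  fit <- stepwise_aic(X)
  expect_true("Lag1" %in% fit$terms)
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "Lag1"], 0.5,
               tolerance = 0.1)

  # never worse than the full or the empty model
  full <- ols_fit(X)$aic
  empty <- ols_fit(X, character(0))$aic
  expect_lte(fit$aic, full)
  expect_lte(fit$aic, empty)

  # pure-noise data with one candidate: empty model selected most of the time
  kept <- vapply(1:50, function(s) {
    set.seed(s)
    Xn <- build_predictor_matrix(rnorm(500), features = list(x = rnorm(500)),
                                 n_lags = 0)
    length(stepwise_aic(Xn)$terms) == 0L
  }, logical(1))
  expect_gte(mean(kept), 0.8)

  # perfectly collinear predictors: the aliased duplicate is dropped
  # deterministically and the survivor carries the signal
  set.seed(25)
  v <- rnorm(60)
  Xc <- build_predictor_matrix(v + rnorm(60, sd = 0.1),
                               features = list(aaa = v, bbb = v), n_lags = 0)
  fitc <- stepwise_aic(Xc)
  expect_false("bbb" %in% fitc$terms)
  expect_true("aaa" %in% fitc$terms)
  # same result no matter how the columns are ordered
  Xc3 <- build_predictor_matrix(v + rnorm(60, sd = 0.1),
                                features = list(bbb = v, aaa = v), n_lags = 0)
  fitc3 <- stepwise_aic(Xc3)
  expect_false("bbb" %in% fitc3$terms)
})

test_that("stepwise AIC agrees with the reference stepwise implementation", {
  set.seed(26)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  y <- 0.8 * d$x1 + 0.3 * d$x3 + rnorm(n)
  X <- build_predictor_matrix(y, features = as.list(d), n_lags = 0)
  mine <- stepwise_aic(X)
  ref <- stats::step(stats::lm(y ~ x1 + x2 + x3 + x4, data = d), trace = 0)
  expect_setequal(mine$terms, attr(stats::terms(ref), "term.labels"))
  expect_equal(mine$aic, stats::AIC(ref), tolerance = 1e-8)
})

test_that("cumulative-sum profiles are standardized partial sums", {
  cp <- cumsum_profile(rep(3, 10))
  expect_true(cp$degenerate)
  expect_true(all(cp$curve == 0))

  # already-standardized alternating input: partial sums pattern
  v <- c(1, -1, 1, -1)
  cp2 <- cumsum_profile(v)
  expect_equal(cp2$curve / cp2$standardized[1], c(1, 0, 1, 0))

  # curves end at zero and max |curve| is affine-invariant
  set.seed(27)
  x <- rnorm(100)
  c1 <- cumsum_profile(x)
  expect_equal(c1$curve[100], 0, tolerance = 1e-10)
  c2 <- cumsum_profile(5 * x - 7)
  expect_equal(max(abs(c1$curve)), max(abs(c2$curve)), tolerance = 1e-10)
})

test_that("two-sample KS statistic and p behave at the extremes", {
  same <- ks_two_sample(1:10, 1:10)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  sep <- ks_two_sample(rep(0, 8), rep(1, 9))
  expect_equal(sep$D, 1)
  # symmetric in its arguments
  set.seed(28)
  a <- rnorm(40); b <- rnorm(50, 0.5)
  expect_equal(ks_two_sample(a, b)$D, ks_two_sample(b, a)$D)
})

test_that("white-noise test flags shifts and passes degenerate input through", {
  wn <- white_noise_test(rep(1, 50))
  expect_true(wn$degenerate)
  expect_equal(wn$p_empirical, 1)

  # a 1-SD mean shift over 20% of the sequence is detected reliably
  set.seed(29)
  hits <- vapply(1:20, function(s) {
    x <- rnorm(400)
    x[161:240] <- x[161:240] + 1
    white_noise_test(x, n_sims = 300, seed = s)$p_empirical < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # reproducible given the seed
  x <- rnorm(80)
  expect_equal(white_noise_test(x, n_sims = 200, seed = 5)$p_empirical,
               white_noise_test(x, n_sims = 200, seed = 5)$p_empirical)
})

test_that("variant-vs-variant cumulative-sum comparison detects a regional shift", {
  set.seed(30)
  base <- rnorm(300)
  shifted <- rnorm(300)
  shifted[100:160] <- shifted[100:160] + 1.5
  cmp <- cumsum_compare(base, shifted)
  expect_true(cmp$ks_D >= 0 && cmp$ks_D <= 1)
  expect_equal(cmp$null_kind, "variant-vs-variant")
  # identical inputs give identical curves
  cmp0 <- cumsum_compare(base, base)
  expect_equal(cmp0$ks_D, 0)
  expect_equal(cmp0$ks_p, 1)
})

test_that("model report TSV mirrors the regression table", {
  set.seed(31)
  X <- build_predictor_matrix(rnorm(50), features = list(x = rnorm(50)), n_lags = 0)
  fit <- ols_fit(X)
  f <- tempfile(fileext = ".tsv")
  write_model_report(fit, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# AIC")
  tab <- utils::read.delim(f, skip = 1)
  expect_equal(tab$term, c("(Intercept)", "x"))
  expect_equal(tab$estimate, tidy(fit)$estimate, tolerance = 1e-6)
})
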