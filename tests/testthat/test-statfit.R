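test_that("compute_statistics matches hand arithmetic and conserves mass", {
  cm <- cm_from(matrix(c(1, 2, 0, 3), 2))   # rows: [1,0], [2,3]
  st <- compute_statistics(cm)
  expect_equal(st$lib_size, c(3, 3))
  expect_equal(st$nonzero_prop, c(1.0, 0.5))
  expect_equal(st$peak_sum, c(1, 5))

  z <- compute_statistics(cm_from(matrix(0, 3, 3)))
  expect_equal(z$lib_size, rep(0, 3))
  expect_equal(z$nonzero_prop, rep(0, 3))

  st2 <- compute_statistics(fixture_ref(300, 100))
  expect_identical(sum(st2$lib_size), sum(st2$peak_sum))
})

test_that("two-component GMM recovers simulated mixture parameters", {
  for (s in 1:3) {
    set.seed(s)
    x <- c(rnorm(2500, 0, 1), rnorm(2500, 6, 1))
    g <- fit_gmm2(x)
    o <- order(g$mean)
    expect_equal(g$mean[o], c(0, 6), tolerance = 0.15)
    expect_equal(g$weight[o], c(0.5, 0.5), tolerance = 0.05)
  }
  # a single tight cluster keeps both means inside the data range
  set.seed(4)
  y <- rnorm(500, 10, 0.1)
  g2 <- fit_gmm2(y)
  expect_true(all(g2$mean >= min(y) & g2$mean <= max(y)))
  # deterministic refit
  expect_identical(fit_gmm2(y), fit_gmm2(y))
  expect_error(fit_gmm2(rep(1, 100)), "degenerate")
})

test_that("log-variant MLE recovers the generating parameter", {
  fit0 <- structure(list(family = "logvariant", par = c(p = 0.98)),
                    class = "discrete_fit")
  set.seed(5)
  x <- sample_discrete(fit0, 10000)
  fit <- fit_discrete(x, "logvariant")
  expect_equal(unname(fit$par[["p"]]), 0.98, tolerance = 0.02)
})

test_that("discrete MLEs match closed forms and a grid-search oracle", {
  set.seed(6)
  x <- rpois(500, 4)
  fp <- fit_discrete(x, "poisson")
  expect_equal(unname(fp$par[["lambda"]]), mean(x))   # MLE identity

  # grid-search oracle for the log-variant parameter
  set.seed(7)
  y <- sample_discrete(structure(list(family = "logvariant", par = c(p = 0.9)),
                                 class = "discrete_fit"), 300)
  grid <- seq(0.5, 0.999, by = 1e-4)
  ll <- vapply(grid, function(p)
    sum(accessim:::dlogvariant(y, p, log = TRUE)), numeric(1))
  fy <- fit_discrete(y, "logvariant")
  expect_equal(unname(fy$par[["p"]]), grid[which.max(ll)], tolerance = 2e-4)
})

test_that("fitted PMFs are normalized over their truncated support", {
  gen <- list(
    logvariant = list(par = c(p = 0.9), kmax = 5000L),
    poisson = list(par = c(lambda = 3), kmax = 5000L),
    negative_binomial = list(par = c(size = 2, mu = 5), kmax = 5000L),
    geometric = list(par = c(prob = 0.3), kmax = 5000L),
    zipf = list(par = c(s = 2.5), kmax = 200000L),
    logarithmic = list(par = c(p = 0.8), kmax = 5000L))
  set.seed(8)
  for (fam in names(gen)) {
    truth <- structure(list(family = fam, par = gen[[fam]]$par),
                       class = "discrete_fit")
    x <- sample_discrete(truth, 400)
    f <- suppressWarnings(fit_discrete(x, fam))
    expect_gte(sum(pmf_discrete(f, 0:gen[[fam]]$kmax)), 1 - 1e-6)
  }
  expect_error(fit_discrete(rpois(100, 3), "weibull"), "unknown family")
})

test_that("family selection prefers the better KS fit", {
  set.seed(9)
  x <- rpois(2000, 4)
  best <- select_best_discrete(x, c("poisson", "geometric"))
  expect_equal(best$family, "poisson")
  one <- select_best_discrete(x, "geometric")
  expect_equal(one$family, "geometric")

  # heavy-tailed log-series-like data favors the log-variant family
  set.seed(10)
  y <- sample_discrete(structure(list(family = "logvariant", par = c(p = 0.995)),
                                 class = "discrete_fit"), 2000)
  besty <- select_best_discrete(y, c("logvariant", "poisson"))
  expect_equal(besty$family, "logvariant")
})

test_that("KDE sampler reproduces the data distribution within its domain", {
  expect_warning(k0 <- fit_kde(rep(2, 50)), "point-mass")
  set.seed(11)
  expect_true(all(sample_kde(k0, 100) == 2))

  set.seed(12)
  k <- fit_kde(rnorm(5000))
  s <- sample_kde(k, 10000)
  expect_lt(ks_statistic(s, qnorm(ppoints(10000))), 0.03)

  # clamped sampler never leaves the domain on any draw
  kc <- fit_kde(log(runif(500, 0.5, 1)), upper = 0)
  set.seed(13)
  expect_lte(max(sample_kde(kc, 5000)), 0)
})

test_that("build_stat_models dispatches backends by mode", {
  ref <- fixture_ref(500, 240, n_types = 2, seed = 3)
  sm <- build_stat_models(ref, "pseudo_cell_type")
  expect_length(sm$models, 2L)
  expect_s3_class(sm$models$type_1$l, "gmm2")
  expect_s3_class(sm$models$type_1$p, "discrete_fit")

  smg <- build_stat_models(ref, "discrete")    # labels present but ignored
  expect_named(smg$models, "global")
  expect_s3_class(smg$models$global$l, "kde_sampler")

  nolab <- count_matrix(ref$counts)
  expect_error(build_stat_models(nolab, "pseudo_cell_type"), "labels")
})

test_that("sampled library sizes recover the reference distribution", {
  ref <- fixture_ref(2000, 1000, n_types = 1, seed = 21)
  sm <- build_stat_models(ref, "pseudo_cell_type")
  set.seed(14)
  lib <- exp(accessim:::sample_gmm2(sm$models$type_1$l, 5000))
  st <- compute_statistics(ref)
  expect_lt(ks_statistic(log(lib), log(st$lib_size)), 0.05)
})

test_that("all samplers converge to their fitted model CDF", {
  set.seed(15)
  g <- fit_gmm2(c(rnorm(1000), rnorm(1000, 4)))
  s <- accessim:::sample_gmm2(g, 10000)
  cdf <- function(q) g$weight[1] * pnorm(q, g$mean[1], g$sd[1]) +
    g$weight[2] * pnorm(q, g$mean[2], g$sd[2])
  grid <- sort(s)
  expect_lt(max(abs(ecdf(s)(grid) - cdf(grid))), 0.02)

  f <- fit_discrete(rpois(500, 2), "poisson")
  set.seed(16)
  sd_ <- sample_discrete(f, 10000)
  kmax <- max(sd_)
  expect_lt(max(abs(ecdf(sd_)(0:kmax) - cumsum(pmf_discrete(f, 0:kmax)))), 0.02)
})
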