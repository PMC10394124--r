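#' Core statistics of a peak-by-cell matrix
#'
#' The simulator preserves three statistics of the reference data: library
#' size (column sum: reads per cell), cell non-zero proportion (fraction of
#' peaks with a non-zero count per cell), and peak summation (row sum: reads
#' per peak). On a binarized matrix the library size equals the per-cell
#' non-zero count.
#'
#' @param cm A [count_matrix()].
#' @return A list of class `stat_triple` with `lib_size` (length ncell),
#'   `nonzero_prop` (length ncell) and `peak_sum` (length npeak).
#' @export
compute_statistics <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (prod(dim(cm$counts)) == 0) stop("empty matrix", call. = FALSE)
  structure(list(lib_size = as.numeric(Matrix::colSums(cm$counts)),
                 nonzero_prop = as.numeric(Matrix::colSums(cm$counts > 0)) / nrow(cm$counts),
                 peak_sum = as.numeric(Matrix::rowSums(cm$counts))),
            class = "stat_triple")
}

# ---- two-component Gaussian mixture ----------------------------------------

#' Fit a two-component Gaussian mixture
#'
#' Used for log library size and log cell non-zero proportion in the
#' pseudo-cell-type mode. Fitting is EM via mclust with unequal variances
#' (equal-variance fallback for near-degenerate data); values are fit as
#' given — any log transform is the caller's convention.
#'
#' @param values Numeric vector (>= 10 finite values, >= 2 distinct).
#' @return An object of class `gmm2`: list with `weight`, `mean`, `sd`
#'   (each length 2) and `loglik`.
#' @export
fit_gmm2 <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need >= 10 finite values", call. = FALSE)
  if (length(unique(values)) < 2) stop("degenerate data: < 2 distinct values",
                                       call. = FALSE)
  fit <- mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- mclust::Mclust(values, G = 2, modelNames = "E",
                                          verbose = FALSE)
  if (is.null(fit)) stop("GMM fit failed", call. = FALSE)
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, 2)
  structure(list(weight = as.numeric(fit$parameters$pro),
                 mean = as.numeric(fit$parameters$mean),
                 sd = as.numeric(sds), loglik = fit$loglik),
            class = "gmm2")
}

sample_gmm2 <- function(model, n) {
  k <- sample.int(2L, n, replace = TRUE, prob = model$weight)
  stats::rnorm(n, mean = model$mean[k], sd = model$sd[k])
}

# ---- discrete families for peak summation ----------------------------------

DISCRETE_FAMILIES <- c("logvariant", "poisson", "negative_binomial",
                       "geometric", "zipf", "logarithmic")

# log-variant: zero-shifted log-series, PMF(k; p) = -p^(k+1) / ((k+1) log(1-p))
dlogvariant <- function(k, p, log = FALSE) {
  ll <- (k + 1) * log(p) - log(k + 1) - log(-log1p(-p))
  ll[k < 0 | k != floor(k)] <- -Inf
  if (log) ll else exp(ll)
}

# standard log-series on 1, 2, ...: PMF(m; p) = -p^m / (m log(1-p))
dlogseries <- function(m, p, log = FALSE) dlogvariant(m - 1, p, log = log)

dzipf1 <- function(m, s, log = FALSE) {  # support 1, 2, ...
  ll <- -s * log(m) - log(pracma::zeta(s))
  ll[m < 1 | m != floor(m)] <- -Inf
  if (log) ll else exp(ll)
}

#' Probability mass function of a fitted discrete family
#'
#' @param fit A `discrete_fit` from [fit_discrete()].
#' @param k Non-negative integer quantiles (the data scale, support
#'   including 0; shifted families are handled internally).
#' @param log Return log-probabilities?
#' @return Numeric vector of probabilities.
#' @export
pmf_discrete <- function(fit, k, log = FALSE) {
  p <- fit$par
  switch(fit$family,
    logvariant = dlogvariant(k, p[["p"]], log = log),
    poisson = stats::dpois(k, p[["lambda"]], log = log),
    negative_binomial = stats::dnbinom(k, size = p[["size"]], mu = p[["mu"]],
                                       log = log),
    geometric = stats::dgeom(k, p[["prob"]], log = log),
    zipf = dzipf1(k + 1, p[["s"]], log = log),
    logarithmic = dlogseries(k + 1, p[["p"]], log = log),
    stop(sprintf("unknown family '%s'", fit$family), call. = FALSE))
}

# one-sample KS statistic of integer data against a fitted family
discrete_ks <- function(values, fit) {
  kmax <- max(values)
  cdf <- cumsum(pmf_discrete(fit, 0:kmax))
  ecdf_v <- stats::ecdf(values)(0:kmax)
  max(abs(ecdf_v - cdf))
}

#' Fit a discrete distribution to peak summations
#'
#' Maximum-likelihood fit of one of six long-tail-capable count families to
#' non-negative integer data. The log-variant family (a zero-shifted
#' log-series) is the default model for peak summation; Poisson, negative
#' binomial, geometric, Zipf and logarithmic serve as alternatives. Zipf
#' and logarithmic have support starting at 1 and are fit to `values + 1`.
#'
#' @param values Non-negative integers, `n >= 50`.
#' @param family One of `"logvariant"`, `"poisson"`, `"negative_binomial"`,
#'   `"geometric"`, `"zipf"`, `"logarithmic"`.
#' @return A `discrete_fit`: list with `family`, `par` (named vector),
#'   `loglik` and `ks` (one-sample KS statistic against the data).
#' @export
fit_discrete <- function(values, family = "logvariant") {
  if (!family %in% DISCRETE_FAMILIES)
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  if (any(values < 0) || any(values != floor(values)))
    stop("values must be non-negative integers", call. = FALSE)
  if (length(values) < 50) stop("need n >= 50", call. = FALSE)
  n <- length(values)
  par <- switch(family,
    poisson = c(lambda = mean(values)),
    geometric = c(prob = 1 / (1 + mean(values))),
    negative_binomial = {
      f <- tryCatch(suppressWarnings(
             MASS::fitdistr(values, "negative binomial")),
           error = function(e) stop("negative binomial fit failed: ",
                                    conditionMessage(e), call. = FALSE))
      c(size = unname(f$estimate["size"]), mu = unname(f$estimate["mu"]))
    },
    logvariant = {
      nll <- function(p) -sum(dlogvariant(values, p, log = TRUE))
      o <- stats::optimize(nll, c(1e-8, 1 - 1e-10))
      if (!is.finite(o$objective)) stop("log-variant fit failed", call. = FALSE)
      c(p = o$minimum)
    },
    logarithmic = {
      v1 <- values + 1
      nll <- function(p) -sum(dlogseries(v1, p, log = TRUE))
      c(p = stats::optimize(nll, c(1e-8, 1 - 1e-10))$minimum)
    },
    zipf = {
      v1 <- values + 1
      nll <- function(s) -sum(dzipf1(v1, s, log = TRUE))
      c(s = stats::optimize(nll, c(1 + 1e-6, 30))$minimum)
    })
  fit <- structure(list(family = family, par = par), class = "discrete_fit")
  fit$loglik <- sum(pmf_discrete(fit, values, log = TRUE))
  if (!is.finite(fit$loglik))
    stop(sprintf("%s fit did not converge to a finite likelihood", family),
         call. = FALSE)
  fit$ks <- discrete_ks(values, fit)
  fit
}

#' Pick the discrete family with the best KS fit
#'
#' Fits each candidate family and returns the fit with the smallest
#' one-sample KS statistic (ties broken by higher log-likelihood). Families
#' that fail to fit are dropped.
#'
#' @param values Non-negative integers.
#' @param families Character vector of >= 2 candidates (or 1, returned
#'   as-is).
#' @return The winning `discrete_fit`.
#' @export
select_best_discrete <- function(values, families = DISCRETE_FAMILIES) {
  fits <- lapply(families, function(f)
    tryCatch(fit_discrete(values, f), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all discrete fits failed", call. = FALSE)
  ks <- vapply(fits, `[[`, numeric(1), "ks")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  fits[[order(ks, -ll)[1]]]
}

#' Draw samples from a fitted discrete family
#'
#' @param fit A `discrete_fit`.
#' @param n Number of draws.
#' @return Integer-valued numeric vector on the data scale (support
#'   includes 0).
#' @export
sample_discrete <- function(fit, n) {
  p <- fit$par
  switch(fit$family,
    poisson = stats::rpois(n, p[["lambda"]]),
    negative_binomial = stats::rnbinom(n, size = p[["size"]], mu = p[["mu"]]),
    geometric = stats::rgeom(n, p[["prob"]]),
    logvariant = , zipf = , logarithmic = {
      # inversion over a truncated support up to the 1 - 1e-9 quantile
      # (draws are renormalized to the truncated table); heavier tails
      # (Zipf) are capped so the table stays bounded
      coverage <- 1 - 1e-9
      kmax <- 1024L
      repeat {
        cdf <- cumsum(pmf_discrete(fit, 0:kmax))
        if (cdf[kmax + 1] >= coverage || kmax > 2^24) break
        kmax <- kmax * 4L
      }
      findInterval(stats::runif(n) * cdf[kmax + 1], cdf)
    })
}

# ---- kernel density sampler -------------------------------------------------

#' Kernel density estimate with a domain-clamped sampler
#'
#' Gaussian KDE with Scott's-rule bandwidth; sampling resamples the data
#' with replacement and adds Gaussian noise at the bandwidth. Samples
#' falling outside `[lower, upper]` are redrawn (up to 100 attempts), then
#' projected onto the boundary.
#'
#' @param values Numeric data, `n >= 10`.
#' @param lower,upper Domain bounds for sampling (default unbounded).
#' @return An object of class `kde_sampler`.
#' @export
fit_kde <- function(values, lower = -Inf, upper = Inf) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need n >= 10", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("zero-variance data: returning a point-mass sampler")
    bw <- 0
  } else bw <- stats::bw.nrd(values)  # Scott's rule
  structure(list(values = values, bw = bw, lower = lower, upper = upper),
            class = "kde_sampler")
}

sample_kde <- function(model, n) {
  draw <- function(m) sample(model$values, m, replace = TRUE) +
    if (model$bw > 0) stats::rnorm(m, 0, model$bw) else 0
  x <- draw(n)
  for (i in seq_len(100)) {
    bad <- which(x < model$lower | x > model$upper)
    if (!length(bad)) break
    x[bad] <- draw(length(bad))
  }
  pmin(pmax(x, model$lower), model$upper)
}

# ---- model bundle -----------------------------------------------------------

#' Fit the statistic sampling models for a simulation
#'
#' Pseudo-cell-type mode fits, per cell type: a two-component GMM to log
#' library size, a two-component GMM to log non-zero proportion, and a
#' discrete family (log-variant by default) to that type's peak summations.
#' Discrete and continuous modes fit global kernel density estimates of all
#' three statistics from the whole matrix, ignoring any labels.
#'
#' @param cm A [count_matrix()].
#' @param mode One of `"pseudo_cell_type"`, `"discrete"`, `"continuous"`.
#' @param labels Per-cell type labels (required in pseudo mode).
#' @param peak_family Discrete family (or families, auto-selected) for peak
#'   summation in pseudo mode.
#' @return An object of class `stat_models`: `mode`, `backend`, and
#'   `models`, a named list (one entry per cell type, or `"global"`) of
#'   lists with samplers `l` (log library size), `c` (log non-zero
#'   proportion) and `p` (peak summation).
#' @export
build_stat_models <- function(cm, mode = c("pseudo_cell_type", "discrete",
                                           "continuous"),
                              labels = NULL, peak_family = "logvariant") {
  mode <- match.arg(mode)
  st <- compute_statistics(cm)
  if (mode == "pseudo_cell_type") {
    if (is.null(labels)) labels <- cm$cells$cell_type
    if (is.null(labels)) stop("pseudo_cell_type mode requires cell-type labels",
                              call. = FALSE)
    stopifnot(length(labels) == ncol(cm$counts))
    models <- list()
    for (ty in unique(labels)) {
      jj <- which(labels == ty)
      if (length(jj) < 10)
        stop(sprintf("cell type '%s' has %d cells (< 10); filter it out first",
                     ty, length(jj)), call. = FALSE)
      psum <- as.numeric(Matrix::rowSums(cm$counts[, jj, drop = FALSE]))
      pf <- if (length(peak_family) > 1)
        select_best_discrete(psum, peak_family) else
        fit_discrete(psum, peak_family)
      models[[ty]] <- list(l = fit_gmm2(log(st$lib_size[jj])),
                           c = fit_gmm2(log(st$nonzero_prop[jj])),
                           p = pf)
    }
    backend <- "gmm2+discrete"
  } else {
    models <- list(global = list(
      l = fit_kde(log(st$lib_size[st$lib_size > 0])),
      c = fit_kde(log(st$nonzero_prop[st$nonzero_prop > 0]), upper = 0),
      p = fit_kde(st$peak_sum, lower = 0)))
    backend <- "kde"
  }
  structure(list(mode = mode, backend = backend, models = models),
            class = "stat_models")
}

# draw correction targets from a fitted model entry
sample_targets <- function(entry, ncell, npeak) {
  s1 <- function(m, n) switch(class(m)[1],
    gmm2 = sample_gmm2(m, n),
    kde_sampler = sample_kde(m, n),
    discrete_fit = sample_discrete(m, n),
    stop("unknown sampler backend"))
  lib <- exp(s1(entry$l, ncell))
  sparsity <- pmin(exp(s1(entry$c, ncell)), 1)
  peak <- pmax(s1(entry$p, npeak), 0)
  list(lib = lib, sparsity = sparsity, peak = peak)
}
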