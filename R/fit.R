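#' Fit the reference statistics model for simulation
#'
#' The estimator front-end: given a reference peak-by-cell matrix, computes
#' the three core statistics (library size, cell non-zero proportion, peak
#' summation) and fits their sampling models — per cell type in the
#' pseudo-cell-type mode (two-component GMMs on the log cell statistics and
#' a discrete family on peak summation), globally by kernel density
#' estimation in the discrete and continuous modes. The returned object is
#' the single input the [simulate()][simulate.cas_fit] method needs.
#'
#' @param x A [count_matrix()] (or a plain/sparse matrix, converted with
#'   default metadata).
#' @param mode Simulation mode the fit will serve: `"pseudo_cell_type"`,
#'   `"discrete"` or `"continuous"`.
#' @param cell_type Optional per-cell labels (defaults to the matrix's
#'   `cell_type` column; required in pseudo mode).
#' @param peak_family Discrete family for peak summation in pseudo mode
#'   (default `"logvariant"`; pass several names to auto-select by KS fit).
#' @return An object of class `cas_fit` with elements `mode`, `models` (a
#'   [build_stat_models()] bundle), `stats` (the reference
#'   [compute_statistics()] triple), `npeak`, `ncell`, `type_counts` and
#'   `binarized`.
#' @seealso [simulate.cas_fit()], [make_fixture()]
#' @examples
#' ref <- make_fixture(npeak = 300, ncell = 120, seed = 7)
#' fit <- cas_fit(ref, mode = "discrete")
#' print(fit)
#' syn <- simulate(fit, seed = 1, covariance = diag(3), ncell = 90)
#' table(syn$cells$population)
#' @export
cas_fit <- function(x, mode = c("pseudo_cell_type", "discrete", "continuous"),
                    cell_type = NULL, peak_family = "logvariant") {
  mode <- match.arg(mode)
  if (!inherits(x, "count_matrix")) x <- count_matrix(x)
  if (is.null(cell_type)) cell_type <- x$cells$cell_type
  models <- build_stat_models(x, mode, labels = cell_type,
                              peak_family = peak_family)
  type_counts <- if (!is.null(cell_type)) table(cell_type) else NULL
  structure(list(mode = mode, models = models,
                 stats = compute_statistics(x),
                 npeak = nrow(x$counts), ncell = ncol(x$counts),
                 type_counts = if (!is.null(type_counts))
                   stats::setNames(as.integer(type_counts),
                                   names(type_counts)) else NULL,
                 binarized = x$binarized, call = match.call()),
            class = "cas_fit")
}

#' @export
print.cas_fit <- function(x, ...) {
  cat(sprintf("cas_fit (%s mode, %s backend)\n", x$mode, x$models$backend))
  cat(sprintf("reference: %d peaks x %d cells%s\n", x$npeak, x$ncell,
              if (x$binarized) " (binarized)" else ""))
  if (x$models$backend != "kde")
    cat(sprintf("cell types: %s\n",
                paste(sprintf("%s (%d)", names(x$type_counts), x$type_counts),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.cas_fit <- function(object, ...) {
  st <- object$stats
  cat(sprintf("cas_fit (%s mode)\n", object$mode))
  cat(sprintf("library size:      median %.0f  [%.0f, %.0f]\n",
              stats::median(st$lib_size), min(st$lib_size), max(st$lib_size)))
  cat(sprintf("non-zero prop:     median %.3f  [%.3f, %.3f]\n",
              stats::median(st$nonzero_prop), min(st$nonzero_prop),
              max(st$nonzero_prop)))
  cat(sprintf("peak summation:    median %.0f  [%.0f, %.0f]\n",
              stats::median(st$peak_sum), min(st$peak_sum), max(st$peak_sum)))
  for (nm in names(object$models$models)) {
    e <- object$models$models[[nm]]
    if (inherits(e$l, "gmm2"))
      cat(sprintf("[%s] log lib size GMM: means %.2f/%.2f, weights %.2f/%.2f; peak family %s\n",
                  nm, e$l$mean[1], e$l$mean[2], e$l$weight[1], e$l$weight[2],
                  e$p$family))
    else
      cat(sprintf("[%s] KDE bandwidths: lib %.3f, prop %.3f, peak %.3f\n",
                  nm, e$l$bw, e$c$bw, e$p$bw))
  }
  invisible(object)
}

#' @export
coef.cas_fit <- function(object, ...) {
  lapply(object$models$models, function(e) {
    lapply(e, function(m) switch(class(m)[1],
      gmm2 = c(weight1 = m$weight[1], mean1 = m$mean[1], sd1 = m$sd[1],
               weight2 = m$weight[2], mean2 = m$mean[2], sd2 = m$sd[2]),
      kde_sampler = c(bandwidth = m$bw, n = length(m$values)),
      discrete_fit = c(m$par, ks = m$ks),
      NULL))
  })
}

#' Simulate synthetic data from a fitted reference model
#'
#' The `simulate` method for [cas_fit()] objects. All [cas_config()]
#' arguments are accepted through `...`; `ncell`/`npeak` default to the
#' reference dimensions, and `count_model` defaults to `"bernoulli"` when
#' the reference was binarized. When the configuration holds two or more
#' [batch_spec()]s the batch pipeline runs instead of the plain mode.
#'
#' @param object A [cas_fit()].
#' @param nsim Number of datasets (default 1; a list is returned when
#'   `nsim > 1`).
#' @param seed Root seed; overrides the config seed when given.
#' @param config Optional prebuilt [cas_config()]; otherwise one is built
#'   from `...`.
#' @param ... [cas_config()] arguments.
#' @return A [count_matrix()] with ground-truth cell metadata, or a list of
#'   them when `nsim > 1`.
#' @export
simulate.cas_fit <- function(object, nsim = 1, seed = NULL, config = NULL,
                             ...) {
  if (is.null(config)) {
    dots <- list(...)
    if (is.null(dots$ncell))
      dots$ncell <- if (!is.null(dots$pop_sizes)) sum(dots$pop_sizes) else
        object$ncell
    if (is.null(dots$npeak)) dots$npeak <- object$npeak
    if (is.null(dots$count_model) && object$binarized)
      dots$count_model <- "bernoulli"
    dots$mode <- object$mode
    config <- do.call(cas_config, dots)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run1 <- function(cfg) {
    if (length(cfg$batches) >= 2) simulate_batches(object, cfg)
    else switch(cfg$mode,
                pseudo_cell_type = simulate_pseudo(object, cfg),
                discrete = simulate_discrete(object, cfg),
                continuous = simulate_continuous(object, cfg))
  }
  if (nsim == 1) return(run1(config))
  lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("sim", i))
    run1(cfg)
  })
}

#' Diagnostic plot of a fitted reference model
#'
#' Histograms of the three reference statistics with 1000 samples from the
#' corresponding fitted samplers overlaid, on the scale each model is fit
#' on (log for the cell statistics).
#'
#' @param x A [cas_fit()].
#' @param ... Passed to `hist`.
#' @return Invisibly, `x`.
#' @export
plot.cas_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  st <- x$stats
  entry <- x$models$models[[1]]
  draw <- function(m, n) switch(class(m)[1],
    gmm2 = sample_gmm2(m, n), kde_sampler = sample_kde(m, n),
    discrete_fit = sample_discrete(m, n))
  panels <- list(
    list(v = log(st$lib_size[st$lib_size > 0]), s = draw(entry$l, 1000),
         t = "log library size"),
    list(v = log(st$nonzero_prop[st$nonzero_prop > 0]), s = draw(entry$c, 1000),
         t = "log non-zero proportion"),
    list(v = st$peak_sum, s = draw(entry$p, 1000), t = "peak summation"))
  for (p in panels) {
    graphics::hist(p$v, freq = FALSE, main = p$t, xlab = NULL,
                   col = "grey85", border = "white", ...)
    graphics::lines(stats::density(p$s), col = "firebrick", lwd = 2)
  }
  invisible(x)
}
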