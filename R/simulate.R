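#' Simulation configuration
#'
#' Bundles and validates every knob of a simulation run. Mode-specific
#' requirements: `discrete` needs a covariance matrix (and optionally
#' `pop_sizes`; default equal split with the remainder going to earlier
#' populations); `continuous` needs a Newick tree; `pseudo_cell_type` takes
#' its cell counts from the fitted reference by default.
#'
#' @param mode `"pseudo_cell_type"`, `"discrete"` or `"continuous"`.
#' @param ncell,npeak Output dimensions.
#' @param nembed Total embedding dimensions (default 12).
#' @param nhete Heterogeneous dimensions (default 10; must be < `nembed`).
#' @param sigma Embedding standard deviation (> 0, default 0.5); larger
#'   values give more within-state dispersion.
#' @param eta PEM zeroing probability in \[0, 1\] (default 0.5).
#' @param activation `"softplus"` (default) or `"exponential"`.
#' @param count_model `"poisson"` (default) or `"bernoulli"` (binarized
#'   output).
#' @param covariance `npop` x `npop` symmetric PSD matrix (discrete mode).
#' @param pop_sizes Optional population sizes summing to `ncell`.
#' @param tree Newick string, file, or [parse_newick()] tree (continuous
#'   mode).
#' @param batches Optional list of [batch_spec()]s (>= 2 for a multi-batch
#'   run).
#' @param hubs Optional list of [hub_spec()]s.
#' @param seed Integer root seed for all stage substreams.
#' @return A validated list of class `cas_config`.
#' @export
cas_config <- function(mode = c("pseudo_cell_type", "discrete", "continuous"),
                       ncell, npeak, nembed = 12, nhete = 10, sigma = 0.5,
                       eta = 0.5, activation = c("softplus", "exponential"),
                       count_model = c("poisson", "bernoulli"),
                       covariance = NULL, pop_sizes = NULL, tree = NULL,
                       batches = NULL, hubs = NULL, seed = 1L) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  count_model <- match.arg(count_model)
  stopifnot(ncell >= 1, npeak >= 1, nembed >= 1)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  if (mode != "pseudo_cell_type" && nhete >= nembed)
    stop("nhete must be < nembed", call. = FALSE)
  if (mode == "discrete") {
    if (is.null(covariance)) stop("discrete mode requires a covariance matrix",
                                  call. = FALSE)
    covariance <- as.matrix(covariance)
    npop <- ncol(covariance)
    if (is.null(pop_sizes)) {
      base <- ncell %/% npop
      pop_sizes <- rep(base, npop)
      extra <- ncell - base * npop
      if (extra > 0) pop_sizes[seq_len(extra)] <- pop_sizes[seq_len(extra)] + 1L
    }
    if (sum(pop_sizes) != ncell)
      stop("pop_sizes must sum to ncell", call. = FALSE)
  }
  if (mode == "continuous") {
    if (is.null(tree)) stop("continuous mode requires a tree", call. = FALSE)
    if (!inherits(tree, "cas_tree")) tree <- parse_newick(tree)
  }
  structure(list(mode = mode, ncell = as.integer(ncell),
                 npeak = as.integer(npeak), nembed = as.integer(nembed),
                 nhete = as.integer(nhete), sigma = sigma, eta = eta,
                 activation = activation, count_model = count_model,
                 covariance = covariance, pop_sizes = pop_sizes, tree = tree,
                 batches = batches, hubs = hubs, seed = as.integer(seed)),
            class = "cas_config")
}

as_stat_models <- function(x) {
  if (inherits(x, "cas_fit")) x$models
  else if (inherits(x, "stat_models")) x
  else stop("expected a cas_fit or stat_models object", call. = FALSE)
}

# rescale sampled peak targets so total peak mass equals total library mass;
# without this the independently sampled target vectors would disagree on the
# total count mass and the final (cell-wise) correction would shift every row
# sum by the ratio
.align_targets <- function(targets) {
  if (sum(targets$peak) > 0)
    targets$peak <- targets$peak * (sum(targets$lib) / sum(targets$peak))
  targets
}

# Alternate the two corrections to joint convergence: the cell-wise power
# shaping perturbs row sums, so a single peak-then-cell pass leaves a
# systematic row-sum distortion that the alternation removes geometrically.
# The loop always ends with the cell-wise step, so the exact library-size
# and non-zero-proportion contracts hold on the returned matrix.
.lambda_pipeline <- function(P, C, l, targets, config, n_iter = 10) {
  m <- activate(raw_param_matrix(P, C), config$activation)
  scores <- as.numeric(l %*% C)
  for (it in seq_len(n_iter)) {
    m$stage <- "activated"
    m <- correct_peakwise(m, targets$peak)
    m <- correct_cellwise(m, targets$lib, targets$sparsity, scores)
  }
  m
}

.sample_counts <- function(fin, config, peaks = NULL, cells = NULL) {
  if (config$count_model == "bernoulli")
    sample_counts_bernoulli(fin, peaks, cells)
  else sample_counts_poisson(fin, peaks, cells)
}

.hub_peaks_df <- function(npeak, hub_truth) {
  peaks <- data.frame(chrom = "chr1",
                      start = seq.int(0L, by = 1000L, length.out = npeak),
                      end = seq.int(500L, by = 1000L, length.out = npeak),
                      peak_id = sprintf("peak_%d", seq_len(npeak)),
                      hub_id = NA_character_, interactive = FALSE)
  if (!is.null(hub_truth)) {
    peaks$hub_id[hub_truth$peak_index] <- hub_truth$hub_id
    peaks$interactive[hub_truth$peak_index] <- hub_truth$interactive
  }
  peaks
}

#' Simulate discrete cell populations
#'
#' Draws population centers from the configured covariance, builds the CEM
#' (heterogeneous block around the centers, homogeneous block shared),
#' generates the PEM and CEV, samples correction targets from the fitted
#' global KDE models, corrects and samples counts. Population labels are
#' emitted in the cell metadata.
#'
#' @param models A [cas_fit()] or [build_stat_models()] result (KDE
#'   backend).
#' @param config A [cas_config()] with `mode = "discrete"`.
#' @return A [count_matrix()] with a `population` column.
#' @export
simulate_discrete <- function(models, config) {
  sm <- as_stat_models(models)
  stopifnot(config$mode == "discrete")
  seed <- config$seed
  n_homo <- config$nembed - config$nhete
  H <- with_stream(seed, "centers",
    generate_discrete_centers(ncol(config$covariance), config$nhete,
                              config$covariance))
  cem <- with_stream(seed, "cem", {
    hete <- generate_discrete_cem(H, config$pop_sizes, config$sigma)
    homo <- generate_homogeneous_cem(n_homo, config$ncell, config$sigma)
    list(C = assemble_cem(homo, hete$C_hete), population = hete$population)
  })
  P <- with_stream(seed, "pem", generate_pem(config$npeak, config$nembed,
                                             config$eta))
  hub_truth <- NULL
  if (length(config$hubs)) {
    hb <- with_stream(seed, "hubs",
      inject_interaction_hubs(P, config$hubs, config$eta))
    P <- hb$P; hub_truth <- hb$peak_truth
  }
  l <- with_stream(seed, "cev", generate_cev(config$nembed))
  targets <- with_stream(seed, "targets",
    .align_targets(sample_targets(sm$models$global, config$ncell,
                                  config$npeak)))
  fin <- .lambda_pipeline(P, cem$C, l, targets, config)
  cells <- data.frame(barcode = sprintf("cell_%d", seq_len(config$ncell)),
                      population = cem$population)
  out <- with_stream(seed, "counts",
    .sample_counts(fin, config, peaks = .hub_peaks_df(config$npeak, hub_truth),
                   cells = cells))
  attr(out, "H") <- H
  attr(out, "lib_targets") <- attr(fin, "lib_targets")
  attr(out, "sparsity_targets") <- attr(fin, "sparsity_targets")
  attr(out, "peak_targets") <- targets$peak
  out
}

#' Simulate continuous differentiation trajectories
#'
#' Cells are placed along the branches of the configured Newick tree and
#' their heterogeneous embeddings evolve by Brownian motion from a common
#' root; branch and pseudotime ground truths are emitted per cell.
#'
#' @inheritParams simulate_discrete
#' @param config A [cas_config()] with `mode = "continuous"`.
#' @return A [count_matrix()] with `branch` and `pseudotime` columns.
#' @export
simulate_continuous <- function(models, config) {
  sm <- as_stat_models(models)
  stopifnot(config$mode == "continuous")
  seed <- config$seed
  n_homo <- config$nembed - config$nhete
  placement <- place_cells_on_tree(config$tree, config$ncell)
  cem <- with_stream(seed, "cem", {
    hete <- generate_continuous_cem(placement, config$nhete, config$sigma)
    homo <- generate_homogeneous_cem(n_homo, config$ncell, config$sigma)
    list(C = assemble_cem(homo, hete$C_hete), branch = hete$branch,
         pseudotime = hete$pseudotime)
  })
  P <- with_stream(seed, "pem", generate_pem(config$npeak, config$nembed,
                                             config$eta))
  hub_truth <- NULL
  if (length(config$hubs)) {
    hb <- with_stream(seed, "hubs",
      inject_interaction_hubs(P, config$hubs, config$eta))
    P <- hb$P; hub_truth <- hb$peak_truth
  }
  l <- with_stream(seed, "cev", generate_cev(config$nembed))
  targets <- with_stream(seed, "targets",
    .align_targets(sample_targets(sm$models$global, config$ncell,
                                  config$npeak)))
  fin <- .lambda_pipeline(P, cem$C, l, targets, config)
  cells <- data.frame(barcode = sprintf("cell_%d", seq_len(config$ncell)),
                      branch = cem$branch, pseudotime = cem$pseudotime)
  out <- with_stream(seed, "counts",
    .sample_counts(fin, config, peaks = .hub_peaks_df(config$npeak, hub_truth),
                   cells = cells))
  attr(out, "lib_targets") <- attr(fin, "lib_targets")
  attr(out, "sparsity_targets") <- attr(fin, "sparsity_targets")
  attr(out, "peak_targets") <- targets$peak
  out
}

#' Simulate pseudo-real cell types
#'
#' For each reference cell type: a homogeneous-only CEM (all `nembed`
#' dimensions), PEM and CEV are generated, correction targets are drawn
#' from that type's fitted models (GMMs for the cell statistics, a discrete
#' family for peak summation), and counts are sampled; the per-type
#' matrices are column-concatenated with `cell_type` labels.
#'
#' @inheritParams simulate_discrete
#' @param config A [cas_config()] with `mode = "pseudo_cell_type"`.
#' @param type_counts Named integer vector of output cells per type;
#'   defaults to the reference's type sizes stored in the fit.
#' @return A [count_matrix()] with a `cell_type` column.
#' @export
simulate_pseudo <- function(models, config, type_counts = NULL) {
  sm <- as_stat_models(models)
  stopifnot(config$mode == "pseudo_cell_type")
  if (sm$backend == "kde")
    stop("pseudo_cell_type mode requires per-type models", call. = FALSE)
  if (is.null(type_counts)) {
    if (inherits(models, "cas_fit")) type_counts <- models$type_counts
    else stop("type_counts required when passing bare stat_models",
              call. = FALSE)
  }
  seed <- config$seed
  parts <- list()
  for (ty in names(sm$models)) {
    n_ty <- type_counts[[ty]]
    C <- with_stream(seed, paste0("cem:", ty),
      generate_homogeneous_cem(config$nembed, n_ty, config$sigma))
    P <- with_stream(seed, paste0("pem:", ty),
      generate_pem(config$npeak, config$nembed, config$eta))
    l <- with_stream(seed, paste0("cev:", ty), generate_cev(config$nembed))
    targets <- with_stream(seed, paste0("targets:", ty),
      .align_targets(sample_targets(sm$models[[ty]], n_ty, config$npeak)))
    fin <- .lambda_pipeline(P, C, l, targets, config)
    cm <- with_stream(seed, paste0("counts:", ty),
      .sample_counts(fin, config,
                     cells = data.frame(barcode = sprintf("%s_cell_%d", ty,
                                                          seq_len(n_ty)),
                                        cell_type = ty)))
    parts[[ty]] <- cm
  }
  counts <- do.call(cbind, lapply(parts, function(p) p$counts))
  cells <- do.call(rbind, lapply(parts, function(p) p$cells))
  rownames(cells) <- NULL
  count_matrix(counts, peaks = parts[[1]]$peaks, cells = cells,
               binarized = config$count_model == "bernoulli")
}

#' Simulate a multi-batch dataset
#'
#' Population centers, the base PEM and the CEV are shared across batches;
#' each batch generates fresh cells, applies its own biological (PEM) or
#' technical (mean-matrix) Gaussian noise, samples counts, and the batch
#' matrices are column-concatenated with batch and population labels. A
#' batch's `pop_sizes` override supports batch-specific missing
#' populations.
#'
#' @inheritParams simulate_discrete
#' @param config A [cas_config()] with `mode = "discrete"` and >= 2 entries
#'   in `batches`.
#' @return A [count_matrix()] with `population` and `batch` columns.
#' @export
simulate_batches <- function(models, config) {
  sm <- as_stat_models(models)
  stopifnot(config$mode == "discrete")
  if (length(config$batches) < 2)
    stop("need >= 2 batch specs", call. = FALSE)
  seed <- config$seed
  n_homo <- config$nembed - config$nhete
  npop <- ncol(config$covariance)
  H <- with_stream(seed, "centers",
    generate_discrete_centers(npop, config$nhete, config$covariance))
  P0 <- with_stream(seed, "pem", generate_pem(config$npeak, config$nembed,
                                              config$eta))
  l <- with_stream(seed, "cev", generate_cev(config$nembed))
  parts <- list()
  for (b in config$batches) {
    stopifnot(inherits(b, "batch_spec"))
    id <- b$batch_id
    sizes <- if (!is.null(b$pop_sizes)) b$pop_sizes else config$pop_sizes
    present <- which(sizes > 0)
    nc <- sum(sizes)
    cem <- with_stream(seed, paste0("cem:", id), {
      hete <- generate_discrete_cem(H[, present, drop = FALSE], sizes[present],
                                    config$sigma)
      homo <- generate_homogeneous_cem(n_homo, nc, config$sigma)
      pops <- rep(sprintf("pop_%d", present), sizes[present])
      list(C = assemble_cem(homo, hete$C_hete), population = pops)
    })
    P <- if (b$kind == "biological")
      with_stream(seed, paste0("noise:", id), add_biological_batch(P0, b))
    else P0
    targets <- with_stream(seed, paste0("targets:", id),
      .align_targets(sample_targets(sm$models$global, nc, config$npeak)))
    fin <- .lambda_pipeline(P, cem$C, l, targets, config)
    if (b$kind == "technical")
      fin <- with_stream(seed, paste0("noise:", id),
                         add_technical_batch(fin, b))
    cm <- with_stream(seed, paste0("counts:", id),
      .sample_counts(fin, config,
                     cells = data.frame(barcode = sprintf("%s_cell_%d", id,
                                                          seq_len(nc)),
                                        population = cem$population,
                                        batch = id)))
    parts[[id]] <- cm
  }
  counts <- do.call(cbind, lapply(parts, function(p) p$counts))
  cells <- do.call(rbind, lapply(parts, function(p) p$cells))
  rownames(cells) <- NULL
  count_matrix(counts, peaks = parts[[1]]$peaks, cells = cells,
               binarized = config$count_model == "bernoulli")
}

#' Generate a self-contained reference fixture
#'
#' Builds a small reference matrix with known, recoverable structure:
#' per-type Gamma-distributed peak programs (long-tailed peak summations),
#' a two-mode lognormal library-size distribution (so the two-component
#' GMM fit is identifiable), and Poisson counts. It stands in for a real
#' reference dataset in examples and tests.
#'
#' @param npeak,ncell Fixture dimensions (default 2000 x 500).
#' @param n_types Number of cell types (default 2).
#' @param seed Integer seed.
#' @param lib_meanlog Two log-scale library modes (default `log(1000)` and
#'   `log(4000)`).
#' @param lib_sdlog Within-mode log-scale sd (default 0.25).
#' @return A [count_matrix()] with a `cell_type` column.
#' @export
make_fixture <- function(npeak = 2000, ncell = 500, n_types = 2, seed = 1,
                         lib_meanlog = log(c(1000, 4000)), lib_sdlog = 0.25) {
  set.seed(substream_seed(seed, "fixture"))
  base_rate <- stats::rgamma(npeak, shape = 0.5, rate = 1)
  types <- rep(sprintf("type_%d", seq_len(n_types)), length.out = ncell)
  types <- sort(types)
  rate_by_type <- sapply(seq_len(n_types), function(t) {
    r <- base_rate
    program <- sample.int(npeak, round(0.2 * npeak))
    r[program] <- r[program] * exp(stats::rnorm(length(program), 1, 0.5))
    r / sum(r)
  })
  comp <- sample.int(2L, ncell, replace = TRUE)
  lib <- exp(stats::rnorm(ncell, lib_meanlog[comp], lib_sdlog))
  lam <- rate_by_type[, as.integer(factor(types)), drop = FALSE] *
    matrix(lib, npeak, ncell, byrow = TRUE)
  x <- matrix(stats::rpois(npeak * ncell, lam), npeak, ncell)
  count_matrix(x, cells = data.frame(barcode = sprintf("cell_%d", seq_len(ncell)),
                                     cell_type = types))
}
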