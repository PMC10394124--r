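#' Batch-effect and interaction-hub specifications
#'
#' Batch effects come in two flavours: biological batches perturb the PEM
#' (so peak-level programs shift while populations stay aligned), technical
#' batches perturb the final Poisson mean matrix. Interaction hubs remodel
#' the PEM rows of designated "interactive" peaks towards a shared effect
#' vector, creating ground-truth co-accessibility.
#'
#' @param batch_id Unique batch label.
#' @param kind `"biological"` (noise on the PEM) or `"technical"` (noise on
#'   the mean parameter matrix).
#' @param noise_mean,noise_sd Gaussian noise parameters (`noise_sd >= 0`).
#' @param pop_sizes Optional per-batch population-size override (enables
#'   batch-specific missing populations).
#' @return A `batch_spec` list.
#' @export
batch_spec <- function(batch_id, kind = c("biological", "technical"),
                       noise_mean = 0, noise_sd = 0, pop_sizes = NULL) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(batch_id = batch_id, kind = kind, noise_mean = noise_mean,
                 noise_sd = noise_sd, pop_sizes = pop_sizes),
            class = "batch_spec")
}

#' @param hub_id Unique hub label.
#' @param peak_indices Indices (into the peak table) of all peaks in the
#'   hub.
#' @param interactive_indices Subset of `peak_indices` flagged interactive.
#' @param effect_sd Within-hub deviation scale around the shared effect
#'   vector (> 0; smaller means tighter co-accessibility).
#' @return A `hub_spec` list.
#' @rdname batch_spec
#' @export
hub_spec <- function(hub_id, peak_indices, interactive_indices,
                     effect_sd = 0.1) {
  if (!all(interactive_indices %in% peak_indices))
    stop("interactive_indices must be a subset of peak_indices", call. = FALSE)
  if (effect_sd <= 0) stop("effect_sd must be > 0", call. = FALSE)
  structure(list(hub_id = hub_id, peak_indices = as.integer(peak_indices),
                 interactive_indices = as.integer(interactive_indices),
                 effect_sd = effect_sd),
            class = "hub_spec")
}

#' Biological batch effect: Gaussian noise on the PEM
#'
#' @param P PEM matrix.
#' @param spec A `batch_spec` with `kind = "biological"`.
#' @return The perturbed PEM.
#' @export
add_biological_batch <- function(P, spec) {
  stopifnot(inherits(spec, "batch_spec"))
  if (spec$kind != "biological")
    stop("spec kind must be 'biological'", call. = FALSE)
  if (spec$noise_sd == 0 && spec$noise_mean == 0) return(P)
  P + matrix(stats::rnorm(length(P), spec$noise_mean, spec$noise_sd),
             nrow(P), ncol(P))
}

#' Technical batch effect: Gaussian noise on the mean parameter matrix
#'
#' Noise is added to the final-stage matrix and clamped at zero so the
#' Poisson means stay valid; the number of clamped entries is recorded in
#' attribute `n_clamped`.
#'
#' @param m A `param_matrix` at stage `"final"`.
#' @param spec A `batch_spec` with `kind = "technical"`.
#' @return A `param_matrix` at stage `"final"`.
#' @export
add_technical_batch <- function(m, spec) {
  stopifnot(inherits(m, "param_matrix"), inherits(spec, "batch_spec"))
  if (spec$kind != "technical")
    stop("spec kind must be 'technical'", call. = FALSE)
  if (spec$noise_sd == 0 && spec$noise_mean == 0) return(m)
  v <- m$values + matrix(stats::rnorm(length(m$values), spec$noise_mean,
                                      spec$noise_sd),
                         nrow(m$values), ncol(m$values))
  n_clamped <- sum(v < 0)
  v[v < 0] <- 0
  out <- param_matrix(v, "final")
  attributes(out)[setdiff(names(attributes(m)), c("names", "class"))] <-
    attributes(m)[setdiff(names(attributes(m)), c("names", "class"))]
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Remodel the PEM to encode cis-regulatory interaction hubs
#'
#' For each hub one shared effect vector is drawn exactly as a PEM row
#' (standard normal entries, zeroed with probability `eta`); every
#' interactive peak's PEM row is replaced by that vector plus independent
#' Normal(0, `effect_sd^2`) deviations, making interactive peaks of a hub
#' co-accessible. Non-interactive hub peaks and all other peaks are
#' untouched.
#'
#' @param P PEM matrix.
#' @param hubs List of [hub_spec()]s with pairwise-disjoint peak sets.
#' @param eta Zeroing probability used for the shared effect vectors.
#' @return A list with `P` (remodeled PEM) and `peak_truth`, a data.frame
#'   (`peak_index`, `hub_id`, `interactive`) covering all hub peaks.
#' @export
inject_interaction_hubs <- function(P, hubs, eta = 0.5) {
  if (inherits(hubs, "hub_spec")) hubs <- list(hubs)
  all_idx <- unlist(lapply(hubs, `[[`, "peak_indices"))
  if (anyDuplicated(all_idx)) stop("hubs must be pairwise disjoint", call. = FALSE)
  if (any(all_idx < 1 | all_idx > nrow(P)))
    stop("hub peak indices out of range", call. = FALSE)
  truth <- list()
  for (h in hubs) {
    w <- stats::rnorm(ncol(P))
    w[stats::runif(ncol(P)) < eta] <- 0
    ii <- h$interactive_indices
    P[ii, ] <- matrix(w, length(ii), ncol(P), byrow = TRUE) +
      matrix(stats::rnorm(length(ii) * ncol(P), 0, h$effect_sd),
             length(ii), ncol(P))
    truth[[h$hub_id]] <- data.frame(peak_index = h$peak_indices,
                                    hub_id = h$hub_id,
                                    interactive = h$peak_indices %in% ii)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(P = P, peak_truth = truth)
}

#' Build genomic peak hubs from gene annotations
#'
#' Convenience helper mirroring the benchmark recipe: gene regions are
#' extended by `flank` bp on both sides, hubs with fewer than `min_peaks`
#' overlapping peaks or overlapping another hub are dropped, and
#' `n_interactive` peaks per hub are chosen at random as interactive.
#'
#' @param peaks BED-style peak table (`chrom`, `start`, `end`).
#' @param genes Data.frame (`chrom`, `start`, `end`, `gene`).
#' @param flank Extension in bp (default 50000).
#' @param min_peaks Minimum peaks per hub (default 50).
#' @param n_interactive Interactive peaks per hub (default 40).
#' @param effect_sd Passed to [hub_spec()].
#' @return A list of [hub_spec()]s.
#' @export
hubs_from_genes <- function(peaks, genes, flank = 50000, min_peaks = 50,
                            n_interactive = 40, effect_sd = 0.1) {
  regions <- data.frame(chrom = genes$chrom,
                        start = pmax(genes$start - flank, 0),
                        end = genes$end + flank, gene = genes$gene)
  keep <- rep(TRUE, nrow(regions))
  for (i in seq_len(nrow(regions))) {       # drop hubs overlapping another hub
    ov <- regions$chrom == regions$chrom[i] &
      regions$start < regions$end[i] & regions$end > regions$start[i]
    if (sum(ov) > 1) keep[i] <- FALSE
  }
  regions <- regions[keep, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(regions))) {
    idx <- which(peaks$chrom == regions$chrom[i] &
                   peaks$start < regions$end[i] & peaks$end > regions$start[i])
    if (length(idx) < min_peaks) next
    inter <- sort(sample(idx, min(n_interactive, length(idx))))
    out[[length(out) + 1L]] <- hub_spec(regions$gene[i], idx, inter, effect_sd)
  }
  out
}
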