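#' Parameter-matrix pipeline: activation, correction, count sampling
#'
#' The raw parameter matrix is the PEM-CEM product and contains negative
#' entries; an elementwise activation makes it positive, a peak-wise
#' correction matches row sums to sampled peak-summation targets, and a
#' cell-wise correction shapes each column so its expected non-zero
#' proportion and its sum match sampled sparsity and library-size targets.
#' Poisson (or Bernoulli) draws from the final matrix give the counts.
#'
#' @name correction
NULL

param_matrix <- function(values, stage) {
  stopifnot(is.matrix(values))
  structure(list(values = values, stage = stage), class = "param_matrix")
}

#' @export
print.param_matrix <- function(x, ...) {
  cat(sprintf("param_matrix (%s): %d x %d\n", x$stage, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Raw parameter matrix from the embeddings
#'
#' @param P PEM, `npeak` x `nembed`.
#' @param C CEM, `nembed` x `ncell`.
#' @return A `param_matrix` at stage `"raw"`, shape `npeak` x `ncell`.
#' @export
raw_param_matrix <- function(P, C) {
  if (ncol(P) != nrow(C))
    stop(sprintf("shape mismatch: P is %dx%d but C is %dx%d",
                 nrow(P), ncol(P), nrow(C), ncol(C)), call. = FALSE)
  param_matrix(P %*% C, "raw")
}

#' Elementwise activation of the raw parameter matrix
#'
#' `softplus` maps x to log(1 + exp(x)) (the default for all modes);
#' `exponential` maps x to exp(x), amplifying embedding differences (used
#' e.g. in batch-effect recipes). The exponential's argument is clipped at
#' `max_exponent` to guard against overflow; the number of clipped entries
#' is recorded in attribute `n_clipped`.
#'
#' @param m A `param_matrix` at stage `"raw"`.
#' @param kind `"softplus"` or `"exponential"`.
#' @param max_exponent Clip point for the exponential (default 30).
#' @return A strictly positive `param_matrix` at stage `"activated"`.
#' @export
activate <- function(m, kind = c("softplus", "exponential"), max_exponent = 30) {
  kind <- match.arg(kind)
  x <- m$values
  n_clipped <- 0L
  if (kind == "softplus") {
    # log1p(exp(x)) computed stably: x + log1p(exp(-x)) for large x
    v <- ifelse(x > 30, x + log1p(exp(-x)), log1p(exp(x)))
  } else {
    n_clipped <- sum(x > max_exponent)
    if (n_clipped > 0)
      warning(sprintf("exponential activation clipped %d entries", n_clipped))
    v <- exp(pmin(x, max_exponent))
  }
  out <- param_matrix(v, "activated")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Peak-wise correction: match row sums to peak-summation targets
#'
#' Targets are rank-matched to the activated row sums (the row with the
#' r-th largest sum receives the r-th largest target) and each row is
#' rescaled to its matched target, so within-row proportions and the
#' ordering of row sums are preserved exactly. Rows with zero raw sum (not
#' reachable through the provided activations, but handled for safety)
#' receive their matched target spread uniformly across cells.
#'
#' @param m A `param_matrix` at stage `"activated"`.
#' @param peak_targets Non-negative vector of length `npeak`.
#' @return A `param_matrix` at stage `"peak_corrected"`.
#' @export
correct_peakwise <- function(m, peak_targets) {
  stopifnot(m$stage == "activated")
  if (length(peak_targets) != nrow(m$values))
    stop("peak_targets length must equal npeak", call. = FALSE)
  if (any(peak_targets < 0)) stop("peak_targets must be >= 0", call. = FALSE)
  rs <- rowSums(m$values)
  matched <- numeric(length(rs))
  matched[order(rs, decreasing = TRUE)] <- sort(peak_targets, decreasing = TRUE)
  scale <- ifelse(rs > 0, matched / rs, 0)
  v <- m$values * scale
  zero <- which(rs == 0)
  if (length(zero)) v[zero, ] <- matched[zero] / ncol(v)
  param_matrix(v, "peak_corrected")
}

# expected non-zero proportion of a Poisson column with mean vector w
.expected_nonzero <- function(w) mean(-expm1(-w))

#' Cell-wise correction: match library sizes and non-zero proportions
#'
#' Library-size targets are rank-matched to the CEV scores `s_j = l . C_j`
#' (a cell with a larger score gets a larger library-size target); sparsity
#' targets are rank-matched alongside. Each column is then shaped by a
#' power transform `lambda -> lambda^gamma` (order-preserving within the
#' cell), with `gamma` solved by bisection so that the column's expected
#' Poisson non-zero proportion matches its sparsity target after the column
#' is renormalized to its library target. Unattainable sparsity targets are
#' clamped to the nearest attainable value (the affected cells are counted
#' in attribute `clamped_cells`, with a warning).
#'
#' @param m A `param_matrix` at stage `"peak_corrected"` (or `"activated"`).
#' @param lib_targets Positive vector of length `ncell`.
#' @param sparsity_targets Vector in (0, 1\] of length `ncell`.
#' @param cev_scores CEV scores, length `ncell`.
#' @param tol Tolerance on the achieved non-zero proportion (default 1e-3).
#' @param gamma_range Bisection interval for the exponent.
#' @return A `param_matrix` at stage `"final"`; column sums equal the
#'   matched library targets to relative error 1e-9. Attributes:
#'   `lib_targets`, `sparsity_targets` (both in cell order, as matched),
#'   `gamma`, `clamped_cells`.
#' @export
correct_cellwise <- function(m, lib_targets, sparsity_targets, cev_scores,
                             tol = 1e-3, gamma_range = c(0.05, 20)) {
  stopifnot(m$stage %in% c("peak_corrected", "activated"))
  v <- m$values
  ncell <- ncol(v)
  if (length(lib_targets) != ncell || length(sparsity_targets) != ncell ||
      length(cev_scores) != ncell)
    stop("target vectors must have length ncell", call. = FALSE)
  if (any(lib_targets <= 0)) stop("lib_targets must be > 0", call. = FALSE)
  # rank-match both target vectors to the CEV scores
  ord <- order(cev_scores)
  lib <- spars <- numeric(ncell)
  lib[ord] <- sort(lib_targets)
  spars[ord] <- sort(sparsity_targets)
  gam <- numeric(ncell)
  clamped <- integer(0)
  for (j in seq_len(ncell)) {
    col <- v[, j]
    L <- lib[j]
    shape <- function(g) {
      w <- col^g
      w * (L / sum(w))
    }
    f <- function(g) .expected_nonzero(shape(g))
    lo <- gamma_range[1]; hi <- gamma_range[2]
    f_lo <- f(lo); f_hi <- f(hi)   # f is decreasing in gamma
    target <- spars[j]
    if (abs(f_lo - target) <= tol) g <- lo
    else if (abs(f_hi - target) <= tol) g <- hi
    else if (target > f_lo) { g <- lo; clamped <- c(clamped, j) }
    else if (target < f_hi) { g <- hi; clamped <- c(clamped, j) }
    else {
      g <- stats::uniroot(function(x) f(x) - target, c(lo, hi),
                          tol = 1e-4)$root
      if (abs(f(g) - target) > tol)
        g <- stats::uniroot(function(x) f(x) - target, c(lo, hi),
                            tol = 1e-8)$root
    }
    gam[j] <- g
    w <- shape(g)
    v[, j] <- w * (L / sum(w))  # exact renormalization
  }
  if (length(clamped))
    warning(sprintf("sparsity target unattainable for %d cell(s) (e.g. cell %d); clamped",
                    length(clamped), clamped[1]))
  out <- param_matrix(v, "final")
  attr(out, "lib_targets") <- lib
  attr(out, "sparsity_targets") <- spars
  attr(out, "gamma") <- gam
  attr(out, "clamped_cells") <- clamped
  out
}

#' Sample synthetic counts from the final parameter matrix
#'
#' Independent Poisson draws with the corresponding mean parameter per
#' entry.
#'
#' @param m A `param_matrix` at stage `"final"`.
#' @param peaks,cells Optional metadata tables passed to [count_matrix()].
#' @return A [count_matrix()].
#' @export
sample_counts_poisson <- function(m, peaks = NULL, cells = NULL) {
  stopifnot(m$stage == "final")
  if (any(!is.finite(m$values))) stop("non-finite Poisson means", call. = FALSE)
  x <- matrix(stats::rpois(length(m$values), m$values),
              nrow(m$values), ncol(m$values))
  count_matrix(x, peaks = peaks, cells = cells, binarized = FALSE)
}

#' Sample a binarized matrix under the Bernoulli framework
#'
#' Entry (i, j) is 1 with probability `1 - exp(-lambda_ij)` — the Poisson
#' probability of a non-zero count — matching the binarized-data adaptation
#' of the framework.
#'
#' @inheritParams sample_counts_poisson
#' @return A binarized [count_matrix()].
#' @export
sample_counts_bernoulli <- function(m, peaks = NULL, cells = NULL) {
  stopifnot(m$stage == "final")
  if (any(!is.finite(m$values))) stop("non-finite parameters", call. = FALSE)
  pr <- -expm1(-m$values)
  x <- matrix(stats::rbinom(length(pr), 1L, pr), nrow(pr), ncol(pr))
  count_matrix(x, peaks = peaks, cells = cells, binarized = TRUE)
}
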