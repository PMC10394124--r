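#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximal absolute difference between the two empirical CDFs.
#'
#' @param x,y Numeric samples.
#' @return The KS statistic in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

#' Quantile-based comparison of a statistic between two datasets
#'
#' Computes `n_quantiles` evenly spaced sample quantiles of each sample
#' (library size is natural-log-transformed first) and measures their
#' disagreement by MAD (median absolute deviation of paired quantiles), MAE,
#' RMSE, 1 - PCC, the Jensen-Shannon divergence of histogram densities on a
#' shared 100-bin grid (natural log base, 1e-12 floor), and the two-sample
#' KS statistic of the samples themselves. All six metrics are 0 when the
#' samples are identical.
#'
#' @param real_values,synth_values Non-empty numeric samples.
#' @param statistic Name of the statistic; `"library_size"` triggers the
#'   log transform. Conventional values: `"peak_mean"`, `"library_size"`,
#'   `"sparsity"`.
#' @param n_quantiles Number of quantiles (>= 2); 1000 for peak-level and
#'   100 for cell-level statistics in the benchmark recipes.
#' @return A list of class `quantile_comparison` with the metric map.
#' @export
quantile_compare <- function(real_values, synth_values,
                             statistic = "generic", n_quantiles = 100) {
  if (n_quantiles < 2) stop("n_quantiles must be >= 2", call. = FALSE)
  if (!length(real_values) || !length(synth_values))
    stop("samples must be non-empty", call. = FALSE)
  r <- real_values; s <- synth_values
  if (statistic == "library_size") { r <- log(r); s <- log(s) }
  probs <- seq(0, 1, length.out = n_quantiles)
  qr <- stats::quantile(r, probs, names = FALSE)
  qs <- stats::quantile(s, probs, names = FALSE)
  d <- qs - qr
  pcc_term <- if (stats::sd(qr) > 0 && stats::sd(qs) > 0)
    1 - stats::cor(qr, qs) else if (isTRUE(all.equal(qr, qs))) 0 else 1
  rng <- range(c(r, s))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = 101)
  p <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), 100) / length(r)
  q <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), 100) / length(s)
  p <- pmax(p, 1e-12); q <- pmax(q, 1e-12)
  p <- p / sum(p); q <- q / sum(q)
  mm <- (p + q) / 2
  jsd <- 0.5 * sum(p * log(p / mm)) + 0.5 * sum(q * log(q / mm))
  structure(list(statistic = statistic, n_quantiles = n_quantiles,
                 metrics = c(MAD = stats::median(abs(d)), MAE = mean(abs(d)),
                             RMSE = sqrt(mean(d^2)), one_minus_PCC = pcc_term,
                             JSD = max(jsd, 0), KSS = ks_statistic(r, s))),
            class = "quantile_comparison")
}

#' @export
print.quantile_comparison <- function(x, ...) {
  cat(sprintf("quantile comparison of %s (%d quantiles):\n", x$statistic,
              x$n_quantiles))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Peak-peak Spearman correlations of highly accessible peaks
#'
#' Selects the `top_k` peaks with the highest total accessibility in the
#' real matrix, keeps the same peaks in the synthetic matrix, and computes
#' Spearman correlations for all peak pairs in both matrices (pairs are
#' subsampled above `max_pairs`).
#'
#' @param real,synth [count_matrix()]s over the same peak space.
#' @param top_k Number of top peaks (default 2000; clamped to npeak).
#' @param max_pairs Cap on the number of pairs returned (default 1e6).
#' @return A list with numeric vectors `real` and `synth` of matched pair
#'   correlations.
#' @export
peak_pair_correlation <- function(real, synth, top_k = 2000, max_pairs = 1e6) {
  stopifnot(inherits(real, "count_matrix"), inherits(synth, "count_matrix"))
  if (nrow(real$counts) != nrow(synth$counts))
    stop("matrices must share the peak space", call. = FALSE)
  if (top_k > nrow(real$counts)) {
    warning("top_k exceeds npeak; clamped")
    top_k <- nrow(real$counts)
  }
  top <- order(Matrix::rowSums(real$counts), decreasing = TRUE)[seq_len(top_k)]
  cr <- suppressWarnings(stats::cor(t(as.matrix(real$counts[top, , drop = FALSE])),
                                    method = "spearman"))
  cs <- suppressWarnings(stats::cor(t(as.matrix(synth$counts[top, , drop = FALSE])),
                                    method = "spearman"))
  ut <- which(upper.tri(cr))
  if (length(ut) > max_pairs) ut <- sample(ut, max_pairs)
  list(real = cr[ut], synth = cs[ut])
}

#' TF-IDF + truncated SVD (LSI) embedding of a peak-by-cell matrix
#'
#' The standard scATAC-seq reduction: the matrix is binarized, term
#' frequencies are scaled by inverse document frequency, log-scaled, and
#' reduced by truncated SVD; cell embeddings are the scaled right singular
#' vectors.
#'
#' @param counts Matrix or sparse Matrix (peaks x cells), or a
#'   [count_matrix()].
#' @param n_dims Number of components (default 30).
#' @param scale_embeddings Standardize each component to zero mean and unit
#'   variance (default `FALSE`, keeping the singular-value scaling used for
#'   clustering; [milisi()] standardizes so that no single depth-driven
#'   component dominates its neighborhood distances).
#' @return An `ncell` x `n_dims` matrix of cell embeddings.
#' @export
lsi_embed <- function(counts, n_dims = 30, scale_embeddings = FALSE) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  b <- methods::as(counts > 0, "dMatrix")
  cs <- Matrix::colSums(b); cs[cs == 0] <- 1
  tf <- b %*% Matrix::Diagonal(x = 1 / cs)
  idf <- log(1 + ncol(b) / (1 + Matrix::rowSums(b)))
  x <- log1p(Matrix::Diagonal(x = idf) %*% tf * 1e4)
  x <- as.matrix(x)
  n_dims <- min(n_dims, ncol(x) - 1L)
  cp <- crossprod(x)                      # ncell x ncell
  eig <- eigen(cp, symmetric = TRUE)
  d <- sqrt(pmax(eig$values[seq_len(n_dims)], 0))
  emb <- eig$vectors[, seq_len(n_dims), drop = FALSE] %*% diag(d, n_dims)
  if (scale_embeddings) {
    sds <- apply(emb, 2, stats::sd)
    sds[sds == 0] <- 1
    emb <- scale(emb, scale = sds)
    attr(emb, "scaled:center") <- attr(emb, "scaled:scale") <- NULL
  }
  rownames(emb) <- colnames(counts)
  emb
}

# per-cell local inverse Simpson's index over a binary (or k-ary) label,
# with perplexity-calibrated Gaussian neighborhood weights
lisi_scores <- function(emb, labels, perplexity = 30) {
  n <- nrow(emb)
  k <- min(3L * perplexity, n - 1L)
  if (n < 3 * perplexity)
    stop("need at least 3 * perplexity cells", call. = FALSE)
  d2 <- as.matrix(stats::dist(emb))^2
  labels <- as.integer(factor(labels))
  nlab <- max(labels)
  out <- numeric(n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    # exact duplicates of cell i (distance 0, the cell itself included) are
    # informationally the cell itself and are excluded from its neighborhood
    tol0 <- 1e-10 * max(d2[i, ])
    cand <- setdiff(order(d2[i, ]), which(d2[i, ] <= tol0))
    nb <- cand[seq_len(min(k, length(cand)))]
    if (!length(nb)) { out[i] <- 1; next }
    di <- d2[i, nb]
    if (max(di) == 0) {
      w <- rep(1 / length(nb), length(nb)) # all ties: uniform neighborhood
    } else {
      beta <- 1; lo <- -Inf; hi <- Inf
      for (iter in 1:50) {                 # t-SNE style entropy calibration
        w <- exp(-di * beta)
        sw <- sum(w)
        if (sw == 0) { H <- 0; w <- rep(1 / length(nb), length(nb)) }
        else {
          H <- log(sw) + beta * sum(di * w) / sw
          w <- w / sw
        }
        if (abs(H - logU) < 1e-5) break
        if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
        else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
      }
    }
    pb <- vapply(seq_len(nlab), function(b) sum(w[labels[nb] == b]), numeric(1))
    out[i] <- 1 / sum(pb^2)
  }
  out
}

#' Median integration LISI between real and synthetic cells
#'
#' The two matrices are embedded jointly (TF-IDF + truncated SVD on the
#' column-concatenated matrix) and the local inverse Simpson's index of the
#' real/synthetic label is computed per cell with perplexity-calibrated
#' Gaussian neighborhood weights over `3 * perplexity` nearest neighbors.
#' The median is ~2 for perfectly mixed datasets and ~1 for fully separated
#' ones.
#'
#' @param real,synth [count_matrix()]s over the same peak space.
#' @param n_dims Embedding dimensions (default 30).
#' @param perplexity Neighborhood size parameter (default 30).
#' @return The median LISI, a number in \[1, 2\].
#' @export
milisi <- function(real, synth, n_dims = 30, perplexity = 30) {
  stopifnot(inherits(real, "count_matrix"), inherits(synth, "count_matrix"))
  if (nrow(real$counts) != nrow(synth$counts))
    stop("matrices must share the peak space", call. = FALSE)
  joint <- cbind(real$counts, synth$counts)
  labels <- rep(c("real", "synthetic"), c(ncol(real$counts), ncol(synth$counts)))
  emb <- lsi_embed(joint, n_dims, scale_embeddings = TRUE)
  stats::median(lisi_scores(emb, labels, perplexity))
}

# ---- partition agreement ----------------------------------------------------

entropy_counts <- function(a) {
  p <- a[a > 0] / sum(a)
  -sum(p * log(p))
}

# expected mutual information under the permutation model (hypergeometric)
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1L, ai + bj - n); hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
    emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (ai * bj)))
  }
  emi
}

#' Partition agreement scores: AMI, ARI and homogeneity
#'
#' Adjusted mutual information (arithmetic-mean normalization), adjusted
#' Rand index (pair-counting with hypergeometric chance correction) and the
#' homogeneity score `1 - H(truth | pred) / H(truth)`. All equal 1 for
#' identical partitions (up to relabeling); ARI and AMI are ~0 in
#' expectation for random labelings.
#'
#' @param truth_labels,pred_labels Equal-length label vectors.
#' @return Named numeric vector `c(AMI, ARI, Homo)`.
#' @export
clustering_scores <- function(truth_labels, pred_labels) {
  if (length(truth_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(truth_labels)
  tab <- table(truth_labels, pred_labels)
  a <- rowSums(tab); b <- colSums(tab)
  # ARI
  sum_nij <- sum(choose(tab, 2)); sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_nij - expected) / denom
  # MI / AMI
  hu <- entropy_counts(a); hv <- entropy_counts(b)
  nz <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[nz]
  mi <- sum((nij / n) * log(n * nij / (a[nz[, 1]] * b[nz[, 2]])))
  emi <- expected_mi(as.numeric(a), as.numeric(b), n)
  denom_ami <- (hu + hv) / 2 - emi
  ami <- if (abs(denom_ami) < 1e-12) 1 else (mi - emi) / denom_ami
  # homogeneity
  homo <- if (hu == 0) 1 else mi / hu
  c(AMI = ami, ARI = ari, Homo = min(homo, 1))
}

#' Best F1 score per interaction hub
#'
#' Within each hub's peak universe, interactive peaks are positives and the
#' remaining hub peaks negatives; each predicted peak set is restricted to
#' the hub and scored by F1 against the positives, and the best score over
#' all predicted sets is reported per hub.
#'
#' @param truth Data.frame (`peak_index`, `hub_id`, `interactive`) as
#'   emitted by [inject_interaction_hubs()], or a list of [hub_spec()]s.
#' @param predicted_sets List of integer vectors of predicted peak indices
#'   (e.g. CCANs from a co-accessibility method).
#' @return Named numeric vector: best F1 per hub.
#' @export
interaction_f1 <- function(truth, predicted_sets) {
  if (!is.data.frame(truth)) {
    truth <- do.call(rbind, lapply(truth, function(h)
      data.frame(peak_index = h$peak_indices, hub_id = h$hub_id,
                 interactive = h$peak_indices %in% h$interactive_indices)))
  }
  if (!length(predicted_sets)) {
    warning("empty prediction list; F1 = 0")
    predicted_sets <- list(integer(0))
  }
  hubs <- unique(truth$hub_id)
  out <- stats::setNames(numeric(length(hubs)), hubs)
  for (h in hubs) {
    universe <- truth$peak_index[truth$hub_id == h]
    pos <- truth$peak_index[truth$hub_id == h & truth$interactive]
    best <- 0
    for (pr in predicted_sets) {
      pr <- intersect(pr, universe)
      tp <- length(intersect(pr, pos))
      if (tp == 0) next
      prec <- tp / length(pr); rec <- tp / length(pos)
      best <- max(best, 2 * prec * rec / (prec + rec))
    }
    out[h] <- best
  }
  out
}
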