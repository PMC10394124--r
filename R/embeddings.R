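#' Generators for the latent embeddings behind a simulation
#'
#' Synthetic counts are driven by three latent objects: a cell embedding
#' matrix (CEM) `C`, split into a homogeneous block shared by all cells and a
#' heterogeneous block carrying cell-state structure; a peak-wise effect
#' matrix (PEM) `P` mapping embeddings to peak propensities; and a cell-wise
#' effect vector (CEV) `l` whose projection onto each cell's embedding ranks
#' cells by intended library size. All generators draw from the current R
#' RNG stream, so wrapping them in `set.seed()` makes them reproducible.
#'
#' @name embeddings
NULL

#' Homogeneous cell embedding block
#'
#' Entries are i.i.d. Normal with unit mean and standard deviation `sigma`;
#' `sigma` controls overall data dispersion and is shared with the
#' heterogeneous block.
#'
#' @param n_homo Number of homogeneous embedding dimensions.
#' @param ncell Number of cells.
#' @param sigma Positive standard deviation.
#' @return An `n_homo` x `ncell` matrix.
#' @export
generate_homogeneous_cem <- function(n_homo, ncell, sigma) {
  stopifnot(n_homo >= 1, ncell >= 1)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  matrix(stats::rnorm(n_homo * ncell, mean = 1, sd = sigma), n_homo, ncell)
}

#' Peak-wise effect matrix
#'
#' Entries are standard normal, then zeroed independently with probability
#' `eta`; the zeroing mask is drawn row by row so every peak keeps a random
#' subset of active embedding dimensions.
#'
#' @param npeak,nembed Matrix dimensions.
#' @param eta Zeroing probability in \[0, 1\] (default 0.5).
#' @return An `npeak` x `nembed` matrix.
#' @export
generate_pem <- function(npeak, nembed, eta = 0.5) {
  if (!is.numeric(eta) || eta < 0 || eta > 1)
    stop("eta must lie in [0, 1]", call. = FALSE)
  p <- matrix(stats::rnorm(npeak * nembed), npeak, nembed)
  mask <- matrix(stats::runif(npeak * nembed) < eta, npeak, nembed, byrow = TRUE)
  p[mask] <- 0
  p
}

#' Cell-wise effect vector
#'
#' @param nembed Length of the vector; entries i.i.d. standard normal.
#' @return A numeric vector of length `nembed`.
#' @export
generate_cev <- function(nembed) {
  stopifnot(nembed >= 1)
  stats::rnorm(nembed)
}

#' Population centers for the discrete mode
#'
#' Each of the `nhete` rows of the center matrix H is an independent draw
#' from an `npop`-dimensional multivariate normal with mean the all-ones
#' vector and covariance `covariance`, so off-diagonal covariance entries
#' make the corresponding populations' center coordinates correlated (and
#' the populations more similar).
#'
#' @param npop Number of populations (>= 2).
#' @param nhete Number of heterogeneous embedding dimensions.
#' @param covariance Symmetric positive semi-definite `npop` x `npop` matrix.
#' @return An `nhete` x `npop` matrix H.
#' @export
generate_discrete_centers <- function(npop, nhete, covariance) {
  stopifnot(npop >= 2, nhete >= 1)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf("covariance is not positive semi-definite (eigenvalue %g)",
                 min(ev)), call. = FALSE)
  MASS::mvrnorm(nhete, mu = rep(1, npop), Sigma = covariance)
}

#' Heterogeneous CEM for the discrete mode
#'
#' Cell `j` in population `k` gets entry `i` drawn from
#' Normal(`H[i, k]`, `sigma^2`).
#'
#' @param H Center matrix from [generate_discrete_centers()].
#' @param pop_sizes Integer vector of population sizes (all > 0).
#' @param sigma Within-population standard deviation.
#' @return A list with `C_hete` (`nhete` x `sum(pop_sizes)`) and
#'   `population` (character labels `pop_1`, `pop_2`, ...).
#' @export
generate_discrete_cem <- function(H, pop_sizes, sigma) {
  H <- as.matrix(H)
  if (any(pop_sizes <= 0)) stop("pop_sizes must all be positive", call. = FALSE)
  if (length(pop_sizes) != ncol(H))
    stop("length(pop_sizes) must equal ncol(H)", call. = FALSE)
  nhete <- nrow(H)
  cols <- lapply(seq_along(pop_sizes), function(k) {
    matrix(stats::rnorm(nhete * pop_sizes[k], mean = H[, k], sd = sigma),
           nhete, pop_sizes[k])
  })
  list(C_hete = do.call(cbind, cols),
       population = rep(sprintf("pop_%d", seq_along(pop_sizes)), pop_sizes))
}

#' Place cells along the branches of a trajectory tree
#'
#' Cells are allocated to branches in proportion to branch length
#' (largest-remainder rounding, every branch gets at least one cell) and sit
#' at uniform spacing `length/n` along each branch, starting one spacing
#' from the branch's parent node; a branch's last cell therefore sits
#' exactly on its child node. The predecessor of a branch's first cell is
#' the last cell of the parent branch (the virtual root cell, index 0, for
#' branches off the root); the virtual root is not emitted as a data cell.
#'
#' @param tree A [parse_newick()] tree.
#' @param ncell Number of cells (must be >= number of branches).
#' @return A data.frame (class `tree_placement`) with one row per cell:
#'   `branch` (label), `position` (along the branch), `pseudotime`
#'   (distance from the root), `predecessor` (row index of the previous
#'   cell, 0 for the virtual root) and `interval` (distance to predecessor).
#' @export
place_cells_on_tree <- function(tree, ncell) {
  stopifnot(inherits(tree, "cas_tree"))
  edges <- tree$edges
  nb <- nrow(edges)
  if (ncell < nb)
    stop(sprintf("ncell (%d) must be >= number of branches (%d)", ncell, nb),
         call. = FALSE)
  quota <- ncell * edges$length / sum(edges$length)
  n_b <- pmax(1L, floor(quota))
  rem <- ncell - sum(n_b)
  if (rem > 0) {  # largest fractional remainder; ties broken by branch order
    frac <- quota - floor(quota)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_b[add] <- n_b[add] + 1L
  } else if (rem < 0) {  # the >=1 floor oversubscribed; take from largest quotas
    for (i in order(quota, decreasing = TRUE)) {
      if (rem == 0) break
      take <- min(n_b[i] - 1L, -rem)
      n_b[i] <- n_b[i] - take; rem <- rem + take
    }
    if (rem != 0) stop("cannot allocate cells to branches", call. = FALSE)
  }
  last_cell_of_edge <- integer(nb)
  out <- vector("list", nb)
  idx <- 0L
  for (b in seq_len(nb)) {
    spacing <- edges$length[b] / n_b[b]
    pos <- spacing * seq_len(n_b[b])
    parent_depth <- tree$depth[edges$parent[b]]
    # predecessor of the first cell: last cell of the parent's edge, or root
    up <- match(edges$parent[b], edges$child)
    first_pred <- if (is.na(up)) 0L else last_cell_of_edge[up]
    preds <- c(first_pred, idx + seq_len(n_b[b] - 1L))
    out[[b]] <- data.frame(branch = edges$label[b], position = pos,
                           pseudotime = parent_depth + pos,
                           predecessor = preds, interval = spacing,
                           stringsAsFactors = FALSE)
    idx <- idx + n_b[b]
    last_cell_of_edge[b] <- idx
  }
  placement <- do.call(rbind, out)
  rownames(placement) <- NULL
  class(placement) <- c("tree_placement", "data.frame")
  placement
}

#' Heterogeneous CEM for the continuous mode (Brownian motion on the tree)
#'
#' Per embedding dimension, independently: the virtual root cell's value is
#' drawn from Normal(1, `sigma^2`); each cell's value is its predecessor's
#' value plus a Normal(0, `interval`) increment, where `interval` is the
#' tree distance between the two cells. The deviation of a cell from the
#' root value is therefore Brownian motion indexed by pseudotime.
#'
#' @param placement A [place_cells_on_tree()] placement.
#' @param nhete Number of heterogeneous embedding dimensions.
#' @param sigma Root-cell standard deviation.
#' @return A list with `C_hete` (`nhete` x `ncell`), `branch`, `pseudotime`,
#'   and `root_value` (length-`nhete` vector of virtual-root values).
#' @export
generate_continuous_cem <- function(placement, nhete, sigma) {
  stopifnot(inherits(placement, "tree_placement"), nhete >= 1)
  ncell <- nrow(placement)
  root <- stats::rnorm(nhete, mean = 1, sd = sigma)
  C <- matrix(0, nhete, ncell)
  for (j in seq_len(ncell)) {
    prev <- if (placement$predecessor[j] == 0L) root else C[, placement$predecessor[j]]
    C[, j] <- prev + stats::rnorm(nhete, 0, sqrt(placement$interval[j]))
  }
  list(C_hete = C, branch = placement$branch,
       pseudotime = placement$pseudotime, root_value = root)
}

#' Assemble the full CEM from its blocks
#'
#' @param C_homo Homogeneous block (`n_homo` x `ncell`).
#' @param C_hete Optional heterogeneous block (`nhete` x `ncell`); absent in
#'   the pseudo-cell-type mode, where all `nembed` dimensions are
#'   homogeneous.
#' @return The stacked CEM, homogeneous rows first.
#' @export
assemble_cem <- function(C_homo, C_hete = NULL) {
  if (is.null(C_hete)) return(C_homo)
  if (ncol(C_homo) != ncol(C_hete))
    stop("C_homo and C_hete must have the same number of cells", call. = FALSE)
  rbind(C_homo, C_hete)
}
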