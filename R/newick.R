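#' Parse a Newick tree into a branch table
#'
#' Trees define differentiation trajectories for the continuous simulation
#' mode: every edge ("branch") receives simulated cells in proportion to its
#' length. Branch lengths are required on every edge and must be positive.
#'
#' @param s A Newick string (or path to a file containing one).
#' @return An object of class `cas_tree`: a list with `edges` (data.frame
#'   `parent`, `child`, `length`, `label`, in depth-first Newick order),
#'   `root` (node id), `depth` (named vector of node distances from the
#'   root) and `total_length`.
#' @export
parse_newick <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (file.exists(s)) s <- paste(readLines(s), collapse = "")
  phy <- tryCatch(ape::read.tree(text = s),
                  error = function(e) stop("Newick parse failure: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse failure: empty tree", call. = FALSE)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("Newick parse failure: every edge needs a branch length", call. = FALSE)
  if (any(phy$edge.length <= 0))
    stop("branch lengths must be positive", call. = FALSE)
  phy <- ape::reorder.phylo(phy, "cladewise")  # depth-first, Newick order
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  labs <- character(ntip + phy$Nnode)
  labs[seq_len(ntip)] <- phy$tip.label
  inner <- if (!is.null(phy$node.label) && any(nzchar(phy$node.label)))
    phy$node.label else sprintf("node_%d", seq_len(phy$Nnode))
  labs[ntip + seq_len(phy$Nnode)] <- inner
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                      length = phy$edge.length, label = labs[phy$edge[, 2]],
                      stringsAsFactors = FALSE)
  depth <- stats::setNames(numeric(ntip + phy$Nnode), labs)
  # cladewise order guarantees parents precede children
  dd <- numeric(ntip + phy$Nnode)
  for (i in seq_len(nrow(edges))) dd[edges$child[i]] <- dd[edges$parent[i]] + edges$length[i]
  depth[] <- dd
  structure(list(edges = edges, root = root, depth = depth,
                 total_length = sum(edges$length), labels = labs),
            class = "cas_tree")
}

#' @export
print.cas_tree <- function(x, ...) {
  cat(sprintf("cas_tree: %d branches, total length %g\n",
              nrow(x$edges), x$total_length))
  invisible(x)
}
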