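#' Peak-by-cell count matrix container
#'
#' A `count_matrix` bundles a sparse non-negative integer matrix of
#' `npeak` peaks (rows) by `ncell` cells (columns) with a BED-style peak
#' table, a cell metadata table, and a flag marking binarized (0/1) data.
#' Ground-truth columns produced by the simulator (population, branch,
#' pseudotime, batch, hub membership) live in the metadata tables.
#'
#' @param counts A matrix or sparse Matrix of non-negative integers,
#'   peaks in rows, cells in columns.
#' @param peaks Optional data.frame with columns `chrom`, `start`, `end`,
#'   `peak_id` (0-based half-open intervals). Autogenerated when omitted.
#' @param cells Optional data.frame with a `barcode` column plus any
#'   metadata (e.g. `cell_type`). Autogenerated when omitted.
#' @param binarized Logical; if `NA` (default) it is inferred: a non-empty
#'   matrix whose maximum entry is 1 is flagged binarized.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, peaks = NULL, cells = NULL, binarized = NA) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (length(counts@x) && any(counts@x < 0))
    stop("count_matrix: negative entries are not allowed", call. = FALSE)
  if (length(counts@x) && any(abs(counts@x - round(counts@x)) > 1e-8))
    stop("count_matrix: non-integer entries are not allowed", call. = FALSE)
  counts@x <- round(counts@x)
  np <- nrow(counts); nc <- ncol(counts)
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = "chr1",
                        start = seq.int(0L, by = 1000L, length.out = np),
                        end   = seq.int(500L, by = 1000L, length.out = np),
                        peak_id = sprintf("peak_%d", seq_len(np)))
  }
  if (is.null(cells)) cells <- data.frame(barcode = sprintf("cell_%d", seq_len(nc)))
  if (nrow(peaks) != np) stop("peak table rows != nrow(counts)", call. = FALSE)
  if (nrow(cells) != nc) stop("cell table rows != ncol(counts)", call. = FALSE)
  if (anyDuplicated(peaks$peak_id)) stop("peak_id not unique", call. = FALSE)
  if (anyDuplicated(cells$barcode)) stop("barcode not unique", call. = FALSE)
  if (is.na(binarized)) binarized <- length(counts@x) > 0 && max(counts@x) == 1
  if (binarized && length(counts@x) && any(!counts@x %in% c(0, 1)))
    stop("binarized matrix must be 0/1", call. = FALSE)
  structure(list(counts = counts, peaks = peaks, cells = cells,
                 binarized = binarized),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d peaks x %d cells (%.2f%% non-zero%s)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts)),
              if (x$binarized) ", binarized" else ""))
  extra <- setdiff(names(x$cells), "barcode")
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Read a peak-by-cell matrix from standard on-disk formats
#'
#' Accepts Matrix Market coordinate format (canonical) or a dense TSV for
#' small fixtures, together with a BED-like peak table and a barcode list.
#' Matrix Market is 1-based on disk; peak coordinates are kept 0-based
#' half-open as in BED.
#'
#' @param matrix_path Path to `.mtx` (Matrix Market) or dense TSV of counts.
#' @param peaks_path BED-like TSV: chrom, start, end (3+ columns, no header).
#' @param barcodes_path One barcode per line.
#' @param labels_path Optional TSV (barcode, cell_type; with header) joined
#'   onto the cell table.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, peaks_path, barcodes_path,
                              labels_path = NULL) {
  if (!file.exists(matrix_path) || file.size(matrix_path) == 0)
    stop(sprintf("empty or missing matrix file: %s", matrix_path), call. = FALSE)
  first <- readLines(matrix_path, n = 1L)
  if (startsWith(first, "%%MatrixMarket")) {
    m <- Matrix::readMM(matrix_path)
  } else {
    m <- as.matrix(utils::read.table(matrix_path, sep = "\t"))
    dimnames(m) <- NULL
  }
  bed <- utils::read.table(peaks_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop(sprintf("peak table %s needs >= 3 columns", peaks_path),
                          call. = FALSE)
  peaks <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                      peak_id = if (ncol(bed) >= 4) bed[[4]] else
                        sprintf("peak_%d", seq_len(nrow(bed))))
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(peaks) != nrow(m))
    stop(sprintf("dimension mismatch: %s has %d rows but %s has %d peaks",
                 matrix_path, nrow(m), peaks_path, nrow(peaks)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("dimension mismatch: %s has %d columns but %s has %d barcodes",
                 matrix_path, ncol(m), barcodes_path, length(barcodes)),
         call. = FALSE)
  cells <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    cells <- merge(cells, lab, by = "barcode", all.x = TRUE, sort = FALSE)
    cells <- cells[match(barcodes, cells$barcode), , drop = FALSE]
    rownames(cells) <- NULL
  }
  count_matrix(m, peaks, cells)
}

#' Write a count matrix to a directory of standard text files
#'
#' Emits `matrix.mtx` (Matrix Market), `peaks.bed`, `barcodes.tsv`,
#' `cell_metadata.tsv` and `peak_metadata.tsv`; reading the output back with
#' [read_count_matrix()] reproduces the counts, peak order and barcode order
#' exactly.
#'
#' @param cm A [count_matrix()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(cm, out_dir) {
  stopifnot(inherits(cm, "count_matrix"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  paths <- file.path(out_dir, c("matrix.mtx", "peaks.bed", "barcodes.tsv",
                                "cell_metadata.tsv", "peak_metadata.tsv"))
  Matrix::writeMM(cm$counts, paths[1])
  utils::write.table(cm$peaks[, c("chrom", "start", "end", "peak_id")], paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cm$cells$barcode, paths[3])
  utils::write.table(cm$cells, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$peaks, paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Filter a reference matrix before statistic estimation
#'
#' Applies, in order: drop cell types with fewer than `min_cells_per_type`
#' cells, drop peaks non-zero in fewer than `min_cells_per_peak` cells, drop
#' cells with fewer than `min_peaks_per_cell` non-zero peaks. The order is
#' fixed so results are reproducible.
#'
#' @param cm A [count_matrix()].
#' @param min_cells_per_type Minimum cells per cell type (needs a
#'   `cell_type` column; default 50).
#' @param min_cells_per_peak Minimum cells in which a peak is non-zero.
#' @param min_peaks_per_cell Minimum non-zero peaks per cell.
#' @return The filtered [count_matrix()].
#' @export
filter_reference <- function(cm, min_cells_per_type = 50,
                             min_cells_per_peak = 0, min_peaks_per_cell = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts; peaks <- cm$peaks; cells <- cm$cells
  if (min_cells_per_type > 0 && !is.null(cells$cell_type)) {
    tab <- table(cells$cell_type)
    keep_type <- names(tab)[tab >= min_cells_per_type]
    jj <- which(cells$cell_type %in% keep_type)
    x <- x[, jj, drop = FALSE]; cells <- cells[jj, , drop = FALSE]
  }
  if (min_cells_per_peak > 0) {
    ii <- which(Matrix::rowSums(x > 0) >= min_cells_per_peak)
    x <- x[ii, , drop = FALSE]; peaks <- peaks[ii, , drop = FALSE]
  }
  if (min_peaks_per_cell > 0) {
    jj <- which(Matrix::colSums(x > 0) >= min_peaks_per_cell)
    x <- x[, jj, drop = FALSE]; cells <- cells[jj, , drop = FALSE]
  }
  if (ncol(x) == 0) stop("filter_reference removed all cells", call. = FALSE)
  rownames(peaks) <- NULL; rownames(cells) <- NULL
  count_matrix(x, peaks, cells, binarized = cm$binarized)
}
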