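#' Window around a transcription start site
#'
#' The window is `[tss - tss_range, tss + tss_range)`: `tss_range` is the
#' flank per side, so the full window spans `2 * tss_range` bp. Near the
#' chromosome start the window is clipped at 0, but the bin grid stays
#' anchored at `tss - tss_range`; bases falling below 0 simply contribute no
#' signal.
#'
#' @param gene One-row data frame (or list) with fields `chrom`, `tss` and
#'   `strand`, as from [read_gene_annotations()].
#' @param tss_range Flank in bp on each side of the TSS (> 0).
#' @return A list with `chrom`, `start`, `end` (clipped at 0), and
#'   `grid_start` (the unclipped anchor `tss - tss_range` used for binning).
#' @export
build_tss_window <- function(gene, tss_range) {
  if (!is.numeric(tss_range) || length(tss_range) != 1L || tss_range <= 0) {
    stop("tss_range must be a single positive number of base pairs")
  }
  tss <- gene$tss
  grid_start <- tss - tss_range
  list(chrom = gene$chrom, start = max(0, grid_start), end = tss + tss_range,
       grid_start = grid_start)
}

#' Bin peak signal over a TSS window
#'
#' Tiles the window into `n_bins = ceiling(2 * tss_range / bin_size)` bins
#' anchored at the window's (unclipped) grid start and returns the mean
#' per-base signal in each bin. A base covered by several overlapping peaks
#' accumulates the sum of their signals; uncovered bases (including bases
#' clipped off below position 0) contribute 0. Binning is linear in the peak
#' signals and invariant to a joint translation of peaks and window.
#'
#' @param peaks Data frame of peaks (`start`, `end`, `signal`), already
#'   restricted to the window's chromosome. May have zero rows.
#' @param window Window from [build_tss_window()].
#' @param bin_size Bin width in bp.
#' @return Numeric vector of length `n_bins`, non-negative.
#' @export
bin_signal <- function(peaks, window, bin_size) {
  if (bin_size <= 0) stop("bin_size must be positive")
  width <- window$end - window$grid_start
  n_bins <- as.integer(ceiling(width / bin_size))
  v <- numeric(n_bins)
  if (nrow(peaks) == 0L) return(v)
  bin_lo <- window$grid_start + (seq_len(n_bins) - 1) * bin_size
  bin_hi <- pmin(bin_lo + bin_size, window$end)
  # clip peaks at 0 (grid bases below 0 carry no signal) and at window edges
  ps <- pmax(peaks$start, max(0, window$grid_start))
  pe <- pmin(peaks$end, window$end)
  keep <- pe > ps
  ps <- ps[keep]; pe <- pe[keep]; sig <- peaks$signal[keep]
  for (i in seq_along(ps)) {
    ov <- pmin(pe[i], bin_hi) - pmax(ps[i], bin_lo)
    ov[ov < 0] <- 0
    v <- v + sig[i] * ov / bin_size
  }
  v
}

#' Build a per-view feature matrix
#'
#' One row per (gene, cell line) sample, ordered deterministically: genes in
#' lexicographic order as the outer loop, cell lines lexicographic inner.
#' Each row is the binned peak signal (see [bin_signal()]) of that cell
#' line's peaks in the window around that gene's TSS. A gene whose chromosome
#' is absent from a cell line's peak set gets a zero row (with a message),
#' not an error.
#'
#' @param peaks_by_cell_line Named list mapping cell line to a peak data
#'   frame (possibly empty) as from [read_narrowpeak()].
#' @param genes Gene annotations from [read_gene_annotations()].
#' @param tss_range Flank per side in bp.
#' @param bin_size Bin width in bp (default 10).
#' @param view View label, e.g. `"tf"` or `"h3k27ac"`.
#' @return An object of class `"feature_matrix"`: a list with `values`
#'   (n_samples x n_bins matrix), `sample_ids` (`gene_id:cell_line`),
#'   `gene_id`, `cell_line`, `view`, `tss_range`, `bin_size`.
#' @export
build_feature_matrix <- function(peaks_by_cell_line, genes, tss_range,
                                 bin_size = 10, view = "tf") {
  if (is.null(names(peaks_by_cell_line)) || any(!nzchar(names(peaks_by_cell_line)))) {
    stop("peaks_by_cell_line must be a named list (names = cell lines)")
  }
  cell_lines <- sort(names(peaks_by_cell_line))
  gene_order <- order(genes$gene_id)
  genes <- genes[gene_order, , drop = FALSE]
  n_bins <- as.integer(ceiling(2 * tss_range / bin_size))
  n <- nrow(genes) * length(cell_lines)
  values <- matrix(0, nrow = n, ncol = n_bins)
  gene_id <- character(n)
  cell_line <- character(n)
  missing_chroms <- character(0)
  row <- 0L
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    window <- build_tss_window(gene, tss_range)
    for (cl in cell_lines) {
      row <- row + 1L
      gene_id[row] <- gene$gene_id
      cell_line[row] <- cl
      peaks <- peaks_by_cell_line[[cl]]
      if (nrow(peaks) > 0L) {
        onchrom <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
        if (nrow(onchrom) == 0L && !gene$chrom %in% peaks$chrom) {
          missing_chroms <- union(missing_chroms, paste0(cl, ":", gene$chrom))
        }
        values[row, ] <- bin_signal(onchrom, window, bin_size)
      }
    }
  }
  if (length(missing_chroms) > 0L) {
    message("chromosomes absent from peak sets (zero rows used): ",
            paste(missing_chroms, collapse = ", "))
  }
  structure(list(values = values,
                 sample_ids = paste(gene_id, cell_line, sep = ":"),
                 gene_id = gene_id, cell_line = cell_line, view = view,
                 tss_range = tss_range, bin_size = bin_size),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix (view:", x$view, ")\n")
  cat("  ", nrow(x$values), "samples x", ncol(x$values), "bins",
      sprintf("(TSS flank %d bp, bin %d bp)\n",
              as.integer(x$tss_range), as.integer(x$bin_size)))
  invisible(x)
}

#' Align two views and an expression table to common samples
#'
#' Restricts both feature matrices and the expression table to the
#' intersection of (gene, cell line) keys present in all three, in one
#' deterministic order (gene then cell line, lexicographic).
#'
#' @param fm_tf,fm_hm Feature matrices from [build_feature_matrix()].
#' @param expr Expression table from [read_expression_table()].
#' @return A list with `fm_tf`, `fm_hm` (reordered feature matrices), `y`
#'   (expression vector), `sample_ids`, `gene_id`, `cell_line`.
#' @export
align_views <- function(fm_tf, fm_hm, expr) {
  key_expr <- paste(expr$gene_id, expr$cell_line, sep = ":")
  common <- intersect(intersect(fm_tf$sample_ids, fm_hm$sample_ids), key_expr)
  if (length(common) == 0L) {
    stop("no (gene, cell_line) samples shared by both views and the expression table")
  }
  ord <- order(common)
  common <- common[ord]
  take <- function(fm, ids) {
    idx <- match(ids, fm$sample_ids)
    fm$values <- fm$values[idx, , drop = FALSE]
    fm$sample_ids <- fm$sample_ids[idx]
    fm$gene_id <- fm$gene_id[idx]
    fm$cell_line <- fm$cell_line[idx]
    fm
  }
  fm_tf <- take(fm_tf, common)
  fm_hm <- take(fm_hm, common)
  y <- expr$expression[match(common, key_expr)]
  list(fm_tf = fm_tf, fm_hm = fm_hm, y = y, sample_ids = common,
       gene_id = fm_tf$gene_id, cell_line = fm_tf$cell_line)
}

#' Serialize / read a feature matrix as TSV
#'
#' Matrices are written with a `sample_id` index column and one column per
#' bin; [read_feature_matrix()] restores the `feature_matrix` object.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `feature_matrix` (reader).
#' @export
write_feature_matrix <- function(fm, path) {
  tab <- data.frame(sample_id = fm$sample_ids,
                    gene_id = fm$gene_id, cell_line = fm$cell_line,
                    fm$values, check.names = FALSE)
  names(tab)[-(1:3)] <- paste0("bin", seq_len(ncol(fm$values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# view=%s tss_range=%s bin_size=%s", fm$view,
                     format_bp(fm$tss_range), format_bp(fm$bin_size)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- c(view = "unknown", tss_range = NA, bin_size = NA)
  if (startsWith(header, "#")) {
    kv <- strsplit(strsplit(sub("^#\\s*", "", header), "\\s+")[[1]], "=")
    meta[vapply(kv, `[`, "", 1L)] <- vapply(kv, `[`, "", 2L)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -(1:3), drop = FALSE])
  dimnames(values) <- NULL
  structure(list(values = values, sample_ids = tab$sample_id,
                 gene_id = tab$gene_id, cell_line = tab$cell_line,
                 view = unname(meta[["view"]]),
                 tss_range = as.numeric(meta[["tss_range"]]),
                 bin_size = as.numeric(meta[["bin_size"]])),
            class = "feature_matrix")
}
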