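#' Read an ENCODE narrowPeak file
#'
#' Parses a narrowPeak (BED6+4) file into a data frame of genomic intervals.
#' Coordinates are kept in the native BED convention: 0-based, half-open
#' `[start, end)`. The per-base enrichment `signal` is taken from column 7
#' (`signalValue`), ENCODE's enrichment field, and is treated downstream as a
#' uniform per-base signal across the peak.
#'
#' @param path Path to a narrowPeak file (tab-separated, >= 10 columns).
#' @param signal_column Which column carries the peak signal. Defaults to 7
#'   (`signalValue`); column 5 (`score`) is the common alternative.
#' @return A data frame with columns `chrom` (character), `start`, `end`
#'   (integer-valued doubles, 0-based half-open), `name`, `strand` and
#'   `signal` (non-negative numeric). Empty file gives zero rows.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tpeak1\t0\t.\t5.5\t-1\t-1\t50", f)
#' read_narrowpeak(f)
#' @export
read_narrowpeak <- function(path, signal_column = 7L) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), strand = character(),
                      signal = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad) > 0L) {
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": expected >= 10 tab-separated columns, found ", nf[bad[1L]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  signal <- suppressWarnings(as.numeric(m[, signal_column]))
  bad <- which(is.na(start) | is.na(end) | is.na(signal))
  if (length(bad) > 0L) {
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": non-numeric coordinate or signal")
  }
  if (any(start < 0)) {
    stop("invalid narrowPeak line ", which(start < 0)[1L], " in ", path,
         ": negative start coordinate")
  }
  if (any(end <= start)) {
    stop("invalid narrowPeak line ", which(end <= start)[1L], " in ", path,
         ": end must be greater than start (0-based half-open)")
  }
  if (any(signal < 0)) {
    stop("invalid narrowPeak line ", which(signal < 0)[1L], " in ", path,
         ": negative signal value")
  }
  data.frame(chrom = m[, 1L], start = start, end = end, name = m[, 4L],
             strand = m[, 6L], signal = signal, stringsAsFactors = FALSE)
}

#' Write intervals to a narrowPeak file
#'
#' Inverse of [read_narrowpeak()]: coordinates and signal round-trip exactly.
#' Columns not represented in the interval data frame are filled with
#' narrowPeak placeholders (`score = 0`, `pValue = qValue = peak = -1`).
#'
#' @param peaks Data frame as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) peaks$name else paste0("peak", seq_len(n))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", n)
  lines <- sprintf("%s\t%s\t%s\t%s\t0\t%s\t%s\t-1\t-1\t-1",
                   peaks$chrom, format_bp(peaks$start), format_bp(peaks$end),
                   name, strand, format_signal(peaks$signal))
  writeLines(lines, path)
  invisible(path)
}

# integer-like coordinates without scientific notation
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
# signals printed with full precision so round-trips are exact
format_signal <- function(x) formatC(x, format = "g", digits = 17)

#' Read gene annotations (BED6 or minimal GTF)
#'
#' Returns one transcription start site per gene. All coordinates are
#' normalised to the 0-based half-open convention: for BED6 input the TSS is
#' `start` on the + strand and `end - 1` on the - strand; GTF 1-based
#' closed coordinates are converted on read (start - 1), so a GTF gene line
#' with `start = 1001` on + gives `tss = 1000`.
#'
#' @param path Path to the annotation file.
#' @param format `"bed6"` (default) or `"gtf"`. GTF parsing is minimal:
#'   feature rows of type `gene` (or `transcript` when no gene rows exist)
#'   with a `gene_id "..."` attribute.
#' @return A data frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   and `tss` (0-based position).
#' @export
read_gene_annotations <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  genes <- switch(format,
    bed6 = read_genes_bed6(path),
    gtf = read_genes_gtf(path))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in ", path, ": ", dup[1L])
  }
  if (any(genes$tss < 0)) stop("negative TSS coordinate in ", path)
  genes
}

read_genes_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED6 line ", which(nf < 6L)[1L], " in ", path,
         ": expected 6 columns")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  if (any(end <= start)) stop("BED interval with end <= start in ", path)
  strand <- m[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("invalid strand '", strand[bad[1L]], "' on line ", bad[1L], " of ",
         path, " (must be + or -)")
  }
  tss <- ifelse(strand == "+", start, end - 1)
  data.frame(gene_id = m[, 4L], chrom = m[, 1L], strand = strand, tss = tss,
             stringsAsFactors = FALSE)
}

read_genes_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF line ", which(nf < 9L)[1L], " in ", path,
         ": expected 9 columns")
  }
  m <- do.call(rbind, fields)
  type <- m[, 3L]
  keep <- type == "gene"
  if (!any(keep)) keep <- type == "transcript"
  if (!any(keep)) stop("no gene or transcript rows in GTF file ", path)
  m <- m[keep, , drop = FALSE]
  start1 <- suppressWarnings(as.numeric(m[, 4L]))  # 1-based inclusive
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) stop("non-numeric coordinates in ", path)
  strand <- m[, 7L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("invalid strand '", strand[bad[1L]], "' in GTF file ", path)
  }
  ids <- regmatches(m[, 9L], regexpr('gene_id "[^"]+"', m[, 9L]))
  if (length(ids) != nrow(m)) stop("GTF gene line without gene_id attribute in ", path)
  gene_id <- sub('gene_id "([^"]+)"', "\\1", ids)
  # convert to 0-based half-open: start-1, end unchanged
  tss <- ifelse(strand == "+", start1 - 1, end1 - 1)
  data.frame(gene_id = gene_id, chrom = m[, 1L], strand = strand, tss = tss,
             stringsAsFactors = FALSE)
}

#' Read an expression table
#'
#' Reads a TSV with header columns `gene_id`, `cell_line`, `expression`.
#' Values are consumed as-is (assumed pre-transformed, e.g. log TPM).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene_id`, `cell_line` (character) and
#'   `expression` (finite numeric); `(gene_id, cell_line)` keys are unique.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "cell_line", "expression")
  if (!all(need %in% names(tab))) {
    stop("expression table ", path, " must have header columns: ",
         paste(need, collapse = ", "))
  }
  expr <- suppressWarnings(as.numeric(tab$expression))
  bad <- which(is.na(expr) | !is.finite(expr))
  if (length(bad) > 0L) {
    stop("non-numeric or non-finite expression value '",
         tab$expression[bad[1L]], "' at data row ", bad[1L], " of ", path)
  }
  key <- paste(tab$gene_id, tab$cell_line, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (gene_id, cell_line) key in ", path, ": ",
         gsub("\r", ", ", d, fixed = TRUE))
  }
  data.frame(gene_id = tab$gene_id, cell_line = tab$cell_line,
             expression = expr, stringsAsFactors = FALSE)
}

#' Write per-sample predictions with residuals
#'
#' Writes a TSV with header `sample_id`, `y_true`, `y_pred`, `residual`,
#' where `residual = y_true - y_pred`. This is the data behind the standard
#' residual and predicted-versus-actual diagnostic plots.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(sample_id, y_true, y_pred, path) {
  if (length(y_true) != length(sample_id) || length(y_pred) != length(sample_id)) {
    stop("sample_id, y_true and y_pred must have equal length")
  }
  tab <- data.frame(sample_id = sample_id, y_true = y_true, y_pred = y_pred,
                    residual = y_true - y_pred)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write predictions to ", path)
  invisible(path)
}
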