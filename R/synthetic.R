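#' Configuration for the synthetic regulatory dataset
#'
#' Describes an ENCODE-shaped world at desk scale: a set of genes on one toy
#' chromosome with non-overlapping TSS windows, a panel of cell lines
#' grouped into latent clusters, per-cell-line peak sets for the two views
#' (TF binding and H3K27ac), and an expression value per (gene, cell line)
#' carrying a planted dependence on the window signal:
#' `y = alpha * s_tf + beta * s_hm + gamma * s_tf * s_hm + N(0, noise_sd)`,
#' where `s_tf`, `s_hm` are the window-mean per-base signals. Cell lines in
#' the same cluster share peak layouts per gene (signals rescaled, positions
#' jittered per member), so the cosine-similarity sample graphs genuinely
#' carry cluster information. The interaction term `gamma` makes purely
#' linear baselines suboptimal by construction.
#'
#' @param n_genes,n_cell_lines,n_clusters Panel dimensions.
#' @param tss_range TSS flank per side in bp (window width `2 * tss_range`).
#' @param bin_size Bin width for the returned feature matrices.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param alpha,beta,gamma Planted effect weights (TF, H3K27ac,
#'   interaction).
#' @param gene_spacing Gap in bp between consecutive TSS windows.
#' @param chrom Toy chromosome name.
#' @param chrom_length Optional chromosome length; an error is raised when
#'   the windows cannot be placed without overlap within it.
#' @param peaks_per_window Range (min, max) of peaks per active window.
#' @param peak_width Range (min, max) of peak widths in bp.
#' @param p_active Probability that a promoter is active for a given (view,
#'   gene, cluster) combination (default 0.7). Inactive promoters get no
#'   peaks in that window, mirroring the zero-inflated, cell-type-specific
#'   occupancy of real TF-binding and H3K27ac landscapes; the planted
#'   interaction term then acts as an AND gate (both marks present), which
#'   is the nonlinear structure linear baselines cannot represent.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 50L, n_cell_lines = 6L,
                             n_clusters = 3L, tss_range = 200,
                             bin_size = 10, noise_sd = 0.1, alpha = 1,
                             beta = 1, gamma = 1, gene_spacing = 1000,
                             chrom = "chrS", chrom_length = NULL,
                             peaks_per_window = c(1L, 3L),
                             peak_width = c(50L, 150L), p_active = 0.7,
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_cell_lines >= 1, n_clusters >= 1,
            tss_range > 0, bin_size > 0, noise_sd >= 0, gene_spacing > 0,
            p_active > 0, p_active <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_clusters = as.integer(min(n_clusters, n_cell_lines)),
                 tss_range = tss_range, bin_size = bin_size,
                 noise_sd = noise_sd, alpha = alpha, beta = beta,
                 gamma = gamma, gene_spacing = gene_spacing, chrom = chrom,
                 chrom_length = chrom_length,
                 peaks_per_window = peaks_per_window,
                 peak_width = peak_width, p_active = p_active,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic two-view regulatory dataset
#'
#' Produces peak sets per view per cell line, gene annotations, an
#' expression table with the planted signal of [synthetic_config()], and the
#' ground truth needed to verify recovery. With `dir` set, everything is
#' also written in the standard formats (`genes.bed`, narrowPeak files under
#' `peaks/`, `expression.tsv`, `ground_truth.tsv`) and round-trips losslessly
#' through [read_narrowpeak()], [read_gene_annotations()] and
#' [read_expression_table()]. Byte-identical output for a given seed.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return A list with `genes`, `peaks` (`$tf`/`$hm`, each a named list of
#'   peak data frames per cell line), `expression` (gene_id, cell_line,
#'   expression), `ground_truth` (per-sample `s_tf`, `s_hm`, `noiseless`,
#'   planted weights as attributes), `clusters` (cell line -> cluster),
#'   `fm_tf`, `fm_hm` (ready-made `feature_matrix` objects), `config`, and
#'   `dir` when written.
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  generate_internal(config, dir, null_expression = FALSE)
}

#' Generate a matched null dataset (negative control)
#'
#' Identical feature generation to [generate_dataset()] (same seeded
#' stream), but expression is independent standard normal noise, carrying no
#' relationship to the window signals. Any model's test R^2 on this data
#' should hover around zero.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()]; `ground_truth$noiseless` is absent.
#' @export
generate_null_dataset <- function(config = synthetic_config(), dir = NULL) {
  generate_internal(config, dir, null_expression = TRUE)
}

generate_internal <- function(config, dir, null_expression) {
  cfg <- config
  with_seed(cfg$seed, {
    # --- gene placement: non-overlapping windows on one toy chromosome ---
    r <- cfg$tss_range
    pitch <- 2 * r + cfg$gene_spacing
    tss <- r + cfg$gene_spacing + pitch * (seq_len(cfg$n_genes) - 1)
    needed <- tss[cfg$n_genes] + r + cfg$gene_spacing
    if (!is.null(cfg$chrom_length) && needed > cfg$chrom_length) {
      stop("cannot place ", cfg$n_genes, " non-overlapping TSS windows on a ",
           cfg$chrom_length, " bp chromosome (need ", needed,
           " bp); increase chrom_length")
    }
    gene_id <- sprintf("G%03d", seq_len(cfg$n_genes))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    gene_len <- 400
    bed_start <- ifelse(strand == "+", tss, tss + 1 - gene_len)
    bed_end <- ifelse(strand == "+", tss + gene_len, tss + 1)
    genes <- data.frame(gene_id = gene_id, chrom = cfg$chrom,
                        strand = strand, tss = tss,
                        bed_start = bed_start, bed_end = bed_end,
                        stringsAsFactors = FALSE)

    cell_lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
    clusters <- rep_len(seq_len(cfg$n_clusters), cfg$n_cell_lines)
    names(clusters) <- cell_lines

    # --- cluster-level peak layouts, per view and gene ---
    views <- c("tf", "hm")
    peaks <- list(tf = stats::setNames(vector("list", cfg$n_cell_lines),
                                       cell_lines),
                  hm = stats::setNames(vector("list", cfg$n_cell_lines),
                                       cell_lines))
    # accumulate rows per (view, cell line)
    acc <- list()
    for (vw in views) {
      for (cl in cell_lines) acc[[paste(vw, cl)]] <- list()
    }
    for (vw in views) {
      for (g in seq_len(cfg$n_genes)) {
        win_lo <- tss[g] - r
        win_hi <- tss[g] + r
        for (k in seq_len(cfg$n_clusters)) {
          # cell-type-specific occupancy: a promoter may be silent for this
          # (view, gene, cluster); silent windows get no peaks at all
          if (stats::runif(1) >= cfg$p_active) next
          # shared layout: cluster's promoter activity for this gene/view
          activity <- stats::runif(1, 0.2, 2.0)
          n_pk <- sample(seq(cfg$peaks_per_window[1L],
                             cfg$peaks_per_window[2L]), 1L)
          width <- sample(seq(cfg$peak_width[1L], cfg$peak_width[2L]), n_pk,
                          replace = TRUE)
          width <- pmin(width, 2 * r - 2)
          pos <- vapply(width, function(w)
            floor(stats::runif(1, win_lo, win_hi - w)), 0)
          base_sig <- activity * stats::runif(n_pk, 0.5, 1.5)
          members <- cell_lines[clusters == k]
          for (cl in members) {
            scale_cl <- exp(stats::rnorm(1L, 0, 0.15))
            jitter <- sample(-5:5, n_pk, replace = TRUE)
            ps <- pmax(win_lo, pmin(pos + jitter, win_hi - width))
            acc[[paste(vw, cl)]][[length(acc[[paste(vw, cl)]]) + 1L]] <-
              data.frame(chrom = cfg$chrom, start = ps, end = ps + width,
                         name = sprintf("%s_%s_%s_pk", vw, cl, gene_id[g]),
                         strand = ".", signal = base_sig * scale_cl,
                         stringsAsFactors = FALSE)
          }
        }
      }
      # background peaks in the gaps between windows (outside every window)
      for (cl in cell_lines) {
        n_bg <- 3L
        gaps <- sample.int(cfg$n_genes, n_bg, replace = TRUE)
        w_bg <- sample(seq(cfg$peak_width[1L], cfg$peak_width[2L]), n_bg,
                       replace = TRUE)
        lo <- tss[gaps] + r + 10
        start_bg <- floor(stats::runif(n_bg, lo,
                                       lo + cfg$gene_spacing - w_bg - 20))
        acc[[paste(vw, cl)]][[length(acc[[paste(vw, cl)]]) + 1L]] <-
          data.frame(chrom = cfg$chrom, start = start_bg,
                     end = start_bg + w_bg,
                     name = sprintf("%s_%s_bg%d", vw, cl, seq_len(n_bg)),
                     strand = ".", signal = stats::runif(n_bg, 0.1, 0.5),
                     stringsAsFactors = FALSE)
      }
    }
    for (vw in views) {
      for (cl in cell_lines) {
        df <- do.call(rbind, acc[[paste(vw, cl)]])
        df <- df[order(df$start, df$end), , drop = FALSE]
        df$name <- sprintf("%s_%s_peak%d", vw, cl, seq_len(nrow(df)))
        rownames(df) <- NULL
        peaks[[vw]][[cl]] <- df
      }
    }

    # --- ground-truth window-mean signals and planted expression ---
    window_mean <- function(pk, lo, hi) {
      if (nrow(pk) == 0L) return(0)
      ov <- pmin(pk$end, hi) - pmax(pk$start, lo)
      sum(pk$signal * pmax(ov, 0)) / (hi - lo)
    }
    n <- cfg$n_genes * cfg$n_cell_lines
    s_tf <- s_hm <- numeric(n)
    gid <- clid <- character(n)
    row <- 0L
    for (g in seq_len(cfg$n_genes)) {      # lexicographic: genes outer,
      for (cl in cell_lines) {             # cell lines inner
        row <- row + 1L
        gid[row] <- gene_id[g]
        clid[row] <- cl
        s_tf[row] <- window_mean(peaks$tf[[cl]], tss[g] - r, tss[g] + r)
        s_hm[row] <- window_mean(peaks$hm[[cl]], tss[g] - r, tss[g] + r)
      }
    }
    noiseless <- cfg$alpha * s_tf + cfg$beta * s_hm + cfg$gamma * s_tf * s_hm
    expr_y <- if (null_expression) {
      stats::rnorm(n)
    } else {
      noiseless + stats::rnorm(n, 0, cfg$noise_sd)
    }
    expression <- data.frame(gene_id = gid, cell_line = clid,
                             expression = expr_y, stringsAsFactors = FALSE)
    ground_truth <- data.frame(gene_id = gid, cell_line = clid,
                               s_tf = s_tf, s_hm = s_hm,
                               stringsAsFactors = FALSE)
    if (!null_expression) ground_truth$noiseless <- noiseless
    attr(ground_truth, "alpha") <- cfg$alpha
    attr(ground_truth, "beta") <- cfg$beta
    attr(ground_truth, "gamma") <- cfg$gamma

    anno <- genes[, c("gene_id", "chrom", "strand", "tss")]
    fm_tf <- build_feature_matrix(peaks$tf, anno, cfg$tss_range,
                                  cfg$bin_size, view = "tf")
    fm_hm <- build_feature_matrix(peaks$hm, anno, cfg$tss_range,
                                  cfg$bin_size, view = "h3k27ac")

    out <- list(genes = anno, genes_bed = genes, peaks = peaks,
                expression = expression, ground_truth = ground_truth,
                clusters = clusters, fm_tf = fm_tf, fm_hm = fm_hm,
                config = cfg)
    if (!is.null(dir)) {
      write_dataset(out, dir)
      out$dir <- dir
    }
    out
  })
}

# write the generated dataset in standard formats
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  g <- ds$genes_bed
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t%s", g$chrom, format_bp(g$bed_start),
                     format_bp(g$bed_end), g$gene_id, g$strand),
             file.path(dir, "genes.bed"))
  for (vw in names(ds$peaks)) {
    for (cl in names(ds$peaks[[vw]])) {
      write_narrowpeak(ds$peaks[[vw]][[cl]],
                       file.path(dir, "peaks",
                                 sprintf("%s_%s.narrowPeak", vw, cl)))
    }
  }
  expr <- ds$expression
  expr$expression <- format_signal(expr$expression)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- ds$ground_truth
  for (cc in setdiff(names(gt), c("gene_id", "cell_line"))) {
    gt[[cc]] <- format_signal(gt[[cc]])
  }
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
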