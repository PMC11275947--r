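# Shared fixture builders: everything is generated in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a tiny peak data frame in the package's 0-based half-open convention
peaks_df <- function(start, end, signal, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.numeric(start), end = as.numeric(end),
             name = if (length(start)) paste0("pk", seq_along(start))
                    else character(0),
             strand = rep_len(".", length(start)),
             signal = as.numeric(signal), stringsAsFactors = FALSE)
}

# random peaks within [0, span); deterministic under the caller's seed
random_peaks <- function(n, span = 2000, chrom = "chr1") {
  start <- sort(sample.int(span - 60, n))
  width <- sample(10:50, n, replace = TRUE)
  peaks_df(start, pmin(start + width, span), round(runif(n, 0.5, 5), 3),
           chrom = chrom)
}

# two well-separated feature clusters with cluster-consistent labels
separable_toy <- function(n_per = 20, d = 8, gap = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, gap / 2), n_per),
             matrix(rnorm(n_per * d, -gap / 2), n_per))
  labels <- rep(c(0L, 1L), each = n_per)
  n <- 2 * n_per
  masks <- split_samples(n, seed = seed)
  list(x = x, labels = labels, masks = masks, n = n)
}

# a small fitted model on a small synthetic world (shared across tests)
small_sim <- function(seed = 7, n_genes = 15L, n_cell_lines = 4L) {
  generate_dataset(synthetic_config(n_genes = n_genes,
                                    n_cell_lines = n_cell_lines, seed = seed))
}

small_fit <- function(sim, seed = 7, ...) {
  genet_fit(sim$fm_tf, sim$fm_hm, sim$expression$expression,
            hidden_size = 32L, n_classes = 3L, epochs = 40L,
            pretrain_epochs = 15L, patience = 40L, seed = seed, ...)
}
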