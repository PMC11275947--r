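test_that("TSS windows are [tss - R, tss + R) with zero-anchored clipping", {
  g <- list(chrom = "chr1", tss = 5000, strand = "+")
  w <- build_tss_window(g, 200)
  expect_equal(c(w$start, w$end), c(4800, 5200))
  # clipped near the chromosome start, grid anchor unchanged
  w2 <- build_tss_window(list(chrom = "chr1", tss = 50), 200)
  expect_equal(c(w2$start, w2$end, w2$grid_start), c(0, 250, -150))
  w3 <- build_tss_window(list(chrom = "chr1", tss = 0), 100)
  expect_equal(c(w3$start, w3$end), c(0, 100))
  expect_equal(bin_signal(peaks_df(0, 100, 1), w3, 10),
               c(rep(0, 10), rep(1, 10)))  # left half zero-padded
  expect_error(build_tss_window(g, -5), "positive")
})

test_that("bin values are mean per-base signal with overlap accumulation", {
  w <- list(chrom = "chr1", start = 1000, end = 1400, grid_start = 1000)
  v <- bin_signal(peaks_df(1050, 1150, 5), w, 100)
  expect_equal(v, c(2.5, 2.5, 0, 0))
  expect_equal(bin_signal(peaks_df(numeric(0), numeric(0), numeric(0)), w, 100),
               rep(0, 4))
  # one peak spanning the whole window -> every bin equals its signal
  expect_equal(bin_signal(peaks_df(900, 1500, 3.2), w, 100), rep(3.2, 4))
  # overlapping peaks add
  v2 <- bin_signal(peaks_df(c(1000, 1000), c(1400, 1400), c(1, 2)), w, 100)
  expect_equal(v2, rep(3, 4))
})

test_that("binning matches the per-base brute-force oracle on random windows", {
  set.seed(19)
  for (rep in 1:12) {
    tss <- sample.int(1500, 1) + 100
    r <- sample(c(50, 100, 250), 1)
    bs <- sample(c(7, 10, 25), 1)
    w <- build_tss_window(list(chrom = "chr1", tss = tss), r)
    pk <- random_peaks(sample.int(8, 1))
    expect_equal(bin_signal(pk, w, bs), oracle_bin_signal(pk, w, bs),
                 tolerance = 1e-12)
  }
})

test_that("binning is linear in signal and translation invariant", {
  set.seed(23)
  pk <- random_peaks(6)
  w <- build_tss_window(list(chrom = "chr1", tss = 900), 150)
  v1 <- bin_signal(pk, w, 10)
  pk2 <- pk
  pk2$signal <- pk2$signal * 2
  expect_equal(bin_signal(pk2, w, 10), 2 * v1)
  for (shift in c(17, 500, -200)) {
    pks <- pk
    pks$start <- pks$start + shift
    pks$end <- pks$end + shift
    ws <- build_tss_window(list(chrom = "chr1", tss = 900 + shift), 150)
    expect_equal(bin_signal(pks, ws, 10), v1)
  }
})

test_that("feature matrices have one row per (gene, cell line) in fixed order", {
  genes <- data.frame(gene_id = c("G2", "G1"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(3000, 1000))
  set.seed(5)
  pbc <- list(b = random_peaks(10), a = random_peaks(10), c = random_peaks(0))
  fm <- build_feature_matrix(pbc, genes, tss_range = 200, bin_size = 10)
  expect_equal(dim(fm$values), c(6L, 40L))
  expect_equal(fm$gene_id, rep(c("G1", "G2"), each = 3))
  expect_equal(fm$cell_line, rep(c("a", "b", "c"), 2))
  # permuting input gene order leaves each sample's row unchanged
  fm2 <- build_feature_matrix(pbc, genes[2:1, ], tss_range = 200,
                              bin_size = 10)
  expect_identical(fm$values, fm2$values)
  expect_identical(fm$sample_ids, fm2$sample_ids)
  # all-empty peak sets give a zero matrix of the right shape
  empty <- lapply(pbc, function(p) p[0, ])
  fm0 <- build_feature_matrix(empty, genes, 200, 10)
  expect_equal(fm0$values, matrix(0, 6, 40))
})

test_that("a gene on a chromosome absent from a peak set gets a zero row", {
  genes <- data.frame(gene_id = "G1", chrom = "chrX", strand = "+",
                      tss = 1000)
  set.seed(6)
  pbc <- list(cl1 = random_peaks(5, chrom = "chr1"))
  expect_message(fm <- build_feature_matrix(pbc, genes, 100, 10),
                 "absent")
  expect_equal(fm$values, matrix(0, 1, 20))
})

test_that("feature matrix TSV serialization round-trips", {
  sim <- small_sim(seed = 31, n_genes = 5L, n_cell_lines = 3L)
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(sim$fm_tf, f)
  back <- read_feature_matrix(f)
  expect_equal(back$values, sim$fm_tf$values, tolerance = 1e-12)
  expect_identical(back$sample_ids, sim$fm_tf$sample_ids)
  expect_equal(back$tss_range, sim$fm_tf$tss_range)
})

test_that("align_views restricts all inputs to common samples in one order", {
  sim <- small_sim(seed = 8, n_genes = 6L, n_cell_lines = 3L)
  fm_tf <- sim$fm_tf
  fm_hm <- sim$fm_hm
  expr <- sim$expression
  # drop different samples from each input
  drop_tf <- seq(1, 18, by = 7)
  keep <- setdiff(seq_len(18), drop_tf)
  fm_tf$values <- fm_tf$values[keep, ]
  fm_tf$sample_ids <- fm_tf$sample_ids[keep]
  fm_tf$gene_id <- fm_tf$gene_id[keep]
  fm_tf$cell_line <- fm_tf$cell_line[keep]
  expr2 <- expr[-c(2, 5), ]
  al <- align_views(fm_tf, fm_hm, expr2)
  expected <- intersect(fm_tf$sample_ids,
                        paste(expr2$gene_id, expr2$cell_line, sep = ":"))
  expect_setequal(al$sample_ids, expected)
  expect_identical(al$fm_tf$sample_ids, al$fm_hm$sample_ids)
  expect_identical(al$sample_ids, al$fm_tf$sample_ids)
  key <- paste(expr2$gene_id, expr2$cell_line, sep = ":")
  expect_equal(al$y, expr2$expression[match(al$sample_ids, key)])
  # identical inputs pass through in full
  al2 <- align_views(sim$fm_tf, sim$fm_hm, expr)
  expect_equal(length(al2$y), 18L)
  # disjoint sets error
  expr3 <- expr
  expr3$gene_id <- paste0("ZZ", expr3$gene_id)
  expect_error(align_views(sim$fm_tf, sim$fm_hm, expr3), "no .*samples")
})
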