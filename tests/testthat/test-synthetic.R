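test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_genes = 8L, n_cell_lines = 4L, seed = 99)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the expression table has one row per (gene, cell line)", {
  sim <- generate_dataset(synthetic_config(seed = 2))
  expect_equal(nrow(sim$expression), 300L)  # 50 genes x 6 cell lines
  expect_false(anyDuplicated(paste(sim$expression$gene_id,
                                   sim$expression$cell_line)) > 0)
  expect_equal(nrow(sim$fm_tf$values), 300L)
  expect_identical(sim$fm_tf$sample_ids,
                   paste(sim$expression$gene_id, sim$expression$cell_line,
                         sep = ":"))
})

test_that("planted effects are recovered exactly from noiseless data", {
  for (s in c(1, 6)) {
    sim <- generate_dataset(synthetic_config(noise_sd = 0, alpha = 1.5,
                                             beta = 0.5, gamma = 2, seed = s))
    gt <- sim$ground_truth
    fit <- lm(sim$expression$expression ~ s_tf * s_hm, data = gt)
    co <- coef(fit)
    expect_lt(abs(co[["(Intercept)"]]), 1e-6)
    expect_lt(abs(co[["s_tf"]] - 1.5), 1e-6)
    expect_lt(abs(co[["s_hm"]] - 0.5), 1e-6)
    expect_lt(abs(co[["s_tf:s_hm"]] - 2), 1e-6)
    expect_equal(gt$noiseless,
                 1.5 * gt$s_tf + 0.5 * gt$s_hm + 2 * gt$s_tf * gt$s_hm,
                 tolerance = 1e-12)
  }
})

test_that("generated files round-trip through the format readers", {
  dir <- tempfile()
  sim <- generate_dataset(synthetic_config(n_genes = 10L, n_cell_lines = 3L,
                                           seed = 5), dir)
  expect_no_warning({
    genes <- read_gene_annotations(file.path(dir, "genes.bed"), "bed6")
    expr <- read_expression_table(file.path(dir, "expression.tsv"))
    pk <- read_narrowpeak(file.path(dir, "peaks", "tf_CL01.narrowPeak"))
  })
  expect_equal(genes$tss, sim$genes$tss)
  expect_equal(genes$strand, sim$genes$strand)
  expect_equal(expr$expression, sim$expression$expression)
  expect_equal(pk$start, sim$peaks$tf$CL01$start)
  expect_equal(pk$signal, sim$peaks$tf$CL01$signal)
})

test_that("re-featurizing the written files reproduces the in-memory matrix", {
  dir <- tempfile()
  sim <- generate_dataset(synthetic_config(n_genes = 6L, n_cell_lines = 3L,
                                           seed = 14), dir)
  genes <- read_gene_annotations(file.path(dir, "genes.bed"), "bed6")
  files <- list.files(file.path(dir, "peaks"), "^tf_", full.names = TRUE)
  pk <- setNames(lapply(files, read_narrowpeak),
                 sub("^tf_(.*)\\.narrowPeak$", "\\1", basename(files)))
  fm <- build_feature_matrix(pk, genes, sim$config$tss_range,
                             sim$config$bin_size, "tf")
  expect_equal(fm$values, sim$fm_tf$values, tolerance = 1e-12)
  expect_identical(fm$sample_ids, sim$fm_tf$sample_ids)
})

test_that("cell-line clusters leave a cosine footprint in the features", {
  for (s in 1:3) {
    sim <- generate_dataset(synthetic_config(seed = s))
    s_cos <- cosine_similarity_matrix(sim$fm_tf)
    cl <- sim$clusters[sim$fm_tf$cell_line]
    gene <- sim$fm_tf$gene_id
    same_gene <- outer(gene, gene, "==") & !diag(nrow(s_cos))
    same_cl <- outer(cl, cl, "==")
    within <- mean(s_cos[same_gene & same_cl])
    between <- mean(s_cos[same_gene & !same_cl])
    expect_gt(within, between)
  }
})

test_that("the null generator shares structure but carries no signal", {
  cfg <- synthetic_config(n_genes = 10L, n_cell_lines = 4L, seed = 77)
  null <- generate_null_dataset(cfg)
  full <- generate_dataset(cfg)
  # identical feature files, different expression
  expect_identical(null$fm_tf$values, full$fm_tf$values)
  expect_identical(null$peaks$hm$CL02, full$peaks$hm$CL02)
  expect_gt(cor(full$expression$expression, full$ground_truth$s_tf), 0.3)
  expect_lt(abs(cor(null$expression$expression, null$ground_truth$s_tf)), 0.3)
  expect_null(null$ground_truth$noiseless)
  expect_identical(generate_null_dataset(cfg)$expression,
                   null$expression)
})

test_that("impossible window placement names the remedy", {
  expect_error(generate_dataset(synthetic_config(n_genes = 50L,
                                                 chrom_length = 10000)),
               "increase chrom_length")
})
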