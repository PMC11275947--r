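# genet

Gene expression prediction from two regulatory views — transcription-factor
(TF) binding and H3K27ac histone acetylation — using per-view graph
convolutional networks over cosine-similarity sample networks, fused
through a cross-feature discovery tensor.

## The problem

How much of a gene's expression is explained by the regulatory signal
sitting right at its promoter? Given called ChIP-seq peaks for TF binding
and for H3K27ac across a panel of cell lines, plus an expression value per
(gene, cell line), `genet` asks whether a model that sees both marks *and*
the similarity structure among samples predicts expression better than
standard regressors on the same features. It is aimed at regulatory
genomics researchers working with ENCODE-style inputs: narrowPeak files per
cell line and view, BED6/GTF gene annotations, and a TSV expression table.

## The model

For each (gene, cell line) sample, peak signal is binned in a window
`[TSS - R, TSS + R)` (default R = 200 bp, 10 bp bins), one matrix per view:

* per view, a weighted sample network with cosine similarity
  `S_ij = <x_i, x_j> / (||x_i|| ||x_j||)`, sparsified and normalized as
  `Â = D̃^{-1/2}(A + I)D̃^{-1/2}`;
* per view, a two-layer GCN `softmax(Â ReLU(Â X W1) W2)` classifying
  expression into c = 5 training-quantile bins, giving a soft label vector
  `p` per sample;
* fusion by the cross-feature discovery tensor `C = p_tf ⊗ p_hm` (a c x c
  label-correlation matrix per sample), flattened and regressed to
  expression by a small ReLU network, trained end to end by backpropagation
  with early stopping on validation MSE.

Evaluation follows a randomized 70/15/15 train/validation/test split, with
MSE, RMSE, MAE, R², and Pearson r; tuning uses a 3 x 3 grid (learning rate
0.001/0.01/0.1 x hidden size 64/128/256) and a TSS window sweep over
{200, 500, 1000, 2000} bp. Five baselines (linear regression, 100-tree
random forest, 100-stage GBM, RBF-kernel SVM, 64-unit neural network) run
on the concatenated view features under the identical split.

## Worked example

Everything runs on a built-in synthetic generator that emulates the shape
of a matched ENCODE panel (peaks per view per cell line, gene BED,
expression TSV) with a planted regulatory signal
`y = s_tf + s_hm + s_tf * s_hm + noise`:

```r
library(genet)

sim   <- generate_dataset(synthetic_config(seed = 1))   # 50 genes x 6 cell lines
masks <- split_samples(nrow(sim$fm_tf$values), seed = 1)
fit   <- genet_fit(sim$fm_tf, sim$fm_hm, sim$expression$expression,
                   masks, seed = 1)
fit
#> Two-view GCN expression model
#>   300 samples, 5 expression classes, hidden size 128
#>   best epoch 168 (val MSE 0.02467)
#>   test: MSE 0.06324, RMSE 0.2515, MAE 0.1694, R2 0.9125

run_all_baselines(concat_views(sim$fm_tf, sim$fm_hm),
                  sim$expression$expression, masks, seed = 1, fit = fit)
#>       model     MSE   RMSE    MAE     R2
#> 1    linreg 0.07178 0.2679 0.1780 0.9007
#> 2        rf 0.13417 0.3663 0.2248 0.8144
#> 3       gbm 0.06791 0.2606 0.1770 0.9061
#> 4   svm_rbf 0.12755 0.3571 0.1975 0.8236
#> 5 simple_nn 0.09688 0.3113 0.1853 0.8660
#> 6     genet 0.06324 0.2515 0.1694 0.9125
```

The fitted model explains 91% of held-out expression variance and posts the
lowest test MSE of the six models: the planted TF x H3K27ac interaction —
expression needs *both* marks — is what the purely linear baseline cannot
represent. `plot(fit)` draws the predicted-versus-actual and residual
diagnostics; `predict(fit, "test")`, `residuals(fit)` and `coef(fit)`
expose the usual surface.

A shell entry point wraps the same functions
(`Rscript inst/cli/genet.R simulate|featurize|build-graph|train|evaluate|baselines|grid-search|sweep-tss ...`);
every run writes a JSON manifest (config, seed, input checksums) from which
it can be reproduced.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch under the given seed — simulates
the dataset to standard-format files, re-reads and featurizes them, fits
the model, evaluates it against all five baselines on one shared split, and
verifies exact recovery of the planted effect weights at zero noise — then
writes the JSON report to `--out`.
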