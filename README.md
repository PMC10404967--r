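# respsound

Cycle-level classification of lung sounds in R.

Auscultation data is analyzed one **respiratory cycle** at a time: a
segment of a stethoscope recording labelled by the presence of
**crackles** (brief exponentially damped transients) and/or **wheezes**
(sustained musical tones at 100–1000 Hz). `respsound` implements a
family of decomposition-driven classification strategies for this
problem, each built from reusable, individually tested parts:

* **Signal decomposition** — empirical mode decomposition (EMD) with a
  paired-noise ensemble variant (opposite-sign white-noise pairs whose
  injected noise cancels exactly in the ensemble mean), and variational
  mode decomposition (VMD) solved by ADMM:

  $$\min_{\{b_k\},\{c_k\}} \sum_{k=1}^{K}
    \Big\lVert \partial_t\big[(\delta(t)+\tfrac{j}{\pi t}) * b_k(t)\big]
    e^{-j c_k t}\Big\rVert_2^2
    \quad \text{s.t.} \quad \sum_k b_k = d,$$

  with automatic selection of the mode number \(K\): the smallest
  \(K\) whose signal-vs-reconstruction similarity (Euclidean,
  Manhattan, Chebyshev, Jaccard or Dice form, all mapped into
  \([0,1]\)) crosses a threshold (default 0.99).
* **Features** — multivariate autoregressive (Granger) coefficients
  \(X_k = (C^\top C)^{-1} C^\top y_k\) with the decomposition modes as
  channels, plus six per-mode descriptors; SVM-based recursive feature
  elimination ranked by squared weights \(w_j^2\).
* **Metaheuristics** — Harris hawks optimization (escape energy
  \(E = 2E_0(1 - t/T)\), Levy-flight dives), differential evolution
  with a fitness-adaptive scale \(S_q = 1/(1+\tanh 2\,\mathrm{CP}_q)\in(0.5,1]\),
  their nested hybrid (the hawks tune the DE controls), grey wolf and
  grasshopper optimizers — continuous and binary (feature-mask) modes.
* **Classifiers** — extreme learning machine
  (\(\hat\beta = H^{+}T\)), K-SVD dictionary learning with
  sparse-representation classification by class-wise residual ratio
  \(\arg\min_i \lVert \tilde M z - D\varphi_i(\alpha)\rVert^2 /
  \lVert\varphi_i(\alpha)\rVert^2\), a domain-adapting ("realm
  revamping") variant with graph-Laplacian + PCA subspace projections,
  a KL-sparsity autoencoder, and a grey-wolf-tuned Gaussian SVC.
* **Pipelines** — six end-to-end strategies under seeded stratified
  10-fold cross-validation with sensitivity/specificity/accuracy
  reports, plus a synthetic crackle/wheeze/normal generator so that
  everything is testable without downloading clinical data.

Readers for the de-facto annotation dialect of public lung-sound
databases (mono WAV + whitespace-delimited cycle rows
`start end crackle wheeze`) are included.

## Worked example

Generate a small balanced three-class dataset, pick the VMD mode number
for one cycle, and cross-validate the VMD + extreme-learning-machine
strategy:

```r
library(respsound)

cfg <- synth_config(n_per_class = 15, snr_db = 10, seed = 42)
ds  <- synthesize_dataset(cfg, label_scheme("three_class"))

cyc <- ds[[1]]
cyc$label
#> [1] "wheeze"
cyc$signal
#> <audio_signal> synth:wheeze:seed2565206: 4000 samples @ 4000 Hz (1.000 s)

sel <- select_vmd_modes(normalize_minmax(cyc$signal),
                        metric = "manhattan", threshold = 0.99, K_max = 6)
sel$K_selected
#> [1] 6
round(sel$similarity_trace, 4)
#>      2      3      4      5      6
#> 0.8913 0.9706 0.9717 0.9872 0.9925

res <- run_strategy(ds, strategy_config("dmvmd_elm", cv_folds = 5, seed = 42))
res
#> <cv_result> 5 folds: accuracy 88.89%, sensitivity 88.89%, specificity 94.44%

compute_metrics(cycle_labels(ds), res$predictions, label_scheme("three_class"))
#> <metrics_report> n=45, overall accuracy 88.89%
#>    class TP TN FP FN sensitivity specificity accuracy
#>   normal 15 29  1  0   100.00000    96.66667 97.77778
#>  crackle 13 28  2  2    86.66667    93.33333 91.11111
#>   wheeze 12 28  2  3    80.00000    93.33333 88.88889
```

The similarity trace shows the mode-number scan: reconstruction
similarity climbs with each trial `K` and crosses the 0.99 threshold at
`K = 6` for this noisy wheeze cycle. The cross-validated report gives
per-class one-vs-rest sensitivity (`TP/(TP+FN)`), specificity
(`TN/(TN+FP)`) and accuracy as percentages; on this deliberately tiny
dataset (15 cycles/class, 5 folds) the strategy reaches 88.9% overall.
The packaged acceptance benchmark (50 cycles/class, 10 folds) is run by
the test suite, where every strategy is required to reach at least 90%.

A command-line wrapper covering synthesis, decomposition, evaluation
and pipeline runs ships in `inst/cli/respsound`:

```sh
Rscript inst/cli/respsound synth --scheme three_class --n 50 --seed 7 --out cycles/
Rscript inst/cli/respsound run --strategy dmvmd_elm --n 15 --seed 42 --out results/
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models,
parameter defaults and units, what the synthetic generator does and
does not emulate, numerical edge-case handling, and the design
decisions taken where the source methods were under-specified.
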