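# scSemiLab

Semi-supervised cell-type annotation for single-cell RNA-seq, for the common
situation where an experiment yields thousands of expression profiles but
expert labels exist for only a small fraction of them. scSemiLab trains a
compact annotator network that uses *both* halves of the data: the unlabeled
cells first shape the representation through contrastive pretraining and then
participate in supervised-style training through pseudo-labels generated by
clustering, each weighted by a learned confidence.

## Method in brief

Given a labeled set $S = \{(X^s, Y^s)\}$, $Y^s \in \{1,\dots,C\}^{N_s}$, and
an unlabeled set $T = \{X^t\}$ on the same $D$ genes, a four-layer MLP
$\Phi$ (ReLU, hidden widths 100–50–25, softmax head) is trained in three
stages:

1. **Contrastive pretraining** on $T$: weak (Gaussian-noise) and strong
   (random-masking) views of each batch are pulled together by the NT-Xent
   loss $\mathcal L_c$ over cosine similarities of the second-layer
   embeddings $\phi_2$, temperature $\tau = 0.5$.
2. **Supervised warm-up** on $S$: cross-entropy $\mathcal L_s$.
3. **Pseudo-label consistency training**: every epoch, class centers
   computed from labeled embeddings seed a spherical K-means
   (cosine distance $\tfrac12(1 - \cos)$, unit-norm centers) over the
   unlabeled embeddings, so cluster index = class label. A confidence
   estimator $e(x) \in [0,1]$ (trained with $\Phi$ frozen, and vice versa)
   weights each pseudo-label inside the consistency loss
   $\mathcal L_u = \overline{e(x)\,[H(\hat y, \Phi(T_w x)) + H(\hat y, \Phi(T_s x))]}$,
   and $\Phi$ minimizes $\mathcal L_s + \lambda \mathcal L_u$ ($\lambda = 0.5$).

Default schedule: stage epochs (100, 200, 150), annotator Adam learning
rates (5e-4, 1e-4, 5e-5), estimator learning rate 1e-4. Evaluation reports
accuracy and macro-F1 (imbalance-robust). The package also ships the
standard preprocessing pipeline (cell/gene filtering, library-size
normalization + log1p, HVG selection by standard deviation, unit-variance
scaling), stratified-CV and label-fraction experiment designs, a
negative-binomial synthetic-data generator with dropout for fully offline
benchmarking, and CSV/TSV + 10X-style MatrixMarket readers/writers.

## Worked example

```r
library(scSemiLab)

fx   <- make_benchmark_fixture("easy", seed = 1)   # 2,000 cells, 5 types, 10% labeled
plan <- training_plan(stage_epochs = c(20L, 40L, 30L), seed = 1)
fit  <- fit_semisup(fx$labeled, fx$unlabeled, plan)
pred <- predict(fit, fx$unlabeled$matrix)
score_annotation(fx$truth, pred$labels_idx, fx$class_names)
#> EvaluationReport: 1799 cells, accuracy 97.832%, macro-F1 97.807%
```

The fixture holds 201 labeled and 1,799 unlabeled cells after preprocessing;
the report says that, training on the 201 labeled cells plus the unlabeled
pool, 97.8% of the held-out (unlabeled) cells are assigned their true type,
with a macro-F1 of 97.8% (the unweighted mean of per-class F1, so rare types
count as much as common ones). The same data trained supervised-only
(`ablation = c("no_pretrain", "no_consistency")`) reaches 64.0% accuracy
under this short schedule — the unlabeled cells carry most of the signal.

## Command line

```sh
Rscript inst/cli/scsemilab fit --matrix X.csv --labels labels.tsv \
    --labeled-frac 0.1 --seed 7 --out model.json
Rscript inst/cli/scsemilab predict --model model.json --matrix query.csv \
    --out predictions.tsv
Rscript inst/cli/scsemilab simulate --out-matrix sim/ --out-labels sim_labels.tsv
Rscript inst/cli/scsemilab benchmark --p 0.02,0.05,0.1,0.2 --seed 1
```

`--config plan.yaml` (or `.json`) mirrors the `training_plan()`,
`augmentation_config()`, `contrastive_config()` and `preprocess_config()`
fields under the keys `plan:`, `augment:`, `contrastive:`, `preprocess:`.

See `vignettes/semisupervised-annotation.Rmd` for the full model
description, the open design choices and their rationale, what the
synthetic generator does and does not emulate, and known limitations.
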