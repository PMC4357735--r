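# methbind

Predicting in vivo transcription-factor (TF) binding from base-resolution
DNA methylation.

## The problem

ChIP-seq maps where a TF binds, but needs a good antibody and plenty of
fresh material, which rules it out for many clinical samples. Whole-genome
bisulfite sequencing (WGBS) is far easier to collect and carries a strong
indirect signal: bound motif sites sit in a local *hypomethylation dip*,
while the genomic background is close to fully methylated. `methbind`
turns that signal into a supervised predictor of TF binding at
PWM-derived candidate sites, for researchers who have methylation data
(and, for training, ChIP-seq peaks from some reference sample) but no
ChIP-seq in the sample they care about.

## The model

Candidate sites come from a genome-wide PWM scan. Around each candidate
*i* the motif interval is taken as the centre window and ten 30-bp
windows are tiled on each side (21 windows total). In window *j* the
methylated read count follows a binomial whose success probability has a
beta prior:

    x_ij | n_ij, p_j  ~  Binomial(n_ij, p_j)
    p_j | bound       ~  Beta(alpha_j, beta_j)     (one beta per window)
    p_j | background  ~  Beta(alpha', beta')       (one shared beta)

so marginally the counts are beta-binomial. Parameters are fitted by the
method of moments on training candidates labelled by peak containment,
after masking windows with fewer than 5 reads and dropping candidates in
CpG islands. The per-site *methylation score* is the log likelihood
ratio summed over windows with covered CpGs:

    lambda_i = sum_{j : #CG > 0} log [ P(x_ij | n_ij, bound) / P(x_ij | n_ij, background) ]

Higher lambda means a more binding-like methylation pattern. The same
machinery applies independently to CG, non-CpG (CH) and 5hmC contexts.
Methylation scores are combined with static genomic features (motif
log-odds score, mean conservation, distance to TSS, distance to the
nearest other candidate, and binary overlaps with TSS/TES/exon/intron/
CpG-island/repeat annotation) in a random-forest classifier. The
predicted probability of binding is the fraction of trees voting
"bound"; feature contributions are reported as Gini (mean decrease in
impurity) importance, and the tree count can be chosen by the stability
of the out-of-bag error.

No random-forest package is assumed: the forest (CART trees, Gini
splits, bootstrap + OOB, per-split feature subsampling) is implemented
in the package's own C++ code with a deterministic RNG, so a model is
fully reproducible from `(data, seed, n_trees)` and serialises to
versioned JSON for cross-sample reuse.

## Worked example

Everything below is self-contained: the synthetic generator emits a toy
genome with planted motif instances, peaks over 30% of them, and
beta-binomial methylation counts with a dip (0.8 down to 0.2) at bound
sites against a 0.85 background.

```r
library(methbind)

bundle <- simulate_dataset(sim_config(seed = 42))
fit    <- run_train(bundle, seed = 7)        # scan, label, QC, fit, train
pred   <- run_predict(fit$model, bundle, sites = fit$test_sites)
roc_curve(pred$prob_bound, fit$test_sites$label)
```

This prints (numbers from the run above):

```
candidates: 417            # PWM hits at 70% of the maximum score
class counts (train): unbound 144, bound 65   (after QC)
OOB error: 0
AUC: 0.9963                # held-out half of the candidates
```

The fitted methylation model recovers the planted dip — its per-window
binding means run `0.83 0.74 ... 0.26 0.16 0.26 ... 0.82` against a
background mean of `0.848` — and the Gini importances identify the CG
methylation score as the dominant feature (0.887, against 0.041 for
distance-to-TSS and 0.016 for the motif score). The top-ranked test
predictions look like:

```
   site_id    chrom  start  end    motif_score meth_score_cg prob_bound
   site_00184 chr1  533916 533931     28.76         87.76       0.910
   site_00374 chr2  484755 484770     28.76         84.71       0.910
```

`meth_score_cg` is lambda above; `prob_bound` is the forest vote
fraction. A model saved with `save_model()` can be loaded in another
session (or applied to another sample's bundle) and yields bit-identical
predictions.

A thin command-line wrapper over the same functions lives at
`inst/scripts/methbind.R`, with subcommands `scan`, `train`, `predict`,
`evaluate` and `simulate` driven by a flat YAML config; each run writes
a JSON provenance record.

## Acceptance script

`scripts/acceptance.R` recomputes the package's structural acceptance
quantity from scratch against the installed package — it builds the
default window layout for a motif placed in the interior of a synthetic
chromosome and reports the resulting window count:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
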