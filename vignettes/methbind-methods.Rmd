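---
title: "methbind: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methbind: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbind)
```

This vignette is the package's own account of its statistics and of the
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The generative picture

TF binding leaves a footprint in bisulfite data: motif sites that are
actually bound sit in a local hypomethylation dip, whereas unbound motif
matches look like the genomic background, which in most mammalian
contexts is close to fully methylated. `methbind` models the *counts*,
not smoothed methylation levels, because at realistic coverage the
binomial noise on a per-CpG proportion is far from negligible.

For candidate site $i$ and window $j$ ($j = 1, \dots, 2f+1$ with $f$
flank windows per side), let $x_{ij}$ be methylated reads and $n_{ij}$
total reads summed over the covered CpGs in the window. Then

$$x_{ij} \mid n_{ij}, p_j \sim \mathrm{Binom}(n_{ij}, p_j), \qquad
  p_j \mid \text{bound} \sim \mathrm{Beta}(\alpha_j, \beta_j), \qquad
  p_j \mid \text{background} \sim \mathrm{Beta}(\alpha', \beta').$$

Bound sites get a separate beta per window — that is what encodes the
dip shape — while background windows share a single beta, reflecting the
assumption that away from binding the methylation level is homogeneous.
The marginal distribution of the counts is beta-binomial, computed
through log-gamma; `betabinom_logpmf()` is checked against numerical
quadrature to $10^{-10}$ in the tests.

The methylation score of a site is the log likelihood ratio

$$\lambda_i = \sum_{j\,:\,\#\mathrm{CG}>0}
  \log \frac{P(x_{ij} \mid n_{ij}, \text{bound})}
            {P(x_{ij} \mid n_{ij}, \text{background})},$$

summed only over windows containing at least one covered cytosine;
windows without data contribute exactly zero rather than being imputed.
$\lambda$ is additive over windows, invariant to window order, and
identically zero when the two hypotheses coincide.

## Window geometry

Defaults: the raw motif interval is the centre window and $f = 10$
flank windows of 30 bp tile each side, 21 windows in total. 30 bp
balances parameter-estimation accuracy (enough CpGs per window) against
spatial resolution of the profile; `window_size = 20` is a supported
alternative and produces a valid model, not necessarily identical
scores. Windows that run past a chromosome end are clipped, and windows
falling entirely outside are dropped *but keep their index*, so
window-specific parameters always align across sites.

Two open points were settled as follows: the centre window uses the raw
motif width (not a fixed width), and flank windows anchor on the motif
edges. Both keep the layout a gap-free tiling for any motif length.

## Training QC and fitting

Before fitting, training windows with fewer than `min_reads = 5` total
reads are masked, and candidates whose motif interval overlaps a CpG
island are removed entirely — CpG islands are constitutively
hypomethylated, so they would teach the model a dip that has nothing to
do with binding. Both filters apply to training only; at prediction
time every covered window is scored.

Parameters are estimated by the method of moments on the per-site
proportions $\hat p = x/n$. A subtlety matters here: the sample
variance $S$ of $\hat p$ mixes the between-site beta variance
$\sigma^2$ with binomial counting noise. Using $S$ directly
overestimates the concentration $\kappa = \alpha + \beta$ by a factor
of roughly $1 + \kappa/\bar n$ — about 10% at coverage 100 for
$\mathrm{Beta}(2,8)$ — so the package removes the binomial component
first, via the moment identity

$$E(S) = \sigma^2 (1 - \bar c) + m(1-m)\,\bar c, \qquad
  \bar c = \operatorname{mean}(1/n_i),$$

and sets $\kappa = m(1-m)/\sigma^2 - 1$, $\alpha = m\kappa$,
$\beta = (1-m)\kappa$. The window mean $\alpha/(\alpha+\beta) = m$ is
unaffected by the correction. This was a deliberate design choice over
the naive proportion-based MOM, whose coverage-dependent bias would make
a "recover $(\alpha, \beta)$ within 10%" check unreliable at exactly the
coverages WGBS produces.

Degenerate slices are clamped rather than allowed to error out:
$\sigma^2 \le 0$ (under-dispersed, including zero sample variance) sets
$\kappa = 10^4$; $\sigma^2 \ge m(1-m)$ (over-dispersion beyond beta
support) sets $\kappa = 0.01$; $m$ is clipped to
$[10^{-6}, 1-10^{-6}]$. A window with fewer than two usable bound
observations inherits the background parameters, with a warning, so the
score stays defined everywhere. The background is pooled from *all*
windows of unbound training candidates (not from a genome-wide sample):
it keeps the two hypotheses conditioned on the same candidate
population.

## Candidate selection and labelling

The PWM is the standard log-odds matrix
$\log_2 \frac{(c_{bk} + s\,q_b)/(N_k + s)}{q_b}$ with pseudocount
$s = 0.8$ split proportionally to the background $q$; the default
background is the genome's mononucleotide frequencies. Both strands are
scanned, reverse hits are reported on forward coordinates, windows with
non-ACGT bases are skipped, and a locus passing on both strands keeps
the higher-scoring one. Thresholds are given as absolute scores or as a
fraction of the maximum attainable score; `choose_threshold()`
operationalises "aim for a target number of candidates" by evaluating a
100-point grid between 50% and 100% of the maximum score.

A candidate is labelled bound when its motif interval is fully
contained in a peak. Containment (rather than 1-bp overlap) is the
stricter reading of "covered by a peak" and is what the synthetic
generator's truth table round-trips against; `min_overlap` relaxes it
when peaks are narrow.

## The classifier

The feature vector per candidate: motif score, one methylation score
per available context, mean conservation over the motif (missing
positions count 0, so unscored regions stay in the set), distance from
the motif midpoint to the nearest TSS, distance to the nearest other
candidate, and six binary annotation overlaps. Undefined distances
(lone candidate on a chromosome, empty reference) are encoded by a
large finite sentinel ($10^9$) — trees handle it as "nothing nearby" —
and the feature schema is stored with the model and enforced at
prediction time.

Because no random-forest implementation is available as a dependency,
the forest is implemented in the package's C++ code: CART trees grown
to purity (node size 1) on bootstrap samples, Gini-impurity splits over
`mtry = floor(sqrt(p))` randomly chosen features per split, vote-
fraction probabilities, and Gini importance accumulated as the
node-weighted impurity decrease, normalised to sum to one. The RNG is a
self-contained splitmix64 stream, so results are identical across
platforms given the seed. A stratified (`balanced`) bootstrap is
available but off by default; candidate sets are naturally imbalanced
and the default mirrors training on the data as it comes.

The number of trees defaults to 500; `select_n_trees()` implements the
out-of-bag stability rule (grid 100/200/500/1000, tolerance 0.005,
first grid point whose OOB error changes by less than the tolerance to
the next, grid maximum with a warning otherwise).

## Evaluation

ROC curves sweep all distinct score thresholds with ties grouped into a
single step; AUC is the trapezoidal integral, which the tests verify
equals Mann–Whitney pair counting with ties counted half.
Precision-recall uses the step-function (non-interpolated) average
precision. `repeated_split_evaluation()` repeats the half-split
train/predict cycle over seeds and summarises the AUC distribution.

## The synthetic world

The generator's defaults *are* the conditions the method assumes, not
tuning knobs: 500 planted motif instances on 2 × 600 kb chromosomes,
30% of them covered by peaks extending 150 bp beyond the motif, a
21-window methylation-mean profile dipping linearly 0.8 → 0.2 → 0.8,
background mean 0.85, beta concentration $\kappa = 20$, and Poisson
coverage with mean 20 reads per cytosine. Where no value was dictated,
the choices were made once: cytosines are placed uniformly at density
0.05/bp (regulatory neighbourhoods are CpG-enriched relative to the
~1% genomic average, and at 30-bp windows this yields the 1–2 covered
CpGs per window the model needs); the planted consensus is 15 bp with a
5% per-base mutation rate, giving a realistic spread of motif scores;
annotation tracks and the conservation track are random and carry no
signal, so they act as honest noise features.

What the generator does *not* emulate: CpG clustering and sequence
composition, read-level artefacts (bisulfite conversion failure,
mapping bias), correlated methylation between neighbouring CpGs, and
any dependence of the annotation features on binding. A green
end-to-end test therefore establishes that the pipeline recovers the
assumed statistical structure — beta-binomial dips against a
near-fully-methylated background — not that real-genome performance
will match; conversely the null bundle (dip replaced by background)
checks that nothing in the pipeline manufactures signal out of noise.

## Numerical and convention choices

* All internal coordinates are 0-based half-open; 1-based dialects
  (fixedStep WIG) are converted on read, and the CpG-table reader has a
  `one_based` switch for foreign tables.
* Model files are versioned JSON with numbers written at 17 significant
  digits, so save/load round-trips reproduce bit-identical predictions.
* Tied vote fractions of exactly 0.5 classify as unbound when computing
  OOB error; tied ROC scores are grouped, not broken.
* Readers fail loudly with line numbers on malformed rows; they never
  silently truncate.

## Known limitations

* The forest is adequate for the feature-table sizes this method
  produces (tens of features, up to a few hundred thousand rows) but is
  not a tuned large-scale implementation; there is no probability
  calibration beyond vote fractions.
* Methylation contexts are fitted independently; correlations between
  5mC, 5hmC and CH signals are left to the forest to exploit.
* Background parameters come from unbound candidates of the same scan,
  so a grossly mis-set scan threshold (flooding the candidate set with
  random loci) shifts the background model with it.
* `distance_to_nearest` and the feature assembly are linear scans per
  chromosome; they are fast at desk scale but would want interval trees
  for whole-genome candidate sets in the hundreds of thousands, which
  the interval machinery (IRanges) already supports if needed.
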