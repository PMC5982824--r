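---
title: "Classifying selective sweeps from unphased genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying selective sweeps from unphased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sweepimage)
```

## The problem

A completed selective sweep — the fixation of a beneficial allele — leaves a
localized footprint in nearby polymorphism: reduced diversity, a skewed
frequency spectrum, extended homozygosity and elevated linkage
disequilibrium. Two complications make calling sweeps from that footprint
hard. First, sweeps from standing variation ("soft" sweeps, starting from a
variant already segregating at frequency $f$) leave weaker, qualitatively
different signatures than sweeps of new mutations ("hard" sweeps). Second,
regions *flanking* a hard sweep can mimic the signature of a soft or partial
sweep (the "soft shoulder"), so any classifier must see the spatial context
of a window, not just the window itself.

`sweepimage` addresses both issues for **unphased diploid genotype data**. A
region is divided into 11 equal subwindows; 12 summary statistics are
computed in each; each statistic's row is normalized to its spatial
distribution across subwindows; and the resulting $12 \times 11$ "feature
image" is classified by a convolutional network into five classes: `hard`,
`soft`, `linkedHard`, `linkedSoft`, or `neutral`, where the class describes
the **central** subwindow.

## The 12 statistics

Writing $x_{ki} \in \{0, 1, 2\}$ for the alternate-allele count of
individual $k$ at site $i$:

1. **SFS block** — $\pi$ (pairwise diversity), Watterson's
   $\hat\theta_w$, and Tajima's $D$, all computable from per-site allele
   counts without phase. No polarization is required by any row.
2. **Genotype-distance block** — the genotype distance
   $g_{kl} = \sum_i \mathbf{1}\{x_{ki} \ne x_{li}\}$ is a lower bound on the
   sequence distance between two individuals. Its distribution over all
   $\binom{n}{2}$ pairs compresses haplotype structure; we use its
   **variance, skewness and kurtosis** (population moments; kurtosis is
   non-excess $m_4/m_2^2$; a constant distribution reports $(0,0,0)$).
3. **Diplotype block** — treating each multilocus genotype vector as an
   entity, we count distinct vectors (`nDiplos`) and compute the diplotype
   analogs of haplotype homozygosity: $J_1 = \sum_i p_i^2$,
   $J_{12} = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$, and
   $J_2/J_1 = (J_1 - p_1^2)/J_1$, with $p_1 \ge p_2 \ge \dots$ the sorted
   diplotype frequencies.
4. **LD block** — genotypic $r^2$ (squared Pearson correlation of genotype
   columns, the unphased analog of gametic $r^2$) feeds Kelly's ZnS (mean
   $r^2$ over site pairs) and $\omega_{\max}$ (within- vs between-block LD
   contrast, maximized over split points).

## The spatial normalization

For each statistic row $x = (x_1, \dots, x_{11})$: if $\min(x) < 0$ the row
is first shifted by $-\min(x)$; then each entry is divided by the row sum.
Each row becomes the *share* of the statistic falling in each subwindow — a
probability vector. Rows that are identically zero after the shift carry no
spatial information and are set to the uniform $1/11$. The transform is
scale-free: multiplying a non-negative row by any $c > 0$ leaves the image
unchanged, which is what lets a classifier trained at one physical scale be
applied at another (the spatial pattern depends on the ratio of
recombination to selection, not on absolute window size).

## Training data: the built-in simulator

Supervised classification needs labeled examples, which come from a
**rescaled forward Wright–Fisher simulator** (`sim_config()`,
`simulate_replicate()`, `build_training_set()`):

* Bitset genomes over `L = 2200` discrete sites; per-generation Poisson
  mutation and crossover; diploid individuals; fitness-proportional parent
  sampling with additive selection ($w = 1 + s \cdot g/2$ for $g$ copies).
* **Hard sweeps**: a single copy is injected at the selected site and the
  run is conditioned on fixation by rejection (re-injection on loss, with a
  retry budget).
* **Soft sweeps**: a single copy is injected and drifts **neutrally** until
  it reaches the drawn starting frequency $f \sim U(0, 0.2)$; only then is
  selection switched on. The standing variant therefore carries a genuine
  neutral haplotype background rather than being painted onto random
  chromosomes.
* After fixation the population evolves neutrally for $\tau \cdot 4N$
  generations before $n$ chromosomes ($n/2$ diploid individuals, both
  chromosomes each) are sampled.
* **Classes**: `hard`/`soft` place the selected site at the center of the
  central subwindow; `linkedHard`/`linkedSoft` place it at the center of one
  of the 10 flanking subwindows (uniformly); `neutral` runs the same
  demography without selection.

### Priors and defaults

| parameter | default | meaning |
|---|---|---|
| $\alpha = 2Ns$ | $U(250, 2500)$ ("moderate"); $U(25,250)$ weak; $U(2500,25000)$ strong | scaled selection strength |
| $\tau$ | $U(0, 0.025)$ (constant size); $U(0, 0.0004)$ (growth) | time since fixation, $4N$ units |
| $f$ | $U(0, 0.2)$ | soft-sweep starting frequency |
| $n$ | 60 chromosomes (30 diploids) | sample size |
| $\theta = 4N\mu$ | 110 per region | gives roughly 40–60 segregating sites per subwindow at $n = 60$ |
| $\rho = 4Nr$ | 550 per region | sized so a moderate sweep's footprint spans a few subwindows |
| $N$ | 100 diploids (rescaled) | simulator population size |
| burn-in | $10N$ generations | neutral equilibration |

$\theta$ and $\rho$ are package choices, not published values: the
simulations behind the original method used command lines that are not
reproduced in the main text of the literature, so the generator is
calibrated to carry comparable per-subwindow information
($\approx 45$–$50$ segregating sites) with $\rho/\theta = 5$, a ratio in
the range used by coalescent training sets in this literature.

### What rescaling does and does not preserve

Holding $\alpha$, $\theta$, $\rho$ fixed while shrinking $N$ keeps the
drift–selection–recombination balance of the coalescent limit, so class
signatures are comparable at a small fraction of the cost. Two distortions
remain. (i) For the strongest $\alpha$ values, $s = \alpha/2N$ exceeds 1 and
a sweep completes within a couple of generations; the discreteness floor
then allows relatively more recombination during the sweep than the
continuum predicts, making very strong hard sweeps look slightly softer and
wider than they should. (ii) Sampling 30 of 100 diploids is a non-trivial
sample fraction. Both effects blur class boundaries relative to training
data drawn from a large-population coalescent, which is visible as reduced
multiclass accuracy in the strong- and weak-selection experiments; the
sweep-versus-unselected task (recall, false positive rate, AUC) is much
less affected. The growth demography is a two-epoch caricature (ancestral
size $N/\text{fold}$, instantaneous growth `duration` before sampling)
sufficient to reproduce the rare-variant excess that strong growth imprints
on neutral data.

The generator also does not emulate: background selection, partial or
recurrent sweeps, migration, sequencing error, or genotype-calling
uncertainty. Passing tests therefore demonstrate correctness of the method
on idealized completed-sweep data, not robustness to those processes.

## The classifier

`build_cnn()` constructs a three-branch convolutional network over the
$12 \times 11 \times 1$ image. Branch one applies two $3 \times 3$
convolutions; branches two and three apply two $2 \times 2$ convolutions
dilated $1 \times 3$ and $1 \times 4$ respectively, so their receptive
fields link subwindows at larger horizontal distances. Each branch is
conv–conv–maxpool–dropout; the flattened branches are concatenated and fed
through two dense layers with dropout onto a five-way softmax. All
convolutions use ReLU activations and "same" zero padding (a "valid"
12-row-filter variant, which removes any dependence on the order of the
statistic rows, is available through `cnn_spec()`).

Defaults (all exposed): 16 filters per convolution, dense widths 64 and 32,
dropout 0.25 after pooling and 0.5 between dense layers, Adam with step
size $10^{-3}$, batch 32. These are conventional settings sized for this
small input; at the training-set sizes used here the network is
data-limited rather than capacity-limited (it tracks the Extra-Trees
baseline closely), so larger layers were not adopted. Training stops when
validation accuracy has failed to improve by at least 0.001 for 5
consecutive epochs, restoring the best-epoch weights; in practice runs stop
well under 40 epochs. The engine is written in R as gather + BLAS matrix
products, with gradients verified against finite differences in the test
suite.

`train_extratrees()` fits the Extra-Trees baseline (via `ranger`, random
split points, no bootstrap) on the flattened 132-vectors for comparison.

Binary sweep detection uses the scalar score $P(\text{hard}) +
P(\text{soft})$; `evaluate_classifier()` reports multiclass accuracy, the
row-normalized confusion matrix, sweep recall, the false positive rate
(unselected examples called `hard` or `soft`), the ROC curve and its
rank-based AUC, and — when sweep positions are known — the fraction of each
predicted class by true sweep offset.

## Numerical choices and degenerate inputs

* Tajima's $D$ returns 0 when undefined ($S = 0$ or fewer than 4 called
  chromosomes): the normalization needs finite entries and a flat row is
  the correct null.
* With missing genotypes: per-site called-chromosome counts for the SFS
  block (per-site $a_1$); pairwise-complete semantics for $g_{kl}$ and
  $r^2$; individuals with any missing call in a window are excluded from
  the diplotype spectrum; sites missing in more than 25% of individuals are
  dropped at VCF read time. $r^2$ pairs undefined after restriction are
  skipped, never zero-filled.
* $\omega_{\max}$ requires at least 6 polymorphic sites and scans splits
  $l \in [3, S-3]$; splits with a zero between-block sum are skipped, and 0
  is returned if no valid split remains, so no infinities reach the
  normalization.
* Empty subwindows report documented degenerate values (zeros; `nDiplos`
  $= 1$ and $J_1 = J_{12} = 1$ since all individuals share the empty
  genotype) and all-zero rows become uniform.
* Diploidization pairs consecutive chromosomes $(2k, 2k+1)$ — coalescent
  samples are exchangeable, so any pairing is valid and this one is
  deterministic.
* VCF positions are converted to 0-based half-open internally; only
  biallelic SNPs are kept; accessibility masks are BED intervals to
  exclude, and sliding-window extraction skips windows in which any
  subwindow has less than 25% of its span accessible.

## Problem sizes

The experiments reproduced by `scripts/acceptance.R` use 500 training and
120 test replicates per class — the lower end of the design the method was
published with (500–2000 per class), chosen so a full four-experiment
reproduction runs in well under half an hour on one CPU. The test suite
runs the same experiments at 250/60 per class plus property-based suites
(oracle equivalence on small random matrices, simplex/scale-invariance,
conservation laws, determinism). Accuracy rises with training-set size, so
the reduced-scale numbers are conservative relative to full-scale runs.

## Known limitations

* Designed for completed sweeps; partial sweeps are out of scope.
* Hard genotype calls only — no genotype likelihoods, no imputation.
* The multiclass accuracies under very strong and very weak selection fall
  short of those reported for coalescent-trained classifiers at
  $n = 2000$ examples per class; the property suites localize the gap to
  the training-data generator (rescaling and parameterization), not to the
  feature vector or classifier implementation.
* The confusion between `linkedSoft` and `neutral` grows as selection
  weakens; for weak selection the binary sweep-versus-unselected score
  remains the reliable output.
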