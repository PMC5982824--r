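# sweepimage

Detection and classification of recent **selective sweeps** from **unphased
diploid genotype data**.

Population geneticists scanning genomes for adaptation face two recurring
obstacles: distinguishing *hard* sweeps (fixation of a new beneficial
mutation) from *soft* sweeps (fixation from standing variation at starting
frequency *f*), and not being fooled by the "soft shoulder" — flanks of a
hard sweep that mimic soft-sweep signatures. Both require looking at a
window *in its spatial context*, and most existing tools additionally
require phased haplotypes, which many datasets lack.

`sweepimage` classifies genomic windows using only genotype calls
(0/1/2 alternate-allele counts):

1. A region is split into **11 subwindows**; the central one is the window
   being classified.
2. In each subwindow, **12 unphased statistics** are computed: π,
   Watterson's θ̂w, Tajima's *D*; the variance, skewness and kurtosis of the
   pairwise genotype-distance distribution *g<sub>kl</sub>* = Σᵢ 1{x<sub>ki</sub> ≠ x<sub>li</sub>};
   the number of distinct multilocus genotypes and the diplotype
   homozygosity statistics J1, J12, J2/J1; and genotypic-LD versions of
   Kelly's ZnS and ω<sub>max</sub>.
3. Each statistic row is normalized to its spatial distribution
   (xᵢ → xᵢ/Σⱼxⱼ, after shifting if any value is negative), giving a
   scale-free **12 × 11 feature image** (132 features).
4. A **three-branch convolutional network** (3×3 filters, plus 2×2 filters
   dilated 1×3 and 1×4; conv–conv–maxpool–dropout per branch; two dense
   layers; softmax) assigns one of five classes: `hard`, `soft`,
   `linkedHard`, `linkedSoft`, `neutral`. An Extra-Trees baseline is
   included for comparison, and *P(hard) + P(soft)* serves as a binary
   sweep score.

Training data come from the built-in **rescaled forward Wright–Fisher
simulator** with selection, recombination, fixation conditioning and
standing-variation soft sweeps — no external simulator is needed — or from
any ms/discoal-style replicate file. Empirical classification reads VCF
(+ optional BED accessibility mask) through sliding windows.

## Worked example

Simulate a balanced training and test set under moderately strong selection
(α = 2Ns ~ U(250, 2500), fixation time τ ~ U(0, 0.025)·4N, n = 60
chromosomes), train the network, and evaluate:

```r
library(sweepimage)

set.seed(1)
ts <- build_training_set(sim_config(), n_per_class = 150, n_test_per_class = 50)
model <- train_cnn(build_cnn(seed = 2), ts, train_config())
ev <- evaluate_classifier(model, ts)
ev
#> <sweep_eval> n = 250 | accuracy 0.452 | sweep AUC 0.924 | recall 0.830 | FPR 0.113
#> confusion (row-normalized):
#>             pred
#> truth        neutral linkedSoft linkedHard soft hard
#>   neutral       0.66       0.12       0.20 0.00 0.02
#>   linkedSoft    0.32       0.18       0.32 0.02 0.16
#>   linkedHard    0.10       0.28       0.48 0.02 0.12
#>   soft          0.18       0.04       0.04 0.14 0.60
#>   hard          0.04       0.02       0.02 0.12 0.80
```

Reading the output: 83% of true sweep windows (hard + soft) are recovered
as sweeps while 11% of unselected windows are miscalled as sweeps; the
binary sweep-versus-unselected AUC is 0.92. The five-class accuracy is much
lower than the binary performance because the residual confusion sits in
scientifically adjacent pairs — `linkedSoft` vs `neutral`/`linkedHard`, and
`hard` vs `soft` — exactly the boundaries that blur as the sweep signal
weakens. (This example uses a deliberately small training set so it runs in
about two minutes; both accuracy and the false positive rate improve
substantially with `n_per_class` — the reproduction script below uses 500
per class.)

Tidy accessors and plots:

```r
glance(ev)            # one-row tibble: accuracy, AUC, recall, FPR
tidy(ev)              # long confusion tibble
autoplot(ev)          # confusion heatmap; autoplot(ev, "roc") for the ROC
tidy(model)           # per-epoch training history
plot_mean_images(ts)  # average feature image per class
```

Classify empirical data:

```r
mask <- read_bed_mask("inaccessible.bed")
geno <- read_vcf_window("cohort.vcf.gz", "3R", 0, 5e6, mask = mask)
fv   <- vcf_feature_windows(geno, window_size = 10000, mask = mask, chrom = "3R")
pred <- predict_sweeps(model, fv)
```

A command-line front end covering the same pipeline (subcommands
`simulate`, `fvec-sim`, `fvec-vcf`, `train`, `predict`, `evaluate`) is
installed at `system.file("scripts", "sweepimage", package = "sweepimage")`.

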