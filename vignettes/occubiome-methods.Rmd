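---
title: "Methods: compositional diversity analysis and occupation classification"
author: "occubiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional diversity analysis and occupation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occubiome)
```

## Scope and model of the data

`occubiome` analyzes annotated metagenomic feature-count tables — species
counts, KEGG pathways, resistance or virulence genes — for cohorts of saliva
and fecal samples labeled by occupation, gender and lifestyle covariates
(smoking, drinking). Sequencing delivers a fixed-size random sample of the
molecules in the underlying ecosystem, so counts are treated as
*compositional*: every analysis operates on relative abundances (or on
zero-replaced compositions), never on raw library sizes.

A table is features × samples of non-negative integers. Preprocessing
removes "undetermined" features (identifiers or lineages matching
*unassigned*/*uncultured*), converts to per-sample proportions, and
optionally restricts to features detected (count > 0) in at least a minimum
number of samples. The prevalence threshold defaults to 10 samples but is a
plain argument: reasonable cohorts can justify anything from "present in a
quarter of samples" upward, and the choice materially changes which rare
features survive, so it is deliberately not hard-coded.

## Alpha diversity and test selection

Within-sample diversity is the Shannon index in log base 2,
$H = -\sum_i p_i \log_2 p_i$, maximal at $\log_2 m$ for a uniform
composition. Group comparisons use a gated test choice that mirrors common
practice in this literature: Shapiro–Wilk normality per group and Levene's
variance homogeneity across groups; the equal-variance t-test is used only
when all three gates pass at `gate_alpha` (default 0.05, a conventional
choice — the gate level is exposed because it is not a law of nature), and
the Wilcoxon rank-sum test otherwise. Constant groups, for which
Shapiro–Wilk is undefined, force the Wilcoxon path with a note. Levene's
test is mean-centered by default; the median-centered Brown–Forsythe
variant is available by flag. Five planned contrasts are run per annotation
and sample type (laborers vs. male students, female vs. male students,
laborers vs. female students, male smokers vs. non-smokers, male drinkers
vs. non-drinkers) and Bonferroni-corrected within that family of five.

## Beta diversity, ordination and ANOSIM

Between-sample dissimilarity is the Hellinger distance
$HD(a,b) = \sqrt{\sum_i (\sqrt{a_i} - \sqrt{b_i})^2}$, i.e. Euclidean
distance of square-root-transformed compositions. Reference equations for
this quantity are printed with a ÷2 in two different places in the
literature; both readings are implemented (`scaled = TRUE` divides by
$\sqrt 2$, giving range [0, 1]). The default is the unscaled convention
because it is what the standard community-ecology workflow
(Hellinger transform + Euclidean distance) produces. The two conventions
differ by an exact factor of $\sqrt 2$, so every rank-based conclusion —
ANOSIM in particular — is identical under either.

Ordination is classical PCoA: Gower double-centering of $-D^2/2$,
eigendecomposition, coordinates scaled by the square root of the positive
eigenvalues. Hellinger distances are Euclidean-embeddable, so no
Lingoes/Cailliez correction is applied; negative eigenvalues (numerical
noise at most) are reported and their axes dropped.

ANOSIM ranks all $M = n(n-1)/2$ pairwise distances with mid-rank ties and
computes $R = (\bar r_B - \bar r_W) / (M/2)$, the standard scaling that
confines $R$ to $[-1, 1]$ with $R = 1$ exactly when every between-group
distance exceeds every within-group distance. The p-value uses the add-one
permutation estimator $(1 + \#\{R_\pi \ge R\}) / (1 + n_\pi)$ with a
seeded permutation stream (default 999 permutations; the permutation count
is a convention, not an estimate), so p is never 0 and reruns are
reproducible. For two small groups, `exact = TRUE` enumerates all
$\binom{n}{n_1}$ label assignments instead, which the test suite compares
against an independent enumeration.

## Differential abundance and the LDA effect-size screen

Per-feature testing applies the same gated t-test/Wilcoxon choice to each
feature's relative abundances and Bonferroni-corrects with the family equal
to all features in the table. For reporting shifts between two groups of
$n_1$ and $n_2$ samples, `pairwise_difference_summary()` enumerates all
$n_1 n_2$ differences and reports their median (the Hodges–Lehmann shift
estimate) with a distribution-free CI taken from the order statistics of
the sorted differences at Wilcoxon rank-sum critical values (the Moses
interval). The CI method is not uniquely determined by its common usage in
figures of this kind; the order-statistic interval was chosen because it is
exact, assumption-free and reproducible, and it matches
`wilcox.test(conf.int = TRUE)` on tie-free data.

The LDA effect-size screen reimplements the two-class core of the
well-known LEfSe procedure: per-sample scaling to a total of $10^6$; a
Kruskal–Wallis screen at `alpha` (for two classes this is the Wilcoxon
test); then, for surviving features, bootstrap iterations (default 30,
each drawing two thirds of every class) fit an LDA on the surviving
features and score feature $j$ by the mean of (i) the absolute class-mean
difference of $x_j w_j$, the feature's component of the unit-norm
discriminant direction, and (ii) the raw absolute class-mean difference.
The reported score is $\log_{10}(1 + \text{mean effect})$ and a feature is
flagged when the screen passes **and** the score strictly exceeds the
threshold (default 4 — a deliberately conservative bar: on the $10^6$
scale it demands an absolute shift around $10^4$ per million). Multi-class
and subclass machinery is out of scope; running the screen per rank table
covers hierarchical use. Degenerate bootstrap draws (constant features,
collinear fits) fall back to the raw mean difference for the affected
features after bounded redraws, which biases the score downward, never
upward.

## Zero replacement and the elimination classifier

Random-forest classifiers cannot digest compositional zeros gracefully, so
counts first undergo Bayesian-multiplicative replacement: within a sample
of total $n$ over $m$ features, a zero becomes its posterior Dirichlet
expectation $t \cdot s/(n+s)$ (uniform base $t = 1/m$) and non-zero
proportions are multiplied by one minus the replaced mass, preserving
their ratios exactly. The default prior is the square-root prior
($s = \sqrt n$) for its closed form; Bayes–Laplace ($s = m$), Perks
($s = 1$) and Jeffreys ($s = m/2$) are available. The geometric
Bayesian-multiplicative prior, whose strength is data-driven, is not
implemented; for the strictly positive outputs the classifier needs, the
uniform-base priors are sufficient and transparent.

The classifier follows a fixed recursive feature-elimination protocol:

1. Train 100 random forests on the training set and average each feature's
   **unscaled** mean-decrease-accuracy importance across forests. The
   unscaled variant is used because the average over forests then equals
   the average over all trees, making the ensemble's ranking independent of
   how trees are grouped into forests. Internally the 100 forests are grown
   from a single seeded RNG stream as one large forest whose trees are
   blocked into 100 groups — statistically identical to 100 independently
   grown forests and considerably faster — and each block votes with its
   own majority; the ensemble predicts by majority of the 100 forest votes
   (ties break to the first class level, deterministically).
2. Record ensemble accuracy on the training and held-out sets, remove the
   single feature with the lowest average importance (ties: the
   lexicographically last identifier, radix order, so elimination is
   deterministic and platform-independent), and repeat until one feature
   remains.
3. Score every step lexicographically by (test accuracy, training
   accuracy); among maximal steps select the one with the fewest features;
   refit that subset with a derived seed.

Forest hyperparameters default to 500 trees per forest and
`mtry = floor(sqrt(m))`; every experiment below uses fewer trees per
forest, which the importance averaging over 100 forests tolerates well.
Female students are excluded from model construction because occupation
and gender are confounded in the cohort design (there are no female
laborers); the train/test split is stratified per occupation with a
fraction of 0.7, i.e. 28/12 for a 20 + 20 cohort, seeded and recorded.

A caution that the null-control test quantifies: because the best-model
rule maximizes test accuracy over all elimination steps, the selected
model's test accuracy is an optimistically biased estimate — under pure
noise its mean sits visibly above 0.5 (around 0.64 in the packaged test at
25 noise features). Reported accuracies of selected models should be read
as model-selection outcomes, not unbiased generalization estimates.

## The synthetic study generator

`simulate_study()` emulates the data structure the pipeline assumes, with
a Dirichlet-multinomial model plus structural zeros:

* one base composition per study from a symmetric Dirichlet
  (concentration 0.5: realistically uneven, a few dominant features);
* a fixed set of informative features whose proportions are multiplied (or
  divided, per a random direction) by the effect size in the laborer
  group, then renormalized;
* per-feature, per-sample structural absence with probability `sparsity`
  (default 0.3 — the generator emulates the moderately prevalent feature
  pool that survives prevalence filtering, not the long tail of taxa seen
  in one or two samples, which a real catalog contains in abundance);
* negative-binomial depths (mean 50,000, dispersion 10; `Inf` gives fixed
  depths for conservation tests) and multinomial counts at that depth;
* covariates drawn independently of counts (the cohort pattern: students
  smoke less, both groups mostly drink); gender defaults to all-male
  because the modeling cohort is male-only, and the female rate is a
  config knob. An explicit coupling hook is not provided.

Default sizes are 20 + 20 samples and 200 features with 5 informative at
8-fold change. What the generator does **not** emulate: taxon-taxon
correlation, per-sample composition heterogeneity beyond zeros and
multinomial noise, batch effects, and catalog-scale feature counts
(~17,000 species in a real study). Passing tests therefore demonstrate
correctness of the algorithms and their calibration under this model, not
performance on real cohorts.

Every generator output is reproducible bit-for-bit from `config$seed`;
sub-seeds for taxonomy, splits, forests and permutations are derived from
master seeds so a single integer pins the entire pipeline.

## Numerical conventions and problem sizes

* Compositions are validated to sum to 1 within `1e-9`; zero-replacement
  outputs to `1e-12`.
* Wilcoxon tests use R's defaults: exact enumeration for small tie-free
  samples, normal approximation with continuity correction otherwise.
* ANOSIM mid-ranks follow `rank()`'s average-tie convention; the `dist`
  lower-triangle storage order is handled explicitly.
* The packaged checks run at deliberately small problem sizes chosen as
  adequate for their purpose: null calibration uses 600 replicate studies
  of 10 + 10 samples × 40 features (Monte-Carlo error ≈ 0.01 on a
  rejection rate of 0.05), LEfSe null control 100 replicates, and the
  recovery study 20 seeds of the default 20 + 20 × 200 configuration with
  100 forests × 25 trees per elimination step.

A related observation from the packaged recovery study (20 seeds of the
default configuration): the minimum-feature rule routinely selects one- or
two-feature models that classify both sets perfectly, because a single
8-fold feature already separates the groups — random forests are not
monotone classifiers, so students' mid-range abundances can be isolated
from laborers' low-plus-replaced-zero values, and the depth-dependent
magnitude of replaced zeros gives trees extra purchase. Every feature so
selected is a genuinely planted one, but recovering *most* of a redundant
informative set is then impossible by construction: perfect small models
preempt larger ones. Feature-set *recall* of the selected model is
therefore a poor measure of pipeline quality under redundancy; precision
of the selected set is the meaningful one.

## Known limitations

* The LDA screen implements only the two-class path.
* ANOSIM's exact mode enumerates two-group assignments only.
* The generator's covariates never influence counts, so the pipeline's
  smoker/drinker contrasts are calibrated but have no power under
  simulation.
* Best-model accuracies are selection-biased upward (see above); an
  untouched validation cohort is the only honest remedy.
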