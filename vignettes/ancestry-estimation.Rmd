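---
title: "Model-based ancestry estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based ancestry estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixprop)
```

## The model

`admixprop` estimates individual ancestry proportions from biallelic
genotypes under the standard binomial admixture model. For individual $i$
and SNP $j$, the genotype $n_{ij}$ (the number of copies of the counted A1
allele) is modelled as

$$ n_{ij} \sim \mathrm{Binomial}\!\left(2,\; \pi_{ij}\right), \qquad
   \pi_{ij} = \sum_{k=1}^{K} q_{ik}\, p_{kj}, $$

where $q_{ik}$ is the fraction of individual $i$'s ancestry attributable to
ancestral population $k$ (each row of $Q$ lies on the $K$-simplex) and
$p_{kj}$ is the frequency of the counted allele at SNP $j$ in population
$k$. SNPs are treated as independent, which is why input panels are
expected to be LD-thinned. The log-likelihood

$$ \mathcal{L}(Q, P) = \sum_{i,j}\Big\{ n_{ij}\log \pi_{ij}
   + (2 - n_{ij})\log(1 - \pi_{ij}) \Big\} $$

is concave in $Q$ for fixed $P$ and in $P$ for fixed $Q$ (biconcave), but
not jointly concave; like every tool in this family the optimizer finds a
local maximum and the likelihood is invariant to permuting cluster labels.

### Haploid (hemizygous) genotypes

For a haploid chromosome — the X in human males, the Y, or any chromosome
named by a `--haploid`-style specification such as `"male:23,24"` — a
hemizygous genotype carries a single allele copy and is conventionally
stored as a homozygote of the observed allele (0 or 2). The correct
contribution of such an entry is a single Bernoulli draw,

$$ \tfrac{n_{ij}}{2} \sim \mathrm{Binomial}(1, \pi_{ij}), $$

i.e. exactly **half** the log-likelihood term of the corresponding
homozygous diploid genotype. The package unifies both cases through a
per-entry draw count $d_{ij} \in \{0, 1, 2\}$ (0 = missing, 1 = haploid,
2 = diploid) and effective success count $x_{ij}$ ($n_{ij}$ for diploid
entries, $n_{ij}/2$ for hemizygote-coded haploid ones), so that

$$ \mathcal{L} = \sum_{i,j}\Big\{ x_{ij}\log \pi_{ij}
   + (d_{ij} - x_{ij})\log(1-\pi_{ij}) \Big\}. $$

A *heterozygous* call at a haploid entry is impossible under hemizygote
coding. Real chip data nevertheless contain such calls, so `build_ploidy()`
demotes them to missing ($d = 0$) and reports a warning tally rather than
failing hard or silently miscoding them; silent miscoding would bias $Q$.
One sex label is accepted per specification; datasets containing
individuals of unknown sex are rejected when a haploid spec is active,
because their ploidy on the named chromosomes is undefined.

## Optimization

### Block relaxation

`fit_unsupervised()` alternates closed-form EM sweeps over the two blocks:

* $Q$-sweep (per individual): $q_{ik} \leftarrow \frac{1}{D_i} \sum_j
  \left[ x_{ij}\frac{q_{ik}p_{kj}}{\pi_{ij}} + (d_{ij}-x_{ij})
  \frac{q_{ik}(1-p_{kj})}{1-\pi_{ij}} \right]$ with $D_i = \sum_j d_{ij}$;
  rows land back on the simplex exactly, and individuals decouple.
* $P$-sweep (per SNP): $p_{kj} \leftarrow A_{kj}/(A_{kj}+B_{kj})$ with
  $A, B$ the expected ancestral allele counts given the current parameters.

Each sweep is a proper EM step, so the log-likelihood never decreases —
this monotone contract is what the tests rely on, and the recorded
`loglik_trace` of every fit is non-decreasing by construction.

Plain EM is reliable but slow near convergence, so the fit loop layers a
*safeguarded* squared-extrapolation step (SQUAREM-style) on top: after two
EM cycles an extrapolated point is formed, projected back onto the feasible
set, stabilized by one further EM cycle, and **kept only if it does not
lower the log-likelihood** (the plain double EM step is used otherwise).
The extrapolation step length is capped, with the cap growing by a factor
of 4 each time it is hit successfully. Acceleration therefore changes speed
but never the monotonicity guarantee. Typical speedups are 5–10-fold on
the simulation sizes below.

Convergence is declared when the absolute log-likelihood increase of an
outer iteration falls below `tol` (default `1e-4`), with a `max_iter`
sweep cap (default 2000).

After the loop, the reported $Q$ is replaced by the exact per-individual
maximizer given the final $P$ — computed by the same routine `project()`
uses. The reported $(Q, P)$ pair is therefore $Q$-block optimal, and
projecting a training set onto its own fitted frequencies reproduces the
fitted ancestry exactly, not merely to within the convergence tolerance.

### Initialization and determinism

$Q$ rows are drawn uniformly on the simplex and $P$ starts at the observed
per-SNP allele frequencies perturbed by uniform noise ($\pm 0.1$), all from
a caller-supplied seed. Identical seeds give bit-identical results; the
global RNG state of the caller is saved and restored around every seeded
entry point.

### Projection

`project()` maximizes the likelihood over each individual's ancestry row
with $P$ fixed — the mode used to carry cluster frequencies learned from a
reference panel over to new samples, to related individuals excluded from
an unrelated training set, or to each chromosome set in the sex-bias
analysis. Rows are optimized independently from a deterministic uniform
start (per-row accelerated EM, per-row convergence test), so the result
for an individual does not depend on which other individuals are present,
duplicated genotype rows give bit-identical ancestry rows, and the work is
embarrassingly parallel across individuals. SNP matching between the
dataset and the frequency matrix is positional; the caller must supply the
same SNPs in the same order.

### Numerical choices

* Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ before logs are taken;
  the guard is invisible at reporting precision (outputs are written with
  six decimals).
* Missing genotypes are excluded through $d = 0$ rather than imputed,
  matching the likelihood's term-skipping semantics.
* Individuals (or SNPs) with no observed genotypes are left unchanged by
  the sweeps, with a warning; projection returns the uniform row for them.
* Cluster label switching is resolved only in reporting and testing via
  `align_clusters()`, which minimizes the summed mean absolute frequency
  difference over label permutations (exhaustively for $K \le 8$, greedily
  above); the optimizer itself is label-agnostic.

### Cross-validation

`cross_validate()` masks a seeded random fold of the *observed* entries
(setting $d = 0$), re-projects, and scores each masked entry by the squared
difference between its effective count $x_{ij}$ and its prediction
$d_{ij}\hat\pi_{ij}$, averaging within and then across folds. The squared
prediction error on masked entries is this package's choice of CV loss; a
high value signals that the projected individuals contain structure (e.g.
a novel population) absent from the reference frequencies.

## The synthetic-data generator

`simulate_dataset()` draws data with exactly the structure the model
assumes: ancestral frequencies independently per cluster and SNP from
Beta(0.5, 0.5) — a U-shaped spectrum resembling ascertained SNP panels,
with an optional `min_separation` redraw that keeps every pair of cluster
frequencies at least a given distance apart (an informative panel);
ancestry rows from a Dirichlet; diploid genotypes Binomial(2, $\pi$); and
haploid entries Binomial(1, $\pi$) hemizygote-coded as twice the draw.
`sex_ratio` is the fraction of males.

What this emulates — and what it does not: the generator produces linkage
equilibrium (the model's own assumption, approximated in practice by LD
thinning), no genotyping error, no ascertainment bias, and no coalescent
structure. Tests passing on such data show that the estimator recovers the
parameters of its own generative model; they do not certify behavior under
model misspecification on real data.

`simulate_sex_bias()` draws autosomes from a base ancestry matrix and the
X from the base shifted by a per-cluster `delta` (rows renormalized;
haploid in males). The shift is deterministic per individual: the
between-individual variance of realized single-chromosome ancestry (a
large effect on real X chromosomes, where a handful of recombination
blocks dominate) is *not* modelled. Consequently a shift of 0.10 is
detected essentially always at realistic panel sizes — estimation noise of
a projected ancestry at $M \approx 3000$ is only about 0.016 — and power
comparisons between analyses are informative only near the detection
threshold (shifts of the order of the estimation noise). The test suite
demonstrates the power advantage of including haploid males at such a
near-threshold shift.

`simulate_pedigree()` produces offspring by Mendelian transmission: at each
SNP one allele is drawn uniformly from each parent's two, independently
across SNPs (no recombination map). Offspring expected ancestry is the
mid-parent average; this ancestry-level shortcut, rather than explicit
X-recombination, is a documented simplification sufficient for testing the
projection-on-relatives workflow.

## Sex-bias statistics

`sex_bias_test()` compares each individual's X and autosomal ancestry per
cluster: the mean difference $\bar{(Q_x - Q_{auto})}$ and a Wilcoxon
signed-rank test. Ancestry proportions are bounded and skewed, so a t-test
is not appropriate. Choices, in order of the conventions involved:

* zero differences are dropped; absolute differences are ranked with
  average ranks for ties;
* the p-value is **exact** for up to 25 nonzero pairs, by enumerating the
  sign-assignment distribution of the rank sum (a dynamic program over
  doubled ranks handles tied, half-integer average ranks exactly); beyond
  25 pairs a normal approximation with tie correction and continuity
  correction is used;
* two-sided by default, with a one-sided option (`one_sided = TRUE` tests
  for an X excess);
* raw p-values only: the per-cluster tests are correlated (rows sum to 1)
  and no multiplicity correction is applied — the printed report says so.

`af_zscore()` standardizes an allele-frequency estimate from $n$ unrelated
diploid samples against a reference frequency $f$:
$z = \sqrt{2n}\,(f_n - f)/\sqrt{f(1-f)}$, which is standard normal when
the estimate is a binomial proportion from $2n$ chromosomes.
`af_accuracy()` benchmarks two competing estimates against a reference
restricted to an interior frequency band (default 5–95 %): RMSEs, a
one-tailed paired t-test on per-SNP squared errors, and the z-score
summaries. Both the signed mean $\bar z$ (directional bias) and the mean
absolute value $\overline{|z|}$ are reported — the two are easily
conflated in summaries, and only the former can be negative.

## Study sizes used by the automated checks

The test suite and `scripts/acceptance.R` generate all inputs at run time.
The main configurations, chosen to exercise realistic panel sizes while
keeping a full run in the tens of minutes on one CPU:

* parameter recovery: $N = 200$, $M = 5000$, $K = 3$, Dirichlet(1, 1, 1)
  ancestries, Beta(0.5, 0.5) frequencies separated at 0.05;
* relatedness workflow: 150 founders, 100 offspring from 20 couples,
  $M = 5000$, $K = 2$ (50 seeded replicates in the test suite, 20 in the
  acceptance script);
* sex bias: $N = 100$, $M_{auto} = 5000$, $M_x = 3000$, base ancestry
  (0.75, 0.25), X shift $\pm 0.10$ (power) or 0 (size; 300 replicates in
  the test suite, 150 in the script).

A note on attainable accuracy at these sizes: with $N = 200$ admixed
individuals and $K = 3$, the effective number of chromosomes informing
each cluster frequency is roughly $2N\,\mathrm{E}[q^2] \approx 67$, so the
*statistical* error of the maximum-likelihood frequency estimates is about
$\sqrt{p(1-p)/67} \approx 0.04$–0.05 on average, and the ancestry errors it
induces reach $\approx 0.08$ in the worst of the $N \times K$ entries.
The optimization itself is far more accurate than this: refining from the
generating truth reaches the same optimum as the seeded random start (to
$5\times 10^{-3}$ in $Q$ and $2\times 10^{-4}$ in $P$), and the fitted
likelihood exceeds the truth's. Accuracy at these sample sizes is limited
by information, not by the optimizer.

## Known limitations

* One local maximum per seed; multiple random starts are the user's
  responsibility (runs are cheap and seeded).
* Projection assumes the reference frequencies describe the projected
  individuals; novel populations inflate the cross-validation error but
  are not otherwise flagged.
* No supervised mode, no bootstrap standard errors, no pseudo-autosomal
  handling (encode PAR SNPs with a diploid chromosome code), no
  VCF/multiallelic/dosage input, and no individual-major `.bed` support.
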