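---
title: "SNP-set association testing with common and rare variants"
author: "SnpSetTest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-set association testing with common and rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SnpSetTest)
```

## The problem

Exome sequencing of a case-control sample yields, for each gene, a mixed bag
of common variants (minor allele frequency at least 1%) and rare variants
(MAF below 1%). Individually, rare variants are almost untestable: their
carrier counts are tiny and single-variant tests pay an enormous
multiple-testing price. SnpSetTest tests each *SNP set* -- the common and
rare variants annotated to one gene -- jointly, combining rare variants into
burden-style scores, reducing common variants to either their raw genotype
vector or a one-dimensional summary, and testing the set with either a
logistic score test or a logistic kernel machine variance-component test,
optionally inside a two-stage screening/testing design that curbs false
positives.

## Data model

The central container is `SnpSetExperiment`, a `SummarizedExperiment` whose
`"geno"` assay holds additive minor-allele counts (variants x samples, 0/1/2,
missing allowed), whose `rowData` carries the variant annotation (gene,
synonymous/nonsynonymous class, MAF, rare/common class, position) and whose
`colData` carries the sample table (case/control status, age, sex, smoking
exposure, subpopulation, PC scores). Conventions worth stating:

* **Minor-allele orientation is recomputed from the data.** VCF REF/ALT
  orientation is ignored; a variant whose ALT frequency exceeds 0.5 is
  recoded so counts refer to the minor allele.
* **Rare means MAF strictly below 1%**; a variant at exactly 1% is common.
  MAF is estimated on non-missing genotypes and folded to `[0, 0.5]`.
* **Missing genotypes** are imputed to the per-variant mean of non-missing
  values at test time, which preserves additive dosage semantics; they are
  excluded from MAF and weight estimation. No further imputation is done.
* **Singleton and monomorphic variants are removed**
  (`filterSingletonVariants`). Variants seen in one carrier cannot support a
  frequency contrast; zero-carrier variants carry no information and break
  standardization, so they are removed on the same pass.
* **Low-burden genes are removed** (`filterLowBurdenGenes`): a gene whose
  rare variants are jointly carried by fewer than 1% of samples is dropped.
  Genes with no rare variants are kept -- the rule is vacuous for them and
  their common variants remain testable.
* **Population structure** is summarized by the top two principal components
  of the centered genotypes of common variants with MAF above 10%,
  optionally thinned to a minimum base-pair spacing by a greedy
  left-to-right scan in position order. Each PC's sign is fixed so its
  loading vector has non-negative sum, making scores reproducible. The PCA
  uses centered minor-allele counts (not variance-scaled), which keeps the
  score of a monomorphic-ish variant near zero.

## Collapsing scores

**Rare variants.** Within each functional class (synonymous /
nonsynonymous), each sample receives a weighted sum of its rare minor-allele
counts, with the Madsen-Browning inverse-standard-deviation weights
estimated from the unaffected samples under a +1/+2 pseudocount:

$$ q_k = \frac{m_k^U + 1}{2 n_k^U + 2}, \qquad
   w_k = \sqrt{n_k \, q_k (1 - q_k)}, \qquad
   \mathrm{WS}_i = \sum_k \frac{I_{ik}}{w_k}. $$

The pseudocount keeps weights finite for variants absent from the controls;
rarer variants get smaller standard deviations, hence larger contributions.
The two class scores are combined as
$\mathrm{WS_{combined}} = \mathrm{WS_{syn}} + 2\,\mathrm{WS_{nonsyn}}$,
doubling the weight of nonsynonymous variants on the prior that they are
more likely functional.

**Common variants.** A gene's common variants are reduced to the
one-dimensional summary $\sum_k c_k I_{ik}$ with
$c_k = m_k^A / (2 n^A) - m_k^U / (2 n^U)$, the case/control difference in
estimated allele frequency. This is the fitted-component direction for a
binary response in the principal-fitted-components sense, taken without
covariance rescaling; `commonSummaryScore()` accepts a pluggable coefficient
function so a rescaled variant can be swapped in. Because every downstream
use standardizes the score, its overall scale is irrelevant.

In the two-stage design the weights and coefficients are always estimated on
the *screening* replicate and applied to the *testing* replicate's
genotypes; the weight source is an explicit argument (`weightSource`), never
implicit state.

## Tests

**Logistic score test** (`logisticScoreTest`). The model is
$\mathrm{logit}\,P(y_i = 1) = X_i'\beta + z_i'a + s_i z_i' b$, with $X_i$
the covariates (intercept, age, sex, two PCs, smoking), $z_i$ the genetic
columns and $s_i$ the exposure; the null is $a = b = 0$. The statistic is
the efficient score: the score vector of the tested block at the null MLE,
normalized by the tested-block information minus its projection through the
nuisance block (Schur complement), referred to a chi-square whose degrees of
freedom equal the number of retained tested columns. Columns that are
constant or collinear in the null-weighted metric are pruned first (rank
detection by QR on the weight-scaled design) and noted. Correctness is
pinned to the likelihood itself in the tests: the statistic is compared
against a Richardson-extrapolated finite-difference score/information
construction, and against the Pearson chi-square in the 2x2 special case.

**Hotelling T-squared** (`hotellingT2`) compares multivariate means with the
pooled covariance; a rank-deficient pooled covariance switches to the
Moore-Penrose pseudoinverse and suppresses the analytic F p-value (the
screening stage uses permutation p-values regardless).

**Gene-environment correlation** (`geCorrelationTest`) tests
$\mathrm{Corr}(G, E \mid Y=0) = \mathrm{Corr}(G, E \mid Y=1)$ by the
difference of Fisher z-transforms, scaled by the classical two-sample
variance $1/(n^A-3) + 1/(n^U-3)$. The analytic variance matters only in the
standalone analytic mode; the pipeline permutes.

**Permutation engine** (`permutationPvalue`). All screening p-values come
from permuting disease status with group totals preserved (a label
permutation preserves both totals by construction). The statistic closure is
re-evaluated in full on each permutation, so anything that depends on status
-- weights, summary-score coefficients, group membership -- is honestly
recomputed. Conventions: add-one estimator $p = (1 + \#\{b : T_b \ge T\}) /
(B+1)$, so $p > 0$ always; ties count as extreme (conservative); two-sided
statistics are passed as absolute values; a permutation on which the
statistic fails (e.g. a constant group after relabeling a near-monomorphic
gene) is redrawn, at most ten times.

## Logistic kernel machine tests

The semiparametric extension replaces $z_i'a + s_i z_i'b$ with $h(z_i) +
g(s_i z_i)$, $h$ and $g$ living in the RKHSs of kernels $K$ and
$\tilde{K}$. Testing "no genetic effect" is equivalent to testing that the
two variance components of the induced logistic mixed model are zero, and
the score statistic splits into two quadratic forms in the null residuals:

$$ q_\tau = \tfrac{1}{2}(y-\hat\mu)' K (y-\hat\mu), \qquad
   q_{\tilde\tau} = \tfrac{1}{2}(y-\hat\mu)' \tilde{K} (y-\hat\mu), $$

with $\hat\mu$ from the null GLM fit on the covariates alone. Null moments
use the efficient projection $P_0 = D - DX(X'DX)^{-1}X'D$,
$D = \mathrm{diag}(\hat\mu(1-\hat\mu))$: mean $\mathrm{tr}(P_0 K)/2$ and
variance $\mathrm{tr}(P_0 K P_0 K)/2$. Each component is matched to a scaled
chi-square $\kappa\chi^2_\nu$ (Satterthwaite: $\kappa = \mathrm{var}/2\mu$,
$\nu = 2\mu^2/\mathrm{var}$), and the combined statistic

$$ Q = q_\tau/\kappa_1 + q_{\tilde\tau}/\kappa_2
   \;\sim\; \chi^2_{\nu_1 + \nu_2} $$

treats the components as approximately independent. This combination rule
was a genuinely open design point (joint moment matching of the sum is the
main alternative); it is isolated in `combinedKernelTest()` so it can be
swapped. Its adequacy is measured, not assumed: the calibration experiments
(acceptance tests and `scripts/acceptance.R`) estimate the empirical type-I
error of both kernel schemes under null simulations at n = 400. The linear
scheme holds its nominal 5% size; the quadratic scheme is conservative
(empirical size near 2%) -- see the calibration subsection below. A
component whose null variance is below 1e-12 is flagged degenerate and
contributes neither to $Q$ nor to the degrees of freedom.

### Calibration of the moment-matched approximation

Two-moment matching with the Gaussian-working variance is exact in neither
moment nor shape for binary outcomes, and the errors pull in opposite
directions. The working variance $\mathrm{tr}(P_0 K P_0 K)/2$ omits the
fourth-cumulant diagonal term
$\sum_i K_{ii}^2\, \mu_i(1-\mu_i)\bigl(1 - 6\mu_i(1-\mu_i)\bigr)/4$, which
is negative at moderate prevalence, so the working variance *overstates*
the true variance -- strongly so for the quadratic kernel, whose diagonal
dominates (parametric-bootstrap variance ratios near 0.56 at the package's
default conditions). Overstated variance inflates $\kappa$ and deflates the
statistic, which by itself is conservative. Pulling the other way are the
$\kappa\chi^2_\nu$ shape approximation (the true law is a weighted
chi-square mixture with heavier right tail) and the ignored positive
correlation between the two components. For the linear kernel these errors
roughly cancel and the test holds its size; for the quadratic kernel the
variance overstatement wins and the test runs conservative (size about
0.02 at nominal 0.05). Substituting the exact binary-outcome variance was
evaluated and rejected: it removes the conservative bias but unmasks the
anti-conservative shape and correlation errors (size about 0.08 for both
schemes). Within two-moment matching -- the construction this package
implements -- the quadratic scheme's conservatism is structural; a
three-moment (skewness) match or an exact mixture p-value would resolve it
but is a different method and deliberately out of scope. Practically: the
quadratic-kernel test loses some power but does not inflate false
positives.

**Kernels.** Linear ($z_i'z_j$) or quadratic ($(1 + z_i'z_j)^2$) for the
main effect; the gene-environment kernel is always linear and is built on
the rows of the standardized design multiplied by the (binary) exposure,
which reproduces the parametric $s \cdot Z$ interaction design in the linear
case. Inputs are standardized to mean 0, SD 1 (n-1 denominator) first;
constant columns standardize to zero and drop out harmlessly. The quadratic
kernel's feature space contains pairwise products, so it is the scheme that
can pick up SNP-SNP interactions; the tests verify it beats the linear
kernel under interaction-only signal and pays for that flexibility with
lower power under purely additive signal.

**Null fit.** `fitNullLogistic` is IRLS (`glm.fit`) run to relative change
1e-10, at most 100 iterations; apparent separation (|coef| > 30 or fitted
probabilities within 1e-10 of the boundary) is an error rather than a
silently divergent fit.

## The two-stage procedure

Replicate pairs (one screening set, one testing set, same genotypes) are
processed as follows.

**Screening** (`screenGene`, threshold 0.1 by default): per gene, (a)
Hotelling T-squared on the common-variant genotype vectors, cases versus
controls, separately within each subpopulation (labels from the sample
table, else k-means with k = 3 on the two PCs); (b) a 2-D Hotelling
T-squared on (WS_syn, WS_nonsyn) over the whole sample; (c) gene-environment
correlation tests for the common summary score and WS_nonsyn (weights
estimated on the same screening data, which is self-consistent because the
permutation recomputes them per relabeling). A gene passes if any available
permutation p-value falls below the threshold; inapplicable tests (no
common variants, degenerate statistic) are recorded as unavailable, not as
p = 1. The default permutation count is B = 1000 per test, configurable.

**Testing** (`testGene`): the five methods of `testingMethods` -- logistic
score test with raw common genotypes or with the common summary score (each
augmented by WS_combined), and kernel machine tests with linear kernel +
WS_combined, linear kernel + WS_nonsyn, or quadratic kernel + WS_combined.
Testing-stage p-values are analytic (chi-square), and within each method
they are Holm-adjusted across the genes that passed screening; a gene is
selected at adjusted p below 0.1. Holm is applied per method, not jointly
across methods, because the five methods are competing alternatives being
compared, not one combined decision family.

## The synthetic data generator

`simConfig`/`simulateGenotypes`/`simulatePhenotypes` emulate a mini-exome
case-control study of unrelated individuals: defaults are 697 samples with
affected/unaffected totals fixed at 209/488, three subpopulations in
roughly equal proportions, 74% rare variants, rare MAFs log-uniform on
[1/(2n), 0.01), common MAFs log-uniform on [0.01, 0.5] (log-uniform gives
the realistic decreasing frequency spectrum), Balding-Nichols divergence
with Fst = 0.05 across subpopulations for common variants (rare variants
share one frequency -- at rare counts drift noise swamps a small Fst), 70%
nonsynonymous labels, smoking prevalence 0.3, age ~ Normal(50, 10), sex ~
Bernoulli(0.5), and covariate log-odds effects 0.01/year (age), 0.25 (sex),
0.5 (smoking, OR about 1.65). About 8 variants per gene (shifted Poisson)
matches an exome-wide variants-per-gene average. The intercept is calibrated
by root finding so the expected prevalence hits the target; fixed totals are
realized by rejection sampling of the status vector (the acceptance
probability at the binomial mode is a few percent, so this is cheap).
Causal genes get any combination of a log-odds effect per standardized rare
nonsynonymous burden, per standardized common variant, an exposure x burden
interaction, and a product of the gene's first two standardized common
variants.

Genotypes, age and sex are generated once and held fixed across all
replicates of a run; exposure and status are re-simulated per replicate.

What the generator does *not* emulate: linkage disequilibrium within genes
(variants are drawn independently given their frequencies), realistic
age/sex-structured ascertainment, related individuals, genotyping error, or
any particular real trait architecture. Calibration and power results on
this generator therefore demonstrate internal correctness of the
statistics, not field performance on real exomes.

## Numerical choices and degenerate inputs

* Standardization uses the n-1 denominator; columns with SD below 1e-12 are
  flagged constant and only centered.
* Rank/collinearity detection in the score test is QR-based on the
  sqrt-weight-scaled design, so "constant after weighting" is what gets
  pruned; the chi-square df always equals the retained column count.
* The Hotelling full-rank check is eigenvalue-based with a relative
  tolerance; the pseudoinverse path is exercised in the tests against a
  reduced-dimension recomputation.
* Variance components with null variance below 1e-12 are degenerate, and a
  kernel test in which both components degenerate is an error ("no variance
  components to test") rather than p = 1.
* All pipeline randomness is derived from explicit integer seeds; derived
  seeds stay below 2^31.

## Scale of the shipped experiments

The acceptance tests and `scripts/acceptance.R` run the statistical checks
at these problem sizes, chosen to give stable Monte-Carlo estimates while
keeping a full run in the minutes range: calibration at n = 400 with 15
rare + 5 common variants over 2000 (tests) or 1000 (script) replicates;
the moment identity over 5000 (tests) or 2000 (script) bootstrap refits at
n = 300; power curves over 500 (tests) or 300 (script) replicates per
effect size; and the two-stage recovery experiment with 50 genes (one
causal: burden log-odds 1.0, common-variant log-odds 0.6, gene-environment
log-odds 0.5), n = 400, screening B = 200, over 20 (tests) or 12 (script)
replicate pairs. The interaction-sensitivity experiment uses an
interaction-only log-odds of 0.8 on three pairs of five common variants, an
effect size at which the quadratic kernel has moderate power so the paired
comparison is informative.

## Known limitations

* The common-variant summary coefficient is the frequency contrast; a
  covariance-rescaled fitted-components coefficient may be more efficient
  when common variants are strongly correlated.
* The combined kernel statistic ignores the correlation between the main
  and gene-environment components; the calibration experiments bound the
  practical effect at the defaults, but extreme exposure prevalence or very
  small samples could stress the approximation (Davies-type exact mixture
  p-values are deliberately out of scope).
* Screening and testing must come from independent replicates; applying
  both stages to one dataset invalidates the testing-stage p-values.
* Binary exposures only, one exposure at a time; no kinship handling.
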