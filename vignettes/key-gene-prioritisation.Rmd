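---
title: "LD-aware key-gene prioritisation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-aware key-gene prioritisation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keygene)
```

## The problem

Most GWAS hits lie in non-coding regions and act in *trans* through
regulatory networks: the variants perturb peripheral genes whose expression
cascades onto a smaller set of core ("key") genes that actually drive the
phenotype.  Ranking genes by their local GWAS signal therefore misses the
genes that matter most.  This package prioritises candidate key genes by
asking a different question: *which genes sit, consistently across the
trait-relevant tissues, at the centre of the co-expression modules that the
GWAS signal is enriched in?*

The pipeline has six stages, each exposed as ordinary R functions:

1. **Gene scores** — variant p-values are aggregated over a ±25 kb window
   around each gene body into a gene-level p-value and z-score, accounting
   for local LD.
2. **Shared signal** — the per-gene average z-score over many traits
   (a two-stage "mean of means" so over-represented trait classes are not
   over-weighted) is kept as a covariate: some genes attract GWAS signal
   for almost any trait.
3. **Gene–gene correlation** — LD also correlates the *gene-level* scores
   of neighbouring genes.  The correlation matrix Ω is estimated from
   thousands of simulated null GWASs, per chromosome arm (zero across
   arms).
4. **Rotated regression** — associations between the gene z-scores and any
   per-gene predictor are estimated by an approximate generalised least
   squares in the truncated eigenbasis of Ω.
5. **Key gene scores** — per tissue, the significantly associated
   expression eigenvectors are combined into a per-gene weighted sum,
   standardised against a permutation null, and meta-analysed across
   tissues with Stouffer's method.
6. **Enrichment** — prioritised genes are tested for overlap with
   rare-disease (HPO-style) and other gene sets by Fisher's exact test and
   a Mann–Whitney AUC.

## Gene-level scores under LD

For the variants in a gene's window, each two-sided p-value is mapped to a
direction-free z, $z_i = \Phi^{-1}(1 - p_i/2)$, and the gene statistic is
$T = \sum_i z_i^2$.  Under the null the variant z-vector is multivariate
normal with correlation equal to the window LD matrix $R$, so
$T \sim \sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the eigenvalues of $R$
(clipped at zero — an estimated $R$ can have small negative eigenvalues).
The sign of a gene z-score deliberately carries no effect direction.

Two tail computations are provided:

* `method = "satterthwaite"` (default): a gamma matched to the first two
  moments.  It is *exact* whenever the non-zero eigenvalues are equal
  (single variant, perfect LD, fully independent variants) and accurate in
  the tails generally; its body-level approximation error is, however,
  detectable by a KS test at a few hundred genes.
* `method = "inversion"`: Imhof's characteristic-function integral,
  numerically exact.  The uniformity checks in the test-suite use this
  method; the cheaper gamma is the default for bulk scoring (e.g. the
  thousands of null GWASs behind Ω), where only correlations are needed.

p-values are floored at `1e-300` before conversion to z, which preserves
ordering while keeping every quantile finite.

## The rotated regression

The response $y$ is the inverse-normal-transformed gene z-score vector
($y_i = \Phi^{-1}((r_i - 0.5)/n)$ on average ranks).  Since Ω need not be
positive-definite, the GLS weight matrix $\Omega^{-1}$ is never formed.
Instead Ω is eigendecomposed per arm block (identical to decomposing the
assembled block-diagonal matrix, far cheaper), negative eigenvalues are
clipped to zero, and the smallest set of leading eigenvectors whose
eigenvalue sum reaches `variance_fraction` (default 0.90) is retained as
$V'$, $\lambda'$.  With $y' = V'^T y$ and $X' = V'^T X$:

$$\beta = (y'^T \Lambda'^{-1} X')(X'^T \Lambda'^{-1} X')^{-1},\qquad
  e = y' - X'\beta,$$
$$rss_w = \frac{e^T \Lambda'^{-1} e}{df},\qquad
  \beta_{se} = \sqrt{\mathrm{diag}\big((X'^T \Lambda'^{-1} X')^{-1}\big)\, rss_w},$$

with p-values from the t-distribution.  Design choices that were genuinely
open, and how they were resolved:

* **Degrees of freedom**: `df = n_eigenvectors_used - ncol(X')` — the
  rotated system has one observation per retained eigenvector.
* **Intercept**: appended as a *rotated* constant column $V'^T\mathbf 1$.
  Rotation does not preserve the constant vector, so an unrotated
  intercept would be misspecified.
* **Numerical guard**: eigenvalues below `1e-10` are excluded from
  $\Lambda'^{-1}$ regardless of the variance threshold.
* **Sidedness**: two-sided p-values, matching standard regression
  reporting.
* **Gene length covariate**: entered as `log10(length)`; the raw scale is
  available via `gene_lengths(genes, log10 = FALSE)`.

With identity Ω and full retention the fit reduces to OLS to machine
precision; with a positive-definite Ω and full retention it equals the
textbook $(X^T\Omega^{-1}X)^{-1}X^T\Omega^{-1}y$ — both are enforced by
tests at 1e-10 / 1e-8.

### Calibration under the null

`calibration_experiment()` reproduces the null experiment at its printed
scale: 300 genes sampled from the strongly-correlated part of a
fixture-built Ω, submatrix projected to the nearest positive-definite
correlation matrix (`Matrix::nearPD`), 1000 random pathway vectors and one
random trait drawn from $\mathcal N(0, \Omega')$, and each pathway
associated with the trait by OLS, approximate GLS (90% retention) and
exact GLS.  Under the study conditions the approximate GLS holds its
nominal 0.05 type-I error (observed ~0.04–0.06 across seeds) while OLS
exceeds 0.40.

## Key gene scores

For every Bonferroni-selected tissue the per-eigenvector effects
$\beta_{eigen}$ are estimated with the rotated regression (covariates:
shared signal and log gene length; Bonferroni within tissue).  The raw key
gene score is the weighted sum $V_{sum} = \sum_i V_{tissue,i}\,
\beta_{eigen,i}$ over the significant eigenvectors; eigenvector sign flips
are absorbed by the sign of $\beta$.

Significance comes from a permutation null: 10,000 draws of
$\beta^* \sim \mathcal N(0, I_m)$, shared across genes within a tissue so
the cross-gene correlation of the null is preserved.  Each gene's null is
summarised by its first four moments and a moment-matched Johnson SU fit.
Because $\beta^*$ is Gaussian the exact null is itself normal; the SU fit
then hugs a normal, and when the empirical kurtosis falls below the
SU-admissible region (roughly half the genes, by chance) a normal fallback
is recorded per gene (`fit_ok = FALSE`).  The SU branch is exercised
directly in tests against genuinely skewed, heavy-tailed moment targets,
where the moment-matching equations (closed-form sinh-normal moments) are
solved to ~1e-6.

The two-sided p-value from the fitted null is converted to
$Z_{tissue} = \Phi^{-1}(1 - p/2)$ *signed by the direction of departure
from the null mean*, so discordant tissues can cancel in the meta-analysis
$Z_{meta} = \sum_i Z_{all,i} / \sqrt k$ (equal weights; a gene absent from
some tissues is combined with its own $k$; an optional multi-tissue module
set is scored but never enters the meta).  "Key genes" are genes with a
Bonferroni-significant meta score *and* an annotation to a caller-supplied
phenotype-matched rare-disease term.

## What the synthetic generators emulate

All inputs can be generated in code, at study conditions chosen once:

* **Genotypes** (`simulate_genotypes`): independent LD blocks of
  AR(1)-correlated latent Gaussians thresholded to dosages.  Thresholding
  attenuates correlation, so the latent coefficient is calibrated
  numerically so the *realized dosage* correlation between adjacent
  variants matches the requested `rho`; one MAF per block keeps high LD
  attainable.  No realistic human LD maps, population structure or eQTL
  effects are emulated.
* **Null GWASs** (`simulate_null_gwas`): standard-normal phenotypes
  regressed on dosages; their gene scores drive Ω.  The package default
  for Ω is 10,000 nulls; fixtures use 200–500, which adds estimation noise
  of order $1/\sqrt{n}$ to Ω that the 90% eigen truncation absorbs.
* **Expression** (`simulate_expression`, and the composite
  `simulate_keygene_study`): Gaussian latent-factor models on the log
  scale.  The end-to-end fixture plants a key-gene architecture: 15
  co-expression factors per tissue with *distinct* variances (so SVD
  eigenvectors track individual factors rather than arbitrary rotations),
  20 core genes loading positively on every factor of three causal
  tissues (hub behaviour), baseline expression of those tissues coupled to
  the summed loading (trait-relevant tissues express trait-locus genes
  relatively highly), and trait z-scores built as summed module loadings
  × effect + N(0,1) noise with variance-proportional module weights.  A
  control tissue shares the marginal structure but has no core genes and
  no trait coupling.

Passing tests on these fixtures show the machinery recovers a strong,
cleanly planted architecture; they do not show sensitivity at realistic
effect sizes, robustness to batch effects or confounded expression, or
anything about the adequacy of real LD reference panels — none of which
the generators emulate.

## Problem sizes and numerical notes

The test-suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is statistically identifiable: 600
genes / 3+1 tissues / 10,000 permutations for the end-to-end fixture; 300
genes × 1000 pathways for the calibration; 550 one-block genes for the
null-uniformity KS check (blocks make gene scores independent, as the KS
test assumes); 10,000 permutations for the Johnson-vs-empirical
comparison, where agreement is assessed per probe *averaged over genes*
because the empirical CDF itself wiggles by ~$1/\sqrt{10^4}$.
Eigen-truncation reconstruction error is reported on the trace (nuclear)
norm — the norm on which the retained-variance fraction is defined, and
the one for which "error ≤ 1 − retained fraction" holds exactly.

Other conventions: coordinates are 1-based inclusive everywhere
(converters to half-open exist and are the only place offsets appear);
genes spanning a centromere are assigned to an arm by midpoint, ties to q;
quantile normalisation delegates to `limma::normalizeQuantiles`; the
variance-stabilising transform is the documented simplified surrogate
`log2(x + 1)` — only the correlation structure matters downstream; mean
expression is computed on the normalised scale, before per-gene scaling;
eigenvector signs are fixed by making the largest-absolute loading
positive.  Fisher enrichment reports the plain cross-product odds ratio
$ad/bc$ (infinite on a zero off-diagonal product); a t-test variant of the
same comparison is kept as an option because both descriptions of the
analysis circulate, and the package does not guess which was intended.

## Known limitations

* The gene-score statistic is a sum of squared z-scores; tools built
  around max-based or fine-mapping-aware statistics will rank dense loci
  differently.
* Ω estimated from few null GWASs is noisy; the truncation threshold
  trades that noise against signal and is not tuned per dataset.
* The permutation null treats eigenvector effects as independent standard
  normals; correlated effect structures across modules are not modelled.
* Tissue selection by mean expression is a coarse filter: a tissue whose
  relevance is purely module-level, with no mean-expression signal, will
  be missed.
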