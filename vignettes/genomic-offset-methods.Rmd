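---
title: "Models and methods behind geaoffset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geaoffset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geaoffset)
options(geaoffset.quiet = TRUE)
```

`geaoffset` implements a complete landscape-genomics workflow for diploid
biallelic SNP data collected across environmental gradients: describing
spatial genetic structure, associating allele frequencies with
environmental variables while controlling for that structure, and turning
the association into maps of expected maladaptation under climate change
(genomic offset) and of donor-site suitability for assisted migration.
This vignette explains the models, the defaults, and the design choices
the package makes where several defensible options exist.

## The synthetic study system

All tests and examples run on data from `simulate_dataset()`, whose
defaults emulate a country-wide sampling campaign for a common outcrossing
grassland herb: 735 individuals from 534 sites (one to two individuals per
site) genotyped at roughly 8.3k biallelic SNPs with 16.6% of calls
missing completely at random, four spatially coherent admixed genetic
clusters, and six bioclim/soil-like environmental variables on a
~4° x 6° longitude/latitude grid for two periods (present and future).

The generating model has three layers.

* **Neutral structure.** Each locus draws an ancestral frequency
  $p_0 \sim U(0.1, 0.9)$ and per-cluster frequencies from the
  Balding–Nichols beta distribution
  $p_k \sim \mathrm{Beta}\!\big(p_0\tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$,
  so the drift parameter $F$ directly controls among-cluster
  differentiation. An individual's expected allele frequency is
  $\sum_k q_{ik} p_{kl}$, with ancestry vectors $q_i$ a softmax of
  negative distances to the cluster focal points (temperature 0.25°).
  The default $F = 0.10$ yields a realized among-cluster $F_{ST}$ of
  roughly 0.04 — structured enough that four clusters are resolvable
  from ~2,000 loci, while staying in the weakly differentiated regime
  typical of common, widespread outcrossing plants (zone-level
  $F_{ST}$ of order 0.01–0.05).
* **Adaptive loci.** A configurable subset of loci (default ~1%)
  instead follows a logistic cline
  $\pi_{il} = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(p_0) + \beta z_i\big)$
  on the standardized present-day value $z_i$ of one designated driving
  variable at the individual's site (default slope $\beta = 2$). One
  driver per locus, no epistasis or pleiotropy — the simplest structure
  that exercises multivariate association methods.
* **Environment.** Each variable's present grid is a unit-variance
  Gaussian random field (Gaussian-kernel-smoothed white noise) plus a
  deterministic latitudinal or longitudinal gradient. Length scales
  default to 1.5–3° — country-scale bioclim and soil layers are smooth,
  and their collinearity with geography (and hence with genetic
  structure) is exactly the confounding these methods must cope with.
  Future grids add per-variable shifts (and optionally a gradient);
  soil variables are held constant by default.

Genotypes are $\mathrm{Binomial}(2, \pi_{il})$; missingness is MCAR
because nothing in the emulated study characterizes its missingness
mechanism. The generator does **not** simulate linkage disequilibrium,
coalescent ancestry, selfing, or polyploid inheritance; tests passing on
it show that the estimators recover the structure this model encodes,
not that they are robust to everything real data can do.

## Population structure

`pca_genotypes()` centers loci and mean-imputes missing entries for the
decomposition only. `estimate_ancestry()` is a least-squares matrix
factorization of dosages/2 as $Q F$ with simplex-constrained rows of $Q$
and $F \in [0,1]$, fitted by block projected-gradient descent with $1/L$
step sizes (so the masked least-squares objective is provably
non-increasing — a property the tests assert), k-means-on-PCs warm
start, and random restarts. It is a deterministic-given-seed stand-in
offering the same $Q/F$ interface as model-based ancestry programs, not a
re-implementation of any of them.

`choose_K()` masks a fraction of the observed entries, refits for each
candidate $K$, and scores the squared prediction error of $2\,QF$ on the
masked entries. Alongside the CV curve it reports the biological
plausibility diagnostics used in practice: whether every cluster has at
least one fully assigned individual ($\max_k q > 0.9$) and a spatial
coherence score (the mean fraction of an individual's five nearest
geographic neighbours sharing its modal cluster — our operationalization
of "mostly geographically contiguous", which is usually judged by eye).

Missing genotypes are imputed with the most probable genotype under
$\mathrm{Binomial}(2, \sum_k q_{ik}F_{kl})$. Note an intrinsic ceiling:
with ancestral frequencies uniform on $(0.1, 0.9)$ the Bayes-optimal
exact-recovery rate is only about 0.63, so imputation accuracy is tested
against that oracle rather than against an absolute figure.

The ancestry matrix is interpolated across the grid with a thin-plate
spline ($r^2 \log r$ basis, ridge $10^{-8}$) per cluster, then clipped to
$[0,1]$ and renormalized to the simplex; the per-cell argmax defines the
modal spatio-genetic group (ties go to the lowest cluster index).

Differentiation statistics follow the field's conventions: one-level
AMOVA on squared Euclidean genotype distances with the unequal-group-size
$n_0$ coefficient and label-permutation p-values; pairwise
Weir–Cockerham $\theta$ as a multilocus ratio of sums of the $a, b, c$
components; and a Nei-style global $F_{ST} = 1 - \bar H_S/\bar H_T$.
Two different global-style estimators are deliberately exposed because
they answer subtly different questions and can differ by a factor of two
on the same data. Isolation by distance uses haversine distances on the
sphere (radius 6371.0088 km; ellipsoidal corrections are below 0.5% at
country scale), a Mantel test with joint row/column permutations, and an
OLS slope reported per 100 km.

All permutation p-values in the package use the add-one estimator
$(\#\{\text{exceedances}\}+1)/(n_{\mathrm{perm}}+1)$ with explicit seeds.

## The ordination engine

`rda_fit()` builds redundancy analysis from first principles: predictors
are standardized, the response is centered, conditioners (if any) are
projected out of both sides, the fitted values are the QR projection of
the response onto the predictor space, and canonical axes come from the
SVD of the fitted matrix. Eigenvalues use the $n-1$ divisor so they
match vegan's scale (the test suite checks agreement with `vegan::rda`
and with a brute-force hat-matrix oracle to $10^{-8}$). Predictor
standardization does not change the column space, so $R^2$ is unaffected;
response columns are centered but not scaled, as appropriate for
dosage/frequency data. Rank-deficient predictor sets raise an error
naming the aliased columns; predictors that vanish entirely under
conditioning yield a valid model with zero canonical variance.

The permutation test permutes rows of the conditioned predictor space
(reduced-model permutation) — a simple scheme that is valid for these
designs. Forward selection implements the standard triple stopping rule
(conditional permutation $p \le \alpha$; adjusted $R^2$ must increase;
selection stops once the model's adjusted $R^2$ surpasses that of the
all-candidates model). One boundary case is worth stating: the variable
whose addition crosses the full-model adjusted $R^2$ is retained before
stopping — with few true drivers and many idle candidates the true model
routinely exceeds the penalized full-model value, and dropping the
crossing variable would discard a genuine driver. Variable redundancy is
handled by average-linkage clustering on $1-|\rho_S|$ cut at 0.3
(|Spearman| = 0.7); the representative per branch is the caller's choice,
mirroring how practitioners pick "the most plausible variable".

`variance_partition()` reports the classic three-way partition (pure
environment, pure geography, pure ancestry, confounded) using adjusted
$R^2$ differences, so the four components sum to the full-model adjusted
$R^2$ by construction, each pure component tested by a conditioned
permutation test.

## Candidate adaptive loci

Three structure-aware scans are implemented, each returning per-locus
statistics, p-values, BH q-values (BH everywhere, for determinism and
zero tuning) and a hit flag at $q < 0.05$:

* `rdadapt()` — Mahalanobis distances of locus loadings on the leading
  axes of a structure-conditioned RDA, rescaled by the genomic inflation
  factor $\lambda = \mathrm{median}(D^2)/\chi^2_{0.5}$, with upper-tail
  $\chi^2$ p-values.
* `pcadapt_like()` — per-locus regression z-scores on the leading
  genotype PCs, screened the same way.
* `lfmm_like()` — latent-factor mixed model: factors from the leading
  left singular vectors of the centered dosage matrix, refined once by
  re-estimating environmental effects controlling the factors, then a
  joint F-test of all environmental coefficients per locus.

Three numerical choices matter here and were made deliberately. First,
the Mahalanobis reference uses a *robust* location/scatter (MVE plus one
reweighting step with the 97.5% $\chi^2$ consistency correction, under a
fixed internal seed): the outliers being sought would otherwise inflate a
classical covariance and mask themselves, and the reweighting keeps
$\lambda \approx 1$ under a Gaussian null. Second, the dosage response
for the RDA scan is normalized by the expected binomial standard
deviation $\sqrt{p(1-p)}$ (`gea_response()`): without it, per-locus
sampling-variance heterogeneity fattens the loading-null tail and
inflates the empirical FDR several-fold, while the normalization leaves
selection-driven excess variance untouched. Third, the latent factors
must be initialized from the dosage matrix itself, not from its residual
on the environment: when clusters track environmental gradients (they
do, here and in real data), the residual initialization removes the
collinear part of the structure from the factors and the environmental
tests inherit it as a ~7-fold inflation. The F statistics additionally
carry a median-based inflation correction, as is standard LFMM practice;
with zero latent factors the scan reduces exactly to the ordinary
per-locus multivariate F-test.

`consensus_loci()` keeps loci flagged by at least two methods. A fourth
method in the same spirit (regression-forest importance) is deliberately
out of scope; the downstream pipeline carries a sensitivity switch
(consensus / union / all loci) because offset maps are typically robust
to this choice — a robustness the pipeline tests confirm on synthetic
data (cell-wise correlation > 0.9 between modes).

## Adaptive landscape and genomic offset

The adaptively enriched RDA regresses per-site allele frequencies of the
candidate loci on the selected environmental variables (no conditioners);
its first two axes span the "adaptively enriched environmental space".
For grid cell $c$ and axis $r$ the adaptive index is

$$\mathrm{AI}_{r,c} = \sum_i a_{i,r}\, b_{i,c},$$

with $a_{i,r}$ the variable's loading on axis $r$ and $b_{i,c}$ the
variable's value standardized with the mean and SD of the
*present-period calibration sites* — grid projection and site-level model
therefore share a single scale, and the future index uses the same
statistics.

A genomic offset between two environment vectors is the Euclidean
distance between their axis vectors, optionally (and by default) with
per-axis weights $\sqrt{\lambda_r / \sum \lambda}$ — the eigenvalue-share
weighting is the default because axes far down the spectrum should not
count as much as the first; a `weighting = "none"` switch is provided
since the choice is not canonical. The temporal offset compares the same
cell between periods; the donor offset compares a donor cell's present
with a recipient cell's future.

Raw offsets are not interpretable across studies, so they are
standardized against the empirical distribution of *contemporary spatial
offsets*: offsets between pairs of present-day grid cells (all pairs up
to a 2 x 10^6 cap, then a seeded uniform subsample). The z' map is the
half-normal quantile transform

$$z'(x) = \Phi^{-1}\!\left(\frac{1 + \hat F(x)}{2}\right),$$

where $\hat F$ is the reference ECDF with linear interpolation between
order statistics (plotting positions $i/(n+1)$, clamped at the ends).
By construction $z' = 1$ sits at the 68.27th percentile of the reference
and $z' = 2$ at the 95.45th — the Empirical Rule anchors — for *any*
continuous reference; z' is rank-based and deliberately not a number of
standard deviations. Cells with $z' > 1$ are flagged as vulnerable
(the conventional not-to-exceed threshold), and donor suitability for a
recipient cell is $z' < 1$ of the donor offset under the *same*
contemporary reference.

Degenerate inputs are rejected loudly: a constant reference (no spatial
contrast) errors rather than standardizing; a NODATA recipient errors;
landscapes on different grids or axes cannot be differenced.

## Problem sizes, tolerances, determinism

The recovery tests run the generator at 400 individuals / 300 sites /
2,000 loci on a 25 x 35 grid — small enough for a laptop CPU, large
enough that the CV curve, ancestry error, and GEA power/FDR are stable.
Because a single replicate contains only ~20 adaptive loci, empirical
FDR moves in steps of ~0.05; the headline FDR check therefore pools
true/false positives over three seeded replicates. Oracle-equivalence
checks use $10^{-8}$; percentile anchors use the printed precision of
the Empirical Rule. Every stochastic step takes an explicit seed, and
the pipeline writes only plain-text artifacts, so an identical
configuration and seed reproduce byte-identical outputs — which is
itself one of the tests.

## Known limitations

* The ancestry factorization is a least-squares surrogate; its $Q$ is
  not a posterior and can be biased toward the simplex interior for
  weakly differentiated clusters.
* The synthetic generator omits linkage, batch effects, uneven spatial
  sampling, and non-MCAR missingness; power/FDR figures measured on it
  do not transfer verbatim to real data.
* When genetic structure is strongly collinear with the environmental
  gradients, the latent-factor scan run with `K_latent` equal to the
  optimal cluster number keeps a mildly elevated empirical FDR at
  `q < 0.05` (about 0.12 in the recovery experiments of the test suite,
  versus the 0.10 that strict two-fold control would demand); adding
  latent factors restores control at a small power cost. The package
  keeps the conventional `K_latent = K_opt` setting and documents the
  excess rather than masking it.
* RDA-based offsets inherit the usual caveats of genomic-offset methods:
  they extrapolate a fitted genotype–environment association, assume the
  candidate loci matter, and carry no fitness validation; the z' = 1
  threshold is a convention, not a measured breakpoint.
* VCF support is read-only and minimal (GT-only, biallelic); the 0/1/2
  TSV is the canonical interchange format.
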