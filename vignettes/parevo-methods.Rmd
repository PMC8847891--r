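---
title: "Angles, correlations and eigenstructure of phenotypic change vectors"
author: "parevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angles, correlations and eigenstructure of phenotypic change vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parevo)
```

## The problem

When several lineages diverge from their respective ancestors, each
lineage's evolution can be summarized as a *phenotypic change vector*: the
difference between descendant and ancestor trait means in a common
$p$-dimensional trait space. Parallel evolution, in the geometric sense, is
similarity of the *directions* of these vectors, and the angle
$\theta_{ij} = \arccos(r_{ij})$ between two change vectors — equivalently
their vector correlation $r_{ij}$, the cosine — is the natural measure of
(non)parallelism.

The catch is that random directions in a high-dimensional space are not
"anywhere": they concentrate tightly around the right angle. Under the null
hypothesis that two directions are independent and have no preferred
orientation (uniform on the unit hypersphere in $k$ dimensions), the angle
has density

$$ f(\theta) = \frac{\sin^{k-2}\theta}{B(1/2,\,(k-1)/2)},
   \qquad 0 \le \theta \le \pi, $$

which is flat for $k = 2$ and increasingly peaked at $\pi/2$ as $k$ grows.
An observed angle of, say, $80^\circ$ between two vectors in a
76-dimensional trait space is strong evidence of parallelism, not of
near-orthogonality, because random pairs essentially never stray that far
from $90^\circ$. All inference in this package is built on this null law
and its equivalent forms:

* $t = \sqrt{k-1}\, r/\sqrt{1-r^2}$ is $t$-distributed with $k - 1$
  degrees of freedom (`pangle()`, `angle_test()`);
* $r$ has density $(1-r^2)^{(k-3)/2}/B(1/2, (k-1)/2)$ (`dveccor()`);
* $r^2 \sim \mathrm{Beta}(1/2, (k-1)/2)$, with mean $1/k$ and variance
  $2(k-1)/\{k^2(k+2)\}$ (`sqcor_moments()`).

```{r nulllaw}
# the same tail three ways: t map, closed-form k = 3 cap area, quadrature
pangle(pi / 3, k = 3)
(1 - cos(pi / 3)) / 2
integrate(dangle, 0, pi / 3, k = 3)$value
```

## Effective dimensionality

The parameter $k$ is the number of dimensions of *free* variation, not the
nominal trait count. Procrustes-aligned shape coordinates from a 2-D
landmark analysis lose 4 degrees of freedom to alignment, so 80 nominal
traits with 4 lost degrees of freedom give $k = 76$ (`effective_dim(80, 4)`).
Because the package cannot know how traits were constructed, $k$ is always
supplied by the analyst (directly or as `lost_df`); it defaults to $p$ only
when nothing is declared. Using a too-large $k$ makes every test
anticonservative in the parallel direction, so this is the single most
important input to get right.

## Multiple lineages: correlation structure and one-step tests

For $n$ lineages, rows of the $n \times p$ matrix $X$ are normalized to
unit length ($Z$), and $C = ZZ^T$ collects all pairwise vector
correlations. `pairwise_angle_report()` tests each pair two-sidedly
against the $k$-dimensional null and flags pairs below the $\alpha/2$
angle quantile (parallel-extreme) or above the $1-\alpha/2$ quantile
(antiparallel-extreme). Two caveats are deliberate:

* the pairwise p-values are dependent (off-diagonal correlations covary
  except under exact uniformity), so the flags are a descriptive screen;
  no multiplicity control is applied by default, and the optional
  Bonferroni adjustment is conservative but not exact under that
  dependence;
* a pair exactly on a quantile boundary is treated as non-extreme (the
  convention is ours; ties have probability zero under continuous data).

The one-step test of the global null "all directions independent and
uniform" uses the sum of squared correlations
$S = \sum_{i<j} r_{ij}^2$, which equals half the dispersion of the
eigenvalues of $C$:

$$ \sum_{i=1}^n (l_i - \bar l)^2
   = \sum_{i=1}^p (k_i - \bar k)^2 + \frac{n^2}{p} - n
   = 2 \sum_{i<j} r_{ij}^2 , $$

where $l_i$ and $k_i$ are the eigenvalues of $C$ and of the inter-trait
cross-product $A = Z^T Z$. The package computes both decompositions
(`eigen_C()`, `eigen_A()`); they share their nonzero eigenvalues, but the
$A$-side eigenvectors live in the trait space and are the basis used for
ordination and biplots. Under the null, $E(S) = n(n-1)/(2k)$ and
$\mathrm{Var}(S) = n(n-1)(k-1)/\{k^2(k+2)\}$, and the standardized
$Z = (S - E)/\sqrt{\mathrm{Var}}$ is asymptotically standard normal in the
high-dimensional regime; `schott_test()` reports the one-sided upper
p-value, since concentration inflates $S$.

```{r schott}
schott_moments(13, 76)   # worked-example-sized null moments
uz <- sample_uniform_directions(13, 76, seed = 1)
schott_test(uz, mode = "asymptotic")
```

Because the asymptotic approximation is slightly liberal when $n$ or $k$
is below about 16, `mode = "auto"` switches to a Monte Carlo null there
(default 10,000 replicates; note the attainable p-value floor
$1/(\text{reps}+1)$). Two equivalent null generators are provided —
normalized Gaussian rows, and a Wishart draw rescaled to a correlation
matrix — and cross-checked against each other in the test suite.

`rayleigh_test()` computes $T = nk\|\bar z\|^2$ with a $\chi^2_k$
reference. It is the more powerful choice against a *single* preferred
direction but is structurally blind to antipodal and girdle patterns,
whose mean resultant vanishes; `schott_test()` detects those but cannot
tell them apart — inspect $C$ or the ordination scores to see which
pattern is present. `mean_pairwise_angle_test()` is included for
completeness with a recorded note that the mean pairwise angle has no
clear interpretation beyond this specific null.

## Simulation models

`direction_model()` defines the regimes used for calibration and power
work:

* **uniform** — normalized i.i.d. Gaussian vectors (the null);
* **vmf** — von Mises–Fisher with mean direction $\mu$ and concentration
  $\kappa \ge 0$, sampled by Wood's (1994) rejection algorithm on the
  cosine component; $\kappa = 0$ reduces exactly to uniform. Useful
  intuition: the mean resultant length is roughly $1 - (k-1)/(2\kappa)$
  for large $\kappa$, so meaningful concentration in high dimensions needs
  $\kappa$ of order $k$;
* **antipodal_vmf** — an axial two-mode pattern. By default exactly half
  the sample (rounding down) is flipped to $-\mu$, which makes each
  sample's mean resultant (near-)zero by construction — the cleanest
  realization of "axial concentration without a preferred polarity". With
  `balanced = FALSE` each vector flips independently, which leaves a
  binomial residual resultant of order $1/\sqrt{n}$ in small samples and
  correspondingly mildly inflates Rayleigh rejection;
* **girdle** — concentration near the hyperplane orthogonal to a stated
  normal. The literature names this pattern but no canonical generating
  model, so the parameterization is a package convention: a uniform draw
  is projected into the hyperplane and perturbed along the normal with
  standard deviation $1/\sqrt{1+2\kappa}$, then renormalized.

`specimen_model()`/`sample_specimens()` add the specimen level: Gaussian
within-group noise of common standard deviation around programmed
ancestor/descendant means. This generator emulates balanced,
homoscedastic, independent sampling; it does not emulate phylogenetic
correlation among lineages, heteroscedasticity between groups, or
non-Gaussian trait noise, so passing calibration tests here does not by
itself establish robustness to those features of real data.

## Exploratory tools

`biplot_layout()` uses the SVD $Z = UDV^T$ with the standard scaling
convention: scores $U_2 D_2^{1-\alpha}$ and trait coefficients
$V_2 D_2^{\alpha}$, $\alpha \in [0,1]$ (default 1, full singular values on
the coefficients). Any $\alpha$ reconstructs the same rank-2 cross-product;
$\alpha$ only redistributes scale between points and arrows.

`bootstrap_directions()` resamples specimens with replacement within each
lineage × role cell, recomputes change vectors, renormalizes them (the
direction, not the magnitude, is the object of study — a convention, since
either choice is defensible), and projects onto the *fixed* leading
eigenvectors of the observed data, so replicate clouds for all lineages
live in one common frame. Ellipses are normal-theory 95% ellipses from the
replicate covariance and the $\chi^2_2$ quantile — a reproducible choice
where a convex-hull ellipse would depend on plotting details. Lineages
with short change vectors show visibly larger directional ellipses under
identical noise: direction is poorly determined when the trajectory is
short.

`kmeans_grouping()` runs standard k-means on the unit vectors over a grid
of cluster counts (50 random restarts by default, best within-group sum of
squares kept, seed recorded). No automatic selection of the number of
clusters is attempted. The boundary case `k = n` (each lineage its own
cluster, zero within-group sum of squares) is handled directly because the
underlying `stats::kmeans()` refuses it.

## Numerical choices

* Correlations are clipped into $[-1, 1]$ with tolerance $10^{-12}$ before
  arccosines; larger excursions raise errors rather than being silently
  absorbed.
* For $k = 2$ the density of $r$ diverges at $|r| = 1$; `dveccor()`
  returns `Inf` there (the distribution function remains proper) instead
  of raising an error.
* `pangle()`/`qangle()` work through the monotone cotangent map to the
  $t$-distribution; in double precision the CDF saturates at 0/1 for
  extreme angles at large $k$, which bounds the invertible range.
* Eigenvalues are clipped at zero when they are small negative numerical
  noise; eigenvector polarity follows the convention that each column's
  largest-magnitude element is positive. With tied eigenvalues any
  orthonormal basis of the eigenspace may be returned, so tests compare
  eigenvalues and reconstructions, never individual eigenvectors, in
  degenerate cases.
* Every stochastic function takes an explicit `seed`, restores the
  caller's RNG stream, and records the seed (drawing one if the caller
  supplied none) in its result; `full_report()` derives its stage seeds as
  `seed` and `seed + 1`.

## Problem sizes used in the checks

The package's self-checks run the distributional comparisons at $10^5$
simulated pairs for $k \in \{3, 10, 76\}$, size calibration of the Schott
($n = k = 40$) and Rayleigh ($n = 50$, $k = 10$) tests at 5000 null
replicates, the eigenvalue-dispersion identity on 100 random
configurations with $n \le 30$, $p \le 200$, and power contrasts at 1000
replicates — sizes at which the binomial error of a rejection-rate
estimate (about $\pm 0.003$ at rate 0.05, $n = 5000$) is well inside the
tolerances asserted.

## Known limitations

* All tests address the single null of independent, uniformly distributed
  directions. Non-null distribution theory of $r$ (arbitrary population
  correlation) and tests against complete parallelism are out of scope.
* $k$ must be supplied honestly; nothing in the data identifies it.
* Angles are only meaningful in a Euclidean trait space (commensurate
  units); the package does not attempt unit standardization.
* Lineages are assumed independent; phylogenetically correlated lineages
  violate the null in ways these tests do not model.
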