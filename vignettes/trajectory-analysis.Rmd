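---
title: "Quantifying repeated evolution with phenotypic trajectory vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeated evolution with phenotypic trajectory vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotraj)
```

## The question and the model

Island radiations of *Anolis* lizards repeatedly evolved the same set of
ecomorphs — species groups adapted to the same microhabitat — on Cuba,
Hispaniola, Jamaica and Puerto Rico. `morphotraj` asks how *repeatable*
that divergence is at the level of the locomotor skeleton: if a pair of
ecomorphs diverged along some direction in trait space on one island, did
the same pair diverge along a parallel direction, and by a similar amount,
on another island?

The unit of analysis is the **trajectory vector** between two groups. For
groups $A$ and $B$ measured on $m$ standardized traits, the vector
$\mathbf{a}$ has one independent two-sample $t$-statistic per trait, signed
as $\bar{x}_A - \bar{x}_B$: each element is the difference in trait means
expressed in standard errors. Two such vectors, one per island, are
compared by

$$\Theta = \arccos\!\left(\frac{\sum_i a_i b_i}
  {\sqrt{\sum_i a_i^2}\sqrt{\sum_i b_i^2}}\right)\cdot\frac{180}{\pi},
  \qquad
  \Delta L = \sqrt{\textstyle\sum_i a_i^2} - \sqrt{\textstyle\sum_i b_i^2}.$$

$\Theta = 0^\circ$ means the islands diverged along parallel directions;
independent random vectors average $90^\circ$. $\Delta L$ compares the
magnitudes of divergence. An alternative parameterisation uses raw
mean-difference vectors instead of $t$-values
(`mean_difference_vector()`); the two give closely correlated angles and
`angle_method_correlation()` quantifies that agreement.

## From specimens to the trait space

The 132-trait space combines heterogeneous measurements, assembled by
`assemble_traits()` in fixed column order:

* **108 Procrustes shape variables** — 18 three-dimensional landmarks on
  each of the pectoral and pelvic girdles, superimposed per girdle by
  generalized Procrustes analysis (`gpa()`): translation to centroid
  origin, scaling to unit centroid size, and iterative rotation-only
  alignment to the evolving mean shape. Right-side girdles are reflected
  onto the left side first (`mirror_configuration()`); because the
  alignment never reflects, mirroring is the user's explicit step.
  No tangent-space projection and no principal-component reduction is
  applied: the seven redundant degrees of freedom of superimposed 3D
  configurations are harmless to vector-based analyses, whereas
  standardizing principal components instead of shape variables would
  distort the biological signal.
* **15 relative limb-bone lengths and 8 relative bone thicknesses** — raw
  millimetre measurements divided by the specimen's pelvic-girdle centroid
  size (`size_correct()`), the body-size proxy.
* **1 body-size trait** — the pelvic centroid size itself.

Occasional missing linear measurements (broken bones; about half a percent
in data of this kind) are completed by iterative PCA imputation
(`impute_missing()`): missing cells start at column means and are
repeatedly replaced by a rank-$q$ reconstruction until the largest change
falls below $10^{-8}$ (default rank 3 — low enough to be stable at a few
hundred specimens, high enough to capture the dominant covariation of limb
measurements; observed cells are never altered).

Finally every column is scaled to standard normal deviates
(`standardize_traits()`, sample sd with the $n-1$ denominator): this is
what makes shape coordinates and relative lengths commensurate so a single
vector can span them. The scaling population matters — $L$ in particular
depends on it — so the per-column means and sds are recorded and any other
rows can be projected onto the same scale. The pipeline standardizes over
the museum specimens for island/ecomorph analyses, and the experimental
specimens are projected onto that scale afterwards.

Measurement repeatability of the landmarking chain is quantified by a
Procrustes one-way ANOVA on re-landmarked specimens (`repeatability()`):
the intraclass correlation $R = s^2_{among}/(s^2_{among} + MS_{within})$
with $s^2_{among} = (MS_{among} - MS_{within})/k_0$, pooled over all
aligned coordinates, and $k_0$ the unbalanced-design effective replicate
count $\left(N - \sum_i k_i^2/N\right)/(n-1)$ — the balanced case reduces
to the familiar $k$.

## Testing parallelism

For every **quartet** — an ecomorph pair crossed with an island pair in
which all four cells have at least `min_n` (default 2) specimens —
`quartet_angle_test()` runs two complementary resampling tests:

* **Permutation test of parallelism.** Island labels are shuffled among
  the specimens of each ecomorph (cell sizes preserved), simulating the
  parallel null in which islands are interchangeable. `p_parallel` is the
  smoothed upper tail $(\#\{\Theta_{null} \ge \Theta_{obs}\}+1)/(n+1)$; an
  analogous tail on $|\Delta L|$ gives `p_length`.
* **Bootstrap test against orthogonality.** Specimens are resampled with
  replacement within each cell and $\Theta$ recomputed; `p_orthogonal` is
  the smoothed fraction of bootstrap angles at or beyond $90^\circ$.

`classify_quartet()` combines the two at level $\alpha$: failing to reject
the parallel null makes the angle *indistinguishable from 0°*; failing to
reject orthogonality makes it *indistinguishable from 90°*; rejecting both
places it *between 0° and 90°*. When neither rejects the quartet is
flagged ambiguous rather than forced into a category.

Decomposing a trajectory vector ranks traits by their contribution.
`outlier_traits()` standardizes the 132 $t$-values against their own
distribution and flags traits outside the two-sided 95% normal band —
the "most divergent" traits of an ecomorph contrast or the "most plastic"
traits of a rearing treatment. On pure noise this flags about
$132 \times 2 \times 0.05 \approx 13$ traits, so observed counts should be
read against that baseline, not against zero.

## Convergence on the phylogeny

`wheatsheaf()` measures whether the species of one ecomorph are more
similar to each other than the radiation at large, discounting similarity
explained by relatedness. Euclidean distances between species means are
penalized by phylogenetic proximity,
$d'_{ij} = d_{ij}\big/\sqrt{t_{ij}/t_{max}}$ with $t_{ij}$ the patristic
distance, and the index is the ratio of the mean penalized distance over
all pairs to the mean over focal pairs; $w > 1$ indicates convergence.
Significance comes from size-matched random focal sets. The penalty
constant may differ from other published implementations of the same idea,
so the package's guarantees about $w$ are property-based (exact $w = 1$
when the focal set is everything; invariance to global trait scaling;
uniform $p$ under Brownian motion) rather than numeric reproduction of any
published table. `signature_scan()` applies the index per trait to find an
ecomorph's "signature traits".

## Sex assignment

Museum specimens of unknown sex are classified from pelvic shape
(`lda_fit()` / `lda_assign()`): a pooled-covariance Gaussian discriminant
whose covariance is shrunk toward its diagonal (default coefficient 0.1),
necessary because 54 shape variables can approach or exceed the available
specimen counts. Assignments are accepted only at posterior $\ge 0.8$;
`split_validate()` reports accuracy among accepted assignments under a
stratified 60/40 split.

## The synthetic study

`simulate_study()` generates a full dataset with the statistical structure
the analysis assumes: a unit-height pure-birth phylogeny; species means
that are Brownian motion plus a shared per-ecomorph effect
$\boldsymbol\beta_e$ plus a $\delta$-scaled island-specific deviation;
individuals iid around species means; landmark configurations built from a
fixed template and an orthonormal deformation basis, then randomly
rotated, translated, scaled and partly mirrored; strictly positive linear
measurements co-scaling with specimen size; and uniform missingness in the
linear table. Every generator records its ground truth so recovery can be
verified.

Defaults emulate the comparative design this package targets: 95 species
on 4 islands × 6 ecomorphs with nested absences (one island missing one
ecomorph, one missing two) — which yields exactly 53 testable quartets —
1–14 individuals per species with mean ≈ 2.7, and a rearing experiment of
two species × two treatments with per-treatment sample sizes 41/34 and
22/23. Two generator scales were fixed a priori rather than estimated:

* $\delta = 1.75$ with per-trait ecomorph-effect sd 2, so that
  between-island trajectory angles land in the moderately-parallel
  mid-50-degree regime typical of this kind of radiation
  ($\cos\Theta \approx \beta^2/(\beta^2 + \delta^2)$ per trait in the
  noise-free limit);
* the rearing-experiment effect magnitude, 30 trait-sd units over 132
  traits, the strong-signal regime in which the $t$-vector noise floor
  ($\sqrt{132} \approx 11.5$ against a signal length of
  $30\sqrt{n/2} \approx 134$ at $n = 40$) attenuates recovered angles by
  only a few degrees.

What the generator does *not* emulate: within-species phylogenetic
structure (individuals are iid around species means), correlated
measurement error between traits, allometry beyond the size-division step,
and ecomorph-dependent sampling effort. Tests passing on synthetic data
therefore validate the inference machinery, not these aspects of real
data.

## Numerical choices and degenerate inputs

* GPA converges when the mean shape moves less than $10^{-10}$ (root sum
  of squares) or after 200 iterations; the output orientation is
  canonicalized to the principal axes of the mean shape with a
  deterministic sign convention, so aligned coordinates do not depend on
  the arbitrary orientation of the input scans.
* Zero-variance traits inside a contrast produce $t = 0$ with a warning
  rather than an error, so dataset-wide sweeps do not abort.
* The angle's $\cos$ argument is clipped to $[-1, 1]$; a zero-length
  vector is an error for user-facing calls, while degenerate resampling
  replicates inside the permutation/bootstrap loops (possible when a cell
  of size 2 resamples to a single unique specimen) yield an undefined
  angle that is simply not counted in the null tail.
* All p-values use the $(\text{count}+1)/(N+1)$ smoothing; every
  stochastic operation takes an explicit seed, and `run_pipeline()`
  derives per-quartet seeds from the master seed by stable label hashing,
  making whole reports bitwise reproducible.
* Welch $t$-statistics are the default (a config switch selects the
  pooled-variance variant); the choice barely moves $\Theta$ but does move
  $L$ when cell variances differ.

## Known limitations

The permutation test's null is *exchangeability of specimens across
islands within an ecomorph*, with species pooled. When species effects are
strong (many specimens per species, large phylogenetic variance), island
cells are internally clustered by species and the pooled-specimen
permutation over-rejects relative to the weaker hypothesis "parallel in
expectation": in a simulation with species-level Brownian effects and
perfectly parallel expected divergence, rejection rates far above nominal
are possible. This is a property of the pooling design itself, which
treats specimens, not species, as the resampling unit. The calibration
guarantees in the test suite are therefore stated under the exchangeable
null (no species-level effects), and quartet p-values on real radiations
should be read as tests of island interchangeability, not of
expectation-level parallelism.

Angles between trajectory vectors are attenuated toward $90^\circ$ by
estimation noise (the $t$-vector noise floor), so weak contrasts are
biased against detecting parallelism; and correlations between
quartet angles computed by different methods are range-restricted when a
design makes all quartets equally parallel.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_perm = 199, n_boot = 199, seed = 7)
report <- run_pipeline(cfg)
report
head(report$quartets)
```

The problem sizes used throughout the test suite (desk scale: 18–95
species, 99–999 resampling replicates, 50–200 simulation replicates per
calibration) were chosen so the whole suite exercises every stage at
meaningful power while remaining quick to run on one core.
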