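# morphotraj

Phenotypic trajectory analysis for repeated evolution in island radiations.

When ecologically equivalent species groups — *ecomorphs*, in the classic
*Anolis* sense — evolve independently on several islands, how repeatable
is their morphological divergence? `morphotraj` answers that question for
multivariate morphometric data: it turns 3D landmark configurations of
the pectoral and pelvic girdles plus linear limb-bone measurements into a
standardized 132-trait space, describes the divergence between a pair of
ecomorphs on one island as a **trajectory vector** of per-trait two-sample
*t*-values, and compares island pairs through the angle and length
difference of their vectors:

```
Θ  = acos( Σ aᵢbᵢ / (√Σaᵢ² · √Σbᵢ²) ) · 180/π        (0° = parallel divergence)
ΔL = √Σaᵢ² − √Σbᵢ²                                    (difference in magnitude)
```

Random vectors average Θ = 90°; parallel evolution shows up as angles well
below it. Permutation of island labels within ecomorphs gives the
significance of deviations from parallel; bootstrapping specimens within
cells tests against orthogonality; each ecomorph-pair × island-pair
"quartet" is classified as indistinguishable-from-0°, between, or
indistinguishable-from-90°. Around this core the package provides:

* generalized Procrustes superimposition (rotation-only, with explicit
  mirroring of right-side structures), centroid sizes, Procrustes-ANOVA
  repeatability, iterative-PCA imputation of missing measurements, size
  correction and standard-normal-deviate scaling;
* a Wheatsheaf-style phylogenetic convergence index with permutation
  significance and per-trait "signature trait" scans;
* outlier-based ranking of the traits driving a contrast;
* discriminant sex assignment from pelvic shape with a posterior ≥ 0.8
  acceptance rule and split validation;
* phylogeny utilities (Newick reading, pruning, grafting new tips onto a
  sister branch);
* a ground-truthed synthetic-study generator (pure-birth tree, Brownian
  species effects, shared ecomorph effects, island deviations, landmark
  emulation, a two-species rearing experiment) so the whole chain is
  testable without any external data;
* `run_pipeline()`, which executes every stage end to end with one master
  seed and returns a full report.

## A worked example

A complete simulated study at the design scale the package targets
(95 species, 4 islands × 6 ecomorphs with three absences, 1–14 specimens
per species) processed end to end:

```r
library(morphotraj)

cfg    <- pipeline_config(n_perm = 199, n_boot = 199, seed = 7)
report <- run_pipeline(cfg)
report
#> run_report
#>   quartets: 53 (mean theta 57.90 deg, sd 4.33)
#>   classification: between_0_and_90 = 53
#>   convergence: 6 ecomorph(s), w in [1.38, 1.68]
#>   PCA: PC1 13.13%, PC2 12.25%

head(report$quartets[, c("e1", "e2", "i1", "i2", "theta", "p_parallel")], 4)
#>            e1         e2         i1         i2    theta p_parallel
#> 1 crown-giant grass-bush       Cuba Hispaniola 63.19299      0.005
#> 2 crown-giant grass-bush       Cuba    Jamaica 68.74716      0.005
#> 3 crown-giant grass-bush Hispaniola    Jamaica 65.81424      0.005
#> 4 crown-giant      trunk       Cuba Hispaniola 54.66456      0.005

report$outliers$divergence
#> outlier_scan: 17 of 132 traits flagged (|z| > 1.645 at prob 0.95)
```

Reading the numbers: the default synthetic radiation has shared ecomorph
effects plus island-specific deviations, so all 53 quartet angles fall
between 0° and 90° — divergence that is consistently better aligned than
chance (90°) yet distinguishable from perfectly parallel (0°), with a mean
angle in the mid-50s. The outlier scan standardizes the 132 *t*-values of
the Cuban trunk-ground vs trunk-crown contrast against their own
distribution and flags the traits outside the two-sided 95% band (≈ 13
expected on pure noise). Real specimen tables in the documented format are
analysed the same way by pointing `pipeline_config()` at the files:

```r
cfg <- pipeline_config(specimen_table = "specimens.csv",
                       tree_file = "phylogeny.nwk", seed = 1)
```

The methods vignette (`vignettes/trajectory-analysis.Rmd`) documents the
model, the scaling choices, the resampling schemes, the generator's
assumptions and the known limitations.

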