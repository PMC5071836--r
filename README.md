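# olfclust

Unsupervised pattern discovery in three-subtest olfactory data.

Clinical olfactory testing scores three components of the sense of smell:
the odor detection **threshold** (dilution steps, 1–16), odor
**discrimination** (0–16) and odor **identification** (0–16). `olfclust`
asks, without supervision, whether subjects' subtest *patterns* form
clusters, and how etiologies of olfactory dysfunction (sinunasal disease,
postinfectious loss, head trauma, congenital anosmia, …) distribute over
the discovered clusters. It is aimed at researchers in clinical
psychophysics and biostatistics who want a fully scripted, seeded version
of this analysis — plus a synthetic cohort generator, so the whole pipeline
is runnable and testable without access to clinical data.

## Method

For subject *i* with age- and sex-corrected scores
*s*<sub>i</sub> = (thr, disc, ident):

1. **Age correction.** Per sex and subtest, OLS `score ~ age`; corrected
   score = residual + grand mean.
2. **Density-based featurization.** Each corrected subtest distribution is
   summarized by Pareto density estimation (sphere counts at the Pareto
   radius *r*, the 18% quantile of pairwise distances) and fitted with a
   Gaussian mixture of *m* = 3 components (EM, then least-squares
   refinement against the PDE curve). The Bayesian posterior
   *p*(component *j* | *x*) = *w*<sub>j</sub> φ(*x*; μ<sub>j</sub>, σ<sub>j</sub>) / Σ<sub>k</sub> *w*<sub>k</sub> φ(*x*; μ<sub>k</sub>, σ<sub>k</sub>)
   turns each subject into a 9-vector (low/mid/high membership × 3
   subtests).
3. **ESOM.** A 50 × 80 toroidal self-organizing map (4,000 neurons — an
   *emergent* map, many more units than clusters) is trained online for 30
   epochs on the 9-dimensional features.
4. **Landscape clustering.** The U-matrix (mean weight distance to the 8
   toroidal neighbors), P-matrix (data count within *r* of each neuron) and
   U\*-matrix (U rescaled by local density) form a landscape; valleys =
   clusters, ridges = borders. A quantile-threshold flood fill extracts the
   clusters and each subject inherits its best-matching unit's cluster.
5. **Association.** Etiology × cluster χ² (df = (r−1)(c−1)),
   relDiff = (n<sub>exp</sub> − n<sub>obs</sub>)/(0.5(n<sub>exp</sub> + n<sub>obs</sub>)) ∈ [−2, 2]
   per cell, and Spearman ρ of the subtest pairs per subgroup.

See the vignette (`vignettes/olfactory-pattern-discovery.Rmd`) for every
design choice, default and limitation.

## Worked example

A scaled study — 2,000 synthetic subjects with the three planted
performance profiles (good / abolished / reduced olfaction), a 20 × 30
toroid, 30 epochs:

```r
library(olfclust)
rep <- run_pipeline(olf_config(n_subjects = 2000, rows = 20, cols = 30,
                               epochs = 30, seed = 11))
print(rep)
```

```
Olfactory subtest pattern discovery: n = 2000 subjects
Diagnoses: anosmia 548, hyposmia 864, normosmia 588 
ESOM 20 x 30, 30 epochs; quantization error 0.0771
Clusters: k = 3
 cluster   n thr_median disc_median ident_median majority_profile
       1 924        5.0          10            9          reduced
       2 538       13.5          13           13             good
       3 538        1.5           5            4        abolished
Association: chi-squared = 1150, df = 16, p <2e-16
```

Reading this: the map recovers exactly three clusters. Cluster 2 is the
"good olfaction" pattern (high threshold score 13.5 = detects dilute odors,
good discrimination/identification); cluster 3 is "abolished" (threshold
at the test floor, near-chance discrimination/identification); cluster 1
is "reduced" (medium threshold ≈ 5, reduced but preserved ability).
Cluster ids are ordered by size, so the labels carry no meaning beyond
that — `majority_profile` ties them back to the planted truth. The 9 × 3
etiology-by-cluster table is strongly non-uniform (χ² on 16 df), as planted:
healthy subjects concentrate in the good cluster, congenital anosmia in the
abolished one, postinfectious loss in the reduced one.

```r
rep$correlations[rep$correlations$group == "global", ]
#>    group       pair       rho    n
#> 1 global disc/ident 0.7620425 2000
#> 2 global   disc/thr 0.7980625 2000
#> 3 global  thr/ident 0.8398746 2000
```

All intermediate objects are in `rep$objects` (features, trained grid,
U/P/U\* matrices, cluster assignment); `olf_config(out_dir = ...)` writes
every artifact as CSV/JSON, and `save_heightmap()` exports a terrain-style
PNG of any landscape matrix.

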