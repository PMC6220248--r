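# connectropy

Entropy-optimal thresholding and trait association for structural brain
connectomes.

## What this is for

Studies of brain structural networks start from per-subject weighted
connectivity matrices — an N × N symmetric, non-negative matrix *A* whose
entry *A<sub>ij</sub>* is the tractography-derived connection strength
between gray-matter regions *i* and *j* (here the 83-region
Desikan–Killiany parcellation with subcortical structures: 41 per
hemisphere plus the brainstem). Relating the topology of these networks to
a behavioral trait score requires three methodological commitments that
this package implements as one tested, seeded pipeline:

1. **Top-K binarization with an entropy-optimal K.** Every subject keeps
   only its K strongest edges. K is chosen by maximizing the difference in
   Shannon entropy of edge occurrence between the observed cohort and a
   degree-preserving null ensemble:

   *H* = Σ<sub>i&lt;j</sub> −[*p<sub>ij</sub>* log₂ *p<sub>ij</sub>* +
   (1−*p<sub>ij</sub>*) log₂(1−*p<sub>ij</sub>*)],

   where *p<sub>ij</sub>* is the fraction of networks containing edge
   {i, j}; K\* = argmax (*H*<sub>null</sub> − *H*<sub>actual</sub>). A
   shared anatomical backbone makes the real cohort much more consistent
   than its degree-matched null, and the gap peaks at the backbone's scale.

2. **Graph measures on the binarized networks**: characteristic path
   length (CPL), global clustering coefficient (GCC, both the
   mean-local-clustering and the transitivity variants), small-worldness
   SMW = (GCC<sub>act</sub>/GCC<sub>rand</sub>) /
   (CPL<sub>act</sub>/CPL<sub>rand</sub>) against degree-preserving
   rewirings, and per-node betweenness centrality (BET). All are verified
   against exhaustive brute-force oracles in the test suite.

3. **LASSO-then-OLS association.** The 88 candidate predictors (age, sex,
   CPL, GCC, SMW, and the 83 BET values) are standardized, screened by
   cross-validated LASSO, and the selected set plus age and sex is refit
   by OLS with a single Cook's-distance outlier pass
   (D<sub>i</sub> &gt; 3 × mean) and a p &lt; 0.01 significance flag,
   reported as standardized β, S.E., t, p.

Because cohorts of this kind are rarely shareable, the package also ships
a **synthetic cohort generator** with full ground truth: a shared sparse
backbone, per-subject log-normal noise, effect nodes whose incident edges
scale as exp(γ·z) with a latent subject factor z, and a 12-item trait
questionnaire calibrated to mean 23.5, SD 7.5 with latent internal
consistency 0.81. It is the substrate for every statistical guarantee the
test suite checks (type-I control under the global null, planted-effect
recovery, planted-K recovery).

## Worked example

```r
library(connectropy)

gen    <- generateCohort(generatorConfig(seed = 101))
cohort <- gen$cohort
cohort
#> ConnectomeCohort: 51 subjects, 83 nodes, 12 trait items

scan <- scanOptimalK(cohort, k_grid = seq(83, 383, by = 20),
                     n_random = 100, seed = 102)
scan
#> EntropyScan over 16 thresholds (nRandom = 100)
#>   optimal K = 343 (delta = 1506 bits)
```

The scan recovers the generator's 343-edge backbone: at K = 343 the
observed cohort is maximally more consistent (1506 bits) than its
degree-matched null. Binarize there, compute measures, and run the
association stage:

```r
nets    <- lapply(connectomes(cohort), binarizeTopK, k = optimalK(scan))
metrics <- computeCohortMetrics(nets, subjectIds(cohort), regions(cohort),
                                n_random = 100, seed = 103)
model   <- runAssociation(metrics, cohort, seed = 104)
model
#> AssociationModel: 6 coefficients, 2 significant at p < 0.01
#>   removed subjects: sub-013, sub-046, sub-049
#>   adjusted R-squared 0.382; F = 6.82 on 5 and 42 df

subset(coefficientTable(model), significant)
#>                  term       beta        se         t           p significant
#> 2                 age -0.3235149 0.1171528 -2.761478 0.008497325        TRUE
#> 6 bet_rt. postcentral -0.5790100 0.1719705 -3.366915 0.001635565        TRUE
```

The generator planted effects at nodes 17 ("lt. paracentral", γ = +0.8)
and 64 ("rt. postcentral", γ = −0.8). At n = 51 the pipeline recovers the
negative effect — the betweenness of "rt. postcentral" carries a
standardized β of −0.58 with the correct sign — while the weaker positive
effect does not clear p < 0.01 at this sample size, a realistic picture of
power at 51 subjects (at n = 200 both nodes are recovered in ≥ 80% of
runs; see the acceptance suite). The age term is a chance inclusion:
covariates are forced into the final model by design.

The full pipeline is also available as one seeded call (and as a thin
command-line wrapper, `inst/scripts/connectropy-pipeline.R`):

```r
res <- runPipeline(list(seed = 1,
                        simulate = list(),   # generator defaults
                        k_min = 83, k_max = 383, k_step = 20,
                        n_random = 100,
                        out_dir = "run1"))
```

which writes the cohort manifest and matrices, `ground_truth.json`,
`entropy_scan.csv`, `metrics.csv`, the association report
(`association.csv` / `association.json`), and a run manifest with
per-stage seeds and timings.

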