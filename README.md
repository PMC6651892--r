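# ChimeraZoo

Chimeric multimodal biometric datasets under Doddington-Zoo constraints,
with seeded reproducibility and open-set verification evaluation.

## What problem this solves

Evaluating multimodal biometric fusion (e.g. face + periocular + ECG)
requires datasets where the same subjects appear in every modality — and
those barely exist. The standard workaround is a *chimeric* dataset:
virtual subjects assembled by pairing one real individual per modality
from unrelated unimodal datasets. Unconstrained random pairing, however,
stacks the difficult subjects unevenly between runs and between methods,
so fusion comparisons become irreproducible.

ChimeraZoo builds chimeric datasets under menagerie constraints. Each
modality's individuals are labeled **sheep** (typical), **goat** (high
intra-class variability: the intra-class dispersion ranks above the 70th
percentile), or **lamb** (low inter-class separation: the one-against-all
mean distance ranks in the lower 30th percentile), using the percentile
index

    index = p/100 × N + 1/2

over the N valid individuals, with a seeded permutation retaining 10% of
the candidates per category. Chimeric individuals combine only
like-labeled sources; each category is capped at the modality with the
fewest individuals of that category (10/10/80 combined with 5/5/400 gives
5 goats, 5 lambs, 80 sheep); assignment is injective; samples pair
sequentially within sessions. Every random stage draws its seed
deterministically from one master seed and the whole build is recorded in
a replayable JSON recipe.

Evaluation is open-set verification in distance space: Euclidean /
Manhattan / Spearman / Hamming matching, feature-level fusion by scaled
concatenation, score-level fusion by the sum / min / product of min-max
normalized per-modality scores, genuine–impostor decidability

    d' = |μ_E − μ_I| / sqrt((σ_I² + σ_E²)/2),

DET curves, and the equal error rate, across intra-session and
inter-session scenarios, aggregated over a repeated (default 30-run)
seeded protocol with Welch t-tests against the best method. A synthetic
multi-session generator with plantable goats and lambs makes the entire
pipeline testable without any external data.

## Worked example

```r
library(ChimeraZoo)

specs <- lapply(1:3, function(k)
  list(modalityId = c("ecg", "eye", "face")[k],
       nIndividuals = c(40L, 44L, 48L)[k]))
suite <- generateSuite(syntheticConfig(modalities = specs, seed = 2024L))

cds <- buildChimericDataset(suite, seed = 7L)
cds
#> ChimericDataset: 40 individuals (32 sheep, 4 goat, 4 lamb), 284 samples, 3 modalities
#> master seed 7
```

The smallest modality (40 individuals) caps the build; 10% became goats
and 10% lambs, the rest sheep. Scoring the inter-session scenario (probe =
test session, gallery = training session):

```r
man <- enumeratePairs(cds, "inter")
uni <- scorePairs(man, cds, suite["eye"])
fus <- scorePairs(man, cds, suite, fusion = "sum")
cat(sprintf("eye alone:  d = %.2f, EER = %.4f\n",
            decidability(uni), equalErrorRate(uni)))
cat(sprintf("sum fusion: d = %.2f, EER = %.4f\n",
            decidability(fus), equalErrorRate(fus)))
#> eye alone:  d = 2.61, EER = 0.0940
#> sum fusion: d = 4.25, EER = 0.0230
```

One build is anecdote; the protocol repeats everything under fresh seeds:

```r
rep <- runProtocol(suite, nRuns = 5L, masterSeed = 7L, scenarios = "inter")
reportSummary(rep)
#>             method scenario decidability_mean decidability_sd eer_mean  eer_sd
#> 1              ecg    inter              2.54          0.0854   0.0976 0.01451
#> 2 ecg+eye+face:sum    inter              4.23          0.3135   0.0301 0.01117
#> 3              eye    inter              2.55          0.0565   0.0933 0.00745
#> 4             face    inter              2.64          0.0793   0.0848 0.00951
compareMethods(rep)
#>   scenario           method eer_mean             best     t        p equivalent_to_best
#> 1    inter              ecg   0.0976 ecg+eye+face:sum  8.24 5.06e-05              FALSE
#> 2    inter ecg+eye+face:sum   0.0301 ecg+eye+face:sum  0.00 1.00e+00               TRUE
#> 3    inter              eye   0.0933 ecg+eye+face:sum 10.52 1.58e-05              FALSE
#> 4    inter             face   0.0848 ecg+eye+face:sum  8.33 3.77e-05              FALSE
```

Sum-rule fusion of the three (independent, comparably strong) modalities
roughly triples decidability's gap over the best unimodal method and cuts
the mean EER by ~65%, and the t-tests flag every unimodal method as
significantly worse than the fused one. `buildRecipe(cds)` +
`writeRecipe()` / `replayRecipe()` reproduce any build exactly.

A thin command-line front end over these functions lives in
`inst/scripts/chimera-cli.R` (subcommands `synth`, `label`, `build`,
`evaluate`, `experiment`; every subcommand takes `--seed` and reports the
recipe it used).

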