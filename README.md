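# formucomet

Transformer-based efficacy scoring and in silico screening of
multi-component nanoparticle formulations.

The transfection efficacy of an RNA lipid nanoparticle (LNP) depends on
the whole recipe — which ionizable lipid, helper phospholipid, sterol and
PEG lipid it contains, their molar percentages, and synthesis parameters
such as the N/P ratio and the aqueous/organic mixing ratio. `formucomet`
models the complete formulation: each component becomes a token
(molecular embedding ⊕ Gaussian molar-percentage embedding ⊕ class
embedding → 256-d), formulation-wide parameters become tokens of their
own, and one learned CLS token per prediction task aggregates the set
through pre-LayerNorm self-attention blocks,

```
score_task(x) = MLP_task( CLS_task after N attention blocks over
                          {component tokens, z_N/P, z_phase, CLS_1..T} )
```

with no positional encoding, so the score is invariant to component order
and the component count is free (dual-ionizable LNPs have five component
tokens; branched poly(beta-amino ester) polymers add repeat-unit and
branching-agent tokens).

Training uses a pairwise ranking objective with a label margin,

```
L = -log sigmoid( s_h - s_l - lambda_margin (y_h - y_l) ),   lambda_margin = 0.01
```

over all 2,016 pairs of each 64-formulation batch, with molar-percentage
noise augmentation (sd = 10% of each value) and conflict-averse gradient
combination (coefficient 0.2) across cell-line tasks. Screening uses a
five-model ensemble whose scores are normalized to mean 0 / sd 1 on a
reference dataset, a relative uncertainty `u = sigma / (score - min
reference score)`, and a funnel: exclude candidates within 10% L1 molar
distance of known hits → keep the top 0.1% by ensemble score → drop the
most-uncertain half → K-means diversity selection of the final hits.
Integrated gradients over the multimodal embeddings attribute predictions
to molecule choice, molar composition, N/P and phase per component class.

A bundled synthetic-study generator (catalogue, design grid, latent
efficacy oracle, plate-based label noise) makes every stage testable end
to end with known ground truth; see the methods vignette
(`vignettes/formucomet-methods.Rmd`) for the model, the generator and all
numerical choices.

## Worked example

Generate a synthetic screening campaign, fit the scorer, and rank
formulations:

```r
library(formucomet)

catalogue <- sample_catalogue()   # 7 ionizable / 2 helper / 3 sterol / 2 PEG
grid      <- reference_grid(catalogue)
oracle    <- oracle_config(catalogue, tasks = "dc24", seed = 1)
study     <- generate_dataset(grid, oracle, n = 400, noise_sd = 0.1,
                              seed = 0, catalogue = catalogue)

cfg  <- comet_config(tasks = "dc24", seed = 1)
data <- comet_data(study$formulations, catalogue, cfg)
fit  <- comet(data, cfg, train_config(max_epochs = 8, seed = 1))
fit
#> Set-transformer formulation scorer (trained)
#>   tasks: dc24
#>   2 blocks x 8 heads, d_token 256, 1,352,705 parameters
#>   8 epochs trained, best validation Spearman 0.826

predict(fit, study$formulations[1:3, ], catalogue = catalogue)
#> SYN00001 SYN00002 SYN00003
#>   -7.825   -6.658   -4.026
```

Scores are relative ranking scores: higher means predicted more
efficacious. Against the generator's hidden ground-truth oracle this
8-epoch model already ranks at Spearman 0.868 over all 400 formulations;
the five-model ensemble used for screening (see below) reaches ≈ 0.96 on
held-out formulations. Continue with `comet_ensemble()` →
`screen_library()` for virtual-library screening,
`lead_optimization_segments()` for local optimization around a hit, and
`integrated_gradients()` / `feature_importance_summary()` for
attribution.

A thin command-line wrapper over the same functions ships in
`inst/exec/formucomet` (subcommands `enumerate`, `simulate`, `train`,
`screen`).

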