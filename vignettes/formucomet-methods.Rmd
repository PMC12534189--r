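---
title: "Scoring multi-component nanoparticle formulations with a set transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-component nanoparticle formulations with a set transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formucomet)
```

## The problem

The transfection efficacy of an RNA lipid nanoparticle (LNP) is a property
of the whole formulation, not of any single ingredient: it depends on which
ionizable lipid, helper phospholipid, sterol and PEG lipid are combined, on
their molar percentages, and on synthesis parameters such as the
nitrogen-to-phosphate (N/P) ratio and the aqueous/organic mixing ratio.
Single-molecule activity models cannot represent this, and grid screening
becomes intractable as the number of design axes grows. `formucomet`
implements an end-to-end formulation scorer: a transformer over a *set* of
component tokens that predicts a relative efficacy score per cell-line
task, the ranking objective and multitask machinery to train it, the
ensemble/uncertainty funnel to screen virtual libraries of millions of
candidates, and integrated-gradients attribution to interpret what the
model has learned.

## Model

Each formulation becomes a token set:

* **Component tokens.** Every component contributes one token built from
  three embeddings: a frozen 512-d molecular embedding of its structure, a
  128-d Gaussian-basis embedding of its molar percentage, and a 128-d
  class embedding (ionizable / helper / sterol / PEG / polymer repeat unit
  / branching agent). The 768-d concatenation passes through a two-layer
  MLP to a 256-d token. The Gaussian layer is shared across components.
* **Formulation-wide tokens.** The N/P ratio is encoded by its own 256-d
  Gaussian-basis layer and enters as a token; the aqueous/organic ratio is
  a categorical embedding over a closed vocabulary (unseen categories are
  errors, never silently embedded).
* **CLS tokens.** One learned 256-d CLS token per task joins the set. All
  tasks' CLS tokens ride in a single joint pass and may attend to each
  other as ordinary set members.

The set passes through pre-LayerNorm transformer blocks
(`x + Attn(LN(x))`, then `x + MLP(LN(x))`), a final layer norm, and a
two-layer MLP head per task that reads that task's CLS state out to a
scalar score. There is **no positional encoding**: the architecture is
permutation-invariant over component tokens by construction, which the
test suite asserts to 1e-5. Variable component counts are free — a
dual-ionizable LNP simply has five component tokens, a polymer-LNP adds
repeat-unit and branching-agent tokens.

Scores are *relative*: the model is trained to rank, so only differences
between scores carry meaning. For screening, per-model scores are
normalized against a reference set (below), which fixes the scale.

### The molecular encoder

The molecular encoder is pluggable (`register_molecular_encoder()`); any
map from SMILES to a fixed-length vector qualifies, including pretrained
3D encoders. The bundled default is deterministic and download-free: a
radius-2 circular fingerprint (ECFP4 via OpenBabel) folded to 504 bits,
concatenated with 8 scaled physicochemical descriptors (MW, logP, TPSA,
molar refractivity, H-bond acceptor/donor counts, fluorine count). The
descriptor block matters: a binary substructure fingerprint assigns
*identical* vectors to chain-length homologues such as C14- and C18-tail
PEG lipids, because elongating an alkyl chain adds no new radius-2
environment. Lipid catalogues are full of homologous series, so without
the descriptors the model is structurally blind to one of the design axes.
The encoder is frozen: no gradient flows into it, which the gradient-norm
audit in the test suite checks.

## Training

* **Pairwise ranking with label margin.** Within each batch of 64
  labelled formulations, every ordered pair (2,016 per full batch)
  contributes `-log sigmoid(s_h - s_l - lambda_margin (y_h - y_l))` with
  `lambda_margin = 0.01`; exact label ties are dropped. At zero score gap
  the loss is `log 2`, the no-information value. A squared-error
  regression objective is available as the ablation arm.
* **Noise augmentation.** Each molar percentage m is perturbed by
  `N(0, (0.1 m)^2)` during training (clipped at zero, composition not
  renormalized) — emulating fluid-handling variability. Labels are never
  touched; assay-level noise is the synthetic generator's job.
* **Multitask combination.** Per-task gradients are merged by
  conflict-averse gradient descent with coefficient `c = 0.2`: the update
  direction maximizes the worst-case task improvement within a ball of
  radius `c ||g0||` around the average gradient `g0`, solved in the
  standard dual form over simplex weights and rescaled by `1/(1+c)` so
  identical task gradients pass through unchanged. `c = 0` recovers plain
  gradient averaging; the tests compare the direction against a
  brute-force minimax solve on 2-d toys.
* **Optimizer and schedule.** Adam with learning rate 1e-3 (the training
  procedure's learning rate and epoch budget are implementation choices;
  we found 1e-3 with early stopping on validation Spearman, patience 8,
  reliable at these model sizes and document both as configurable
  defaults). All randomness flows from explicit seeds; two runs with the
  same seed produce bit-identical weights.

### Network size defaults

Token width 256, 8 heads, feed-forward width 512 and head width 128
follow the architecture described above; the number of transformer blocks
defaults to **2**. Scoring quality on the bundled synthetic study is
indistinguishable between 2 and 4 blocks while training cost roughly
halves, and the package targets CPU-scale experimentation; deeper stacks
are one `comet_config(n_blocks = )` away.

## Ensembling, uncertainty and the screening funnel

Five models are trained on five disjoint validation folds
(`comet_ensemble(mode = "folds")`; `mode = "seeds"` gives the fixed-split,
different-initialization variant used for in silico evaluation). Because
ranking objectives leave each model's score scale arbitrary, each model is
normalized by the mean and standard deviation of its scores on the
reference (training-role) dataset — population standard deviations
throughout, for exact reproducibility — making the reference scores mean 0
/ sd 1 per model and the ensemble mean invariant to per-model affine
rescaling. The relative uncertainty of a candidate is the ensemble
standard deviation divided by the shifted score
`yhat = ensemble - min(reference ensemble)`; candidates with `yhat <= 0`
are dropped outright.

`screen_library()` chains the full funnel: stream the virtual library in
chunks (the library object decodes formulations from their index — a
50-million-candidate space is never materialized); exclude candidates
within a 10% L1 molar distance (inclusive) of known hits, comparing only
candidates with the same lipid set; keep the top `floor(0.001 N)` by
ensemble score (ties broken by enumeration order); drop flagged
candidates and the most-uncertain half (`floor(N/2)` retained); cluster
the survivors' composition vectors with K-means (best of 1,000 restarts by
total within-cluster sum of squares) and return the top scorer per
cluster. Stage counts are monotone nonincreasing and every stage is
deterministic given the seed and grid.

`lead_optimization_segments()` implements local search around a known hit
through three disjoint zones — same lipids within 20% L1, at least one
substituted lipid within 20% L1, and a synthesis-parameter zone (different
N/P for lipid leads; dual-ionizable variants for polymer leads) — and
returns the ensemble-best candidate per zone.

## Attribution

`integrated_gradients()` works in embedding space: the inputs are the
768-d component concatenations, the N/P Gaussian token and the phase
token. The baseline is the class-conditional mean embedding of a
reference dataset (each component is compared against the mean embedding
of reference components of its own class; N/P and phase tokens against
their reference means). Gradients along the straight path are accumulated
with a midpoint rule (`n_steps` default 128) and summed into feature
groups: molecule choice per class (fingerprint + class-embedding
coordinates), molar percentage per class (Gaussian coordinates), N/P, and
phase. Completeness — grouped attributions summing to
`f(x) - f(baseline)` — holds to well under 1% of the score gap whenever
the gap is non-degenerate; for gaps near zero the relative criterion is
ill-posed because midpoint quadrature noise at ReLU kinks (about 1e-3
absolute at these model sizes) dominates, so the tests assert the relative
bound only for gaps above 0.1. Per-model group attributions are normalized
to maximum absolute value 1 and averaged across ensemble members.
`export_representations()` emits the CLS states of the ensemble member
most Spearman-correlated with the ensemble scores, optionally class
balanced with dual-ionizable formulations as their own class, ready for
t-SNE or any other embedding viewer.

## The synthetic study

`sample_catalogue()` + `reference_grid()` + `oracle_config()` +
`generate_dataset()` reproduce the *shape* of a large real screening
campaign so every stage is testable without measured data:

* A catalogue of 7 ionizable lipids, 2 helpers, 3 sterols and 2 PEG lipids
  drawn from a bundled pool of representative structures (PEG lipids
  truncated to short PEG segments; some multi-amine lipidoids simplified —
  the pool is a synthetic stand-in, not reference data), padded with
  chain-elongated homologues when more molecules are requested.
* A design grid of 13 named molar compositions built from a BASE ratio
  (35/16/46.5/2.5 ionizable/helper/sterol/PEG) by single-class
  variations, molar sweeps (24 points, 10–80%) for three classes,
  ionizable/RNA weight ratios 10/15/20 (converted to N/P through amine
  and per-nucleotide stoichiometry), two phase ratios, and 60:40
  dual-ionizable pairs.
* A latent oracle with additive per-molecule potencies (largest spread
  for ionizable lipids), quadratic penalties around per-class molar
  optima, a dual-ionizable synergy matrix, a smooth N/P bump and a
  phase-by-helper interaction — the effect families reported in real
  screens.
* A plate model: formulations are assigned to plates with a per-plate
  standard; each replicate readout is standard x 10^(standardized oracle)
  x lognormal handling noise (multiplicative before the log transform,
  hence additive in log space, matching bioluminescence assay behaviour);
  four replicates are averaged on the ratio scale, log-transformed and
  min–max normalized to [0, 1] — exactly the pipeline `normalize_labels()`
  applies to real plate data. The log base is 10 by default and irrelevant
  after min–max scaling.

The oracle values ship in a separate object from the labelled table, so
they cannot leak into model inputs. At the default handling noise (sd 0.1
in natural log), labels and oracle agree at Spearman ≈ 0.9997 — the noise
perturbs labels but barely the ranking, so recovery failures indicate
modelling problems, not label noise.

What the generator does *not* emulate: cell-line-specific biology beyond
independent oracle draws per task, lot-to-lot reagent variability,
plate-position effects, or any systematic measurement bias. Passing the
recovery study therefore shows the architecture, training loop, and
funnel are sound — not that the model will reach any particular accuracy
on real measured campaigns.

## Problem sizes and numerical choices

The bundled validation study trains a five-model fold ensemble on 2,000
synthetic formulations (batch 64, at most 15 epochs with patience 5) and
evaluates against the hidden oracle on a 400-formulation held-out test
set; on one CPU core this takes a few minutes and reaches ensemble
Spearman ≈ 0.96, comfortably above the 0.8 recovery bar, with the
ensemble at or above the mean single-model Spearman. Other fixed choices:

* Molar compositions must sum to 100%; sums off by at most 0.01 are
  renormalized with a warning, larger deviations are rejected.
* Molar percentages enter the Gaussian encoder on the 0–100 scale;
  Gaussian means are initialized evenly over [0, 100] (molar) and
  [0, 60] (N/P) with widths equal to the grid spacing, parameterized as
  log-widths so positivity survives training.
* Population (divide-by-N) standard deviations everywhere scores are
  normalized; floor semantics for the top-fraction and half-drop stages;
  ties broken by enumeration order. These make every selection
  deterministic and reproducible from the run manifest.
* K-means restarts default to 1,000, combined by best inertia.
* Degenerate inputs: empty batches, unknown molecule/task/phase labels,
  non-positive readouts, all-equal labels and zero reference spread are
  errors with named messages, not silent coercions.

## Known limitations

* The default molecular encoder is a fingerprint-plus-descriptor stand-in;
  structure resolution is limited to what radius-2 substructures plus bulk
  descriptors can express. Plug in a pretrained 3D encoder through the
  registry for more chemistry-aware embeddings.
* Ranking scores have no absolute units; cross-study comparisons require
  the reference-set normalization path.
* The polymer representation carries the repeat unit's molar percentage
  and the branching agent's identity only; branching stoichiometry and
  molecular-weight distributions are not modelled.
* Particle physicochemical characterization (size, PDI, zeta potential,
  encapsulation) is deliberately out of scope; such measurements are weak
  proxies for efficacy.
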