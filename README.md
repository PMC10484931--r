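# foldrank

Consensus ranking, refinement control and evaluation for protein
structure model pools.

## What problem this solves, and for whom

AlphaFold2-era structure prediction pipelines generate *pools* of
candidate models per target — from diverse multiple sequence alignments,
alternative template databases and repeated sampling, plus monomer
models cut out of predicted protein assemblies. The accuracy of the
final submission then hinges on the decision layer: scoring the pool,
picking five models, deciding whether to refine, and composing the
submission when assembly-derived models are present. `foldrank` is that
decision layer as a reusable, fully offline R package, aimed at
structural bioinformaticians building or studying CASP-style prediction
pipelines.

The heavy engines (sequence search, structure search, the folding
network) are abstracted behind two one-function backend contracts, with
deterministic mock backends included, so the entire workflow — including
the iterative refinement loop — runs and is tested without any external
tool or download.

## The statistics at its core

For a pool of $n$ models with pairwise structural similarity
$S_{ij}$ (TM-score by default) and per-model global confidence
$p_i$ (mean pLDDT, 0–100):

- consensus (APOLLO) score
  $a_j = \frac{1}{n-1}\sum_{i\neq j} S_{ij}$,
- pLDDT-weighted similarity
  $w_j = \frac{1}{n-1}\sum_{i\neq j} S_{ij}\,p_i$ (the weight is the
  *other* model's confidence),
- the hybrid average $\tfrac12\,(a_j + p_j/100)$,
- global pLDDT itself.

Supporting machinery: TM-score with
$d_0 = \max(1.24\,(L-15)^{1/3}-1.8,\,0.5)$, GDT-TS over 1/2/4/8 Å
cutoffs, superposition-free CA-lDDT, Kabsch superposition, per-target
ranking loss and Pearson correlation, pool diversity (PSS), a weighted
z-score combiner, A3M alignment handling with 90% redundancy filtering
and Neff, conversion of structure-search hits into alignment rows, a
five-iteration pLDDT-gated refinement controller, assembly-aware
submission composition and region grafting, and deterministic synthetic
fixtures. See the methods vignette
(`vignettes/foldrank-methods.Rmd`) for definitions and design choices.

## Worked example

Score, rank and evaluate a synthetic pool with a known answer:

```r
library(foldrank)

native <- make_helix(30, model_id = "native", target_id = "T_demo")
pool   <- make_pool(native, sigmas = c(0.3, 0.8, 1.5, 2.5, 4), seeds = 1:2)

sim    <- similarity_matrix(pool)          # pairwise TM-score, symmetrised
scores <- qa_scores(pool, sim = sim)
head(dplyr::arrange(scores, dplyr::desc(apollo_plddt_avg)), 3)
#> # A tibble: 3 × 5
#>   model_id    plddt_global apollo apollo_plddt_avg apollo_plddt_weight
#>   <chr>              <dbl>  <dbl>            <dbl>               <dbl>
#> 1 m01_s0.3_r1         74.1  0.367            0.554                14.6
#> 2 m02_s0.3_r2         74.1  0.357            0.549                14.3
#> 3 m03_s0.8_r1         44.9  0.360            0.405                15.1

pss(sim)
#> [1] 0.2697
```

The two gently perturbed models (noise 0.3 Å) top the hybrid ranking —
they are both self-confident and close to the pool consensus — and the
low PSS (0.27) correctly flags a conformationally diverse pool.
Evaluating against the hidden native confirms the selector:

```r
ev <- evaluate_against_native(pool, native,
        scores = tibble::tibble(model_id = scores$model_id,
                                score = scores$apollo_plddt_avg))
glance(ev)
#> # A tibble: 1 × 9
#>   target_id n_models best_tm_score best_gdt_ts correct_topology_fraction ...
#> 1 T_demo          10         0.893           1                       0.4 ...
```

`best_gdt_ts = 1` is the lowest-noise model scoring (numerically) full
marks; the correct-topology fraction is the share of models with
TM-score > 0.5. Refinement, planning and assembly composition follow the
same pattern — `run_refinement()`, `build_sampling_plan()`,
`compose_submission()`, `rank_and_select()` — and
`demo_pipeline(seed)` chains all of them end to end. A thin CLI over the
same functions ships in `inst/exec/foldrank`
(`simulate`, `plan`, `rank`, `augment`, `refine`, `extract-chain`,
`graft`, `curate-templates`, `evaluate`).

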