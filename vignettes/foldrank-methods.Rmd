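---
title: "Model pool ranking, refinement and evaluation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model pool ranking, refinement and evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldrank)
```

## The problem this package addresses

Modern protein structure predictors readily produce *pools* of candidate
models for a target — different alignments, different template sets,
different random seeds. The scientific work then shifts to the decision
layer: which of these models is best, can the best one be improved, and
how should a five-model submission be composed when some models were cut
out of a predicted protein assembly? `foldrank` implements that decision
layer — quality assessment, consensus ranking, iterative
structure-search-driven refinement control, assembly-aware selection and
native-based evaluation — with every heavy engine (sequence search,
structure search, the folding network itself) abstracted behind a small
backend contract so the logic runs, and is tested, entirely offline.

All structural reasoning is CA-based: a model is a sequence of residues
with one alpha-carbon coordinate and one confidence value (pLDDT on the
0–100 scale, stored in the PDB B-factor column as AlphaFold-family
predictors do). Residues of two models of the same target are
corresponded strictly by residue number; no re-alignment is ever done
between models of one target.

## Similarity metrics

Three complementary metrics quantify agreement between a model and a
reference:

* **TM-score**, normalised by the reference length $L$:
  $\max \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2}$ with
  $d_0 = \max(1.24\,(L-15)^{1/3} - 1.8,\; 0.5)$. The 0.5 Å floor keeps
  $d_0$ meaningful for short chains, a standard convention. Scores above
  0.5 conventionally indicate the correct fold, above 0.8 high accuracy.
* **GDT-TS**: the mean over cutoffs 1, 2, 4, 8 Å of the maximal fraction
  of corresponded residues placeable within the cutoff under a rigid
  superposition.
* **CA-lDDT**: superposition-free; over residue pairs with sequence
  separation ≥ 2 whose reference CA distance is below 15 Å, the fraction
  whose model-vs-reference distance deviates by less than a threshold,
  averaged over thresholds 0.5, 1, 2, 4 Å. Full-atom lDDT is out of
  scope.

TM-score and GDT-TS require maximising over rigid superpositions, which
is NP-hard in general. The search space is restricted to least-squares
(Kabsch) fits on residue subsets. For small correspondences (M ≤ 12
shared residues, at most 4017 subsets) the package enumerates every
subset of size ≥ 3 — exact maximisation is cheaper than any heuristic
there, and it makes the metric exactly equal to the brute-force
subset-superposition bound on small inputs. Above that size a seed
search is used: contiguous fragments of lengths M, M/2, M/4 and 4 at
every offset seed a fit, each fit is refined by re-superposing on the
residues currently inside a distance cutoff until the included set
stabilises (at most 20 rounds), and the best score over all seeds,
cutoffs and rounds is kept. Every superposition examined is still a
subset fit, so the heuristic is bounded above by the exhaustive
enumeration it replaces.

For pairwise model–model similarity the normalising length is the larger
of the two models' residue counts (a stand-in for the target length,
which both models approximate), the score is computed in both
orientations, and the two values are averaged; the matrix diagonal
is 1. Against a designated reference (a native structure), the
reference's own length normalises.

## Consensus quality scores

Given the pool similarity matrix $S$ (TM-score by default, GDT-TS
selectable) and per-model global pLDDT values $p_i$ (mean per-residue
confidence), four scores are available for ranking:

* consensus (APOLLO) score: $a_j = \frac{1}{n-1}\sum_{i \ne j} S_{ij}$;
* pLDDT-weighted similarity:
  $w_j = \frac{1}{n-1}\sum_{i \ne j} S_{ij}\, p_i$ — note the weight is
  the *other* model's confidence, so a model surrounded by confident,
  similar neighbours scores high;
* their average $\tfrac{1}{2}(a_j + p_j/100)$ — pLDDT is rescaled by 100
  first so both addends live in [0, 1]; the weighted score, by contrast,
  is left on its natural 0–100-ish scale because only its ranking is
  ever consumed;
* the global pLDDT itself, the only single-model score of the four.

The pool diversity statistic PSS is the mean off-diagonal similarity
(equivalently the mean consensus score): values above 0.9 flag a
collapsed pool, low values flag alternative conformations, exactly the
regime where consensus scores earn their keep — they require that a
plurality of the pool sits near the truth.

Evaluation statistics follow the standard definitions: per-target
ranking loss is the true quality (GDT-TS) of the best pool model minus
that of the model the selector ranked first; per-target correlation is
the Pearson correlation between predicted scores and true GDT-TS.
Constant score vectors raise an error rather than silently producing
`NaN`. The weighted z-score combiner standardises each component column
with the *population* standard deviation (a deliberate choice — the pool
is the entire population being ranked, and the convention for the
official combined score is not recorded); constant columns contribute
z = 0 rather than an error. The default grouping weighs four components
at 1/16, three at 1/12 and three at 1/6, mirroring the official CASP15
combined-score structure; the component metrics themselves are inputs,
not implemented here.

## Alignments, identity and Neff

Alignments use the A3M dialect: uppercase and `-` are match states,
lowercase letters are insertions, and the query (row 1) is pure
uppercase. Two definitional choices are stand-ins, because the
filtering and counting tools they mirror do not publish exact formulas:

* **identity** between two rows counts match columns where both carry
  the same uppercase letter, normalised by the smaller of the two rows'
  uppercase counts (the `-id` semantics of the common filtering tool);
  insertions are ignored;
* **Neff** is the inverse-cluster-size sum
  $\sum_i 1/n_i$, where $n_i$ counts rows at ≥ 80% identity to row i
  (including itself), with no length normalisation. A single-sequence
  alignment has Neff 1. Only the ordering of log-Neff is consumed
  downstream, which any monotone variant preserves.

Redundancy filtering is a greedy scan in row order: the query is always
kept, and a row is dropped iff its identity to an already-kept row is
*strictly* greater than the threshold (default 0.90) — a row at exactly
the threshold survives. Greedy filtering guarantees no surviving pair
exceeds the threshold, which the test suite audits all-vs-all.

## Structure-search hits and MSA augmentation

Structure-search output is a tab-separated hit table (query, target,
e-value, optional TM-score, interval coordinates, gapped alignment
strings); the column order is configurable because tabular search output
is. Each hit's alignment is projected onto the query's match columns:
positions outside the hit interval or aligned to a target gap become
`-`, aligned target letters become match states, target letters opposite
a query gap become lowercase insertions. Hits are converted in ascending
e-value order, capped at 50 per augmentation so a flood of
near-identical hits cannot dominate the alignment (the cap is a design
choice; nothing downstream is sensitive to its exact value), appended,
and the redundancy filter is applied at 90%. Hits whose query side is
all gaps are dropped before conversion.

Template selection takes the top k = 4 hits by ascending e-value, ties
broken by descending TM-score then lexicographic id. Template-database
curation applies three filters in order: resolution > 8 Å removed
(records with no resolution — predicted structures — pass, since the
filter targets experimental quality), length < 30 removed, then a greedy
redundancy pass removing records at > 90% sequence identity to a kept
record. Curation identity is computed by global alignment with free end
gaps (via `Biostrings::pairwiseAlignment`, type `"overlap"`), normalised
by the shorter sequence — the construction recipe names neither aligner
nor normalisation, so these are recorded choices. All three boundaries
are strict in the direction stated: resolution exactly 8, length exactly
30 and identity exactly 90% all survive.

## The refinement loop

Refinement iterates: search the current model against a structure
database (backend), convert the hits and deepen the MSA, select the top
hits as templates, fold five new models (backend), and accept the best
new model iff its global pLDDT *strictly* exceeds the current input's.
The loop stops at the first rejected iteration or after 5 iterations,
whichever comes first, and returns the highest-confidence model
generated in *any* iteration — not necessarily the last accepted one.

Design choices where the procedure leaves room:

* **Cumulative augmentation.** Each iteration augments the previous
  iteration's filtered alignment, not the original one, so the
  deeper-MSA effect — the mechanism the refinement credits for its
  gains — compounds across iterations.
* Each iteration searches with the current accepted model, not the
  original input.
* Templates are re-selected from the latest search only; earlier
  iterations' templates are not retained.
* If the very first search returns no hits there is nothing to refine:
  the trace records one empty iteration and the input model is returned
  unchanged, letting callers fall back to unrefined models.

The top-five rule pools the five refined outputs with the five unrefined
inputs and keeps the five with the highest global pLDDT (ties broken by
model id), so refinement can never push a submission below its unrefined
baseline *as judged by pLDDT*. Predictor policies wrap these pieces:
rank by pLDDT alone (`deep`), by the pLDDT/consensus average (`egnn`,
and `human` as the same ranking over a generally larger pool — manual
re-ranking and learned QA are out of scope), refine the hybrid-ranked
top five (`refine`), or refine the five models of the default sampling
combination (`qa`, which re-pools refined and unrefined models the same
way; whether the original procedure re-pooled is unrecorded, so the
conservative pooling rule is reused).

## Assembly integration and grafting

For a target that is a subunit of an assembly, monomer models cut out of
predicted assembly structures (coordinates kept exactly as in the
assembly, confidence from the B-factor column) join the pool under the
`assembly_extracted` tag. Submissions then prefer them: the top-ranked
assembly-derived models fill the first `assembly_slots` positions
(default 4, configurable 3–4 — the original per-target choice was
manual), remaining slots go to the best single-chain models. Confidence
scores produced by a monomer predictor and an assembly predictor are not
guaranteed to be comparable; the provenance tag surfaces the mix and no
rescaling is applied, deliberately.

Region grafting replaces a residue span of a full-length model with a
separately folded region model. The region is first rigidly superposed
onto the full model using up to 10 flank residues on each side of the
span that exist in both models (falling back to the span itself when no
flanks are shared). Superposing on flanks rather than the span preserves
the region's global placement while replacing its local geometry — the
span is being replaced precisely because its geometry is poor, so it is
the wrong thing to fit on. Residues outside the span are bit-identical
after grafting; numbering and length never change.

## Sampling plans

The per-target sampling plan pairs each of eight canonical MSA variants
with its fixed template database (the `_seq_temp` variants with the
curated database, the rest with the standard one) at five models per
combination and engine settings `num_ensemble = 8`, `num_recycles = 8` —
up to 40 models per target. The two deep-search variants (`img`,
`img_seq_temp`) are reserved for hard targets: they are dropped when the
default MSA's depth is strictly greater than 200 rows. The planner is a
pure function of the available MSA names and that depth; the searches
behind the MSAs are backends and out of scope.

## The synthetic generator

Every statistical claim in the test suite runs on synthetic data with
known ground truth:

* `make_helix(n)` builds an ideal helical CA trace (rise 1.5 Å, radius
  2.3 Å, 100° per residue — the canonical ~3.83 Å CA–CA spacing), by
  default poly-alanine at pLDDT 90. Any realistic trace would do for the
  metric tests; the helix is merely compact and reproducible.
* `perturb_model(model, sigma, seed)` adds i.i.d. Gaussian noise
  (sd `sigma`) per coordinate and sets every residue's confidence to
  $100\,e^{-\sigma}$ — a *monotone proxy* tying self-estimated
  confidence to true quality so that QA-recovery experiments have a
  known answer. Pre-superposition RMSD concentrates at
  $\sigma\sqrt{3}$.
* `make_pool` crosses noise levels with seeds, so the true quality
  ordering of a pool is known by construction; `make_hits_from_models`
  and the mock search/folding backends synthesise the structure-search
  and folding sides of the refinement contract deterministically under a
  seed.

What the generator does **not** emulate: real decoys are not isotropic
Gaussian clouds around the native — they have correlated, segment-wise
errors, compact wrong folds and confidence miscalibration. Passing the
QA-recovery tests therefore shows the estimators implement their
definitions and recover orderings under honest noise; it does not show
field performance on real model pools, which only external benchmarks
can.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use toy targets of 14–40
residues, pools of 6–10 models, 100 random instances (M between 5
and 10) for the oracle-equivalence check, and 20 replicate pools for the
QA-recovery experiments; these sizes were chosen so the full suite
exercises every statistical property at meaningful replication while
remaining a desk-scale computation. Other numerical details: Kabsch fits
reject (near-)collinear point sets at a 1e-8 singular-value tolerance
and exclude reflections; score ties during ranking and selection are
always broken lexicographically by model id, so every ordering in the
package is deterministic; all randomness flows through explicit integer
seeds.

## Known limitations

* Metrics are CA-only by design; no sequence-dependent/independent
  alignment modes, no full-atom lDDT, no GDT-HA.
* The heuristic superposition search above M = 12 is not guaranteed
  optimal (exact maximisation is NP-hard); it is bounded by, and on
  small inputs equal to, the exhaustive subset enumeration.
* The identity and Neff definitions are explicit stand-ins (see above).
* The z-score combiner implements the combining arithmetic only; the
  ten component metrics of the official formula are external inputs.
* No folding, sequence-search or structure-search engine is run; the
  backend contracts and deterministic mocks define the interface that a
  production deployment would implement with the real tools.
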