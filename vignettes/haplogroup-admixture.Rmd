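---
title: "Modelling populations as admixtures of haplogroup central vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling populations as admixtures of haplogroup central vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgadmix)
```

## The problem

Ancient and modern human populations can be summarized by the frequency
distribution of their mitochondrial haplogroups (Hgs). Because every study
reports haplogroups at different phylogenetic resolution -- `H`, `H1`,
`H13a`, or seventeen-character subclade strings -- per-population frequency
vectors from heterogeneous sources live in incompatible coordinate systems.
`hgadmix` builds a *common haplogroup basis* so that every population
becomes a point in one vector space, clusters those points into local
condensations whose centres ("central vectors", CVs) behave like
hypothetical ancestral populations, and then models any population as an
optimal weighted linear combination of the CVs -- an admixture model fit by
gradient search. Distance-matrix correlation and Mantel permutation tests
validate the reduced representation against an external reference such as a
pairwise Fst matrix computed upstream (e.g. by Arlequin); computing Fst
itself from sequence data is out of scope.

## Label nomenclature and the common basis

A haplogroup label is a run-length alternation of letters and digits.
`hg_tokenize()` splits a label into these runs and the number of runs is its
*phylogenetic depth*: `H` has depth 1, `H1a` depth 3, `K1a1b1a` depth 7. The
leading token is the maximal alphabetic run, so two-letter clades (`HV`,
`JT`) count as depth 1; published tables mix cases, so labels are
canonicalized (leading run upper-case, later alphabetic runs lower-case)
before any comparison.

Deep subclades rarely recur across populations, so the basis is built at a
maximal depth (default 3) and each observed label is mapped onto it by one
of two rules:

* **cumulating** (default): a label is assigned to its *deepest ancestor*
  present in the basis, at token level. With basis `{A, B, A1, B2a}`,
  `A2a1 -> A`, `A1b -> A1`, `B2a3 -> B2a`, `B -> B`. Token-level matching
  matters: `H1` is not an ancestor of `H13a`.
* **cutting**: only labels literally present in the basis survive.

Cumulating preserves strictly more individuals than cutting (a tested
invariant), and empirically preserves distance structure far better; the
cutting rule is kept for sensitivity analysis. Two filters then reduce the
candidate set:

1. **Prevalence**: a basis haplogroup is kept only if its pooled assignment
   count over the *whole* database exceeds a fraction 0.0005 of all
   individuals (strict inequality -- a label at exactly the threshold is
   dropped). Counts are computed under the same assignment mode used
   downstream, because cumulating changes pooled counts.
2. **Joint propagation**: haplogroups that took part in shared demographic
   processes show rank-correlated frequencies across a subset of
   populations. For every pair of basis haplogroups,
   `best_subset()` greedily removes populations (the one whose removal most
   increases Spearman's rho, ties broken at the lowest index) until the
   correlation reaches `rho_min` (default 0.8) or only `min_pops` (default
   10) populations remain; `select_correlating_hgs()` keeps haplogroups with
   at least one accepted partner. The upstream literature describes this
   subset search only by citation, so the greedy leave-one-out shrink here
   is a reconstruction; its parameters are exposed so users can explore
   alternatives, and raising either threshold provably never enlarges the
   selected set. Zero-frequency populations are retained in the rank
   vectors (tied at the bottom) because absence is informative for
   propagation.

Frequency rows are normalized by default over *classified* individuals
(rows sum to 1); normalization by the total population size is available
for sensitivity analysis, since published descriptions leave the
denominator ambiguous. Populations with no classifiable individual are
flagged unusable and excluded from distances with a warning rather than
silently dropped.

## Growing central-vector clustering

`fit_soc()` looks for the local condensation centres of the population
vectors. The binding requirement is the stopping rule: the *radius* of a
cluster (mean Euclidean distance of members to their centre) must be less
than 1/3 (the `ratio` parameter) of the distance from the centre to its
nearest neighbouring centre, for every multi-member cluster; singletons
pass trivially. The number of centres grows from `n_start = 2` until the
criterion is satisfied, or `max_n` is reached (then `converged = FALSE` and
the best solution is returned, never a silently invalid one).

The refinement inside each size N is a restart-stabilized
nearest-assignment / centroid-update iteration run to a centre-movement
tolerance of 1e-9, taking the best of `n_restarts = 10` random starts plus
one *growth* start that splits the worst-criterion-violating cluster at its
farthest member. Empty clusters are re-seeded at the point farthest from
their centre. The original "Self-Organizing Cloud" update schedule is
published elsewhere and not restated in the source literature; this
reconstruction reproduces the stated stopping rule, which is the only
binding specification, and we deliberately do not claim
membership-for-membership agreement with the original 35-cluster solution.
All randomness flows from the mandatory `seed`, so a fit is exactly
reproducible.

Diagnostics mirror the published ones: `significance_check()` runs a
one-sided paired t-test per cluster that member distances to the own centre
are smaller than to the nearest other centre (reported as `1 - p`;
well-separated clusters exceed 0.99; clusters with fewer than 3 members or
zero variance are reported as not computable, never as an exception).
`inherence_matrix()` is the binary same-cluster indicator;
`inherence_distance_correlation()` correlates its off-diagonal upper
triangle with a distance matrix. We report the *signed* Pearson value: when
a clustering tracks the distances, within-cluster pairs are closer, so good
correspondence appears as a negative value (the source text reports a
magnitude while stating that negative values indicate good correspondence;
we resolve that tension by documenting the sign convention).

## The admixture model

A population's distribution `h` (a D-vector) is modelled as

    h = a1 v1 + a2 v2 + ... + aN vN + eps

with error power `H = sum_k eps_k^2` and normalized error
`J = H / sum_k h_k^2`. `J` is 0 for a perfect model and exactly 1 for the
null model (all weights zero). The CVs are generally *not* orthogonal, so
the weights are not coordinates, are not constrained to sum to one, and may
exceed one. The analytic gradient is `dH/da_m = -2 sum_k eps_k v_{m,k}`.

`solve_weights()` minimizes `H` by steepest descent *from the all-zero
weight vector* -- this makes `J <= 1` guaranteed and anchors the
"unsuccessful" model -- with backtracking step control: the initial step is
`learning_rate = 0.1` relative to a Gershgorin bound on the Gram-matrix
spectrum, halved until a step decreases `H` and grown by 1.2 after each
acceptance, so `H` is non-increasing by construction. Descent stops when
the relative improvement of `H` falls below `tol` (default 1e-12), when no
descending step exists at machine precision, when `H` falls below
`1e-24 * sum(h^2)` (an exact representation), or at `max_iter = 1e5`. The
tolerance is deliberately tight: with relative-improvement stopping, the
residual gap scales like the Gram condition number times `tol * H`, and
1e-12 keeps even ill-conditioned full-rank instances within 1e-6 relative
agreement with the closed-form least-squares solution. That closed-form
(pseudoinverse) solver ships both as the independent test oracle and as a
`solver = "exact"` fast path; the gradient search remains the reference
implementation of the method. An optional `nonneg = TRUE` projects weights
onto the non-negative orthant after each step (with a Lawson--Hanson active
set in the exact path) for a strict admixture reading; it is off by
default because the model itself places no sign constraint.

`fit_admixture()` runs the solver for every population and reports the
per-population weight table with `H`, `J` and the mean `J`; a failing fit
is flagged in the `failed` column instead of aborting the batch.

## Distance validation

`euclidean_matrix()` computes unweighted Euclidean distances between
frequency rows; `matrix_correlation()` is the Pearson correlation over the
*off-diagonal upper triangle* only (the diagonal would inflate the value;
the symmetric lower triangle would change nothing but double-count).
`mantel_test()` permutes the rows and columns of the second matrix
*jointly* -- the standard Mantel scheme; permuting rows alone would break
symmetry -- and reports the one-sided p-value with the +1-corrected
estimator `p = (1 + #{r_perm >= r_obs}) / (1 + n_permutations)`, whose
smallest achievable value is `1/(n_permutations + 1)`; p is never reported
as zero. `mds_embedding()` (classical scaling), `threshold_edges()` (pairs
below a fraction, default 35%, of the maximal distance) and
`minimum_spanning_tree()` provide the relationship-graph summaries, drawn
together by `plot_cv_graph()`.

## What the synthetic generator emulates

The generator is first-class, tested code, and fixes the study conditions
for every end-to-end check:

* `generate_profiles()` draws K ancestral frequency profiles from a
  symmetric Dirichlet (default concentration 0.5 -- sparse, distinct
  profiles of the kind real macro-regional Hg pools show).
* `generate_populations()` builds P populations either as noisy copies of
  single profiles (`pure`, for clustering tests) or as convex Dirichlet
  mixtures (`admixed`, for the solver), adding truncated Gaussian
  coordinate noise (default sd 0.01) and renormalizing; the planted
  profiles, weights and partition are recorded as truth.
* `sample_individuals()` draws multinomial individuals per population and
  deepens each drawn basis label into a random legal subclade (alternating
  1--2-digit / 1--2-letter tokens, extension probability 0.5 per level, up
  to depth 7), never colliding with an existing basis label, so cumulating
  assignment recovers the drawn label exactly and the sampled frequency
  matrix converges to the planted one at the multinomial rate.

What it does *not* emulate: phylogenetic dependence between basis axes
(real sister clades co-vary), unequal sampling depth between ancient and
modern populations, and nomenclature noise (synonyms, renamed clades).
Passing tests therefore demonstrate algorithmic correctness on data with
the assumed statistical structure, not robustness to curation artifacts in
real databases.

Test and example problem sizes (tens of populations, basis dimension 8--20,
hundreds of individuals per population, 100-replicate noise sweeps, 200
random solver instances, 1000-replicate Mantel calibration) were chosen as
the smallest scales at which the statistical claims are sharp; all scale
linearly if users want larger studies.

## Numerical choices and degenerate inputs

* Ties in the greedy population removal and in nearest-centre assignment
  are broken at the lowest index, for exact reproducibility.
* Spearman correlation on a constant vector is an error in
  `spearman_rho()` but treated as negative infinity inside the subset
  search (such a pair can never be accepted).
* A label at exactly the prevalence threshold is removed (strict `>`).
* Unusable populations propagate as flagged `NA` rows, excluded with
  warnings at the distance layer.
* `error_terms()` refuses an all-zero `h` (J undefined); `solve_weights()`
  refuses non-finite inputs.
* Distance matrices must be symmetric to 1e-12; MDS truncates negative
  eigenvalues with a warning.

## Reproduction of the published study

The pipeline defaults (`pipeline_config()`) equal the published analysis
settings: depth 3, cumulating, prevalence 0.0005, rho 0.8 over at least 10
populations, ratio 1/3. Reproducing the published numbers additionally
requires the study's supplementary workbooks (the per-individual database,
the 172 x 74 frequency table and the paired Euclidean/Fst matrices), which
are publisher downloads not shipped here; `import_supplementary()` reads
them and fails loudly on any unrecognized layout rather than guessing. The
dedicated acceptance test for that reproduction is expected to fail until
the workbooks are placed under the path named by
`options(hgadmix.supplementary_path = ...)`.

## Known limitations

* The subset-search and clustering internals are reconstructions of
  methods specified only by citation; counts that depend on them (basis
  size, number of CVs) should be read as algorithm-conditional.
* The greedy subset search is O(P^2) correlation evaluations per pair and
  all-pairs selection is O(B^2) in the basis size; for hundreds of basis
  labels over hundreds of populations expect minutes, not seconds.
* Cluster counts from the growth criterion are sensitive to the noise
  level; overlapping condensations legitimately end `converged = FALSE`.
* The admixture weights are descriptive regression coefficients on
  correlated regressors; they are not identifiable ancestry proportions
  unless the CVs are well conditioned.
```{r session, eval = FALSE}
sessionInfo()
```
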