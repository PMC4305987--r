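---
title: "Integrative GO semantic similarity: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative GO semantic similarity: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`integosim` computes gene-to-gene functional similarity over one Gene
Ontology aspect by integrating seven candidate semantic similarity
measures instead of committing to one. The premise is that each measure
exploits a different slice of the ontology — annotation-set overlap
(SimUI, term overlap, SimGIC), information content of the most
informative common ancestor (Resnik, Schlicker), DAG topology (Wang), or
IC along paths to leaf terms (HRSS) — and that the value all concordant
measures agree on is more trustworthy than any single one.

The pipeline has three stages.

**Rank normalization.** For a gene set $GS$, each measure's raw scores
over all $\binom{|GS|}{2}$ unordered pairs are ranked ascending and
rescaled:

$$\mathrm{RankSim}(g_1 g_2, m) = \frac{2\,\mathrm{rank}(g_1 g_2, m)}{|GS|^2}.$$

Ranks use fractional (average) tie handling, which preserves rank sums and
makes the result invariant under permutation of tied pairs. Note the
divisor is $|GS|^2$, not the pair count, so the largest attainable value
is $(|GS|-1)/|GS| < 1$; we keep the definition verbatim and document the
ceiling rather than "fix" it, since only comparability across measures
matters. A consequence users must keep in mind: **scores are relative to
the query gene set**. Scoring the same pair inside two different gene
sets legitimately gives two different values.

**Seed measure selection.** Per gene pair, the candidate measures'
RankSim values are placed on the $[0,1]$ axis and the pair's *seed
measure group* is the largest contiguous run of at least $c$ values
(default 3) with spread at most $d'$ (default 0.10). The original
procedure is described as agglomerative grouping on the axis with a
gradually reduced distance threshold, iteratively discarding isolated
measures; on one dimension single-linkage pruning and maximal-diameter
window search retain the same contiguous core, and the window search is
deterministic and insensitive to input order, so that is the formulation
implemented (and the one the brute-force test oracle checks).
Tie-breaking among equally large windows: smaller diameter, then the
window containing the median value, then the lower window. The group is
labelled by where the discarded measures sit: more below than above the
window means the group occupies the high end (`high`), the mirror case is
`low`, and equal counts are `mix`. Two deliberate edge-case policies:

* if no window of size $\ge c$ fits within $d'$, the pair falls back to
  *all* measures with label `mix` — integration degrades gracefully to an
  all-measure combination rather than failing;
* a genuinely central isolated cluster cannot occur under contiguous
  window selection, so the "middle" case collapses into the equal-counts
  `mix` rule.

**Type-conditional addition model.** With $V$ the seed measures' RankSim
values for a pair of group type $t \in \{\text{high}, \text{low},
\text{mix}\}$:

$$\mathrm{Sim}(g_1, g_2) = \sum_{i \in \text{seeds}} w_t[i]\,V_i
  + \alpha_t \max V + \beta_t \min V + \gamma_t\,\overline{V},$$

with all parameters non-negative and each type block summing to one
(tolerance $10^{-9}$). Weights are indexed by *candidate* measure — seed
sets vary per pair, so per-seed weights have no consistent identity — and
a weight whose measure is not in a pair's seed group contributes nothing
to that pair. We apply the model verbatim, without renormalizing over the
active subset; whether renormalization was intended is not decidable from
the method's description, and the verbatim form is the conservative
reading. See "Known limitations" for a consequence.

# The objective and the trainer

Training data are genes grouped by evidence independent of GO: enzyme
commission numbers for molecular function (groups of at least 3 genes) or
pathway membership for biological process (at least 2). For a gene $g$ in
group $e_i$ and a disjoint group $e_j$, with $I = G(e_i)\setminus\{g\}$
and $J = G(e_j)$:

$$\mathrm{diff}_g(e_i, e_j) = \ln\frac{|I| \sum_{g' \in J} (1 - \mathrm{Sim}(g, g') + c)}
                                      {|J| \sum_{g^* \in I} (1 - \mathrm{Sim}(g, g^*) + c)},$$

a log fold change of inter- over intra-group smoothed distance.
$\mathrm{LogFC}(e_i)$ averages $\mathrm{diff}_g/|G(e_j)|$ over all genes
of $e_i$ and all disjoint $e_j$, normalized by the number of disjoint
groups, and the training objective is the mean LogFC over all groups that
have at least one disjoint partner. Two numerical notes:

* the smoothing constant $c$ (`c_smooth`, default 0.01) is specified only
  as a small positive number; 0.01 keeps the log arguments at least two
  orders of magnitude above zero for similarities up to 0.99 while
  perturbing well-separated fixtures negligibly, and it is configurable;
* the inner divisor is $|G(e_j)|$ as printed; a `divisor = "ei"` switch
  provides the arguably intended $|G(e_i)|$ variant for sensitivity
  checks. The printed form is the default everywhere.

The same symbol is used in the source description for the seed-group size
threshold and the smoothing constant; the package names them
`seed_min_size` and `c_smooth` to keep them apart.

**Tabu search.** Parameters are fitted one type block at a time (high,
then low, then mix, cycling while any block improves). Moves transfer
mass `min(step, donor)` between two parameters of the active block, so
every neighbor stays on the simplex. The best neighbor is accepted
outright when it improves the best solution so far (aspiration);
otherwise the best non-tabu neighbor is taken — non-improving drift is
allowed — and every accepted solution's fingerprint (the parameter vector
rounded to 4 decimals) enters a bounded tabu list. A block stops after
`stability_patience` consecutive moves without a new best; the whole
search runs `restarts` independent restarts from symmetric Dirichlet(1)
draws and returns the best result. Defaults — steps $\{0.05, 0.01\}$,
tabu capacity 50, patience 25, 5 restarts — are the package's own: the
two step sizes give a coarse and a fine resolution of the simplex, the
capacity and patience are sized to the $\le$ 220-neighbor moves the
default measure set produces, and 5 restarts empirically stabilize the
returned objective on the bundled fixtures. With patience 0 the search
degenerates to evaluating the initial draw, which the tests rely on as a
contract. All randomness flows from a single seed; identical seeds give
identical parameter sets.

Because RankSim values and seed groups are frozen before the search, the
objective reduces to sparse matrix products in the candidate solutions,
and whole neighborhoods are evaluated in one BLAS call; the loop-based
objective implementation is kept as the reference and the two are asserted
equal in the tests.

# The synthetic benchmark

The generator builds a rooted `is_a` tree of configurable depth and
branching, adds ~10% random `part_of` edges pointing strictly upward in
depth (acyclicity by construction), partitions the leaf terms into one
pool per functional group, and annotates each of the group's genes with
every pool term with probability `p_in` and every off-pool leaf with
probability `p_out`. The defaults (depth 4, branching 3, 5 groups × 6
genes, `p_in` 0.8, `p_out` 0.1) are the package's standard training
benchmark: 30 genes is large enough that all seven measures separate the
planted groups while a wrong measure clearly does not, and small enough
that a full training run takes seconds. The cross-validation experiment
uses 20 groups × 5 genes so that a 1/5 group holdout still contains
several disjoint groups and ~80 training genes — at smaller scale the
addition model's 3 × (|measures| + 3) free parameters visibly overfit a
handful of groups and the comparison against the averaging baseline
becomes noise. The robustness experiment uses synthetic score matrices (4
groups × 8 genes, one group-separating measure plus four uniform-noise
measures) because it needs a *known* informative measure, which the
GO-derived measures on a planted corpus cannot provide (they are all
informative there).

What the generator emulates: a multi-level DAG with both relation types,
annotation sets that are closed under ancestors, groups whose members
share terms more often than non-members, and an adversarial "fake"
measure that copies Resnik scores on a random half of the pairs and
returns reversed 0/1 values on the rest. What it does not emulate: the
scale-free topology and depth distribution of the real Gene Ontology,
evidence-code heterogeneity, annotation bias toward well-studied genes,
or inter-group similarity structure (planted groups are exchangeable).
Passing tests therefore demonstrate correctness of the machinery and the
qualitative claims (integration ≥ best single measure on the training
objective, trained integration > plain averaging out of sample,
robustness to losing noise measures), not performance on any real
organism.

# Other design choices

* **Relations.** Only `is_a` and `part_of` edges are traversed;
  `regulates`-family relations are ignored, matching the conventions of
  the integrated measures' original definitions.
* **IC.** Natural log of the gene-level annotation frequency; the
  denominator is the number of annotated genes, not annotation rows, so
  term probability matches the gene-level similarity use. Terms annotating
  no gene carry an undefined-IC sentinel and are excluded from MICA
  candidacy.
* **Closure is reflexive** (a term is its own ancestor), so identical
  annotation sets reach similarity 1 under the set measures.
* **Evidence codes.** All retained by default with an allowlist argument;
  the corpora the method was originally applied to are not specified at
  that level of detail.
* **Gene-level lift.** Term-level measures are lifted to gene pairs by
  best-match average over the direct annotation sets — the dominant
  convention in this literature and symmetric by construction.
* **Term overlap** is normalized by the smaller closed set so it lives in
  $[0,1]$; ranks, which are all that enter the pipeline, are unaffected.
  Resnik is left un-normalized for the same reason.
* **Wang weights** are 0.8 (`is_a`) / 0.6 (`part_of`), configurable.
* **HRSS degenerate cases** ($\alpha = \beta = 0$, e.g. the root against
  itself) are pinned to 0; a leaf's most informative leaf descendant is
  itself, so leaf self-similarity is exactly 1.
* **Schlicker** at the root-against-root corner (IC sum zero) is defined
  as 0.
* **Fake measure.** The random half is sampled uniformly, not stratified
  by group; pairs lacking any group assignment on the reversed half count
  as different-group (score 1) and are logged.

# Known limitations

* Because non-member weights contribute nothing, the model family
  contains "switch" solutions — mass on a measure that is a seed member
  for some pairs and not others yields near-zero similarity for the
  latter. On small training sets the optimizer can exploit such
  membership patterns as pair-selective indicators; this inflates the
  training objective without transferring out of sample. The
  cross-validation fixture size above was chosen so that honest solutions
  dominate; users training on very small groupings should expect the same
  effect and prefer more groups over more restarts.
* The fake measure's reversed half encodes the training grouping itself,
  so a trained model can partially invert it; this leakage is inherent to
  that experimental design and is another reason the robustness
  conclusions are qualitative.
* Rank normalization makes all outputs relative to the query set; there
  is no cross-dataset calibration.
* Cellular component is supported structurally but not exercised by any
  bundled experiment, and cross-aspect similarity is out of scope.
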