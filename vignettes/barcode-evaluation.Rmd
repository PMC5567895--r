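---
title: "Evaluating single- and multilocus DNA barcodes with barcodeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single- and multilocus DNA barcodes with barcodeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A DNA barcode is useful when sequences from the same species are
consistently more similar to each other than to sequences from any other
species.  `barcodeval` quantifies that claim for a reference library of
aligned, species-labelled sequences — single loci or concatenated
multilocus barcodes — with the three families of methods that barcoding
surveys conventionally report side by side:

1. **Distance structure**: Kimura two-parameter (K2P) pairwise distances,
   intra- vs inter-specific divergence summaries, and the *barcoding gap*
   (global histogram separation, and the per-species "local" gap
   contrasting the maximum intra-specific distance with the
   nearest-neighbour distance).
2. **Similarity-based identification**: the TaxonDNA-style *Best Match*
   (BM), *Best Close Match* (BCM) and *All Species Barcodes* (ASB)
   criteria, reported as dataset-level percentages of correct, ambiguous
   and incorrect identifications.
3. **Tree-based resolution**: neighbour-joining (NJ) bootstrap consensus
   trees scored for per-species monophyly above a support cutoff, plus
   Fitch parsimony statistics (tree length, CI, RI, RC) and a heuristic
   maximum-parsimony search.

```{r}
library(barcodeval)
aln <- worked_fixture()      # a hand-constructed 4-species example
ev <- barcode_eval(aln, bootstrap = 100, seed = 1)
ev
```

## Models and conventions

### K2P distances with pairwise deletion

For each sequence pair, only sites where both sequences carry an
unambiguous base (`A/C/G/T`) are compared (*pairwise deletion*); gaps,
`N` and IUPAC ambiguity codes are treated as missing throughout the
package — in distance computation, in site-state counting, and in
parsimony (where they become fully ambiguous states).  With transition
proportion $P$ and transversion proportion $Q$,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

When $1-2P-Q \le 0$ or $1-2Q \le 0$ (saturation) or no site is
comparable, the distance is flagged *undefined*.  Undefined pairs are
excluded from all summaries and reported in a side count — they are
never clamped to a ceiling, which would fabricate a value where the
model has none.  Tree building refuses matrices with undefined pairs
(naming them); bootstrap replicates that become saturated are dropped
and counted, with a warning above 10%.

Divergence summaries use the *all-pairs* convention: the mean
intra-specific distance averages every conspecific pair in the dataset
(not per-species means), and the `±` value attached to each mean is the
standard error of that mean.  Per species, `theta` is the mean and the
*coalescent depth* the maximum conspecific distance; singleton species
contribute nothing to intra-specific statistics and are listed.

### Barcoding-gap analysis

Distances are binned at width 0.005 (half-open bins $[kw,(k+1)w)$).  A
*global* gap is a maximal run of completely empty bins strictly between
the occupied intra-specific and inter-specific ranges; overlapping
distributions have no global gap, and the fraction of inter-specific
mass above the maximum intra-specific distance is always reported as the
graded alternative.  The *local* gap scores each species by whether its
nearest-neighbour distance strictly exceeds its maximum intra-specific
distance — a tie counts as no gap, matching the "above the 1:1 line"
reading of the conventional dot plot.  Singletons have no intra-specific
distance; they are recorded with `max_intra = 0` and excluded from the
percentage by default (`include_singletons = TRUE` includes them).

### Identification criteria

All three criteria work on the full K2P matrix, excluding the query from
its own candidate set.  Ties are detected with an absolute tolerance of
$10^{-12}$ — floating-point distances need an explicit tie contract.

* **BM**: the query is `correct` if every equally-closest sequence is
  conspecific, `incorrect` if none is, `ambiguous` if they span species.
* **BCM**: BM restricted to candidates within a distance threshold;
  an empty candidate set is `no_match` (unidentified).  The conventional
  threshold is 0.03; `percentile_threshold()` provides the data-driven
  alternative (the linearly interpolated percentile — R's type-7
  quantile — of all intra-specific distances, conventionally at 95%).
* **ASB**: within the threshold, `correct` only if *every* conspecific
  is strictly closer than every heterospecific; `incorrect` if some
  heterospecific is strictly closer than some conspecific; `ambiguous`
  only when the farthest conspecific ties the nearest heterospecific.
  A query whose species has no other representative within the threshold
  cannot be `correct`.  This is a design decision worth making explicit:
  the boundary between "interleaved" and "some heterospecific closer" is
  not uniquely defined in the literature, and our rule resolves it in
  favour of `incorrect`, reserving `ambiguous` for exact ties.

Published three-column success tables fold unidentified queries into the
incorrect column; `classify_dataset(..., fold_no_match = TRUE)` (the
default) reproduces that convention, and `FALSE` keeps `no_match`
separate.

### Trees, monophyly and parsimony

NJ trees are built from the K2P matrix with negative branch-length
estimates clamped to zero.  The bootstrap resamples alignment columns
with replacement, rebuilds distance matrix and NJ tree per
pseudo-replicate, and returns the 50% majority-rule consensus; each
bipartition's support is the percentage of (non-dropped) replicates
containing it.  A species is *resolved* when the unrooted bipartition
separating exactly its specimens occurs with support strictly above the
cutoff (default 60%).  Using unrooted bipartitions avoids outgroup
choice entirely — apt, since outgroups can land inside the ingroup in
unrooted analyses of taxonomically entangled genera.  Species with one
specimen cannot be tested for monophyly and are listed as excluded; a
species comprising all but one specimen is a trivial bipartition,
present with full support by construction.

Parsimony scoring is classical Fitch counting with missing data fully
ambiguous: `CI = min/L` (minimum conceivable steps over tree length),
`RI = (max - L)/(max - min)`, `RC = CI x RI`; an invariant alignment has
length 0 and the indices are flagged undefined.  Multifurcations are
scored on an arbitrary binary resolution.  The heuristic search
(`mp_search()`) uses random stepwise-addition starts with NNI
hill-climbing (SPR optionally); the number of starts is a scale choice,
not an algorithmic one, and results are deterministic under a fixed
seed.  Exhaustive enumeration over all topologies (the test oracle)
confirms the search attains the optimum on small problems.

## The simulator: what it emulates, and what it does not

`simulate_barcodes()` generates species-complex reference libraries so
the whole pipeline can be exercised and calibrated without external
data.  Its defaults mirror a realistic barcode survey of a complex tree
genus: 41 species with 3–5 individuals each, and three loci — a
conserved 636 bp plastid gene (rate multiplier 0.08), a fast 598 bp
plastid gene (rate 1) and a slightly faster 605 bp nuclear spacer (rate
1.05) carrying short shared indels (1–4 bp whole-column gap runs in all
individuals of a random species, probability 0.01 per site).

The generative model is deliberately the analysis model: a Kimura
two-type substitution process (transition/transversion ratio `kappa`,
default 2; equal base frequencies, the K2P assumption) along a species
genealogy whose branch lengths are in expected substitutions per site,
so K2P estimates recover path lengths and closed-form recovery checks
are exact.  The species tree is a Yule draw rescaled to height
`inter_scale/2`, with every species stem lengthened by `inter_scale/2`.
The stem floor is the one place where we deviate from a plain
depth-rescaled Yule tree, and deliberately so: raw Yule depths make the
most recent sister pairs arbitrarily close, which contradicts the
generator's contract that `inter_scale` (default 0.08) is the expected
*sister-species* divergence and would make well-separated test
conditions impossible to state.  With the floor, between-species paths
lie in `[inter_scale, ~2*inter_scale]`.  Within species, individuals
radiate from the species sequence as a star with pendant depth
`intra_scale/2` (default `intra_scale` 0.004), making the expected
conspecific distance exactly `intra_scale` — analytically checkable, at
the cost of having no within-species genealogical structure.

Passing tests on these simulations therefore show that the pipeline is
*correct* — distances, verdicts, supports and scores are what the model
implies — under clean separation.  They do not show that any particular
real locus has a barcoding gap: real data add alignment error,
overlapping intra/inter distributions (conserved loci can have
between-species distances of zero), uneven sampling, introgression and
gene-tree discordance, none of which the star-within-Yule model
generates.  On such data the package reports low success rates rather
than failing; that is precisely what it is for.

```{r}
sim <- simulate_barcodes(sim_spec(n_species = 8, individuals = 3,
                                  seed = 42))
evs <- run_evaluation(sim,
                      combinations = list(c("plastid_fast",
                                            "nuclear_its")),
                      bootstrap = 50, seed = 42)
evs
```

## Numerical choices and degenerate inputs

* Histogram binning uses `floor(d/w + 1e-9)` so distances sitting on a
  bin boundary up to rounding error land in the intended bin.
* Tie tolerance for identification is absolute, $10^{-12}$, on distances
  of magnitude $\le 1$.
* `quantile(type = 7)` (linear interpolation) defines the percentile
  threshold; a degenerate distance distribution returns its constant.
* Two-sequence alignments are valid inputs for distances and
  identification but not for trees (NJ needs three leaves); the
  orchestrator records the per-stage note and completes the rest.
* Concatenation joins on specimen ids by default; the `"species"` mode
  (one representative per species per locus, lexicographically first
  specimen id — a deterministic, if arbitrary, pick) exists because real
  multilocus libraries rarely sequence every specimen at every locus,
  so per-combination sample sizes shrink to the intersection.
* Random number use (bootstrap, MP starts, simulation) is seeded from
  the interface and recorded on the result; identical seeds give
  byte-identical outputs.

## Problem sizes used by the shipped analyses

The test-suite simulations use 5–20 species with 3–4 individuals and
400–600 bp loci, 100 replicate loci for parameter-recovery checks, 25
runs for the end-to-end success checks, and bootstrap depths of 30–100;
`scripts/acceptance.R` runs the full study-scale design (41 species,
three loci and their four combinations) with 100 bootstrap replicates
and a 2-start MP search.  These sizes are the package's own choices:
they keep each check sharp enough to fail loudly while completing on a
single CPU in seconds to a few minutes.  Deeper bootstraps (the
conventional 1000) and more MP starts change support values by at most
sampling noise and are available through the same arguments.

## Known limitations

* Maximum-likelihood tree inference is intentionally absent; NJ and MP
  cover the resolution analysis, and ML adds heavy machinery without a
  new evaluation surface.
* The ASB tie/interleave boundary is a convention (see above); other
  implementations may place borderline queries in `ambiguous` where we
  report `incorrect`.
* `mp_search()` offers NNI and SPR rearrangements, not TBR; on the
  problem sizes where we can enumerate exhaustively, NNI from random
  addition already attains the optimum.
* The simulator's star-shaped within-species model cannot produce
  paraphyletic species or shared haplotypes across species; use real
  data to study those regimes.
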