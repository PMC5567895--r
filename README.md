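# barcodeval

Evaluation of single- and multilocus DNA barcodes for species
delimitation.

## What it is for

Given a reference library of aligned DNA sequences in which every
sequence carries a specimen id and a binomial species label, `barcodeval`
answers the practical barcoding question — *can this locus (or
combination of loci) tell the species apart?* — with the three method
families such surveys report together:

* **Distance structure.** Kimura two-parameter (K2P) pairwise distances
  with pairwise deletion,

  d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q),

  where P and Q are the transition and transversion proportions over the
  comparable sites of a pair; intra- vs inter-specific divergence
  summaries (ranges, means ± SE, per-species theta and coalescent
  depth); the global barcoding-gap histogram (bin width 0.005) and the
  per-species local gap (maximum intra-specific distance vs
  nearest-neighbour distance, strict 1:1-line rule).
* **Similarity-based identification.** TaxonDNA-style *Best Match*,
  *Best Close Match* (fixed 3% or percentile-derived threshold) and
  *All Species Barcodes* verdicts per query, aggregated into the usual
  correct / ambiguous / incorrect percentages.
* **Tree-based resolution.** Neighbour-joining bootstrap 50%
  majority-rule consensus (negative branch lengths clamped to zero),
  per-species monophyly as an unrooted-bipartition criterion above a
  support cutoff (default 60%), and Fitch parsimony scores (tree
  length, CI, RI, RC) with a heuristic maximum-parsimony search.

A seeded simulator (`simulate_barcodes()`) generates species-complex
libraries with controlled intra-/inter-specific divergence so every
stage can be exercised, calibrated and tested without external data.

## Worked example

The package ships a hand-constructed 4-species × 3-individual alignment
of 120 bp whose substitution counts are known by design
(`worked_fixture()`), together with independently computed expected
outputs in `inst/extdata/`.

```r
library(barcodeval)
aln <- worked_fixture()
ev <- barcode_eval(aln, bootstrap = 100, seed = 1)
ev
#> Barcode evaluation of 'fixture' (12 sequences, 4 species)
#>   variable sites: 38 / 120
#>   mean intra 0.0113 +/- 0.0012, mean inter 0.1537 +/- 0.0049
#>   local gap: 100.0% of species above the 1:1 line
#>   BCM correct: 100.00% (threshold 0.03)
#>   NJ resolution: 100.0% of species (> 60% support)
```

Reading the numbers: conspecific individuals differ by 1–2 transitions
(K2P 0.0084–0.0170), species blocks by 10–20 substitutions (K2P
0.0912–0.2122), so every species shows a local barcoding gap, every
query finds a conspecific best close match within the 3% threshold, and
every species forms a monophyletic clade with bootstrap support above
60%.  `summary(ev)` prints the full per-stage reports and `plot(ev)`
draws the gap histogram and the nearest-neighbour dot plot.

For real data, read one FASTA per locus (species parsed from the
headers), then evaluate loci singly and concatenated:

```r
loci <- list(rbcL = "rbcL.fasta", matK = "matK.fasta", ITS = "ITS.fasta")
res <- run_evaluation(loci,
                      combinations = list(c("matK", "ITS"),
                                          c("rbcL", "matK", "ITS")),
                      bcm_threshold = 0.03, bootstrap = 1000,
                      seed = 7, output_dir = "results/")
res$identification   # correct/ambiguous/incorrect per dataset and method
res$resolution       # per-dataset monophyly resolution
```

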