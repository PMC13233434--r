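# robfold

Rule-based detection of conserved structural scaffolds in protein
families, anchored on a functional motif.

Protein families keep a rigid structural scaffold around their functional
centres while tolerating substitutions and rearrangements in the flanks.
`robfold` locates that scaffold for any family by fixing an **anchor
motif** — a short, functionally critical pattern given as a regular
expression, e.g. the CXXC redox site (`C..C`) of protein disulfide
isomerases or the EEVD C-terminal tail of HSP70 chaperones — and testing
how far conservation persists from the anchor on three layers:

* **Primary sequence** — symmetric padded windows of radius *r* around
  every anchor (window length *m* + 2*r*), positional frequency matrices,
  threshold consensus strings, Chou–Fasman structural-equivalence
  translation, and the identity curve
  *SI* = 100 × (1 − *D*/*L*) (Hamming distance *D* over window length *L*).
* **Secondary structure** — anchor-aligned 3-state consensus (DSSP input
  reduced to H/E/C) at ≥ 50 % and 100 % recurrence, plus element-level
  topology search (e.g. the thioredoxin-like β–α–β–α–β core).
* **Geometry** — pairwise Cα Kabsch-superposition RMSD across all
  same-length windows, and the **conservation radius**: the largest
  window length whose mean RMSD stays below a cutoff (15 Å default).

Validation comes from a composition-preserving permutation **null model**
(permuted motifs at margin-matched random positions; a real scaffold
stays above the null envelope) and a site-level **IoU benchmark** against
reference motif annotations (e.g. a PROSITE pattern scan; built-in
PROSITE-syntax compiler included). A synthetic-family generator with
planted ground truth makes the whole pipeline testable offline.

The package is aimed at structural bioinformaticians studying motif-
centred conservation (redox enzymes, chaperones, or any family with a
known anchor) and at protein designers who need interpretable, rule-based
maps of which regions a scaffold can and cannot tolerate changing.

## Worked example

```r
library(robfold)

fam <- generateFamily(familySpec(nProteins = 8, length = 260,
                                 anchorsPerProtein = 1,
                                 motif = "CGHC", pattern = "C..C",
                                 seed = 7))
pat  <- motifPattern("CXXC", "C..C")
sets <- buildExpansionSets(fam$records, pat, radii = c(0, 10, 20, 30))

conservationCurve(sets)
#>   window_length n_windows n_pairs   mean_si
#> 1             4         8      28 100.00000
#> 2            24         8      28 100.00000
#> 3            44         8      28 100.00000
#> 4            64         8      28  75.83705
```

Identity is total out to window 44 — the planted conserved core — and
drops once windows reach the variable flanks. The fully conserved
consensus at window 24 recovers the core sequence around the motif
(variable positions would be shown as `X`):

```r
as.character(consensusSequence(frequencyMatrix(sets[["24"]]), 1))
#> [1] "LTGNQMKIAMCGHCRFVCAMHCAG"
```

The 100 % secondary-structure consensus contains exactly one
β–α–β–α–β element chain, and the geometric layer confirms the
scaffold: RMSD is ~0 inside the core and the conservation radius is the
largest analysed window still below 15 Å:

```r
cons <- ssConsensus(alignSecondary(sets[["64"]]), 1)
length(findTopologyPattern(cons, c("E", "H", "E", "H", "E")))
#> [1] 1

pw <- pairwiseRMSD(sets, cutoff = 15)
pw$summary
#>   window_length n_pairs    mean_rmsd fraction_below
#> 1             4      28 1.370181e-15              1
#> 2            24      28 7.256261e-16              1
#> 3            44      28 1.166643e-13              1
#> 4            64      28 5.345600e+00              1

conservationRadius(pw, 15)$radius_window_length
#> [1] 64
```

The n_pairs column is C(8, 2) = 28: every unordered pair of the eight
anchor windows is superposed. See
`vignettes/motif-anchored-conservation.Rmd` for the model, parameter and
design details.

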