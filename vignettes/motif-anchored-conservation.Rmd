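---
title: "Motif-anchored detection of conserved structural scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-anchored detection of conserved structural scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(robfold)
```

## The problem and the model

Protein families evolve by conserving a structural scaffold — the part of
the fold that carries function — while tolerating substitutions and
rearrangements in flexible flanks. `robfold` implements a deterministic,
rule-based procedure that locates such scaffolds by *anchoring* all
analysis on a short functional motif (the CXXC redox site of protein
disulfide isomerases, the EEVD C-terminal tail of HSP70 chaperones, or any
user-supplied pattern) and asking how far from the anchor conservation
persists, on three structural layers:

1. **Primary sequence.** Around every motif occurrence, symmetric windows
   of radius $r$ are cut ($r = 10, 20, \dots, 200$ residues per side by
   default; window length $m + 2r$ for a motif of length $m$). Positions
   beyond a chain terminus are padded with the neutral symbol `X`, keeping
   all windows of one radius comparable across proteins of different
   lengths. Per-position frequency matrices, threshold consensus strings
   and the pairwise sequence identity
   $$ SI = 100 \times \left(1 - \frac{D}{L}\right) $$
   (with $D$ the Hamming distance and $L$ the window length) quantify how
   identity decays with distance from the anchor. Residues are also
   translated into Chou–Fasman structural equivalence classes
   (helix-former H, sheet-former E, turn-former T), which exposes
   conservation of *folding tendency* hidden behind sequence divergence.
2. **Secondary structure.** Three-state assignments (H/E/C, reduced from
   8-state DSSP output) are stacked anchor-relative; per column the modal
   label forms a consensus at a recurrence threshold — ≥ 50 % (partial)
   or 100 % (complete). Run-length encoding of the consensus supports
   element-level topology queries such as the thioredoxin-like
   $\beta\alpha\beta\alpha\beta$ arrangement around CXXC.
3. **Geometry.** For every pair of coordinate-complete same-length windows
   the Cα traces are superposed by least squares (Kabsch, proper rotations
   only) and the RMSD recorded. The **conservation radius** is the largest
   window length whose mean pairwise RMSD stays below the cutoff (15 Å by
   default): inside it the family superposes as a rigid scaffold, beyond
   it lie adaptive linkers.

Two validation instruments accompany the pipeline: a
composition-preserving **null model** (permuted motifs placed at
margin-matched random positions; a real scaffold keeps its SI curve above
the null envelope far beyond the motif) and a site-level
**intersection-over-union benchmark** of detected sites against reference
annotations such as a PROSITE pattern scan (sites match at IoU ≥ 0.5,
matched greedily by descending IoU, one-to-one).

## A worked example on a synthetic family

```{r example}
fam <- generateFamily(familySpec(nProteins = 8, length = 260,
                                 anchorsPerProtein = 1,
                                 motif = "CGHC", pattern = "C..C",
                                 seed = 7))
pat <- motifPattern("CXXC", "C..C")
sets <- buildExpansionSets(fam$records, pat, radii = c(0, 10, 20, 30))
conservationCurve(sets)
as.character(consensusSequence(frequencyMatrix(sets[["24"]]), 1))
cons <- ssConsensus(alignSecondary(sets[["64"]]), 1)
findTopologyPattern(cons, c("E", "H", "E", "H", "E"))
pw <- pairwiseRMSD(sets, cutoff = 15)
pw$summary
conservationRadius(pw, 15)
```

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| expansion radii | 10…200, step 10 | residues/side | typical domain sizes; spans motif-centred functional regions |
| consensus threshold | 1.0 | fraction | the fully conserved nucleus; the frequency matrix is exported so any other threshold can be applied downstream |
| SS recurrence thresholds | 0.5 and 1.0 | fraction | partial vs complete element recurrence |
| `minCoverage` | 2 | windows | a single assigned row is not a consensus |
| `minRun` | 2 | residues | single-residue H/E calls are treated as assignment noise |
| RMSD cutoff | 15 | Å | boundary of the conserved/flexible transition observed in pairwise RMSD distributions of redox and chaperone families; exposed as `--rmsd-cutoff` |
| null trials `n` | 50 | trials | enough to place a stable envelope around the decay curves |
| IoU threshold | 0.5 | fraction | site-level agreement criterion for the benchmark |

## Design choices where the design was open

* **Overlapping motif matches** are returned by default (lookahead scan).
  Multi-domain families carry adjacent or overlapping active sites, and a
  non-overlapping scan silently drops some of them; it remains available
  via `overlapping = FALSE`.
* **Padding in sequence identity.** `X` is treated as an ordinary 21st
  symbol (two padded positions match). The alternative — excluding padded
  positions from both $D$ and $L$ — is available as `excludePad = TRUE`;
  the choice is recorded in output metadata.
* **Recurrence denominators are padding-aware**: a column's consensus is
  judged among the windows that actually reach that offset, so terminal
  columns are not diluted by short chains. Exact ties (e.g. 50/50 H/E)
  yield `x`; a label requires a unique mode at or above the threshold.
* **Consensus ties** below threshold 1.0 are broken alphabetically and
  logged, keeping runs deterministic.
* **Chou–Fasman classes** come from the canonical propensity table
  (`chouFasmanTable()` exports it verbatim). Cysteine's sheet and turn
  propensities are exactly equal (119); the fixed tie priority
  H > E > T classifies it as a sheet-former, in line with its common
  classification.
* **Windows pair across proteins and across multiple anchors of one
  protein** in the geometric layer: for a family with $k$
  coordinate-complete windows at a length, all $\binom{k}{2}$ pairs are
  scored. This is what makes site counts and pair counts consistent for
  families whose members carry several copies of the motif.
* **Null anchoring is position-based**: the permuted motif labels the
  trial, and windows are cut at the sampled positions of the real
  sequences. This is the only reading under which the full pipeline can
  be re-run per trial — a permuted motif need not occur verbatim anywhere.
  The safety margin takes the *minimum* terminal distances over the
  family's biological anchors, the least restrictive structurally-matched
  constraint.
* **Degenerate benchmark rates**: precision with zero predictions (and
  recall with zero references) is reported as 1.0 with a logged note, so
  perfect-agreement tables stay well defined.
* **Indexing** is 1-based with closed intervals throughout the R API;
  every user-facing coordinate in reports is an author (PDB) residue
  number, never a position in an extracted sequence string. Crystal
  chains that start above residue 1 (e.g. at 22, after an excluded
  hetero-group) therefore report sites at their deposited numbers.
* **Chain selection** takes the first polymer chain unless a chain id is
  configured; alternate locations keep blank/'A'; MSE is retained as M,
  other non-standard residues are skipped with a warning; residues whose
  author numbers do not increase (insertion-code duplicates) keep their
  first occurrence.

## What the synthetic generator emulates — and what it does not

`familySpec()`/`generateFamily()` produce homolog sets from a common
ancestor: a planted motif at evenly spaced anchors (with spurious pattern
occurrences removed by targeted resampling, so ground-truth site counts
are exact), per-position substitution at a step profile (rate 0 within 20
residues of an anchor, 0.5 beyond, by default), an idealized
helix/strand/coil Cα template (1.5 Å rise and 100°/residue for helices,
3.3 Å rise for strands) with isotropic noise scaled by the substitution
profile, per-homolog random terminal extensions (up to 30 residues,
giving realistic chain-length variation — without it the null model's
safety margins would pin every null anchor onto the biological position),
and configurable author-numbering offsets to emulate crystal structures.
With several anchors per protein the core context of the first anchor is
duplicated to the others, as in the duplicated thioredoxin domains of
disulfide isomerases.

The generator does **not** emulate: indels inside the core (windows are
strictly colinear around anchors), correlated substitutions, physically
realistic backbone geometry or side chains, multi-chain assemblies, or
assignment noise in secondary structure. Passing tests on these fixtures
therefore demonstrate the correctness of the *rules* — coordinate
bookkeeping, consensus arithmetic, superposition, matching — not the
biological claims themselves, which require real family structures.

## Numerical notes

Superposition uses SVD of the 3×3 cross-covariance with a determinant
guard, so mirror images are never superposed by an improper rotation;
RMSD is symmetric to 1e−9 and invariant under rigid motions of either
input. Windows with fewer than two members (or, in the geometric layer,
fewer than two coordinate-complete members) are omitted from curves with
a warning rather than treated as errors. All randomness — generator,
null trials — flows through R's RNG from a single user-supplied seed, and
identical inputs give byte-identical outputs.

The test-suite and acceptance analyses run on deliberately small
problems (families of 4–11 proteins of 100–600 residues, radii up to
60–110, 50 null trials), chosen so the full suite completes in well under
a minute while still exercising every rule at realistic family shapes.

## Limitations

Only sequence-regex anchors are supported (no structural-fingerprint
anchoring); superposition is sequence-order dependent and rigid (no
flexible or fragment alignment); NMR ensembles use the first model only;
DSSP output is ingested, not computed — pair the package with any DSSP
build when assignments are needed. The biological-vs-null separation is
reported as curves and envelopes; no significance statistic is attached.
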