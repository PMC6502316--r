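---
title: "Methods: rule-based C2H2 zinc-finger family surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based C2H2 zinc-finger family surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsurvey)
```

## The model

The classical C2H2 zinc finger is a short domain — about 30 residues —
in which two cysteines and two histidines tetrahedrally coordinate a
single Zn²⁺ ion. Plant fingers are distinctive in two ways: the α-helix
carries a highly conserved **QALGGH** hexamer ending at the first His
ligand, and the spacing between fingers within one protein is long and
variable, unlike the short "HC links" of tandem animal fingers.

`zfsurvey` treats a finger purely as a ligand geometry. A candidate is a
quadruple of residue indices `(c1, c2, h1, h2)` with Cys at `c1`, `c2`
and His at `h1`, `h2`, whose spacings (residues strictly between two
ligands) satisfy the union envelope

```
c2 - c1 - 1 ∈ 1..4,   h1 - c2 - 1 ∈ 1..max_ch,   h2 - h1 - 1 ∈ 1..8
```

plus His-less triples (the D geometry) when the Cys₂–His spacing is 12
or 13 and no His completes the quadruple. Types are then assigned by a
total, exclusive decision tree:

| condition | type |
|---|---|
| no second His | `D` |
| Cys₂–His₁ spacing > 12 | `Z1` |
| Cys₂–His₁ spacing < 12 | `Z2` |
| spacing 12, QALGGH intact | `Q` |
| spacing 12, k of QALGG degraded (k = 1..5) | `M1`..`M5` |

The published spacing table carries per-subtype variants for the M rows
(e.g. extra Cys–Cys or His–His spacings for M3–M5). Those variants
conflict with a single uniform tree in rare geometries; the classifier
follows the defining property shared by all M rows — canonical spacing
12 with a degraded motif — and the simulator's `zf_spec()` validates the
per-row variants when *planting* domains. The degraded count ignores the
sixth motif position (it is the His ligand itself); `X` counts as a
mismatch and never as a ligand.

Protein-level subsets follow the tandem/dispersed dichotomy: the linker
is the number of residues strictly between the last His of one finger
and the first Cys of the next (mirroring the "HC link" convention).
Proteins whose linkers are all ≤ 11 are tandem (`Br-t1-SF` for 2–5
fingers, `Br-t2-SF` for 6+); dispersed proteins are binned by finger
count and collapsed type (`Br-1i-*`, `Br-2i-*`, `Br-3i-SF`, `Br-4i-SF`).

## Tunable parameters

* `max_ch` (default **35**): upper bound on the Cys₂–His₁ spacing. The
  taxonomy only says "> 12" for Z1; a cap is needed to bound the
  enumeration, and 35 keeps the whole domain near its ~30-residue size.
  Configurable everywhere it appears.
* Leading `X2` context: the consensus patterns begin with two arbitrary
  residues, which we treat as context, not a precondition — matches at
  the sequence start are legal and spans clamp at 0.
* Tandem linker threshold (**11**), array gap (**100 kb**) and
  intervening-gene allowance (**1**): the linker threshold is stated by
  the source classification; the array criteria are not stated anywhere
  and follow the common plant gene-family convention, exposed as
  `call_tandem_arrays(max_gap_kb=, max_intervening=)` precisely because
  they are a convention.
* Clock rate `R` (**1.5e-8** subs/site/year): the standard dicot rate
  used in `T = Ks / 2R`; `divergence_time()` reports MY.
* Expression: pseudocount **+1** in `log2(FPKM + 1)` (a bare log2 is
  undefined at 0; +1 keeps zeros at zero), Euclidean distance, average
  (UPGMA) linkage, and a group count `k` (default 7 in the pipeline)
  cut from the tree; groups are renumbered by descending size, which
  makes labels stable but only *approximately* comparable to any
  published roman-numeral grouping obtained from a visual dendrogram
  cut.

## Design choices where the rules were open

* **Span convention.** The survey's domain "span" is reported half-open,
  `[c1 - 2, last_ligand + 1)` (D spans include the two consensus
  residues after the His). The source notation mixes inclusive pattern
  endpoints with half-open intervals; we standardised on half-open with
  the final ligand inside its own span.
* **Overlap resolution.** The published inventories report
  non-overlapping fingers but no tie-break rule. We use deterministic
  greedy selection on ligand-disjointness with priority: canonical
  spacing 12 first, quadruples before D triples, then smaller span,
  then smaller `c1`. Greedy selection guarantees maximality (no
  rejected candidate is ligand-disjoint from the selection), which the
  tests verify exhaustively on short sequences.
* **Mixed linkers.** A protein with some linkers ≤ 11 and some ≥ 12 has
  no defined class; we assign by linker majority, break ties toward
  tandem, and flag `mixed_linker` so downstream users can filter.
* **≥ 5 dispersed fingers.** No subset exists for this; the protein is
  `Unclassified` with a warning rather than forced into a bin.
* **NG86 in place of ML.** The original analysis used codeml; this
  package implements the Nei–Gojobori counting method because it is
  fully specifiable and desk-verifiable by brute force. Outputs carry
  `estimator = "NG86"`; small systematic differences from ML values are
  expected and no test asserts agreement with ML output. Stop-codon
  handling: in site counting, changes creating stops count as
  non-synonymous so per-codon site counts always sum to 3; in difference
  counting, mutational orderings passing through a stop are excluded,
  falling back to all orderings if every one hits a stop. Saturated
  proportions (p ≥ 3/4) return an infinite, flagged distance that
  summaries exclude with a warning.
* **pI.** Bisection on the Henderson–Hasselbalch net-charge curve over
  pH (0, 14) with the Bjellqvist pKa set (side chains C 9.0, D 4.05,
  E 4.45, H 5.98, K 10.0, R 12.0, Y 10.0; C-terminus 3.55;
  residue-specific N-terminal pKas, default 7.5) to |charge| < 1e-4.
  Tests compare against an independent grid-search oracle to 1e-3 pH.
* **Config format.** Pipeline and generator configs are JSON (or plain R
  lists); no YAML reader is assumed in the runtime environment.
* **Segmental duplication** is read off synteny block labels (same
  ancestral block, different subgenomes), never re-derived from
  sequence, matching how such surveys actually source it.

## What the simulators emulate — and what a green test establishes

`simulate_proteome()` builds proteins as
`flank | domain | linker | domain | ... | flank` with background drawn
from an 18-letter alphabet **excluding C and H**. Under that exclusion
the planted fingers are provably the only candidates, so scan+classify
recovering 100 % of planted types, coordinates and subset labels is an
oracle-exact correctness statement about the scanner and classifier —
*not* evidence about sensitivity/specificity on real proteomes, where
the original survey additionally relied on homology search and manual
curation that rule-based scanning cannot reproduce. A `decoys = TRUE`
mode sprinkles isolated C/H residues to exercise overlap resolution;
robustness is tested there against exhaustive optimal selection on
short sequences. Template geometries keep dispersed Z2 spacings at 9
and D fingers away from closely trailing fingers, because extreme
corner geometries (e.g. two spacing-1 Z2 fingers one residue apart) can
legitimately create a higher-priority spurious candidate spanning both
— a property of the rule system itself, not a bug.

`simulate_cds_pair()` places each requested substitution in a distinct
codon, choosing positions/alternatives that realise the requested
synonymous/non-synonymous status without creating stops; the ledger is
the ground truth the NG86 tests check against. It deliberately models
no codon-usage bias, indels, or multiple hits per codon (multi-hit
pathway averaging is instead exercised by comparing fully random codon
pairs against the pathway-enumeration oracle).

`simulate_expression()` draws log-normal FPKM (non-negative,
right-skewed) with high/low median 50/0.5 and `sdlog` 0.5 — a strong,
clean tissue preference. Exact two-group recovery at `k = 2` therefore
validates the clustering plumbing, not the resolvability of real
expression atlases, whose visual seven-group structure is explicitly
not an acceptance surface.

One scanner invariant needs a caveat: "appending residues never removes
a reported match" holds for quadruples and for D candidates whose
His-completion window `[h1+2, h1+9]` lies inside the sequence. A D
candidate whose window is cut off by the sequence end is provisional by
construction — appending a His inside the window lawfully upgrades it
to a quadruple — and the property test scopes it accordingly.

## Numerical notes

* All coordinates are 0-based and spans half-open in every file and
  message.
* Case-insensitive residue matching; any character outside the 20
  amino-acid letters plus `X` is an error naming the offending
  position.
* Jukes–Cantor: `d = -(3/4) ln(1 - (4/3) p)`; monotone, → p as p → 0.
* `2^-ΔΔCt`: replicate Ct values are averaged *before* ΔCt; ΔΔCt is
  taken against the control condition at the same gene and timepoint.
* Average-linkage clustering and group cuts are deterministic given the
  input; group renumbering by size makes the labels order-invariant.
* All simulators take an integer seed and are byte-deterministic given
  it; the pipeline seeds once from its config.

## Known limitations

* Rule-based scanning cannot reproduce a curated domain inventory that
  used homology search plus manual inspection; headline inventory
  counts from any real survey are out of reach by design and never
  asserted.
* NG86 ≠ ML: Ka/Ks values differ systematically from codeml output.
* The published supplementary spreadsheets are binary XLSX and not
  redistributable here; the table-shaped code paths are exercised on
  synthetic stand-ins with independent tally oracles instead.
* Group-identity matching between cluster cuts and published
  roman-numeral expression groups is approximate (by size rank) and not
  tested numerically.
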