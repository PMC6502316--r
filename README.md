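# zfsurvey

Genome-wide surveys of **C2H2 zinc-finger protein (ZFP) families** are a
staple of plant comparative genomics: the classical C2H2 zinc finger is a
~30-residue domain whose two cysteines and two histidines coordinate one
Zn²⁺, and in plants its α-helix carries the hallmark **QALGGH** hexamer.
`zfsurvey` re-implements such a survey as a reusable, fully tested R
pipeline for anyone who needs to detect, type and classify these domains
from a proteome and carry the family through duplication, divergence-dating
and expression analyses — without any external web services.

## What it computes

* **Domain scanning** — exhaustive enumeration of Cys/Cys/His(/His) ligand
  arrangements under the spacing envelope
  `C-X(1–4)-C-X(1–35)-H-X(1–8)-H`, with deterministic overlap resolution.
* **Domain typing** — the plant taxonomy: `Q` (intact QALGGH, Cys₂–His₁
  spacing 12), `M1–M5` (k degraded residues in QALGG at spacing 12),
  `Z1`/`Z2` (spacing > 12 / < 12), `D` (missing the second His).
* **Protein classification** — tandem subsets (`Br-t1-SF`, `Br-t2-SF`;
  adjacent fingers linked by < 12 residues) and dispersed subsets
  (`Br-1i-{Q,M,Z,D}-SF`, `Br-2i-{Q,M,Z,Mix}-SF`, `Br-3i-SF`, `Br-4i-SF`),
  plus ProtParam-style length, molecular weight and isoelectric point
  (Bjellqvist pKa set, bisection on the net-charge curve).
* **Genome organisation** — tandem gene-array calling from coordinate
  tables; subgenome (LF/MF1/MF2) occupancy and ortholog copy-number
  profiles from synteny tables of a whole-genome-triplicated genome.
* **Molecular evolution** — Nei–Gojobori (NG86) Ka/Ks with Jukes–Cantor
  correction, selection summaries, and divergence dating `T = Ks / 2R`
  (default `R = 1.5e-8` synonymous substitutions/site/year for dicots).
* **Expression** — all-zero-gene filtering, `log2(FPKM + 1)`, hierarchical
  clustering (Euclidean, average linkage), expression-group × subset
  cross-tabs, ortholog expression correlation over five shared tissues,
  and qPCR `2^-ΔΔCt` fold changes.
* **Simulators** — proteomes with planted fingers, CDS pairs with exact
  synonymous/non-synonymous budgets, gene maps with planted tandem
  arrays, synteny tables with known copy numbers, and grouped expression
  matrices — every downstream stage is testable against planted truth.

## Worked example

```r
library(zfsurvey)

sim <- simulate_proteome(
  list(list(zf_spec("Q"), zf_spec("Q"), zf_spec("Q")),
       list(zf_spec("M2")),
       list(zf_spec("Q"), zf_spec("Z1", ch_spacing = 20L))),
  list(c(5L, 8L), integer(0), 20L), seed = 42)

matches <- classify_domains(scan_proteome(sim$sequences))
matches[, c("protein_id", "c1", "c2", "h1", "h2", "motif6", "type_label")]
#>   protein_id c1 c2 h1 h2 motif6 type_label
#> 1    prot001  5  8 21 25 QALGGH          Q
#> 2    prot001 31 34 47 51 QALGGH          Q
#> 3    prot001 60 63 76 80 QALGGH          Q
#> 4    prot002  5  8 21 25 QDLDGH         M2
#> 5    prot003  5  8 21 25 QALGGH          Q
#> 6    prot003 46 49 70 73 QALDGH         Z1

classify_proteome(matches)
#>   protein_id n_domains types       subset mixed_linker
#> 1    prot001         3 Q,Q,Q     Br-t1-SF        FALSE
#> 2    prot002         1    M2   Br-1i-M-SF        FALSE
#> 3    prot003         2  Q,Z1 Br-2i-Mix-SF        FALSE
```

Coordinates are 0-based (`c1`/`c2` the cysteines, `h1`/`h2` the
histidines); `prot001`'s three QALGGH fingers linked by 5 and 8 residues
make it a tandem `Br-t1-SF` protein, while `prot003`'s two fingers, 20
residues apart and of different types, fall in the dispersed mixed subset.

```r
p <- simulate_cds_pair(60, n_syn = 4, n_nonsyn = 1, seed = 42)
r <- ng86_kaks(p$cds_a, p$cds_b)
sprintf("Ka %.4f  Ks %.4f  Ka/Ks %.4f  T %.2f MY",
        r$ka, r$ks, r$omega, divergence_time(r$ks))
#> "Ka 0.0075  Ks 0.0917  Ka/Ks 0.0820  T 3.06 MY"
```

Four planted synonymous changes against one non-synonymous change give
Ka/Ks ≪ 1 (purifying selection) and a synonymous divergence of ~3 million
years under the dicot clock.

The whole pipeline can also be driven from one JSON config via
`run_survey()` (stages `scan`, `genome`, `kaks`, `express`, `qpcr`) or
the CLI wrapper `inst/cli/zfsurvey.R`; it writes per-stage TSVs and a
provenance-stamped `survey_report.json`.

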