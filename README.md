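# aexapr

Physicochemical classification of aggregation-prone regions (APRs) in
therapeutic proteins.

Short, mostly hydrophobic peptide stretches can nucleate aggregation of a
biologic drug; aggregates in turn drive anti-drug-antibody (ADA) responses
that alter clearance and safety. `aexapr` implements a descriptor-based
classifier that separates such APR peptides from non-aggregating control
peptides, and extends it into a sliding-window scanner for whole protein
sequences. It is aimed at developability assessment in non-clinical biologic
drug development.

## The model

Each peptide is summarized by eight sequence-level physicochemical
descriptors: counts of non-conjugated amine groups (AM), carboxylic acid
groups (AC), rotatable bonds (ROT), hydrogen-bond acceptors (HBA),
non-aromatic ring atoms (NON), summed ionization potential (IP, eV), and two
whole-molecule predictions aggregated as sequence means — Caco-2
permeability (QPCaco, nm/s) and aqueous solubility (QPlogS). Count-like and
energy-like descriptors accumulate along the chain (sum rule); QPCaco and
QPlogS are averaged over the number of distinct residue types (mean rule).

The scoring expression combines six of them:

    AEx = Ln(AM − IP + AC × ROT) − (QPCaco − NON)

Paired with solubility, AEx splits the (QPlogS, AEx) plane into four
classes, evaluated in order with the first match winning:

| class | rule                    | reading                     |
|-------|-------------------------|-----------------------------|
| A     | QPlogS > 0 and AEx < 0  | soluble, low score          |
| B     | QPlogS ≥ 0 and AEx > 0  | soluble, high score         |
| C     | QPlogS < 0 and AEx ≥ 0  | insoluble, high score       |
| D     | QPlogS ≤ 0 and AEx ≤ 0  | **aggregation-prone**       |

Class D is the APR call. Model validation uses Cooper statistics
(sensitivity, specificity, accuracy, predictivities and their complements)
over a reference set of 84 APR peptides versus 42 control 5-mers sliced
from 22 tregitope sequences, plus Mann-Whitney rank tests and a Toplis
ratio check.

The reference table only gives descriptors at sequence level. To score new
sequences, `aexapr` recovers per-residue descriptor tables from the 148
reference rows by minimum-norm least squares on the residue-composition
matrix; the integer count descriptors are recovered exactly, and held-out
rows are predicted exactly under cross-validation.

## Worked example

```r
library(aexapr)

ref <- apr_reference()          # 148 validated records
fit <- classify_dataset(ref)    # quadrant classes from the published scores
fit$class_counts
#>   group         A     B     C     D     U
#> 1 APR           0     9     8    67     0
#> 2 TREGITOPE     6     4     6     6     0
#> 3 CONTROL       2    22    17     1     0

tidy(cooper_statistics(fit))
#>   statistic value
#> 1 sn        79.8      # sensitivity: 67 of 84 APRs called
#> 2 sp        97.6      # specificity: 41 of 42 controls cleared
#> 3 ac        85.7
#> 4 er        14.3
#> 5 pp        98.5
#> 6 np        70.7
#> 7 fp_oc      2.38
#> 8 fn_uc     20.2
#> 9 pas       97.6
```

67 of the 84 APR peptides fall in class D while only one control does; the
classifier trades some sensitivity (17 missed APRs sit in classes B/C) for
near-perfect specificity.

Scanning a whole sequence with tables recovered from the reference set:

```r
tabs <- infer_descriptor_tables(ref)
scan <- scan_protein(ref$sequence[87], tabs$tables, id = "treg_87")
dplyr::filter(scan, apr_flag)
#>   seq_id  start end window   qplogs    aex class
#> 1 treg_87     2   6  STYRV  -0.0484 -0.291 D
#> 2 treg_87     3   7  TYRVV  -0.0988 -0.725 D
#> ...
#> 5 treg_87     6  10  VVSVL  -0.0871 -7.58  D
#> ...
#> 9 treg_87    10  14  LTVLH  -0.107  -2.68  D
autoplot(scan)
```

The flagged window run covers the VVSVLTVL patch of this tregitope — the
same stretch that appears verbatim among the reference APR peptides.

A command-line interface wrapping these functions ships at
`inst/exec/aexapr` (subcommands `data-dump`, `reproduce`, `score`,
`infer-params`).

## Known data caveats

The packaged table is reproduced as published, including its quirks: row
129 (VVSVL) carries a printed AEx of 0.00 where the formula gives −2.46
(flagged everywhere it matters); the printed control-set mean AEx (2.23)
recomputes to 2.20; and the printed Mann-Whitney Z values (7.172 / 6.270)
recompute to 7.137 / 6.089 from the printed columns — consistent with the
original ranking having used unrounded scores. The reproduction report
states the recomputed values rather than silently matching the printed
ones.
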