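---
title: "Methods: descriptor-based classification of aggregation-prone regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor-based classification of aggregation-prone regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aexapr)
```

## The problem and the data

Aggregation-prone regions (APRs) are short, largely hydrophobic peptide
stretches that can nucleate aggregation of a therapeutic protein; because
aggregates are immunogenic, flagging APRs early matters for biologic drug
design. `aexapr` implements a classifier that separates known APR peptides
from non-aggregating controls using eight physicochemical descriptors, and
a scanner that applies it along arbitrary protein sequences.

The packaged reference set holds 148 records: 84 APR peptides excised from
therapeutic proteins (5–11 residues), 22 tregitope sequences (14–26
residues), and 42 control 5-mers derived from the tregitopes. Tregitopes
are regulatory-T-cell epitopes associated with a tolerogenic response, so
peptides drawn from them are a reasonable "does not aggregate, is present
in therapeutic proteins" control. The control derivation takes residues
1–5 and 6–10 of each tregitope (44 windows) and drops both occurrences of
the doubly-selected window VSWYQ, leaving 42. Two quirks of the published
table are reproduced deliberately: VVSVL (row 129) is retained even though
the accompanying narrative says it was removed — the published class
counts (controls 2/22/17/1 across A–D) only reconcile with it present —
and duplicate 5-mers arising from distinct tregitopes (GGLVQ, MHWVR) stay
as separate records. Every load re-validates row/group counts, the residue
alphabet, integrality of the count descriptors and per-column checksums.

## Descriptors and the AEx score

Six descriptors aggregate by the **sum rule** — per-residue value times
occurrence count, summed over residue types: amine-group count (AM),
carboxylic-acid count (AC), rotatable bonds (ROT), hydrogen-bond
acceptors (HBA), ionization potential (IP, eV) and non-aromatic ring
atoms (NON). Two whole-molecule predictions aggregate by the **mean
rule** — the same weighted sum divided by N: Caco-2 permeability (QPCaco,
nm/s) and aqueous solubility (QPlogS).

Whether N counts distinct residue types or all residues is ambiguous in
the model's original description ("non-repeated amino acids"). Both
conventions are implemented (`denominator = "distinct"` / `"length"`);
`"distinct"` is the default because fitting the reference data under both
hypotheses (see below) leaves a smaller residual under the distinct-count
reading. The two coincide for repeat-free sequences.

The score is

$$\mathrm{AEx} = \ln(\mathrm{AM} - \mathrm{IP} + \mathrm{AC}\cdot\mathrm{ROT}) - (\mathrm{QPCaco} - \mathrm{NON}),$$

with the natural logarithm — the only base that reproduces the published
per-row scores (e.g. $\ln(24.95) - 4.41 = -1.19$ for ALLVN). When the log
argument is non-positive the score is undefined; `compute_aex()` returns
`NA` with a warning rather than throwing, so that window scanners can skip
such windows and keep going. At least three of the six terms (AM, AC, IP)
describe charge character, which is the model's distinctive emphasis
alongside the classical solubility/hydrophobicity axis.

## The quadrant rule

Classes partition the (QPlogS, AEx) plane, evaluated in order A → B → C →
D with the first match winning: A (QPlogS > 0, AEx < 0), B (QPlogS ≥ 0,
AEx > 0), C (QPlogS < 0, AEx ≥ 0), D (QPlogS ≤ 0, AEx ≤ 0). Class D is
the APR call. The ordering matters exactly on the boundary AEx = 0 with
QPlogS < 0, which the ordered rule sends to C; this is the only resolution
that reproduces the published per-class counts given the retained VVSVL
row (whose printed AEx is 0.00). The single gap in the predicates —
QPlogS > 0 with AEx = 0 — is returned as class U (unclassifiable) rather
than guessed; no reference record occupies it.

Validation contrasts APR (positive) against controls (negative), with
class D as the positive call; tregitopes are excluded, giving n = 126.
The nine Cooper statistics are computed from the confusion counts exactly
as conventionally defined, each as a percentage. One published equation is
reproduced as printed even though it conflicts with the published value:
P\_as = Tn/(Tn + Fp) equals specificity (97.62 %), while the published
figure (85.71 %) equals accuracy. The package computes the equation and
reports the conflict instead of patching either side.

Two modes are kept strictly separate: *reproduction* classifies from the
published descriptor columns verbatim; *scoring* recomputes descriptors
from per-residue tables. `classify_dataset()` never mixes them in one run.

## Recovering per-residue tables

The published table gives sequence-level descriptor values only, and the
original per-residue values came from proprietary descriptor software. To
score arbitrary sequences the package inverts the aggregation: with C the
148 × 20 residue-composition matrix and s the sequence-level column, the
sum rule is the linear system C v = s, solved by minimum-norm least
squares on the SVD with explicit numerical-rank reporting. All 20
canonical residues occur in the reference sequences and the system has
full rank 20. For the integer count descriptors (AM, AC, ROT, NON) the
solution is rounded to integers; the rounded tables reproduce all 148
training rows *exactly*, and in a 120/28 split reproduce the 28 held-out
rows exactly, so for these descriptors the recovery is effectively
lossless. HBA is recovered to numerical precision and IP to the printed
two-decimal rounding (max residual ≈ 0.0055 eV).

For the mean-rule descriptors the system is C v = s·N under both
denominator hypotheses; the hypothesis with the smaller residual norm is
selected and recorded. On the reference data the distinct-count
denominator wins for both QPCaco and QPlogS, but residuals remain well
above rounding noise (max ≈ 10 nm/s for QPCaco, ≈ 0.26 for QPlogS): the
original whole-molecule predictions are simply not an exact linear
function of residue composition. Scanner scores for novel sequences
therefore carry meaningful uncertainty in the QPCaco and QPlogS terms,
and scan output should be read as a ranking of candidate regions, not as
reproductions of descriptor-software output. Residues absent from a
fitted table make scoring a sequence containing them an error, never an
extrapolation; rank deficiency is reported, not fatal.

## Statistics

`group_summary()` uses the sample SD (n − 1), SE = SD/√n with n the
group's own size, and m ± 1.96·SE for the 95 % interval. The per-group n
(rather than the pooled total) and the normal multiplier are the only
conventions that reconcile the published per-class standard errors (e.g.
SD ≈ 1.17 over n = 67 giving SE ≈ 0.143).

`mann_whitney_z()` uses midranks for ties and the normal approximation
with tie-corrected variance. The reported statistic `zc` = |Z| carries no
continuity correction — the convention behind the published Z\_c values —
while `p_two_sided` applies the usual 1/2 continuity correction, matching
`stats::wilcox.test()`; without it the two-sided p is a poor estimate of
the exact-enumeration p at small n (it can miss by > 0.15 even at
balanced sizes, because the symmetric exact p equals 1 at the central U).
Exhaustive enumeration over all untied rank configurations shows the
corrected p stays within 0.05 of the exact p for every split with both
samples ≥ 2 and total ≥ 6; one-member samples are outside the
approximation's validity and are tested accordingly.

Recomputing the two rank tests from the printed columns gives |Z| = 7.137
(AEx) and 6.089 (QPlogS) against published values of 7.172 and 6.270. No
convention tried (continuity correction on/off, ordinal ranking,
full-precision recomputed AEx, alternative group compositions) reproduces
the published figures from the printed table; the needed rank sums
indicate the original ranking used unrounded scores that are not
recoverable. The package reports its recomputed values.

`toplis_check()` guards against overfitting: training-set size over
descriptor count must strictly exceed 5. The model's AEx-plus-QPlogS form
uses 7 descriptors over 84 training APRs, ratio 12.

## Numerical and design choices

* Internal computation is at full double precision; comparisons against
  published two-decimal values round half-away-from-zero only inside
  tests.
* Undefined AEx is a sentinel (`NA`), not an exception; classification of
  an `NA` score is an error instructing callers to skip the window.
* The SVD rank tolerance is `max(dim) * max(singular value) * eps`, the
  standard pseudoinverse cutoff.
* Randomized procedures (`random_peptides()`, the cross-validation split)
  take explicit seeds; the reference 120/28 split uses 20160707 by
  default. The synthetic-peptide generator draws residues uniformly over
  the 20-letter alphabet — adequate for property tests of algebraic
  invariants, but deliberately not a model of natural sequence
  composition, so passing tests say nothing about performance priors on
  real proteomes.
* Reproduction-report problem sizes: all reference computations run on
  the packaged 148 rows; property tests use 200 simulated peptides of
  length 5–10 and exhaustive rank enumeration up to n = 9, sizes at which
  the brute-force oracles are exact and fast.

## Known limitations

* The model was calibrated on 5-mers against tregitope-derived controls;
  long sequences dilute the signal (the published discussion itself notes
  long tregitopes score APR-like), so scanning uses short windows
  (default 5) rather than whole-sequence scores.
* Recovered per-residue tables are calibration constants of this model,
  not chemically interpretable single-residue properties; the mean-rule
  recovery is approximate (above).
* The published table's own inconsistencies (VVSVL's printed score, the
  control-set mean AEx 2.23 vs recomputed 2.20, the per-class APR means,
  the printed P\_as and Z values) are reported by the reproduction
  machinery rather than reconciled; where a published number cannot be
  derived from the published data, the package sides with the data.
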