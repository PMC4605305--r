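---
title: "Quantifying PSF-dependent splicing from RASL-Seq ligation products"
author: "raslPSI maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PSF-dependent splicing from RASL-Seq ligation products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raslPSI)
```

## The assay and the model

RASL-Seq (RNA-mediated oligonucleotide Annealing, Selection and Ligation
with sequencing) measures cassette-exon alternative splicing without
genome alignment. For each interrogated event, two probe pairs anneal
adjacent to the two possible splice junctions — one pair across the
exon-inclusion ("long isoform") junction, one across the skipping
("short isoform") junction. Juxtaposed probes are ligated, amplified with
an inline sample barcode, and sequenced; each read is therefore a barcode
followed by one junction sequence, and counting reads per junction counts
isoform molecules.

The quantity of interest is percent spliced in,

$$\mathrm{PSI} = 100 \times \frac{n_{\mathrm{long}}}{n_{\mathrm{long}} + n_{\mathrm{short}}},$$

computed per event and replicate, then averaged within a condition.
Condition contrasts are expressed as
$\Delta \mathrm{PSI} = \overline{\mathrm{PSI}}_a - \overline{\mathrm{PSI}}_b$
(always first-named minus second-named condition).

The biological system modelled here is the JSL1 T-cell line, where PMA
stimulation changes the inclusion of many exons, the splicing regulator
PSF (SFPQ) drives a subset of those changes, and TRAP150 (THRAP3)
sequesters PSF in resting cells. The experimental design is three
biological replicates each of unstimulated wild type (`WT_U`),
PMA-stimulated wild type (`WT_S`) and PMA-stimulated PSF knockdown
(`PSF_KD_S`), optionally extended with unstimulated TRAP150 knockdown
(`TRAP150_KD_U`).

## Decision rules

Two published, deliberately distinct rules identify PSF-dependent
PMA-induced events; both are implemented as named, composable filters.

**Absolute delta-PSI rule** (`callPsfDependentMethods`): an event passes
when $|\overline{\mathrm{PSI}}_{WT\text{-}S} -
\overline{\mathrm{PSI}}_{PSF\text{-}KD\text{-}S}| \ge 10$ (inclusive) and
the replicate-level p value is below 0.05.

**Stimulation-response / rescue rule** (`callPsfDependentResults`): the
event must respond to stimulation,
$|\overline{\mathrm{PSI}}_{WT\text{-}S} -
\overline{\mathrm{PSI}}_{WT\text{-}U}| > 9$ (strict), and PSF knockdown
must revert at least 60% of that response. The rescue fraction

$$r = \frac{\overline{\mathrm{PSI}}_{WT\text{-}S} -
\overline{\mathrm{PSI}}_{PSF\text{-}KD\text{-}S}}
{\overline{\mathrm{PSI}}_{WT\text{-}S} -
\overline{\mathrm{PSI}}_{WT\text{-}U}}$$

is interpreted sign-aware: the knockdown and stimulation shifts must have
the same sign and $r \ge 0.6$ (inclusive). This reading treats
PSF-enhanced and PSF-repressed exons symmetrically — it is invariant
under replacing every PSI $x$ by $100 - x$ — which an absolute-value
reading would not be for repressed exons. Events with a zero stimulation
response have an undefined rescue fraction and are excluded with a flag
rather than silently dropped.

Boundary semantics are literal throughout: $\ge 10$ inclusive, $> 9$
strict, $\ge 0.6$ inclusive. The two thresholds (10 vs 9) are kept as two
separate rules rather than reconciled, since nothing in the data decides
whether they reflect one underlying cutoff.

**Direction**: an event is `PSF_enhanced` when
$\overline{\mathrm{PSI}}_{WT\text{-}S} >
\overline{\mathrm{PSI}}_{PSF\text{-}KD\text{-}S}$ (knockdown lowers
inclusion, so PSF promotes it) and `PSF_repressed` otherwise; an exact
zero is left indeterminate.

**TRAP150 antagonism** (`callTrap150Antagonism`): if TRAP150 sequesters
PSF in resting cells, depleting TRAP150 without stimulation should move a
PSF-target exon toward its stimulated value. An event is `antagonistic`
when the resting-cell knockdown shift
($\mathrm{PSI}_{TRAP\text{-}KD\text{-}U} - \mathrm{PSI}_{WT\text{-}U}$)
has the same sign as the stimulation shift
($\mathrm{PSI}_{WT\text{-}S} - \mathrm{PSI}_{WT\text{-}U}$) and magnitude
at least the margin; `same_direction` when the signs oppose; below the
margin the call is `indeterminate`. The default margin of 5 PSI points
matches the assay's replicate standard deviation (at most about 5 points
in the underlying RT-PCR measurements), so shifts below it are not
interpreted.

## The packaged 39-event table and magnitude-only mode

`psfEventFixture()` ships the published set of 39 PSF-dependent
PMA-induced events with integer condition-mean PSI values. Since only
means are printed (no replicate-level values), calls on this table run in
**magnitude-only mode**: the p-value term of each rule is skipped and the
calls are flagged accordingly. On this table the absolute delta-PSI rule
retains all 39 events and the direction labels split 13 enhanced / 26
repressed.

Decomposing the second rule on the integer-rounded means exposes a
rounding artifact worth stating plainly: the stimulation-response filter
retains 39/39, but the 0.6 rescue filter fails two events — SESTD1
($18/34 \approx 0.529$) and NFYA ($13/23 \approx 0.565$). Both events
were published as passing, which is consistent with the original call
having used unrounded means; at the printed integer precision the ratios
fall below 0.6. The package asserts this discrepancy in its tests rather
than hiding it, and the absolute delta-PSI rule (which reproduces 39/39
on the rounded values) is therefore the default criterion in the
pipeline.

```{r fixture}
fx <- psfEventFixture()
calls <- callPsfDependentMethods(fx)
sum(calls$passes_methods_criterion)
table(calls$direction)
res <- callPsfDependentResults(fx)
res$event_id[!res$passes_results_criterion]
```

## The significance test

The published analysis states only "P < 0.05"; the test itself is
unspecified, and whether it was run on replicate PSI values or on counts
is unknowable from the text. The package's declared choice is a
two-sided Welch (unequal-variance) two-sample t test on the replicate
PSI values (`testPsiDifference`), the standard small-sample comparison
for three-versus-three replicates. No arcsine or logit transform is
applied (none is mentioned in the source analysis), and no
multiple-testing correction is applied by default because the published
threshold is a raw p value; `stats::p.adjust` can be applied to the
returned vector by users who want FDR control.

The test is implemented in closed form rather than via `stats::t.test`
so that degenerate inputs are well defined: fewer than two defined
replicates on either side yields `NA` (untestable, flagged); two
constant groups yield p = 1 when equal and p = 0 when not, where
`t.test` would error. On non-degenerate input it agrees with
`stats::t.test(..., var.equal = FALSE)` to machine precision (asserted
in the test suite). Magnitude-only mode exists precisely to isolate the
fixture-based results from this assumption.

## The synthetic-data generator

No sequencing data were deposited for the original screen, so the
generator is the package's substitute ground truth. It emulates the
statistical structure the analysis assumes, not the biochemistry:

* **Probe library** (`makeProbeLibrary`): uniform random junction
  sequences, unique across the library, 40 nt by default (a ligated
  20+20 probe pair — a typical RASL geometry; the published probe
  lengths are not stated, so this is a convention, not a claim).
* **Depth** (`simulateCounts`): per event × sample totals are negative
  binomial with mean `mean_depth` and size `dispersion`
  (`Inf` = Poisson). The count law is not stated in the source either;
  NB is the standard overdispersed model for sequencing counts. The
  default `mean_depth = 300` and `dispersion = 10` represent a
  realistically deep, moderately overdispersed targeted assay.
* **Isoform split**: binomial on the total at the true PSI — the
  measurement model PSI estimation inverts.
* **Reads** (`emitReads`): barcode + junction with iid per-base
  substitutions at `read_error_rate` (default 0) and constant
  placeholder qualities (the analysis never reads them).

What the generator does **not** emulate: oligo-dT selection efficiency,
ligation failure, PCR amplification bias, indels, quality-score
structure, or correlated errors. Passing tests therefore demonstrate
that the pipeline's counting and estimation are correct under the
assay's idealized statistical model — they do not validate robustness to
those real-data artifacts.

Counting (`demultiplexAndCount`) matches barcodes exactly (standard for
short inline barcodes) and junctions by a nearest-match rule with a
unique minimum, one mismatch allowed by default; ties within the budget
are conservatively discarded as unassigned. Raising the mismatch budget
can only gain assigned reads (asserted as a property test).

## Numerical and degenerate-input choices

* PSI is percent (0–100) throughout, matching the published tables.
* A replicate with zero coverage has undefined PSI and is excluded from
  the condition mean, never imputed; the mean's backing replicate count
  is exposed via `replicatesUsed()`.
* The coverage filter ("minimum of 10 reads averaged across all
  replicates and conditions") is read as mean ≥ 10, inclusive.
* All simulation functions are deterministic given their seed; the
  pipeline derives per-stage seeds from one master seed and writes no
  timestamps, so reruns are byte-identical.

## Problem sizes used in the checks

The shipped verification suite exercises: exact pipeline identity
(simulate → emit → demultiplex at zero error) on 200 events × 6 samples
at mean depth 300; estimator recovery within 1 PSI point on 100 events
at Poisson depth 10,000 with 3 replicates (and within 0.5 points at
depth 100,000); null calibration of the Welch test on 1,000 events at 3
vs 3 replicates (rejection fraction in [0.03, 0.07] at α = 0.05); and
the LEF1 / OPA1 events re-simulated at their published inclusion values
through the full read-level pipeline, recovering 88 and 75 after
rounding. These sizes were chosen as the smallest at which the binomial
standard errors make the stated tolerances meaningful.

## Limitations

The package analyses two-isoform cassette events only — the two-junction
ratio cannot represent multi-path splicing. There is no batch
correction, no expression-level modelling beyond the junction ratio, and
the antagonism call uses condition means only (no replicate test), which
is why it carries an explicit indeterminacy margin rather than a p
value.
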