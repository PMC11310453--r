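---
title: "Differential HDX-MS analysis with HDXdelta"
author: "HDXdelta maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS analysis with HDXdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(HDXdelta)
```

## The problem

Bottom-up hydrogen–deuterium exchange mass spectrometry (HDX-MS) measures
the deuterium taken up by backbone amides of proteolytic peptides as a
function of exposure time. Dynamic or solvent-exposed regions exchange
fast; structured or protected regions exchange slowly. A typical
differential experiment compares several *protein states* — apo versus
ligand-bound, wild type versus mutant — each measured over several
exposure times with replicate injections, producing hundreds of peptides
times states times timepoints times replicates. The analysis questions are
always the same: which peptides differ *significantly* in uptake between a
state and the reference, where do those peptides sit on the sequence and
the structure, and how should the dataset be summarised for publication.

HDXdelta covers that post-processing path: it ingests peptide-level
exports of the kind produced by HDExaminer's "all results" tables, aligns
peptides across states, applies a hybrid significance test, computes the
standard summary statistics, and renders the comparison as tables, plots
and PyMOL coloring scripts that all share one color convention.

## Data model

Three S4 containers carry the pipeline:

* `HDXDataSet` — validated long-format records
  (state, sequence, residue span, charge, exposure, replicate, uptake in
  Da, percent deuteration), produced by `readHDExaminer()`. Rows that fail
  numeric parsing or violate the record invariants are skipped and
  counted, never silently altered.
* `MatchedUptake` — the peptides common to *all* states at *all* shared
  exposure times, organised as a peptide × state × timepoint × replicate
  array (`matchPeptides()`). The first state is the comparison reference
  and can be rotated with `reorderReference()`.
* `HDXComparisonSet` — per-peptide, per-timepoint differential statistics
  of every non-reference state against the reference, plus one global
  critical interval per comparison (`compareStates()`).

Matching identity is the peptide's biological identity — sequence plus
1-based inclusive residue span. Charge states of the same peptide
observation are averaged before matching; keeping a "best" charge state
instead would discard replicate information asymmetrically, and averaging
makes the aggregation explicit and testable. Exposure times are
normalised to seconds at parse time ("30s", "5m", "1h" tokens, or bare
numbers interpreted through the dialect's `timeUnit`). Undeuterated
(0 s) rows are retained for uptake plots but excluded from every test.

## The hybrid significance test

A peptide–timepoint cell is called significant for a comparison only if it
passes **both** of:

1. **Welch's t-test** on the replicate uptake values (Daltons) of the two
   states,
   $$t = \frac{\bar{x}_t - \bar{x}_r}{\sqrt{s_r^2/n_r + s_t^2/n_t}},$$
   with Welch–Satterthwaite degrees of freedom and a two-sided p-value,
   requiring $p < \alpha$;
2. **the global critical interval**: $|\Delta D| > CI$, where
   $$CI = t_{1-\alpha/2,\; n_r+n_t-2} \cdot
     \sqrt{s_{p,r}^2/n_r + s_{p,t}^2/n_t}$$
   and $s_{p}$ is, per state, the square root of the mean of the per-cell
   replicate variances over **all** peptides and timepoints of the
   comparison.

The two filters fail in complementary ways: with 2–4 replicates a cell can
reach a small p-value by chance when its variance estimate collapses, but
such cells rarely also exceed a variance threshold pooled over the whole
dataset; conversely a large but noisy difference can exceed the interval
without being statistically stable. The conjunction is therefore
conservative relative to $\alpha$ — on null data the package's own
validation observes flagged fractions far below $\alpha$ — and no
additional multiple-testing correction is applied across peptides; the
dataset-wide interval is the guard against multiplicity. Users who prefer
a per-test guarantee can lower `alpha`.

Choices inside the critical interval that the method description leaves
open, fixed here once:

* per-cell variances enter the pool only when the cell has ≥ 2 replicates
  (a variance needs `n ≥ 2`); if every cell is excluded the computation
  errors rather than guessing;
* under unequal replication the per-state $n$ entering the interval is the
  *minimum* replicate count among pooled cells — the conservative choice
  (smaller $n$ widens the interval);
* the degrees of freedom are the pooled $n_r + n_t - 2$, matching the
  two-sample construction the interval mimics;
* $\alpha = 0.01$ by default, a conservative level common in differential
  HDX practice; it applies to both filters and is user-configurable.
* testing operates on uptake in Daltons; percent deuteration is carried
  through for display only, so the variance pool lives in one physical
  unit. $\Delta D$ is test − reference: positive means more exchange
  (deprotection) in the test state.

When both replicate SDs of a cell are exactly zero the Welch statistic is
undefined; the documented convention is $p = 1$ for equal means and
$p = 0$ otherwise, with a warning. Cells with fewer than two replicates in
either state stay in the results for plotting (`tested = FALSE`) and are
never flagged.

## Summary statistics

`buildSummary()` assembles the per-state publication table: exposure
times, replicate count, peptide count, sequence coverage, mean peptide
length, redundancy, pooled SD, critical interval, and back exchange.
Conventions:

* **Coverage / redundancy** come from per-residue peptide depth;
  redundancy is averaged over *covered* residues only, the convention of
  published HDX summary tables.
* **Back exchange** per peptide is
  $100\,(1 - u_{FD} / (u_{max}\, d))$, with $u_{FD}$ the fully-deuterated
  control uptake, $d$ the buffer deuterium fraction (default 1.0) and
  $u_{max}$ the exchangeable-amide count. The default count is
  $L - 2 - P$ (first two backbone amides fast-exchanging, prolines at
  position ≥ 3 have none); `convention = "L-1-P"` switches to the laxer
  count. Without an FD control the fields are reported as "n.d.", never
  as zero. The FD control is treated as experiment-wide, so the same
  back-exchange summary is reported for every state.
* **Protein length** defaults to the largest observed peptide end; pass
  the real length when termini are uncovered.

## Visualization and structure export

All plot builders consume one `hdxColorScheme()`: blue = significant
protection, red = significant deprotection, grey = not significant, plus
an ordered timepoint palette and a diverging blue–white–red gradient.
Every builder invisibly returns the geometry it drew, which is what the
package's tests assert on.

* `plotVolcano()` — $\Delta D$ vs $-\log_{10} p$ with guides at $\pm CI$
  and $-\log_{10}\alpha$; zero p-values are clipped to the smallest
  positive double before the log.
* `plotWoods()` — per-peptide segments at $\Delta D$ over residue
  coordinates, all-peptides or significant-only, with the $\pm CI$ band.
* `plotRobot()` — the mirrored butterfly variant: residue-number x-axis,
  reference %D up, test %D down, peptide-range bars at the mean %D,
  vertical ±SD bars, and one midpoint dot per timepoint — colored by the
  timepoint palette when that timepoint is significant, grey otherwise.
  Only peptides significant at ≥ 1 timepoint appear. Each dot sits on its
  own timepoint trace; stacking all dots at one height was the obvious
  alternative but hides which timepoint fired.
* `plotSignificantPeptideMap()` — first-fit greedy packing of peptide
  intervals into non-overlapping display rows.
* `plotResidueHeatmap()` on `residueMatrix()` — residue-level projection;
  overlapping peptides are aggregated by *unweighted mean* $\Delta D$
  (shortest-peptide priority was considered and rejected as harder to
  reason about); uncovered residues are `NA`, rendered blank, and never
  conflated with $\Delta D = 0$.
* `pymolScript()` — a self-contained `.pml` script that defines its
  colors, colors the polymer neutral, then colors residues either by
  significance class (consecutive residues merged into minimal
  `resi a-b` runs) or per-residue from the gradient. Scripts color by
  residue rather than by peptide so overlaps resolve deterministically,
  carry no `load` line and no absolute paths, and accept a chain
  restriction and an integer numbering offset.

## The synthetic-data generator

`simulateHDXExport()` exists so every module is testable without any
external download, and doubles as a power-analysis tool. It emulates: a
random protein (natural amino-acid frequencies), a peptide map of random
8–20-residue spans, saturating single-exponential uptake kinetics
$D(t) = u_{max}(1 - e^{-kt})$ with per-peptide rates log-uniform in
$[10^{-4}, 10^{-1}]\,s^{-1}$, uniform back-exchange attenuation, optional
injected uptake shifts per (peptide, state, timepoint), i.i.d. Gaussian
replicate noise (clamped at the physical floor of 0 Da), and an optional
fully-deuterated control state. Defaults mirror a realistic large
campaign — 8 states, 4 timepoints (log-spaced 30 s to 4 h), 4 replicates,
50 peptides on a 250-residue protein, 0.05 Da replicate noise, 15% back
exchange. The seed fully determines the output down to the byte.

It deliberately does **not** emulate: heteroscedastic or correlated
replicate noise, EX1/bimodal exchange, charge-state disagreement,
retention-time drift, missing cells, or carry-over. Passing tests
therefore demonstrate correctness of the statistical machinery under
well-behaved noise, not robustness to every pathology of real exports —
the parser and matcher handle missing and malformed rows, but the power
and type-I figures quoted by the validation are for the idealised model.

## Numerical and validation notes

* Round-trippable outputs: tabular CSVs are written at `%.10g`, so
  re-reading reproduces values exactly at written precision; p-values are
  serialized with ≥ 6 significant digits.
* Determinism: fixed generator seeds give byte-identical exports;
  repeated pipeline runs give byte-identical tables and PyMOL scripts
  (PDF plot files differ only in their embedded creation timestamp).
* Validation sizes: the package validates Welch statistics against an
  independent incomplete-beta tail formulation on 1000 random draws
  (≤ 1e-10 relative on t and df), type-I behaviour on 50 null simulations
  of 200 peptides × 4 timepoints × 3 replicates, and recovery of 1.0 Da
  injections over 20 seeds (sensitivity 1.0; mean $\Delta D$ error within
  $3\sigma_{\bar\Delta}$). These sizes were chosen to make the binomial
  slack on the type-I bound tight while keeping the default test run
  comfortably interactive.
* Degenerate inputs error loudly and specifically: unresolvable headers
  name the missing canonical columns, an empty peptide intersection names
  the least-overlapping state, an unknown reference lists the available
  labels, and a failing pipeline run removes its partial outputs.

## Worked example

```{r example, eval = FALSE}
# simulate a 3-state campaign with one truly shifted peptide
cfg <- hdxSimConfig(nStates = 3, nPeptides = 40, nReplicates = 3,
                    seed = 42,
                    effects = data.frame(peptide = 7, state = 2,
                                         deltaDa = 1.0))
sim <- simulateHDXExport(cfg, path = "export.csv")

ds <- readHDExaminer("export.csv")
mt <- matchPeptides(ds)                  # reference = State1
cs <- compareStates(mt, alpha = 0.01)
significantPeptides(cs)                  # the injected peptide, only

buildSummary(mt, ds)                     # publication summary fields
plotVolcano(cs, "State2")
plotRobot(cs, "State2")
writePymolScript(
  pymolScript(residueMatrix(cs, "State2", timepoint = 30,
                            mode = "significant")[, 1],
              comparison = "State2", timepoint = 30),
  "state2_30s.pml")

# or everything at once:
runPipeline("export.csv", "results_dir")
```

## Limitations

* The critical interval is a single global threshold per comparison; it
  does not adapt to timepoint-specific variance structure.
* Back exchange assumes one FD control shared by all states.
* Percent-deuteration values are taken from the export as-is; the package
  does not re-derive them from the exchangeable-amide count.
* xlsx output is not produced; all tables are CSV.
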