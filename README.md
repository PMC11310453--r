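# HDXdelta

Differential analysis of hydrogen–deuterium exchange mass spectrometry
(HDX-MS) experiments that compare multiple protein states.

Bottom-up HDX-MS reports, per proteolytic peptide, the deuterium taken up
by backbone amides over a series of exposure times. Comparing protein
states (apo vs ligand-bound, wild type vs mutant, …) means matching
hundreds of peptides across states, timepoints and replicates, deciding
which uptake differences are statistically real, and turning the result
into publication tables, plots and structure colorings. HDXdelta does that
post-processing for peptide-level long-format exports of the kind
HDExaminer produces, for any number of states at once — by default every
state is compared to the first (reference) state, and the reference can be
changed freely.

## The statistic at the core

A peptide–timepoint cell is significant for a comparison only if it passes
**both** parts of a hybrid test:

1. **Welch's t-test** on replicate uptake (Da):

   t = (x̄_test − x̄_ref) / √(s²_ref/n_ref + s²_test/n_test),

   with Welch–Satterthwaite degrees of freedom and a two-sided p-value,
   requiring p < α (default α = 0.01);

2. **a global critical interval** on the uptake difference:
   |ΔD| > CI, with

   CI = t(1 − α/2, n_ref + n_test − 2) · √(s²_p,ref/n_ref + s²_p,test/n_test),

   where s_p is, per state, the root-mean of per-cell replicate variances
   pooled over *all* peptides and timepoints of the comparison.

The conjunction is conservative relative to α; no further
multiple-testing correction is applied — the dataset-wide interval is the
guard against multiplicity. Downstream, "significant" peptide sets,
filtered plots (volcano, Woods, robot, residue heatmaps,
significant-peptide maps) and PyMOL scripts all share one color scheme:
blue = protection, red = deprotection, grey = not significant.

## Worked example

The package ships a ground-truth generator, so a full analysis needs no
external data. Simulate a 3-state campaign with one peptide truly shifted
by +1 Da in State2, then analyze it:

```r
library(HDXdelta)

cfg <- hdxSimConfig(nStates = 3, nPeptides = 40, nReplicates = 3, seed = 42,
                    effects = data.frame(peptide = 7, state = 2, deltaDa = 1.0))
sim <- simulateHDXExport(cfg, path = "export.csv")

ds <- readHDExaminer("export.csv")
mt <- matchPeptides(ds)              # reference = State1 (first in file)
cs <- compareStates(mt, alpha = 0.01)
cs
#> HDXComparisonSet: 2 comparisons vs 'State1' at alpha = 0.01
#>   State2: 40 peptides x 4 timepoints, CI = 0.1826 Da, 4 significant cells
#>   State3: 40 peptides x 4 timepoints, CI = 0.1943 Da, 0 significant cells

significantPeptides(cs)
#> $State2
#>        sequence start end
#> 1 MVIMCAIKYACML    13  25
#>
#> $State3
#> [1] sequence start    end
#> <0 rows> (or 0-length row.names)
```

The injected peptide — and only it — is flagged, at all four timepoints of
the State2 comparison (4 significant cells); the null State3 comparison
flags nothing. Each comparison's critical interval (≈0.18–0.19 Da here)
is the minimum |ΔD| a significant peptide must clear in addition to
p < 0.01. The publication summary gives the per-state reporting fields:

```r
buildSummary(mt, ds)
#>    state           timepoints nReplicates nPeptides coveragePct
#> 1 State1 30; 235; 1839; 14400           3        40       88.71
#> 2 State2 30; 235; 1839; 14400           3        40       88.71
#> 3 State3 30; 235; 1839; 14400           3        40       88.71
#>   avgPeptideLength avgRedundancy pooledSdDa criticalIntervalDa
#> 1             14.4         2.618    0.04929                 NA
#> 2             14.4         2.618    0.04787             0.1826
#> 3             14.4         2.618    0.05400             0.1943
#>   avgBackExchangePct backExchangeMinPct backExchangeMaxPct
#> 1              14.98              13.95              16.92
#> 2              14.98              13.95              16.92
#> 3              14.98              13.95              16.92
```

Coverage, redundancy and peptide length describe the peptide map; the
pooled SD is the replicate precision the critical interval is built from;
back exchange (≈15% mean here, matching the simulation's setting) comes
from the fully-deuterated control. One call writes the whole output suite
— matched CSV, per-comparison verbose statistics, summary table, plot set
and PyMOL scripts:

```r
runPipeline("export.csv", "results_dir")
```

or from a shell:

```sh
Rscript inst/scripts/hdxdelta.R analyze --input export.csv --output-dir results_dir
```

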