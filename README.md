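# troqsar

Screening QSAR training sets by the acute-to-chronic toxicity ratio.

## The problem

Single-descriptor QSAR models of aquatic toxicity regress the acute endpoint
log LC50 (mg/L) on hydrophobicity, log K<sub>OW</sub>. That baseline-toxicity
line only describes **narcosis-type** compounds — toxicants acting by
non-specific, accumulation-driven membrane perturbation. Reactive compounds
(covalent or receptor-specific mechanisms) show *excess toxicity* below the
baseline line and degrade the regression when left in the training set.

The **toxicity rank order** (TRO) flags them from toxicity data alone. For a
compound with acute LC50 and chronic NOEC (both mg/L):

```
log TRO = log10(LC50) - log10(NOEC)
```

Narcotic toxicity is persistent with exposure, so acute and chronic endpoints
sit close together; reactive toxicity is not, so the gap is wide. Thresholds
on |log TRO| classify the mode of action (MOA):

| |log TRO| | MOA class |
|---|---|
| [0, 1) | narcosis |
| [1, 3) | transition |
| [3, ∞) | reactive |

The package computes TRO, classifies MOA, screens a compound table down to
the retained classes (narcosis by default, after CAS-keyed deduplication),
fits the line `log LC50 = a + b · log Kow` by ordinary least squares before
and after screening, and reports the R² improvement under both denominator
conventions in circulation: `(R²im − R²in)/R²in × 100` ("as defined") and
`(R²im − R²in)/R²im × 100` ("as reported").

This package is for ecotoxicologists and QSAR modellers curating endpoint
tables before regression: it makes the screening step explicit, flags
suspicious records (NOEC above LC50, missing endpoints, conflicting
log/linear columns, duplicates) instead of dropping them silently, and ships
a synthetic-data generator for power/recovery experiments.

## Worked example

The packaged dataset `organophosphate_esters()` holds 12 literature records
of organophosphate and phthalate esters with log K<sub>OW</sub>, log LC50,
log NOEC, and the log TRO / MOA type reported in the source compilation.

```r
library(troqsar)
fit <- tro_qsar(data = organophosphate_esters())
fit
#> TRO-screened QSAR fit (log LC50 ~ log_kow )
#>   records: 9 retained (NARCOSIS), 3 excluded
#>   unscreened: QSAR line: log LC50 = 2.314 + -0.5198 * log Kow   (n = 11)
#>   R-squared = 0.8231   SDEP = 0.4572 log10 mg/L
#>   screened:   QSAR line: log LC50 = 2.644 + -0.5856 * log Kow   (n = 9)
#>   R-squared = 0.8703   SDEP = 0.4098 log10 mg/L
#>   R-squared 0.8231 -> 0.8703: +5.74% (initial denom) / +5.43% (improved denom)
```

Reading the output: the unscreened fit uses the 11 deduplicated
TRO-computable records; screening removes tripropyl phosphate (transition,
|log TRO| = 1.33) and tricresyl phosphate (reactive by its endpoints,
|log TRO| = 7.31), and the baseline fit tightens from R² 0.823 to 0.870 with
a steeper, less attenuated slope. `summary(fit)` lists the excluded records
with reasons; `plot(fit)` draws both lines over the MOA-colored scatter;
`write_report(fit, "report.json")` serializes everything.

The dataset's reported values contain three discrepancies, which the package
enumerates rather than reproduces silently:

```r
subset(reported_concordance(organophosphate_esters()), !log_tro_match)
#>                   name abbreviation recomputed_log_tro reported_log_tro ...
#> 6  Tripropyl phosphate          TPP               1.33             1.36
#> 7    Diethyl phthalate          DEP               0.31             0.30
#> 11 Tricresyl phosphate          TCP               7.31             0.30
#> 12   Diethyl phthalate          DEP               0.31             0.30
```

Synthetic benchmarking with a known generating line:

```r
rec <- recovery_experiment(synthetic_config(), n_replicates = 200,
                           base_seed = 100)
rec
#> TRO screening recovery over 200 replicates:
#>   screened R2 > unscreened R2 in 100.0% of replicates
#>   mean |slope - true|: screened 0.0233, unscreened 0.0608 (true -0.5)
```

A thin command-line wrapper lives at `exec/troqsar`
(`classify`, `fit`, `compare`, `simulate`, `fixture` subcommands).

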