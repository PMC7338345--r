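# taguchiBiocat

Taguchi orthogonal-array optimization and bioprocess calculators for
enzymatic esterification studies.

## What it is for

Biocatalysis labs optimizing an esterification (e.g. fatty acid ethyl
ester production from free fatty acids and ethanol with an immobilized
lipase) need two kinds of arithmetic done reproducibly:

1. **Design-of-experiments statistics.** Four three-level process factors
   (temperature, time, FFA:alcohol molar ratio, biocatalyst loading)
   screened in a 9-run L9 orthogonal array; per-run larger-is-better
   signal-to-noise ratios
   `S/N = -10 log10( (1/n) Σ 1/y_i² )`
   (= `20 log10(y)` for a single response); a main-effects response table
   with delta ranking; a pooled ANOVA with percent contribution; and the
   additive predicted optimum
   `S/N_pred = mean(S/N) + Σ_j (S/N_j − mean(S/N))`
   with back-transformation to the conversion scale.
2. **Bench calculators.** Titration acidity index
   `AI = MM·M·f·V/m` (mg NaOH/g) and FFA conversion
   `100·(AI_B − AI_S)/AI_B`; p-NPB hydrolytic activity from the 348 nm
   absorbance slope via Beer–Lambert (ε = 5150 /M/cm by default);
   immobilization yield, theoretical and recovered activity; and
   first-order thermal-deactivation half-life `t½ = ln2/k` from a
   log-linear fit.

A synthetic-data module generates run sheets, titrations and decay series
with known ground truth so the whole pipeline is testable without any
laboratory data. A worked L9 esterification experiment (babassu-oil FFAs +
ethanol, *R. miehei* lipase on magnetite nanoparticles) is bundled as
`faee_run_sheet()`.

## Worked example

```r
library(taguchiBiocat)
report <- run_pipeline(faee_run_sheet())
print(report)
```

```
== Per-run S/N (dB) ==
 run Temperature Time Molar ratio Biocatalyst conversion  snr
   1          30    2         1:1           1       14.6 23.3
   ...
   6          40    6         1:1           5       81.7 38.2
   ...
   9          50    6         1:3           1        5.4 14.6

== Response table ==
S/N ratios response (dB)
        Temperature Time Molar ratio Biocatalyst
1              29.8 25.8        33.2        18.2
2              29.7 29.3        27.3        30.5
3              24.3 28.7        23.4        35.1
Delta           5.5  3.5         9.8        16.8
Ranking           3    4           2           1
Grand mean S/N: 27.9 dB over 9 runs

== ANOVA ==
ANOVA of S/N ratios (pooled sources in braces; * p < 0.05 )
      Factor  DF     SS    MS F-value p-value Contribution (%)
 Temperature   2   60.0  30.0     2.9   0.253              8.8
        Time {2} {20.4}     -       -       -              3.0
 Molar ratio   2  147.1  73.5     7.2   0.122             21.6
 Biocatalyst   2  454.9 227.4    22.3 0.043 *             66.7
    Residual   2   20.4  10.2       -       -                -
       Total   8  682.3     -       -       -            100.0

== Predicted optimum ==
Predicted S/N: 43.6 dB at Temperature=L1, Time=L2, Molar ratio=L1, Biocatalyst=L3
Back-transformed response: 151.1  [exceeds 100%: additive-model extrapolation]
```

Reading it: run 6 (40 °C, 6 h, 1:1, 5% biocatalyst) gave the best measured
conversion (81.7%, S/N 38.2 dB). Biocatalyst content dominates — largest
delta (16.8 dB), rank 1, 66.7% contribution, and the only factor
significant at α = 0.05 (p ≈ 0.043). The time factor has the smallest SS
and is pooled into the residual (braces). The additive optimum (30 °C, 4 h,
1:1, 9%) back-transforms above 100% and is flagged: the combined best
levels were never run, so the dB-additive prediction is an extrapolation —
confirm with a validation run, don't report the number as a conversion.

Bench calculators work the same way:

```r
recovered_activity(at_b = 341.3, at_t = 458.0)       # 74.5 (%)
hydrolytic_activity(activity_assay(0.515))           # 5.2 (U/mL)
d <- simulate_decay(k = log(2)/105, times = seq(0, 210, 15),
                    noise_sd = 2, seed = 1)
half_life(d$time, d$activity)                        # t1/2 ≈ 105 min
```

A thin CLI wrapper over the same functions is installed at
`inst/cli/taguchi-biocat.R`
(`Rscript taguchi-biocat.R run --input runs.csv --json out.json`).

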