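# pcipos

**Phase Coordination Index and point-of-stabilization detection for gait
trials.**

`pcipos` is for researchers and clinicians who assess bilateral gait
coordination from heel-strike timing — on treadmills, with wearable
sensors, or in classic gait labs — and need to know **how many strides are
enough** for a reliable estimate. Long trials fatigue elderly and impaired
participants; too-short trials yield unstable coordination values. This
package computes the Phase Coordination Index and detects, for each
individual trial, the stride count from which the estimate stops changing.

## The metric and the detector

Each stride of one leg spans a 360° gait cycle; the contralateral heel
strike ideally falls at a stepping phase of φ = 180°. From heel-strike
times `t_A` (stepping leg) and `t_B` (striding leg),

    φ_i = 360° · (t_Ai − t_Bi) / (t_B(i+1) − t_Bi)

and the Phase Coordination Index combines phase consistency and accuracy:

    PCI [%] = 100 · sd(φ)/mean(φ) + 100 · mean(|φ − 180°|)/180°

Lower PCI = better coordination. The *cumulative* PCI series puts at
position j the PCI of the first j+1 strides; the **point of stabilization
(POS)** is the stride count from which the series stops fluctuating.

Detection works in two stages on size-adapting moving windows: a backward
(right-to-left) search for the first window of K = 15 values whose
coefficient of variation exceeds 0.05 — run both with consecutive windows
and with windows dispersed evenly to the series end — followed by a
recursive zoom inside that window down to two elements. Each window shape
yields a candidate POS and the maximum of the two is reported. On
simulated healthy cohorts the POS averages roughly 20–24 strides, which is
why ~23 strides is a practical trial-length target for healthy adults.

## Worked example

```r
library(pcipos)
set.seed(4)

p <- simulate_participant(simulation_config(), id = "walker01")
p
#> Simulated participant 'walker01': 50 strides, final average PCI 3.474 %

round(as.numeric(p$pci_avg)[1:10], 3)
#>  [1] 2.765 2.981 4.056 4.154 4.006 3.849 3.835 3.787 3.822 3.764

detect_pos(p$pci_avg)
#> POS for 'walker01' (average): 17 strides
#>   consecutive-window option: 17   dispersed-window option: 17
#>   windows tested: 71

error_at_fixed_stride(p$pci_avg, 23, pos = 17)
#>   participant_id pos stride pci_at_ref pci_end       te      ae
#> 1       walker01  17     23      3.242   3.474 -0.06665 0.06665
```

Reading the output: this virtual participant's cumulative average-PCI
series stabilized after **17 strides** (both window options agree, and the
trial stabilized well before its end). Stopping at the cohort-level
reference of 23 strides would estimate PCI as 3.242% against a trial-final
3.474% — a true error of −6.7% (the estimate sits slightly below the final
value), absolute error 6.7%.

The same functions apply to real data: `read_heel_strikes()` ingests
heel-strike CSV/TSV files (long `time_s,leg` or wide `left_s,right_s`
layout), `compute_phase_series()` + `cumulative_pci_series()` build the
series for either phase convention, and `read_pci_table()` ingests
precomputed multi-participant PCI tables (participants in columns,
delimited text or xlsx). `cumulative_cv_series()` extends the detector to
other metrics such as stride-to-stride-time CV. A command-line interface
is installed at `exec/pcipos` inside the package directory, with
subcommands `simulate`, `compute-pci`, `detect-pos`, `evaluate`,
`sweep-k` and `run`.

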