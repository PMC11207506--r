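# qappg — quality-aware PPG processing for long-term heart-rate monitoring

Wrist photoplethysmography (PPG) from wearables is cheap to record but
easily corrupted by motion. The classical answer — run every segment
through a powerful motion-artifact removal algorithm — wastes energy on
the many segments that are already clean, which matters when the battery
has to last for days. `qappg` implements an energy-aware alternative for
people building (or studying) wearable HR pipelines:

1. **Score** each non-overlapping 10 s PPG segment with 14 cheap
   signal-quality indices (SQIs): median, range, SD, excess kurtosis,
   skewness, amplitude-histogram entropy, point PSDs at 1/3/5/7 Hz, band
   powers over 0.01–1 and 1–3 Hz, their ratio, and the SD of the
   magnitude spectrum.
2. **Select** a processing algorithm with a cascade of boosted binary
   classifiers (logistic-loss gradient-boosted trees), one per algorithm
   of a portfolio, evaluated cheapest-first with early exit; if no stage
   accepts, the segment is **discarded**.
3. **Process and estimate**: heart rate is the periodogram argmax inside
   the cardiac band 0.83–2.16 Hz (zero-padded to ≥ 8192 points, i.e. a
   grid finer than 0.75 BPM); a segment is *usable* when its error
   against the ECG reference is ≤ 5 BPM.

The portfolio itself is built from data: every candidate algorithm gets a
binary *outcome vector* (usable / not, per segment); algorithms are
compared by normalised Hamming distance d(u, v) = #{i : uᵢ ≠ vᵢ}/n; after
dropping algorithms whose energy cost exceeds the budget (admissible iff
overhead + cost ≤ budget, overhead 35.536 mJ), a greedy rule starting
from mandatory BYPASS repeatedly adds the candidate with the highest mean
distance to the already-selected set, up to three algorithms.

The candidate pool (per-segment energy in mJ): BYPASS 0, wavelet
filtering (db8 MODWT) 9.73, band-pass 0.5–15 Hz 10.05, low-pass 2.5 Hz
10.28, cubic-spline baseline removal 10.85, high-pass 0.5 Hz 14.57,
SVD-truncated STFT 333.03, EMD detrending 2268.50, singular spectrum
analysis 28767.42. All Butterworth filters are 5th order and applied
forward–backward (zero phase).

Three frameworks are compared under per-segment energy accounting:

* **OFA** (one-for-all): one fixed algorithm for everything; bare
  algorithm energy; rejects nothing.
* **SQA** (quality gating): score with one quality classifier, discard
  the worst 30 %, estimate on raw signal; overhead energy only.
* **QAP** (quality-aware processing): the cascade mechanism; overhead
  plus the selected algorithm's energy.

Because the original 12-subject recordings are not public, the package
ships a seeded synthetic wrist-PPG generator emulating the session
protocol (5 × [2 min static + 1 min typing] = 15 min; PPG 100 Hz, ECG
256 Hz) with clean two-Gaussian pulse waveforms, baseline wander, and
graded typing-burst artifacts. See the methods vignette for what the
generator does and does not emulate.

## Worked example

A desk-scale experiment on a synthetic corpus (6 subjects, 2 protocol
blocks each, 216 segments; portfolio fixed to bypass/BPF/CUB):

```r
library(qappg)
ps  <- protocol_spec(repetitions = 2L)
res <- run_experiment(seed = 1, n_subjects = 6L, ps = ps,
                      tc = training_config(grid = expand.grid(
                        max_depth = 3L, eta = 0.3, nrounds = 100L), seed = 1),
                      portfolio_ids = c("BYPASS", "BPF", "CUB"),
                      ofa_ids = c("BYPASS", "WVL"), calibrate_tol = 0.05)
print(res$comparison, digits = 4)
```

```
                 metric OFA(BYPASS) OFA(WVL)      SQA      QAP
1          accuracy_pct      87.037   88.889 100.0000 100.0000
2               mae_bpm       5.105    4.211   0.1997   0.2006
3           mae_std_bpm      13.320   11.858   0.1492   0.1513
4              rmse_bpm      14.235   12.558   0.2490   0.2510
5 energy_per_segment_mJ       0.000    9.730  35.5360  37.4510
6            reject_pct       0.000    0.000  30.0926  30.0926
```

Reading: processing every segment with a fixed algorithm leaves accuracy
at 87–89 % (errors dominated by typing segments). Both gating frameworks
discard the worst 30 % and reach 100 % on the retained set on this
synthetic corpus; QAP additionally routes 39 segments through BPF and 2
through CUB for 1.9 mJ/segment over the bare SQI overhead — about 0.1 %
of the energy an always-SSA pipeline would burn. The four-group analysis
shows the learned quality gradient (accuracy *without* processing):

```r
print(res$groups, digits = 3)
```

```
  group algorithm_id   n accuracy mae_bpm mae_std_bpm
1     I       BYPASS 110    1.000   0.193       0.147
2    II          BPF  39    1.000   0.210       0.141
3   III          CUB   2    1.000   0.399       0.347
4    IV      DISCARD  65    0.569  16.498      20.183
```

Segments routed to bypass are pristine; discarded segments would have
erred by 16.5 BPM on average had they been kept.

Reading a recording from disk (CSV + JSON sidecar):

```r
rec  <- load_record(system.file("extdata", "example_ppg.csv", package = "qappg"))
segs <- segment_signal(rec)                  # two 10 s segments
estimate_hr_ppg(segs[[1]])$bpm               # 71.77734
```

## Command line

```sh
Rscript -e 'qappg::qappg_cli()' simulate --out corpus/ --seed 1 --subjects 12
Rscript -e 'qappg::qappg_cli()' run --out results/ --seed 1 --subjects 6
```
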