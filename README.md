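# fitfuse

Automatic fitness-activity diarization from wearable sensing nodes that
each record tri-axial acceleration (125 Hz, units of g) and one surface-EMG
channel (2 kHz), worn over the biceps brachii, deltoideus medius and triceps
brachii. Given manually labeled exercise segments, the package recognises
which of four exercises — biceps curl (BC), lateral raise (LR), vertical
raise (VR), isometric biceps hold (IM) — each analysis window contains,
training on some subjects and predicting on held-out subjects.

The package is aimed at researchers in wearable human-activity recognition
who want a complete, testable reference implementation of the two-stage
score-fusion pipeline, including a synthetic cohort generator so every
stage runs without access to laboratory recordings.

## Method

1. **Preprocessing.** Zero-phase low-pass filtering at 0.625 Hz
   (Blackman-Harris windowed sinc; 8192 taps at 125 Hz, 65536 taps at
   2 kHz, group delay compensated exactly). The sEMG is rectified first,
   yielding the mean-absolute-value (MAV) envelope, normalized by its
   whole-recording mean.
2. **Segment-adaptive windowing.** A segment of duration *T*<sub>E</sub> is
   cut into ⌈*T*<sub>E</sub>/*T*<sub>S</sub>⌉ windows of *T*<sub>W</sub> = 8 s whose exact shift
   *T̂*<sub>S</sub> = (*T*<sub>E</sub> − *T*<sub>W</sub>)/(count − 1) stretches the nominal
   *T*<sub>S</sub> = 4 s so whole windows exactly tile the segment.
3. **Features per window.** From acceleration: the rotation vector
   **r** = α (**c**₁ × **c**₂)/‖**c**₁ × **c**₂‖ with
   α = atan2(‖**c**₁ × **c**₂‖, **c**₁ · **c**₂), where **c**₁, **c**₂ are
   the clustered movement-endpoint gravity directions (axis-angle summary
   of the arm swing; zero when the arm is still). From the sEMG envelope:
   the mean *m* and the peak-to-mean ratio *z* = *p*/*m* (≈ 1 for isometric,
   ≈ 2 for burst-like dynamic activation).
4. **Classifier-level fusion.** One classifier per modality (SVM linear /
   polynomial / Gaussian, tree, k-NN or LDA) produces per-class probability
   scores; the concatenated scores (width = 2 × classes) train a
   second-stage classifier that emits the final label.
5. **Evaluation.** Leave-two-subjects-out over all 45 splits of a
   10-subject cohort; confusion matrices are summed across splits and the
   averaged matrix (sum ÷ 9) has row sums equal to the dataset's per-class
   window counts. Reports give mean/min/max accuracy.

## Worked example

```r
library(fitfuse)

# a small synthetic cohort: 5 subjects, 1 set of each exercise, 30 s sets
filters <- list(accel = fir_spec(801, 0.625, 125),
                emg   = fir_spec(4001, 0.625, 2000))
feats <- simulate_features(n_subjects = 5, sets_per_class = 1,
                           set_duration_s = 30, seed = 42, filters = filters)
head(feats[, c("subject", "label", "window_start_s", "r2x", "z1", "m2")], 3)
#>   subject label window_start_s r2x       z1        m2
#> 1     s01    BC       6.000000   0 1.824168 0.5304959
#> 2     s01    BC       9.142857   0 1.803816 0.5299090
#> 3     s01    BC      12.285714   0 1.773392 0.5329903

fused <- run_evaluation(feats, classifier_spec("svml"), classifier_spec("svml"),
                        classifier_spec("lda"), test_count = 1)
fused
#> <eval_report> fusion svm_linear+svm_linear/lda | 5 split(s), 0 skipped
#>   accuracy: mean 100.0%, min 100.0%, max 100.0%
#>   averaged confusion (rows = true):
#>     predicted
#> true BC LR VR IM
#>   BC 40  0  0  0
#>   LR  0 40  0  0
#>   VR  0  0 40  0
#>   IM  0  0  0 40

acc_only <- single_modality_baseline(feats, "acc", classifier_spec("svml"),
                                     test_count = 1)
emg_only <- single_modality_baseline(feats, "emg", classifier_spec("svml"),
                                     test_count = 1)
sprintf("no fusion: acc %.1f%%, emg %.1f%%",
        100 * acc_only$mean_accuracy, 100 * emg_only$mean_accuracy)
#> [1] "no fusion: acc 75.0%, emg 60.6%"
```

The biceps-curl windows show `r2x = 0` (still upper arm — the deltoid-node
rotation vector vanishes) with `z1 ≈ 1.8` (bursty biceps activation), the
signature that motivates fusing the two modalities: acceleration alone
leaves BC/IM confused (75% here), the envelope alone struggles elsewhere,
and the fused system separates all four classes on every held-out subject.

A command-line front end with `simulate`, `extract-features`, `train`,
`evaluate` and `diarize` subcommands is installed at
`inst/scripts/fitfuse` (see `--help`-style usage in the file header).

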