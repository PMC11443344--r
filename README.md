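# fluorChill

Grading and classification of chilling (cold-stress) injury in leaves from
chlorophyll fluorescence images.

Chlorophyll fluorescence imaging maps photosystem-II activity across a leaf
and reveals low-temperature damage before any visible symptom: injured
tissue fluoresces less. On instrument pseudo-color renderings, healthy
tomato leaf tissue appears red, chilling-damaged tissue yellow-green and
the background black. `fluorChill` implements the full analysis chain for
such images, aimed at plant-stress phenotyping work:

1. **Injury grading.** Leaf and injured regions are segmented by HSV
   thresholding and the injury ratio is computed as

   `Lk = A1 / A = N1 / N`

   (injured pixels over leaf pixels). Grades follow the four-level
   convention: A "sound" (`Lk < 5%`), B "slight" (`5–15%`), C "moderate"
   (`15–30%`), D "severe" (`Lk ≥ 30%`).

2. **Feature extraction.** 36 features per image: nine color descriptors
   (mean R, G, B; H, S, V; CIELAB L, a, b over the leaf) and their nine
   ratios; four gray-histogram statistics (mean, standard deviation, third
   moment, smoothness); six gray-gradient co-occurrence matrix (GGCM)
   features (low/high-gradient advantage `T1 = Σ_i Σ_{j≤T} H(i,j)/H`,
   `T2 = Σ_i Σ_{j>T} j²H(i,j)/H`, gray/gradient distribution
   non-uniformity, mean gradient, gradient standard deviation); and eight
   gray-level co-occurrence matrix (GLCM) features (energy `ΣΣQ²`,
   entropy `−ΣΣQ log Q`, inertia `ΣΣ(i−j)²Q`, correlation, each as
   mean and standard deviation over the 0°/45°/90°/135° directions).

3. **Feature screening.** Tie-corrected Spearman rank correlation
   (`Rs = 1 − 6Σd²/(n³−n)` for untied data) between each feature and the
   grade level; features with `|Rs| ≥ 0.8` ("very strong") become the
   classifier input — canonically the nine gray-image features.

4. **Classification.** A bidirectional LSTM reads the screened features as
   a scalar sequence, concatenates the two directions' final hidden states
   and classifies into the four grades. Its learning rate, hidden size and
   L2 coefficient are tuned by the dung beetle optimizer (DBO), a
   population metaheuristic with roller, brood-ball and forager update
   rules on a shrinking region `R = 1 − t/Tmax`.

5. **Evaluation.** 4×4 actual-vs-predicted confusion matrices with
   per-class and macro-averaged precision, recall and F1 (percent).

Because fluorescence image sets of this kind are rarely deposited, the
package ships a seeded synthetic-image generator (`makeLeafImage()`,
`makeLeafDataset()`) that emulates the pseudo-color convention with exact
ground-truth masks, so every stage is testable end to end.

## Worked example

```r
library(fluorChill)

img <- makeLeafImage(seed = 7, target_lk = 0.35)
img
#> FluorescenceImage 'leaf_s7': 96 x 96
#>   truth: lk = 0.3500, grade = D (2306 leaf px, 807 injured px)

leaf <- segmentLeaf(img)
injuryRatio(segmentInjury(img, leaf), leaf)
#> Injury measurement: 807 / 2306 leaf px, Lk = 0.3500, grade D (level 4)
```

The generator asked for a 35% injured area; segmentation recovers exactly
the 807 injured of 2306 leaf pixels, and `Lk = 0.35 ≥ 0.30` grades the
leaf D (severe). Evaluating a test-set confusion matrix (here, the one a
DBO-tuned BiLSTM produced on a 44-leaf test split of 10/12/12/10 per
grade):

```r
cm <- matrix(c(10, 0, 0, 0,
                0, 10, 2, 0,
                0, 0, 12, 0,
                0, 0, 0, 10), 4, 4, byrow = TRUE)
metricReport(cm)
#> Metric report
#>       predicted
#> actual  A  B  C  D
#>      A 10  0  0  0
#>      B  0 10  2  0
#>      C  0  0 12  0
#>      D  0  0  0 10
#> accuracy 95.45 | macro precision 96.43 | recall 95.83 | F1 95.80
```

42 of 44 leaves are correct (accuracy 95.45%); the macro metrics are the
unweighted means of the per-class one-vs-rest values. The full workflow —
generate, grade, extract, screen, tune, train, evaluate — is one call:
`runPipeline(pipelineConfig(seed = 1))`, or `inst/scripts/fluorchill
pipeline --seed 1 --out results/` from a shell.

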