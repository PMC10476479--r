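# maxentseg

Maximum-entropy multilevel thresholding for 2D grayscale images, aimed at
CT-style liver/lesion scenes where tissue classes occupy distinct (but
noisy) intensity bands.

Threshold segmentation reduces an image to its gray-level histogram
`q = (q_0, ..., q_{Z-1})` and picks a sorted vector of integer cuts
`u_1 < ... < u_m` that splits the gray range into `m + 1` classes.
`maxentseg` selects the cuts by the classical maximum-entropy (Kapur)
criterion: each class contributes the Shannon entropy of its renormalized
sub-histogram,

```
J_i = - Σ_{u_i ≤ o < u_{i+1}}  (q_o / e_i) log (q_o / e_i),    e_i = Σ q_o over the class,
u*  = argmax_u  Σ_{i=0}^{m}  J_i(u),
```

with `0·log 0 = 0` and any vector inducing an empty class ruled
infeasible.  Two maximizers are provided:

* `exhaustive_search()` — exact enumeration of all feasible vectors
  (prefix-sum evaluation, lexicographic tie-breaking); the oracle that
  anchors the test suite.
* `population_search()` — a seeded, fully reproducible integer-coded
  genetic algorithm (elitist mu+lambda selection, blend/exchange
  crossover, local-step + boundary-reset mutation, steepest-ascent polish,
  stagnation restarts) for gray ranges where enumeration is too expensive.

Around the core sit a synthetic abdominal-CT-like phantom generator with
exact ground truth (`generate_phantom()`), segmentation evaluation with
Dice/Jaccard/confusion/threshold-recovery metrics
(`evaluate_segmentation()`), PNG/TIFF/NIfTI image I/O, and a CLI pipeline
with reproducibility manifests.

## Worked example

Generate the built-in three-class liver phantom (background mean 40,
liver 120, tumor 200, Gaussian noise sd 10), segment it with two
thresholds, and score the result against the exact ground truth:

```r
library(maxentseg)

ph  <- generate_phantom(phantom_preset("liver3"), seed = 1)
ph$image
#> <gray_image> 256 x 256, Z = 256, range [0, 230]

seg <- segment(ph$image, m = 2, method = "exhaustive")
seg$result
#> <search_result:exhaustive> u* = (57, 141), J = 16.408701 (base 2), 32385 evaluations

evaluate_segmentation(seg$labels, ph$truth,
                      reference_cuts = c(80L, 160L), pred_cuts = seg$thresholds)
#> <eval_report>
#>   accuracy: 0.9593
#>   dice:     0.9748 0.9245 0.9095
#>   jaccard:  0.9509 0.8596 0.8340
#>   |cut error|: 23 19
```

The optimal cuts (57, 141) lie strictly between the class means but *not*
at the midpoints (80, 160): the entropy criterion places a cut about
1.7 noise standard deviations above the mean of the larger, darker class.
Background is recovered at Dice 0.97; the leak of background/liver tail
pixels into the smaller classes above them caps liver and tumor Dice near
0.92 — an inherent property of the criterion on strongly unbalanced
scenes, discussed in the methods vignette
(`vignettes/maxent-thresholding.Rmd`).

The genetic search reproduces the exhaustive optimum from a tiny fraction
of the evaluations, deterministically for a fixed seed:

```r
h <- compute_histogram(ph$image)
population_search(h, search_config(m = 2, seed = 42))
#> <search_result:population> u* = (57, 141), J = 16.408701 (base 2), 1388 evaluations
```

## Command line

A thin launcher is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "maxentseg.R", package = "maxentseg"))')
Rscript $CLI phantom  --preset liver3 --seed 1 --out-dir out/ph
Rscript $CLI segment  --input out/ph/phantom.png --m 2 --method exhaustive --out-dir out/seg
Rscript $CLI evaluate --pred out/seg/labels.png --truth out/ph/truth.png \
                      --n-classes 3 --out out/eval.json
Rscript $CLI landscape --input out/ph/phantom.png --m 1 --out out/landscape.csv
```

Every verb writes a `manifest.json` (resolved parameters, seed, input
digests, RNG contract) sufficient to re-run it exactly.  Exit codes:
0 success, 2 bad flags or malformed input, 3 infeasible segmentation
(e.g. a constant image).

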