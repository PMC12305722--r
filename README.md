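# gimbalScan

Simulated gimbal-gantry ultrasound scanning and optimal tumor-slice search,
in R.

## The problem

In ex vivo pathology workflows, a motorized gantry can carry an ultrasound
probe over an excised tissue block, acquire B-mode slices from many poses,
and hand the pathologist the slice most likely to contain the tumor.  A
purely *linear* gantry slides the probe along one rail and images a fixed
vertical slab: a tumor displaced laterally from the scan line is simply
never imaged.  Adding a two-servo *gimbal* (pitch and roll) lets tilted
planes reach off-axis tissue, at the cost of a much larger pose space that
must be searched efficiently.

`gimbalScan` is a complete desk-scale simulation of that system, for people
who want to study, test or extend the scan-search procedure without
hardware: a digital breast-phantom generator with ground-truth lesion
labels, a B-mode slice synthesizer, a stepper/servo motion model, a
tumor-presence scorer with saliency validation, and the two-level search
itself, validated against an exhaustive-search oracle.

## The search procedure

The probe pose is $(x, \theta, \phi)$: rail position, pitch, roll.  The
search runs in rounds:

- **Stations.** Round 1 visits `nstep` stations spaced `slin0` mm apart.
  At each station the zero-angle slice is scored (`lprob`), then a zigzag
  **angular sweep** visits every pose $(\theta, \phi) = (\alpha i, \alpha j)$
  for $i, j \in \{-s_\theta, \dots, s_\theta\}$ in a serpentine order whose
  every move is a single $\alpha$-step of a single servo; the sweep's best
  score is `aprob`.  The station keeps the zero-angle pose when
  `lprob >= aprob`, otherwise the sweep's argmax $(\theta_{pos}, \phi_{pos})$.
- **Refinement.** Each later round divides the linear step by
  `refine_factor` and re-scans a window of half-width equal to the previous
  step, centered on the incumbent best $x$; rounds continue while the step
  is at least $\epsilon$.  The result is the best pose $L_{max}$ and its
  probability $P_{max}$.

Slices are scored by a deterministic surrogate for a trained classifier:
$p = a / (a + a_0)$ where $a$ is the lesion area fraction of the slice and
$a_0$ the half-saturation fraction.  Saliency (which image regions drive
the score) is computed model-agnostically by patch occlusion and validated
against the ground-truth mask with Dice and IoU.

## Worked example

```r
library(gimbalScan)

fx  <- makeFixture("two_tumor", seed = 1)   # tumor 1 on the scan line, tumor 2 offset 40 mm
cmp <- compareLinearAngular(fx$scan, fx$geometry, fx$phantom, fx$scorer,
                            seed = 1, imaging = fx$imaging, halfSat = fx$halfSat)
cmp$table
#>   lesion    mode    maxArea probability detected
#> 1      1  linear 0.03978495   0.6654676     TRUE
#> 2      2  linear 0.00000000   0.0000000    FALSE
#> 3      1 angular 0.04671858   0.7002334     TRUE
#> 4      2 angular 0.04362801   0.6856730     TRUE

cmp$angular
#> ScanResult (angular mode)
#>   evaluations: 3050 over 3 rounds
#>   Pmax = 0.8115 at ProbePose: x = 75.000 mm, pitch = -4.00 deg, roll = -20.00 deg
```

The table is the package's core qualitative result: under the linear-only
gantry the off-axis tumor is never imaged (probability exactly 0); the
angular gantry detects both tumors, and its best slice — a rolled plane that
catches both lesions at once — scores higher than any straight-down slice.

A full run (`runExperiment(defaultRunConfig())`) additionally writes the
winning B-mode slice and mask as PNG, the occlusion-saliency map and its
Dice/IoU against ground truth, per-mode coverage maps as NIfTI, the
evaluation trace as CSV, and a JSON report.  A thin command-line front end
is installed at `inst/scripts/gimbalscan`
(`gimbalscan scan-compare --config cfg.yaml --out out/`).

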