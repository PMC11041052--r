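# PCLseg

Automated detection of pancreatic cystic lesions (PCLs) on abdominal CT.
PCLs are frequent, under-reported incidental findings that can precede
pancreatic cancer; detecting them reliably on routine CT is a
needle-in-a-haystack segmentation problem. PCLseg implements a complete,
tested detection pipeline in R:

* **Preprocessing** — soft-tissue Hounsfield windowing (50 ± 100 HU →
  [0, 1]) and central in-plane cropping (512 × 512 → 240 × 240 at
  clinical resolution) around the expected pancreas position.
* **Segmentation** — a 2D/3D attention-gated U-Net
  (background / pancreas / cyst). Skip connections pass through additive
  attention gates `α = σ(ψ ReLU(Wₓx + W_g g + b))`, `output = α ⊙ x`,
  with the gating signal `g` taken from the coarser decoder stage.
  Forward pass, backpropagation, Kaiming initialization, Adam and the
  plateau learning-rate schedule are implemented in the package itself
  on small C++ (RcppArmadillo) kernels — no deep-learning framework is
  used.
* **Training** — multiclass soft-Dice loss
  `1 − mean_c (2Σp_c y_c + ε)/(Σp_c + Σy_c + ε)`, Adam, random patch
  sampling with class-balanced foreground anchoring.
* **Inference** — sliding-window patch inference with test-time
  augmentation: rotations of +7° and −11°, in-plane translations of +5
  and +10 voxels; per-class scores are inverse-transformed, averaged,
  then softmaxed and argmaxed.
* **Postprocessing** — three false-positive filters in order: eroded
  abdomen mask, pancreas-contact requirement, and a 10-voxel minimum
  cyst component size.
* **Evaluation** — study-level sensitivity/specificity (a case counts as
  detected when a surviving predicted cyst component overlaps the true
  cyst mask), stratified by cyst risk group, plus per-class voxel Dice.

A synthetic abdominal phantom generator (superellipse abdomen, fat ring,
bone, pancreas ellipsoid, near-water cysts seeded on the pancreas
boundary, Gaussian noise) makes the whole pipeline testable end to end
without any clinical data.

## Worked example

Desk-scale end-to-end run: 30 cyst cases + 12 controls, split 2:1 into
training and held-out studies, a 2-scale/8-channel 3D network trained
500 steps on 32³ patches, TTA inference and full postprocessing on the
14 held-out studies:

```r
library(PCLseg)

cohort <- generateCohort(30, 12, phantomSpec(), seed = 101,
                         trainFraction = 2/3)
tcfg <- trainConfig(epochs = 50, stepsPerEpoch = 10, batchSize = 2,
                    lrInitial = 1e-3, patchInplane = 32, patchDepth = 32,
                    seed = 202)
acfg <- agnetConfig(nScales = 2, baseChannels = 8)
preCfg <- preprocessConfig(cropSize = 64)
fit <- trainAGNet(cohort, acfg, tcfg, preCfg)

pipeCfg <- pipelineConfig(preprocess = preCfg, agnet = acfg, train = tcfg,
                          tta = TRUE, patchSize = c(32, 32, 32),
                          stride = c(16, 16, 32), seed = 1)
testSet <- Filter(function(r) r@split == "test", cohort)
outcomes <- lapply(testSet, function(r) {
  seg <- segmentVolume(r@ct, fit$model, pipeCfg)
  classifyStudy(seg$pred, r@labels, isCase = isCase(r),
                studyId = studyId(r), riskGroup = riskGroup(r))
})
cohortMetrics(outcomes)
#> Cohort metrics: sensitivity 1.000, specificity 1.000
#>   low-risk sensitivity 1.000
#>   high-risk sensitivity 1.000
#>   mean Dice: pancreas 0.969, cyst 0.925
```

Every held-out case is detected (all 10 TP: each surviving predicted
cyst component overlaps the true cyst), no control produces a surviving
false-positive cyst (4 TN), and the voxel-level Dice columns summarise
segmentation quality. The whole run takes under ten minutes on one CPU
core.

Batch processing from files works through a cohort manifest:

```r
manifest <- writeCohort(cohort, "cohort_dir")   # NIfTI pairs + manifest.csv
runPipeline(manifest, pipeCfg, fit$model, "out_dir", split = "test")
```

which writes per-study prediction NIfTIs, `metrics.json`, the resolved
configuration, and a component report per study. A thin command-line
front end with `make-phantoms` / `train` / `infer` / `postprocess` /
`evaluate` / `run` subcommands ships in `inst/cli/pclseg.R`.

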