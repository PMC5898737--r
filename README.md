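# fetseg

Fully automated lesion **detection and segmentation of 18F-FET PET brain
volumes** with a 3-level volumetric U-Net, implemented end-to-end in R
(with C++ kernels for the network primitives — no external deep-learning
framework is required).

O-(2-[18F]fluoroethyl)-L-tyrosine (FET) is an amino-acid PET tracer with
low normal-brain uptake, used to image gliomas at high contrast.
Delineating the biological tumor volume (BTV) on FET-PET matters for
biopsy targeting, radiotherapy planning and response assessment, but
manual delineation is slow and observer-dependent. `fetseg` implements a
two-step automated procedure for users who study such pipelines:

1. **Detection.** A 3-level 3D U-Net (two 3×3×3 convolutions + ReLU per
   resolution block, 2×2×2 max-pooling, channels doubling from 16,
   nearest-neighbour upsampling with channel-halving up-convolutions,
   skip concatenations, and a single-channel sigmoid 1×1×1 head —
   387,889 trainable parameters over 11 convolution layers) is trained
   with Adam (lr 10⁻⁴, batch 5) on minus the soft Dice coefficient
   −(2Σpt + s)/(Σp + Σt + s).
2. **Segmentation.** The predicted mask P is refined as
   dilate(P) ∩ {I ≥ 1.3 · mean(I over mirror(P))}: a 3×3×3 cube dilation
   intersected with an adaptive threshold at 1.3× the activity under the
   *hemispheric swap* of P — the same 1.3×-background rule used to build
   the reference segmentation from a 10 cm³ contralateral spherical VOI.

Evaluation covers the Dice similarity coefficient
DSC(P,T) = 2|P∩T|/(|P|+|T|), voxel-level Se/Sp/PPV/NPV with 95% Wald
intervals, and lesion-level detection via 26-connected components.

Because no patient data ship with the package, a **dynamic PET brain
phantom simulator** (`phantomSpec`/`generateCohort`) produces synthetic
subjects — ellipsoidal brain background with venous-sinus and
peri-orbital hot structures, one heterogeneous lesion at 2–4× background
per subject, 10 × 5-min frames, 5 mm FWHM Gaussian PSF, additive noise —
with known lesion masks, so the whole pipeline runs and is tested
without external inputs. See the methods vignette
(`vignettes/fetseg-methods.Rmd`) for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(fetseg)

# one synthetic dynamic subject on the MNI-like 2 mm grid
s <- generateSubject(phantomSpec(), seed = 7)
s
#> PhantomSubject (seed 7): lesion on right side, 7870 lesion voxels

# semi-automatic reference segmentation: 10 cm3 contralateral VOI,
# threshold at 1.3 x background on the 20-40 min summation image
gt <- groundTruthSegment(s)
gt$backgroundMean
#> [1] 4.003249
dsc(gt$mask, s@truthLesion)
#> [1] 0.9170807
```

The background mean sits at ≈4× the phantom's unit background because
the summation image pools four 5-minute frames. The reference BTV
overlaps the simulated lesion support at Dice 0.92 — they differ at the
blurred rim, by construction.

A complete scaled experiment (20 phantoms, 14 train / 6 validation,
32×32×24 network space, 30 epochs):

```r
cfg <- pipelineConfig(nSubjects = 20, seed = 11,
                      preprocess = preprocessConfig(targetShape = c(32, 32, 24)),
                      augment = NULL,
                      train = trainConfig(maxEpochs = 30))
res <- runExperiment(cfg, verbose = TRUE)
res
#> Experiment (seed 11): 20 subjects, 14 train / 6 validation
#>   mean validation Dice: 0.7898 (U-Net) -> 0.9485 (refined)
#>   detection: 6/6 lesions, 0 false-positive components
#>   voxel level: Se 0.956 Sp 1.000 PPV 0.969 NPV 1.000
```

The two printed Dice values are the validation mean before and after the
dilation + adaptive-threshold refinement; the refinement recovers rim
voxels the network misses, so it should not decrease the mean. The
voxel-level block pools the confusion counts over all validation
subjects. On a single CPU this run takes roughly ten minutes.

`runExperiment(cfg)` with `outDir` set writes `report.csv` (one row per
validation subject: Dice before/after refinement, detection flag,
false-positive components, TP/FP/FN/TN), `history.csv` (per-epoch
training/validation loss and Dice), `manifest.json` (all configurations,
seeds and the parameter count) and the model checkpoint — all
reproducible byte-for-byte for a fixed seed.

A thin command-line front-end with `simulate | groundtruth | predict |
refine | evaluate | run` subcommands is installed at
`inst/exec/fetseg`.

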