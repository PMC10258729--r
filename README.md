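# swirprobe

Forward modeling and neural-network inversion for a wearable
multi-distance shortwave-infrared (SWIR) diffuse optical probe that
quantifies **water and lipid volume fractions** in turbid media —
tissue, emulsion phantoms, Intralipid suspensions.

In the SWIR band (here 980, 1200, 1300 nm) water and lipid are the
dominant absorbers, and a continuous-wave probe with a few
source–detector separations (7, 10, 13, 16 mm) measures a 12-channel
diffuse reflectance vector that encodes their concentrations. The
package is aimed at biomedical-optics researchers who want to simulate,
calibrate, or invert such measurements without device firmware or GPU
Monte Carlo.

## What it implements

* **White Monte Carlo photon transport** in a homogeneous slab
  (`runWhiteMC()`): random walk at zero absorption with
  Henyey–Greenstein scattering (g = 0.7), Fresnel boundary for the
  index mismatch (n = 1.435 emulsions / 1.33 dilute suspensions), and
  post-hoc Beer–Lambert absorption rescaling of recorded path lengths
  (`rescaleAbsorption()`). Validated against the closed-form
  extrapolated-boundary diffusion solution (`diffusionRd()`).
* **Reflectance look-up tables** (`buildLUT()`, `lutLookup()`) over
  μs′ ∈ [0.2, 10] mm⁻¹ and μa ∈ [0.001, 0.2] mm⁻¹ per separation.
* **Spectrally constrained sample synthesis** (`makeDataset()`):
  Beer's-law absorption over a shipped chromophore table
  (water, lipid, D2O = water/10), power-law scattering
  μs′(λ) = A (λ/980)^(−b) with A ~ U(0.2, 10), b ~ N(1.29, 0.52),
  and 5 % relative Gaussian noise. Datasets are
  `SummarizedExperiment` objects.
* **A compact MLP inverse model** (`trainInverseModel()`,
  `predictFractions()`): 12–20–20–20–2 ReLU network on log-normalized
  reflectance, Adam (lr 0.001), 200-epoch-window early stopping,
  trained on fraction-scaled labels and reporting percent.
* **A measurement pipeline** (`correctFrames()`, `buildCalibration()`,
  `toReflectance()`, `snrDB()`, `driftRate()`) that turns raw probe
  voltage frames (gain, dark, drift) into calibrated reflectance and
  instrument metrics.
* **Experiment drivers**: `runWavelengthComparison()` (SWIR vs
  first-window NIR recovery under one protocol),
  `runEmulsionRecovery()` and `runD2ODilution()` (synthetic end-to-end
  stand-ins for five-phantom emulsion and ten-step heavy-water
  dilution studies).

A thin command-line wrapper lives at `inst/cli/swirprobe.R`
(`build-lut`, `make-data`, `train`, `compare-swir-nir`, `emulsion`,
`d2o`, `snr`, `drift`).

## Worked example

```r
library(swirprobe)

# forward model: a small LUT (seconds); use nPhotons = 2e5 for production
lut <- buildLUT(swirGeometry(), nPhotons = 3e4, seed = 1)
tab <- defaultChromophoreTable()

# synthesize training/test data: water + lipid = 100 %, random scattering
cfg   <- generatorConfig("sum100", noiseSigma = 0.05)
train <- makeDataset(8000, cfg, swirGeometry(), lut, tab, seed = 2)
test  <- makeDataset(4000, cfg, swirGeometry(), lut, tab, seed = 3)

model <- trainInverseModel(train, epochs = 300, seed = 4)
evaluateRecovery(model, test)
#> RecoveryReport over 4000 samples (estimated - true, %):
#>   water   -0.54 % +/-  1.57 %
#>   lipid   +0.46 % +/-  1.56 %
```

The report says the network recovers the water fraction of unseen noisy
samples with essentially no bias and a ~1.5 % spread at this reduced
scale; at the reference scale (2×10⁵-photon LUT, 30k training samples,
1500 epochs) the spread tightens to ~1.2 %, against ~1.9 % for the same
protocol on the NIR wavelength set (900/930/970 nm) — the quantitative
form of the SWIR band's advantage for water/lipid sensing.

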