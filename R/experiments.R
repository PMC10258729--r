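#' Fixture scattering laws for the phantom experiments
#'
#' `emulsionScatteringLaw()` matches the reduced scattering of dense
#' (>= 65 percent lipid) water-in-oil emulsions, whose scattering is
#' nearly saturated by dependent scattering: 8.9 mm^-1 at 980 nm falling
#' to 4.8 mm^-1 at 1300 nm. `intralipidScatteringLaw()` matches a 1
#' percent Intralipid suspension: 0.78 mm^-1 at 980 nm falling to 0.49
#' mm^-1 at 1300 nm. Both are power laws through the end points of the
#' respective literature ranges.
#'
#' @return A [ScatteringPowerLaw-class].
#' @export
emulsionScatteringLaw <- function()
  ScatteringPowerLaw(amplitude = 8.9,
    slope = log(8.9 / 4.8) / log(1300 / 980))

#' @rdname emulsionScatteringLaw
#' @export
intralipidScatteringLaw <- function()
  ScatteringPowerLaw(amplitude = 0.78,
    slope = log(0.78 / 0.49) / log(1300 / 980))

.phantomOptics <- function(water, lipid, d2o, law, geometry, table) {
  wl <- geometry@wavelengths
  list(
    mua = drop(.muaMatrix(table, wl, water, lipid, d2o)),
    musp = scatteringAt(law, wl))
}

#' Compare water/lipid recovery between SWIR and NIR wavelength sets
#'
#' Runs the full simulation study under one protocol for both wavelength
#' sets: draw sum-to-100 water/lipid compositions with power-law
#' scattering, forward-model through the Monte Carlo LUT, add relative
#' Gaussian noise, train one inverse network per wavelength set, and
#' evaluate recovery errors on an independently seeded noise-added test
#' set. The two runs share seeds and hyperparameters and differ only in
#' the wavelength set, so the comparison isolates the information content
#' of the spectral bands.
#'
#' @param lut A [ReflectanceLUT-class] with the probe separations (the
#'   same LUT serves both wavelength sets: reflectance depends on optical
#'   properties, not wavelength).
#' @param table A [ChromophoreTable-class] covering both wavelength sets.
#' @param nTrain,nTest Training and test set sizes.
#' @param noiseSigma Relative noise SD (default 0.05).
#' @param epochs Maximum training epochs.
#' @param trainOnNoise Train on noise-added data (`TRUE`, default) or on
#'   noiseless data.
#' @param seed Master seed; all dataset and training seeds derive from it.
#' @param ... Further arguments passed to [trainInverseModel()].
#' @return A list of class `"WavelengthComparison"` with elements `swir`
#'   and `nir` (each a list with the `model`, its `report` from
#'   [evaluateRecovery()], and the test `scatter` data of true vs
#'   recovered values), plus the shared `config`.
#' @export
runWavelengthComparison <- function(lut, table, nTrain = 75000,
    nTest = 25000, noiseSigma = 0.05, epochs = 3000,
    trainOnNoise = TRUE, seed = 1, ...) {
  config <- generatorConfig("sum100", noiseSigma = noiseSigma)
  arm <- function(geometry, armSeed) {
    train <- makeDataset(nTrain, config, geometry, lut, table,
      seed = armSeed)
    test <- makeDataset(nTest, config, geometry, lut, table,
      seed = armSeed + 1L)
    model <- trainInverseModel(train, epochs = epochs,
      assay = if (trainOnNoise) "reflectance" else "noiseless",
      seed = armSeed + 2L, ...)
    report <- evaluateRecovery(model, test)
    truth <- compositions(test)
    pred <- predictFractions(model, test)
    list(model = model, report = report,
      scatter = data.frame(trueWater = truth$water,
        recoveredWater = pred[, "water"], trueLipid = truth$lipid,
        recoveredLipid = pred[, "lipid"]))
  }
  out <- list(swir = arm(swirGeometry(), seed),
    nir = arm(nirGeometry(), seed + 10L),
    config = list(nTrain = nTrain, nTest = nTest,
      noiseSigma = noiseSigma, epochs = epochs,
      trainOnNoise = trainOnNoise, seed = seed))
  class(out) <- "WavelengthComparison"
  out
}

#' @export
print.WavelengthComparison <- function(x, ...) {
  cat("SWIR vs NIR recovery comparison (", x$config$nTrain, "train /",
    x$config$nTest, "test, noise", 100 * x$config$noiseSigma, "%)\n")
  cat("SWIR: "); print(x$swir$report)
  cat("NIR:  "); print(x$nir$report)
  invisible(x)
}

#' Synthetic emulsion-phantom recovery experiment
#'
#' End-to-end stand-in for the five-phantom water-in-oil emulsion study:
#' phantoms at 65-85 percent lipid (steps of 5, water filling to 100)
#' share the dense-emulsion scattering fixture; their true reflectance is
#' forward-modeled, fabricated into voltage frames
#' ([simulateVoltageFrames()]), calibrated against the 85 percent lipid
#' phantom, converted back to reflectance and inverted with a 9-channel
#' network (the 16 mm separation is excluded for low signal). Error
#' statistics exclude the calibration phantom, which is recovered
#' near-exactly by construction.
#'
#' @param lut A [ReflectanceLUT-class] built for dense emulsions
#'   (g = 0.7, n = 1.435) covering the 7/10/13 mm separations.
#' @param table A [ChromophoreTable-class].
#' @param nTrain Training set size.
#' @param noiseSigma Relative noise SD used both for training data and
#'   for the fabricated voltage frames.
#' @param epochs Maximum training epochs.
#' @param nFrames Fabricated time points per phantom (1 Hz).
#' @param seed Master seed.
#' @param ... Passed to [trainInverseModel()].
#' @return A list of class `"PhantomRecovery"`: per-phantom table
#'   (`phantoms`), error statistics excluding the calibration phantom
#'   (`stats`), the calibration phantom's own error (`calibrationError`),
#'   and the trained `model`.
#' @export
runEmulsionRecovery <- function(lut, table, nTrain = 20000,
    noiseSigma = 0.05, epochs = 1000, nFrames = 10, seed = 1, ...) {
  geometry <- emulsionGeometry()
  config <- generatorConfig("sum100", noiseSigma = noiseSigma)
  train <- makeDataset(nTrain, config, geometry, lut, table, seed = seed)
  model <- trainInverseModel(train, epochs = epochs, seed = seed + 2L, ...)
  law <- emulsionScatteringLaw()
  lipid <- seq(65, 85, by = 5)
  water <- 100 - lipid
  calIdx <- which(lipid == 85)
  phantoms <- lapply(seq_along(lipid), function(i) {
    opt <- .phantomOptics(water[i], lipid[i], 0, law, geometry, table)
    rdTrue <- forwardReflectance(
      data.frame(water = water[i], lipid = lipid[i], d2o = 0),
      geometry, lut, table, fixedScattering = opt$musp)
    frames <- simulateVoltageFrames(drop(rdTrue), geometry,
      nFrames = nFrames, sigma = noiseSigma, seed = seed + 100L + i)
    list(optics = opt, frames = frames)
  })
  calOpt <- phantoms[[calIdx]]$optics
  calibration <- buildCalibration(phantoms[[calIdx]]$frames,
    calOpt$mua, calOpt$musp, geometry, lut)
  perPhantom <- do.call(rbind, lapply(seq_along(lipid), function(i) {
    rd <- toReflectance(phantoms[[i]]$frames, calibration)
    pred <- predictFractions(model, rd)
    data.frame(trueWater = water[i], trueLipid = lipid[i],
      recoveredWater = mean(pred[, "water"]),
      recoveredLipid = mean(pred[, "lipid"]),
      sdWater = sd(pred[, "water"]), sdLipid = sd(pred[, "lipid"]),
      isCalibration = i == calIdx)
  }))
  errW <- perPhantom$recoveredWater - perPhantom$trueWater
  errL <- perPhantom$recoveredLipid - perPhantom$trueLipid
  keep <- !perPhantom$isCalibration
  out <- list(phantoms = perPhantom,
    stats = data.frame(quantity = c("water", "lipid"),
      mean = c(mean(errW[keep]), mean(errL[keep])),
      sd = c(sd(errW[keep]), sd(errL[keep]))),
    calibrationError = c(water = errW[calIdx], lipid = errL[calIdx]),
    model = model)
  class(out) <- "PhantomRecovery"
  out
}

#' Synthetic heavy-water dilution experiment
#'
#' End-to-end stand-in for the D2O dilution study: ten phantoms of 1
#' percent Intralipid with the water fraction stepping from 99 down to 9
#' percent (in steps of 10) and D2O filling the remainder, at fixed
#' 1-percent-Intralipid scattering. D2O absorbs one tenth of water, so
#' the dilution titrates absorption at constant scattering. The inverse
#' network is trained on the unconstrained d2o generator mode (water and
#' lipid need not sum to 100), all 12 channels are used, and the 99
#' percent phantom calibrates the pipeline.
#'
#' @param lut A [ReflectanceLUT-class] built with n = 1.33 (dilute
#'   aqueous suspension) covering all four separations.
#' @inheritParams runEmulsionRecovery
#' @return A list of class `"PhantomRecovery"` with water-recovery
#'   statistics over the nine non-calibration phantoms.
#' @export
runD2ODilution <- function(lut, table, nTrain = 20000, noiseSigma = 0.05,
    epochs = 1000, nFrames = 10, seed = 1, ...) {
  geometry <- swirGeometry()
  law <- intralipidScatteringLaw()
  musp <- scatteringAt(law, geometry@wavelengths)
  config <- generatorConfig("d2o", fixedScattering = musp,
    noiseSigma = noiseSigma)
  train <- makeDataset(nTrain, config, geometry, lut, table, seed = seed)
  model <- trainInverseModel(train, epochs = epochs, seed = seed + 2L, ...)
  water <- seq(99, 9, by = -10)
  lipid <- rep(1, length(water))
  d2o <- 100 - water - lipid
  calIdx <- 1L
  phantoms <- lapply(seq_along(water), function(i) {
    opt <- .phantomOptics(water[i], lipid[i], d2o[i], law, geometry, table)
    rdTrue <- forwardReflectance(
      data.frame(water = water[i], lipid = lipid[i], d2o = d2o[i]),
      geometry, lut, table, fixedScattering = musp)
    frames <- simulateVoltageFrames(drop(rdTrue), geometry,
      nFrames = nFrames, sigma = noiseSigma, seed = seed + 200L + i)
    list(optics = opt, frames = frames)
  })
  calOpt <- phantoms[[calIdx]]$optics
  calibration <- buildCalibration(phantoms[[calIdx]]$frames,
    calOpt$mua, calOpt$musp, geometry, lut)
  perPhantom <- do.call(rbind, lapply(seq_along(water), function(i) {
    rd <- toReflectance(phantoms[[i]]$frames, calibration)
    pred <- predictFractions(model, rd)
    data.frame(trueWater = water[i],
      recoveredWater = mean(pred[, "water"]),
      sdWater = sd(pred[, "water"]), isCalibration = i == calIdx)
  }))
  errW <- perPhantom$recoveredWater - perPhantom$trueWater
  keep <- !perPhantom$isCalibration
  out <- list(phantoms = perPhantom,
    stats = data.frame(quantity = "water", mean = mean(errW[keep]),
      sd = sd(errW[keep])),
    calibrationError = c(water = errW[calIdx]),
    model = model)
  class(out) <- "PhantomRecovery"
  out
}

#' @export
print.PhantomRecovery <- function(x, ...) {
  cat("Synthetic phantom recovery over", nrow(x$phantoms), "phantoms",
    "(errors exclude the calibration phantom):\n")
  for (i in seq_len(nrow(x$stats)))
    cat(sprintf("  %-6s %+6.2f %% +/- %5.2f %%\n", x$stats$quantity[i],
      x$stats$mean[i], x$stats$sd[i]))
  cat(sprintf("  calibration phantom error: %s\n",
    paste(sprintf("%s %+0.3f%%", names(x$calibrationError),
      x$calibrationError), collapse = ", ")))
  invisible(x)
}
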