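#' Scattering power law
#'
#' Spectral model for the reduced scattering coefficient,
#' \eqn{\mu_s'(\lambda) = A (\lambda/\lambda_{ref})^{-b}}, with amplitude
#' `A` (mm^-1, referenced to `refWavelength`) and dimensionless slope `b`.
#'
#' @slot amplitude Scattering amplitude `A` in mm^-1 at the reference
#'   wavelength.
#' @slot slope Dimensionless scattering slope `b`.
#' @slot refWavelength Reference wavelength in nm (default 980).
#' @aliases ScatteringPowerLaw-class
#' @exportClass ScatteringPowerLaw
setClass("ScatteringPowerLaw",
  representation(amplitude = "numeric", slope = "numeric",
    refWavelength = "numeric"),
  prototype(amplitude = 1, slope = 1.29, refWavelength = 980))

setValidity("ScatteringPowerLaw", function(object) {
  msg <- NULL
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude) ||
      object@amplitude <= 0)
    msg <- c(msg, "amplitude must be a single positive number")
  if (length(object@slope) != 1L || !is.finite(object@slope))
    msg <- c(msg, "slope must be a single finite number")
  if (length(object@refWavelength) != 1L || object@refWavelength <= 0)
    msg <- c(msg, "refWavelength must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' @param amplitude,slope,refWavelength See slot descriptions.
#' @return `ScatteringPowerLaw()` returns a `ScatteringPowerLaw` object.
#' @rdname ScatteringPowerLaw-class
#' @examples
#' law <- ScatteringPowerLaw(amplitude = 2, slope = 1)
#' scatteringAt(law, 490)  # 4 mm^-1
#' @export
ScatteringPowerLaw <- function(amplitude, slope, refWavelength = 980) {
  new("ScatteringPowerLaw", amplitude = amplitude, slope = slope,
    refWavelength = refWavelength)
}

#' Sample composition
#'
#' Volume fractions (percent, 0-100) of water, lipid and heavy water (D2O)
#' in a sample, plus its scattering power law. Fractions need not sum to
#' 100; generators that require the sum-to-100 constraint enforce it
#' themselves.
#'
#' @slot water,lipid,d2o Volume fractions in percent.
#' @slot scattering A [ScatteringPowerLaw-class] object.
#' @aliases SampleComposition-class
#' @exportClass SampleComposition
setClass("SampleComposition",
  representation(water = "numeric", lipid = "numeric", d2o = "numeric",
    scattering = "ScatteringPowerLaw"))

setValidity("SampleComposition", function(object) {
  f <- c(object@water, object@lipid, object@d2o)
  if (length(f) != 3L || any(!is.finite(f)))
    return("water, lipid and d2o must each be a single finite number")
  if (any(f < 0) || any(f > 100))
    return("volume fractions must lie in [0, 100] percent")
  if (sum(f) > 100 + 1e-9)
    return("water + lipid + d2o must not exceed 100 percent")
  TRUE
})

#' @param water,lipid,d2o Volume fractions in percent.
#' @param scattering A [ScatteringPowerLaw-class] object.
#' @return `SampleComposition()` returns a `SampleComposition` object.
#' @rdname SampleComposition-class
#' @export
SampleComposition <- function(water, lipid, d2o = 0,
    scattering = ScatteringPowerLaw(1, 1.29)) {
  new("SampleComposition", water = water, lipid = lipid, d2o = d2o,
    scattering = scattering)
}

#' Probe measurement geometry
#'
#' The set of illumination wavelengths and source-detector (S-D)
#' separations of a multi-distance probe. The measurement channel set is
#' the cartesian product in wavelength-major order (all separations for the
#' first wavelength, then the second, ...), which is the stable ordering
#' used for every reflectance vector in the package.
#'
#' @slot wavelengths Illumination wavelengths in nm, strictly ascending.
#' @slot separations S-D separations in mm, strictly ascending.
#' @aliases ProbeGeometry-class
#' @exportClass ProbeGeometry
setClass("ProbeGeometry",
  representation(wavelengths = "numeric", separations = "numeric"))

setValidity("ProbeGeometry", function(object) {
  msg <- NULL
  for (nm in c("wavelengths", "separations")) {
    v <- slot(object, nm)
    if (length(v) < 1L || any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, paste(nm, "must be positive and non-empty"))
    else if (is.unsorted(v, strictly = TRUE))
      msg <- c(msg, paste(nm, "must be strictly ascending"))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param wavelengths,separations See slot descriptions.
#' @return `ProbeGeometry()` returns a `ProbeGeometry` object.
#' @rdname ProbeGeometry-class
#' @examples
#' geom <- swirGeometry()
#' nChannels(geom)  # 12
#' head(channels(geom))
#' @export
ProbeGeometry <- function(wavelengths, separations) {
  new("ProbeGeometry", wavelengths = sort(wavelengths),
    separations = sort(separations))
}

#' Chromophore absorption table
#'
#' Absorption coefficients of pure chromophores (mm^-1 per unit volume
#' fraction) at discrete wavelengths, with a provenance note per entry.
#' D2O is not tabulated: its absorption is modeled as water scaled by
#' exactly 1/10 (see [absorptionAt()]).
#'
#' @slot entries A `data.frame` with columns `chromophore`,
#'   `wavelength_nm`, `mua_per_unit_fraction_mm1`, `source`.
#' @aliases ChromophoreTable-class
#' @exportClass ChromophoreTable
setClass("ChromophoreTable", representation(entries = "data.frame"))

setValidity("ChromophoreTable", function(object) {
  e <- object@entries
  need <- c("chromophore", "wavelength_nm", "mua_per_unit_fraction_mm1",
    "source")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return("entries must be non-empty")
  if (any(e$mua_per_unit_fraction_mm1 <= 0))
    return("all absorption coefficients must be > 0")
  if (anyDuplicated(e[c("chromophore", "wavelength_nm")]))
    return("duplicate (chromophore, wavelength) entries")
  TRUE
})

#' Diffuse reflectance look-up table
#'
#' Monte Carlo-derived spatially resolved diffuse reflectance Rd
#' (dimensionless, per mm^2 of detector area) tabulated on a grid of
#' reduced scattering (`muspGrid`) and absorption (`muaGrid`) coefficients
#' at each source-detector separation.
#'
#' @slot muspGrid,muaGrid Strictly ascending grids in mm^-1.
#' @slot separations S-D separations in mm.
#' @slot values 3-D array `[musp, mua, separation]` of Rd values.
#' @slot metadata List recording the transport medium (g, n, slab size),
#'   photon budget, ring half-width, seed and package version.
#' @aliases ReflectanceLUT-class
#' @exportClass ReflectanceLUT
setClass("ReflectanceLUT",
  representation(muspGrid = "numeric", muaGrid = "numeric",
    separations = "numeric", values = "array", metadata = "list"))

setValidity("ReflectanceLUT", function(object) {
  msg <- NULL
  if (is.unsorted(object@muspGrid, strictly = TRUE))
    msg <- c(msg, "muspGrid must be strictly ascending")
  if (is.unsorted(object@muaGrid, strictly = TRUE))
    msg <- c(msg, "muaGrid must be strictly ascending")
  d <- dim(object@values)
  if (length(d) != 3L ||
      !all(d == c(length(object@muspGrid), length(object@muaGrid),
        length(object@separations))))
    msg <- c(msg, "values must be a [musp x mua x separation] array")
  if (any(object@values < 0)) msg <- c(msg, "all Rd values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Neural-network inverse model
#'
#' A fully connected network mapping a log-normalized multi-channel diffuse
#' reflectance vector to water and lipid volume fractions. Hidden layers
#' use rectified-linear activations; the two-node output layer is linear.
#' Labels are scaled to fractions (0-1) internally; predictions are
#' reported in percent.
#'
#' @slot weights List of weight matrices `W` and bias vectors `b` per layer.
#' @slot normStats Per-channel mean and SD of log-reflectance fitted on the
#'   training set (applied to every input before the network).
#' @slot channels `data.frame` of the channel ordering
#'   (`wavelength_nm`, `separation_mm`) the model was trained on;
#'   prediction refuses vectors with a different channel set.
#' @slot training List of training metadata: per-epoch loss trace,
#'   epochs run, stopping reason, seed, hyperparameters.
#' @aliases InverseModel-class
#' @exportClass InverseModel
setClass("InverseModel",
  representation(weights = "list", normStats = "list",
    channels = "data.frame", training = "list"))

setValidity("InverseModel", function(object) {
  if (length(object@weights) == 0L) return("weights must be non-empty")
  if (!all(c("mean", "sd") %in% names(object@normStats)))
    return("normStats must contain 'mean' and 'sd'")
  w1 <- object@weights[[1L]]$W
  if (nrow(w1) != nrow(object@channels))
    return("input width must match the channel table")
  TRUE
})

#' Labeled reflectance dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding
#' forward-modeled samples: assays `"reflectance"` (noise-added) and
#' `"noiseless"` are channels x samples matrices; `rowData` carries the
#' channel table (`wavelength_nm`, `separation_mm`); `colData` carries the
#' sample compositions (`water`, `lipid`, `d2o`, in percent) and scattering
#' parameters (`A`, `b`).
#'
#' @aliases ReflectanceSet-class
#' @exportClass ReflectanceSet
setClass("ReflectanceSet", contains = "SummarizedExperiment")

setValidity("ReflectanceSet", function(object) {
  msg <- NULL
  if (!all(c("reflectance", "noiseless") %in% assayNames(object)))
    msg <- c(msg, "assays 'reflectance' and 'noiseless' are required")
  if (!all(c("wavelength_nm", "separation_mm") %in% names(rowData(object))))
    msg <- c(msg, "rowData must contain wavelength_nm and separation_mm")
  if (!all(c("water", "lipid", "d2o", "A", "b") %in% names(colData(object))))
    msg <- c(msg, "colData must contain water, lipid, d2o, A, b")
  if (is.null(msg)) TRUE else msg
})
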