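# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-sample generator configuration
#'
#' Defines how random sample compositions are drawn for training and test
#' datasets. Three modes are supported:
#' \describe{
#'   \item{`"sum100"`}{water ~ U(0, 100) percent, lipid = 100 - water,
#'     no D2O: a two-chromophore sample fully composed of water and lipid.}
#'   \item{`"d2o"`}{water ~ U(0, 100), lipid ~ U(0, `lipidMax`) (capped so
#'     fractions sum to at most 100), D2O fills the remainder: emulates a
#'     heavy-water dilution series at essentially constant scattering.}
#'   \item{`"fixed"`}{every draw is the single composition in
#'     `fixedComposition` (water, lipid, d2o percent).}
#' }
#' Scattering is drawn per sample as a power law with amplitude
#' A ~ U(`ampRange`) mm^-1 (referenced to 980 nm) and slope
#' b ~ N(`slopeMean`, `slopeSD`) — typical soft-tissue values — unless
#' `fixedScattering` supplies one reduced-scattering value per probe
#' wavelength, in which case the power-law draw is skipped. Relative
#' Gaussian noise of `noiseSigma` is applied by [addNoise()].
#'
#' @param mode One of `"sum100"`, `"d2o"`, `"fixed"`.
#' @param ampRange Uniform range of the scattering amplitude, mm^-1.
#' @param slopeMean,slopeSD Normal parameters of the scattering slope.
#' @param fixedScattering Optional per-wavelength reduced scattering
#'   (mm^-1), in the order of the geometry's wavelengths.
#' @param noiseSigma Relative noise SD (default 0.05, i.e. 5 percent).
#' @param lipidMax Upper bound of the lipid fraction in `"d2o"` mode
#'   (percent, default 2).
#' @param fixedComposition `c(water, lipid, d2o)` in percent, `"fixed"`
#'   mode only.
#' @return A `GeneratorConfig` object.
#' @aliases GeneratorConfig-class
#' @exportClass GeneratorConfig
#' @export generatorConfig
setClass("GeneratorConfig",
  representation(mode = "character", ampRange = "numeric",
    slopeMean = "numeric", slopeSD = "numeric",
    fixedScattering = "numeric", noiseSigma = "numeric",
    lipidMax = "numeric", fixedComposition = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msg <- NULL
  if (!object@mode %in% c("sum100", "d2o", "fixed"))
    msg <- c(msg, "mode must be one of 'sum100', 'd2o', 'fixed'")
  if (length(object@ampRange) != 2L || any(object@ampRange <= 0) ||
      diff(object@ampRange) < 0)
    msg <- c(msg, "ampRange must be a positive increasing pair")
  if (object@slopeSD < 0) msg <- c(msg, "slopeSD must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@mode == "fixed" && length(object@fixedComposition) != 3L)
    msg <- c(msg, "fixed mode needs fixedComposition = c(water, lipid, d2o)")
  if (is.null(msg)) TRUE else msg
})

generatorConfig <- function(mode = c("sum100", "d2o", "fixed"),
    ampRange = c(0.2, 10), slopeMean = 1.29, slopeSD = 0.52,
    fixedScattering = numeric(0), noiseSigma = 0.05, lipidMax = 2,
    fixedComposition = numeric(0)) {
  new("GeneratorConfig", mode = match.arg(mode), ampRange = ampRange,
    slopeMean = slopeMean, slopeSD = slopeSD,
    fixedScattering = fixedScattering, noiseSigma = noiseSigma,
    lipidMax = lipidMax, fixedComposition = fixedComposition)
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: mode '%s', A ~ U(%g, %g), b ~ N(%g, %g), noise %g%%\n",
    object@mode, object@ampRange[1], object@ampRange[2], object@slopeMean,
    object@slopeSD, 100 * object@noiseSigma))
})

#' Draw random sample compositions
#'
#' Draws `n` compositions according to the generator mode (see
#' [generatorConfig()]). When scattering is drawn as a power law, the
#' (A, b) pair is rejected and redrawn whenever the implied reduced
#' scattering at any probe wavelength would leave `muspBounds` (the LUT
#' coverage), so every drawn sample is forward-modelable; the rejection
#' rate is recorded in the `"rejectionRate"` attribute.
#'
#' @param n Number of samples.
#' @param config A `GeneratorConfig`.
#' @param geometry A [ProbeGeometry-class].
#' @param muspBounds Length-2 bounds on reduced scattering (mm^-1),
#'   typically `range(muspGrid(lut))`.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `water`, `lipid`, `d2o` (percent)
#'   and `A`, `b` (NA when `fixedScattering` is in effect).
#' @export
drawCompositions <- function(n, config, geometry,
    muspBounds = c(0.2, 10), seed = 1) {
  stopifnot(is(config, "GeneratorConfig"), n >= 1)
  validObject(config)
  .withSeed(seed, {
    comp <- switch(config@mode,
      sum100 = {
        water <- runif(n, 0, 100)
        data.frame(water = water, lipid = 100 - water, d2o = 0)
      },
      d2o = {
        water <- runif(n, 0, 100)
        lipid <- runif(n, 0, pmin(config@lipidMax, 100 - water))
        data.frame(water = water, lipid = lipid,
          d2o = 100 - water - lipid)
      },
      fixed = {
        fc <- config@fixedComposition
        data.frame(water = rep(fc[1], n), lipid = rep(fc[2], n),
          d2o = rep(fc[3], n))
      })
    if (length(config@fixedScattering) > 0L) {
      if (length(config@fixedScattering) != length(geometry@wavelengths))
        stop("fixedScattering must supply one musp per probe wavelength")
      comp$A <- NA_real_
      comp$b <- NA_real_
      attr(comp, "rejectionRate") <- 0
    } else {
      lam <- geometry@wavelengths / 980
      A <- numeric(n); b <- numeric(n)
      need <- seq_len(n)
      tried <- 0L; rejected <- 0L
      while (length(need) > 0L) {
        m <- length(need)
        Ai <- runif(m, config@ampRange[1], config@ampRange[2])
        bi <- rnorm(m, config@slopeMean, config@slopeSD)
        musp <- outer(Ai, lam, function(a, l) a) * outer(bi, lam,
          function(bb, l) l^(-bb))
        ok <- musp >= muspBounds[1] & musp <= muspBounds[2]
        ok <- rowSums(ok) == length(lam)
        tried <- tried + m
        rejected <- rejected + sum(!ok)
        A[need[ok]] <- Ai[ok]
        b[need[ok]] <- bi[ok]
        need <- need[!ok]
      }
      comp$A <- A
      comp$b <- b
      attr(comp, "rejectionRate") <- rejected / tried
    }
    comp
  })
}

#' @describeIn drawCompositions Draw a single composition as a
#'   [SampleComposition-class] object.
#' @export
drawComposition <- function(config, geometry, muspBounds = c(0.2, 10),
    seed = 1) {
  d <- drawCompositions(1L, config, geometry, muspBounds, seed)
  scat <- if (is.na(d$A[1])) ScatteringPowerLaw(1, 0)
    else ScatteringPowerLaw(d$A[1], d$b[1])
  SampleComposition(water = d$water[1], lipid = d$lipid[1], d2o = d$d2o[1],
    scattering = scat)
}

#' Forward-model compositions into reflectance vectors
#'
#' Computes the absorption (Beer's law over the chromophore table) and
#' reduced scattering (power law or fixed per-wavelength values) of each
#' sample at every probe wavelength, then looks up diffuse reflectance in
#' the LUT for every channel of the geometry, in the stable
#' wavelength-major channel order.
#'
#' @param compositions A `data.frame` as returned by [drawCompositions()]
#'   (columns `water`, `lipid`, `d2o`, and `A`, `b` unless
#'   `fixedScattering` is given), or a single [SampleComposition-class].
#' @param geometry A [ProbeGeometry-class].
#' @param lut A [ReflectanceLUT-class] covering the implied optical
#'   properties; out-of-bounds properties raise an error identifying the
#'   channel.
#' @param table A [ChromophoreTable-class].
#' @param fixedScattering Optional per-wavelength reduced scattering
#'   (mm^-1) overriding the per-sample power law.
#' @return A samples x channels matrix of noiseless Rd values.
#' @export
forwardReflectance <- function(compositions, geometry, lut, table,
    fixedScattering = NULL) {
  if (is(compositions, "SampleComposition")) {
    sc <- compositions@scattering
    compositions <- data.frame(water = compositions@water,
      lipid = compositions@lipid, d2o = compositions@d2o,
      A = sc@amplitude, b = sc@slope)
  }
  nS <- nrow(compositions)
  wl <- geometry@wavelengths
  mua <- .muaMatrix(table, wl, compositions$water, compositions$lipid,
    if (is.null(compositions$d2o)) 0 else compositions$d2o)
  if (!is.null(fixedScattering)) {
    if (length(fixedScattering) != length(wl))
      stop("fixedScattering must supply one musp per probe wavelength")
    musp <- matrix(fixedScattering, nrow = nS, ncol = length(wl),
      byrow = TRUE)
  } else {
    if (anyNA(compositions$A))
      stop("compositions lack power-law parameters; ",
        "supply fixedScattering instead")
    musp <- outer(compositions$A, rep(1, length(wl))) *
      outer(compositions$b, wl / 980, function(b, l) l^(-b))
  }
  ch <- channels(geometry)
  rd <- matrix(NA_real_, nrow = nS, ncol = nrow(ch))
  colnames(rd) <- sprintf("%gnm_%gmm", ch$wavelength_nm, ch$separation_mm)
  for (c in seq_len(nrow(ch))) {
    iwl <- match(ch$wavelength_nm[c], wl)
    rd[, c] <- tryCatch(
      lutLookup(lut, musp[, iwl], mua[, iwl], ch$separation_mm[c]),
      error = function(e) stop("channel ", colnames(rd)[c], ": ",
        conditionMessage(e), call. = FALSE))
  }
  rd
}

#' Add relative Gaussian noise to reflectance
#'
#' Each element x becomes x (1 + e) with e ~ N(0, sigma^2) i.i.d. —
#' multiplicative noise, matching the relative (shot/gain) noise behavior
#' of the detector across channels whose Rd spans orders of magnitude.
#' Results are floored at `1e-12` so downstream log transforms stay
#' defined (at the default 5 percent noise the floor is never reached in
#' practice).
#'
#' @param x Numeric vector or matrix of Rd values.
#' @param sigma Relative noise SD (>= 0).
#' @param seed Integer seed.
#' @return Noisy values, same shape as `x`.
#' @export
addNoise <- function(x, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  .withSeed(seed, {
    noisy <- x * (1 + rnorm(length(x), 0, sigma))
    noisy <- pmax(noisy, 1e-12)
    if (is.matrix(x)) noisy <- matrix(noisy, nrow = nrow(x),
      dimnames = dimnames(x))
    noisy
  })
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n` compositions, forward-models them through the LUT and applies
#' relative Gaussian noise, returning a [ReflectanceSet-class] (a
#' `SummarizedExperiment`) with assays `"reflectance"` (noise-added) and
#' `"noiseless"`, channel annotation in `rowData` and the composition
#' labels in `colData`. The generating config, seed and rejection rate are
#' stored in `metadata()`.
#'
#' @inheritParams drawCompositions
#' @param lut A [ReflectanceLUT-class].
#' @param table A [ChromophoreTable-class].
#' @param noiseSeed Separate seed for the noise draw (defaults to
#'   `seed + 1e6`), so the noiseless forward model is a deterministic
#'   function of the composition draw.
#' @return A [ReflectanceSet-class] with `n` samples.
#' @export
makeDataset <- function(n, config, geometry, lut, table, seed = 1,
    noiseSeed = seed + 1e6) {
  comp <- drawCompositions(n, config, geometry,
    muspBounds = range(lut@muspGrid), seed = seed)
  fixed <- if (length(config@fixedScattering) > 0L)
    config@fixedScattering else NULL
  clean <- forwardReflectance(comp, geometry, lut, table,
    fixedScattering = fixed)
  noisy <- addNoise(clean, config@noiseSigma, seed = noiseSeed)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(noisy), noiseless = t(clean)),
    rowData = channels(geometry),
    colData = S4Vectors::DataFrame(comp),
    metadata = list(config = config, seed = seed, noiseSeed = noiseSeed,
      rejectionRate = attr(comp, "rejectionRate"),
      geometry = geometry))
  new("ReflectanceSet", se)
}

#' @describeIn ReflectanceSet-class Samples x channels matrix of one assay
#'   (`"reflectance"` or `"noiseless"`).
#' @param x A `ReflectanceSet`.
#' @param assay Assay name.
#' @export
reflectanceMatrix <- function(x, assay = "reflectance") {
  t(SummarizedExperiment::assay(x, assay))
}

#' @describeIn ReflectanceSet-class Composition labels as a `data.frame`
#'   (water, lipid, d2o in percent, plus A and b).
#' @export
compositions <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn ReflectanceSet-class Channel table of the dataset.
#' @export
setMethod("channels", "ReflectanceSet", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})
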