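#' Load a chromophore absorption table
#'
#' `readChromophoreTable()` reads a delimited text file with columns
#' `chromophore`, `wavelength_nm`, `mua_per_unit_fraction_mm1`, `source`.
#' `defaultChromophoreTable()` loads the table shipped with the package:
#' pure-water absorption from the Hale & Querry / Segelstein compilations
#' and soybean-oil lipid absorption from van Veen et al. (2005), at the six
#' probe wavelengths 900, 930, 970, 980, 1200 and 1300 nm.
#'
#' Coefficients are absorption per unit volume fraction of the pure
#' chromophore, in mm^-1, so a sample's absorption follows Beer's law as a
#' fraction-weighted sum. The shipped values reproduce the expected bulk
#' properties of common phantoms, e.g. 1 percent Intralipid in water gives
#' mu_a between 0.048 and 0.137 mm^-1 across 980-1300 nm.
#'
#' @param file Path to a tab- or comma-delimited table.
#' @return A [ChromophoreTable-class] object.
#' @examples
#' tab <- defaultChromophoreTable()
#' absorptionAt(SampleComposition(water = 100, lipid = 0), 980, tab)
#' @export
readChromophoreTable <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  e <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  new("ChromophoreTable", entries = e)
}

#' @rdname readChromophoreTable
#' @export
defaultChromophoreTable <- function() {
  readChromophoreTable(system.file("extdata", "chromophores.tsv",
    package = "swirprobe", mustWork = TRUE))
}

# scalar lookup; errors name the missing chromophore and wavelength
.muaPure <- function(table, chromophore, wavelength) {
  e <- table@entries
  hit <- e$chromophore == chromophore & e$wavelength_nm == wavelength
  if (!any(hit))
    stop("no absorption entry for chromophore '", chromophore,
      "' at ", wavelength, " nm", call. = FALSE)
  e$mua_per_unit_fraction_mm1[which(hit)[1L]]
}

#' Absorption coefficient of a sample composition
#'
#' Beer's-law mixing: \eqn{\mu_a(\lambda)} is the volume-fraction-weighted
#' sum of the pure-chromophore coefficients. Heavy water contributes as
#' water scaled by exactly 1/10, reflecting its strongly reduced (and
#' spectrally collinear) absorption in the SWIR.
#'
#' @param composition A [SampleComposition-class] object.
#' @param wavelength Wavelength in nm (must be tabulated for every
#'   chromophore with a nonzero fraction).
#' @param table A [ChromophoreTable-class] object.
#' @return Absorption coefficient in mm^-1.
#' @export
setMethod("absorptionAt",
  signature(composition = "SampleComposition", wavelength = "numeric",
    table = "ChromophoreTable"),
  function(composition, wavelength, table) {
    vapply(wavelength, function(wl) {
      mua <- 0
      if (composition@water > 0 || composition@d2o > 0) {
        ew <- .muaPure(table, "water", wl)
        mua <- mua + composition@water / 100 * ew +
          composition@d2o / 100 * ew / 10
      }
      if (composition@lipid > 0)
        mua <- mua + composition@lipid / 100 * .muaPure(table, "lipid", wl)
      mua
    }, numeric(1L))
  })

# vectorized Beer's-law mixing over many samples at the geometry's
# wavelengths; returns samples x wavelengths matrix (internal fast path)
.muaMatrix <- function(table, wavelengths, water, lipid, d2o = 0) {
  ew <- vapply(wavelengths, function(wl) .muaPure(table, "water", wl),
    numeric(1L))
  el <- vapply(wavelengths, function(wl) .muaPure(table, "lipid", wl),
    numeric(1L))
  outer(water / 100, ew) + outer(lipid / 100, el) + outer(d2o / 100, ew / 10)
}

#' Reduced scattering coefficient from the power law
#'
#' Evaluates \eqn{\mu_s'(\lambda) = A (\lambda/\lambda_{ref})^{-b}}.
#'
#' @param law A [ScatteringPowerLaw-class] object.
#' @param wavelength Wavelength(s) in nm.
#' @return Reduced scattering coefficient(s) in mm^-1.
#' @export
setMethod("scatteringAt",
  signature(law = "ScatteringPowerLaw", wavelength = "numeric"),
  function(law, wavelength) {
    stopifnot(all(wavelength > 0))
    law@amplitude * (wavelength / law@refWavelength)^(-law@slope)
  })

#' @describeIn ProbeGeometry-class Channel table in the package's stable
#'   wavelength-major order.
#' @param x A `ProbeGeometry`.
#' @export
setMethod("channels", "ProbeGeometry", function(x) {
  data.frame(
    wavelength_nm = rep(x@wavelengths, each = length(x@separations)),
    separation_mm = rep(x@separations, times = length(x@wavelengths)))
})

#' @describeIn ProbeGeometry-class Number of measurement channels.
#' @export
setMethod("nChannels", "ProbeGeometry", function(x)
  length(x@wavelengths) * length(x@separations))

#' @describeIn ProbeGeometry-class Wavelengths in nm.
#' @export
setMethod("wavelengths", "ProbeGeometry", function(x) x@wavelengths)

#' @describeIn ProbeGeometry-class S-D separations in mm.
#' @export
setMethod("separations", "ProbeGeometry", function(x) x@separations)

setMethod("show", "ProbeGeometry", function(object) {
  cat("ProbeGeometry:", length(object@wavelengths), "wavelengths x",
    length(object@separations), "separations =",
    nChannels(object), "channels\n")
  cat("  wavelengths (nm):", paste(object@wavelengths, collapse = ", "), "\n")
  cat("  separations (mm):", paste(object@separations, collapse = ", "), "\n")
})

setMethod("show", "ChromophoreTable", function(object) {
  cat("ChromophoreTable with", nrow(object@entries), "entries (",
    paste(unique(object@entries$chromophore), collapse = ", "), ")\n")
})

setMethod("show", "ScatteringPowerLaw", function(object) {
  cat(sprintf("ScatteringPowerLaw: A = %g mm^-1 at %g nm, b = %g\n",
    object@amplitude, object@refWavelength, object@slope))
})

setMethod("show", "SampleComposition", function(object) {
  cat(sprintf("SampleComposition: water %g%%, lipid %g%%, d2o %g%%\n",
    object@water, object@lipid, object@d2o))
})

#' Standard probe geometries
#'
#' `swirGeometry()` is the SWIR probe layout: 980, 1200 and 1300 nm LEDs at
#' 7, 10, 13 and 16 mm source-detector separations (12 channels).
#' `nirGeometry()` is the first-window NIR comparison set (900, 930,
#' 970 nm, same separations). `emulsionGeometry()` drops the 16 mm
#' separation (low signal on dense emulsions), giving 9 channels.
#'
#' @return A [ProbeGeometry-class] object.
#' @export
swirGeometry <- function()
  ProbeGeometry(c(980, 1200, 1300), c(7, 10, 13, 16))

#' @rdname swirGeometry
#' @export
nirGeometry <- function()
  ProbeGeometry(c(900, 930, 970), c(7, 10, 13, 16))

#' @rdname swirGeometry
#' @export
emulsionGeometry <- function()
  ProbeGeometry(c(980, 1200, 1300), c(7, 10, 13))
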