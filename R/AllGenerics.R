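#' @export
setGeneric("absorptionAt", function(composition, wavelength, table)
  standardGeneric("absorptionAt"))

#' @export
setGeneric("scatteringAt", function(law, wavelength)
  standardGeneric("scatteringAt"))

#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("separations", function(x) standardGeneric("separations"))

#' @export
setGeneric("muspGrid", function(x) standardGeneric("muspGrid"))

#' @export
setGeneric("muaGrid", function(x) standardGeneric("muaGrid"))

#' @export
setGeneric("lutValues", function(x) standardGeneric("lutValues"))

#' @export
setGeneric("lutLookup", function(lut, musp, mua, separation)
  standardGeneric("lutLookup"))

#' @export
setGeneric("predictFractions", function(model, x, ...)
  standardGeneric("predictFractions"))
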