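#' Build a diffuse reflectance look-up table
#'
#' Runs one white Monte Carlo simulation per reduced-scattering grid value
#' and rescales the recorded photon paths over the absorption grid
#' ([rescaleAbsorption()]), tabulating spatially resolved Rd per
#' source-detector separation. Because absorption rescaling is nearly free,
#' the absorption grid can be dense; the default grids are 15 log-spaced
#' reduced-scattering points over 0.2-10 mm^-1 and 20 log-spaced absorption
#' points over 0.001-0.2 mm^-1.
#'
#' @param separations Detector ring centers in mm, or a
#'   [ProbeGeometry-class] whose separations are used.
#' @param muspGrid,muaGrid Strictly ascending grids in mm^-1.
#' @param nPhotons Photons launched per reduced-scattering grid value.
#' @param seed Integer seed; node `i` of the grid uses `seed + i - 1`.
#' @param g,n,slab Transport medium parameters (see
#'   [TransportMedium-class]).
#' @param ringHalfwidth Detector ring half-width in mm.
#' @return A [ReflectanceLUT-class] object.
#' @examples
#' \donttest{
#' lut <- buildLUT(swirGeometry(), muspGrid = c(1, 5), muaGrid = c(0.01, 0.1),
#'   nPhotons = 1e4, seed = 7)
#' lutLookup(lut, musp = 2, mua = 0.05, separation = 10)
#' }
#' @export
buildLUT <- function(separations,
    muspGrid = exp(seq(log(0.2), log(10), length.out = 15)),
    muaGrid = exp(seq(log(0.001), log(0.2), length.out = 20)),
    nPhotons = 2e5, seed = 1, g = 0.7, n = 1.435, slab = c(60, 60, 100),
    ringHalfwidth = 1.5) {
  if (is(separations, "ProbeGeometry"))
    separations <- separations@separations
  if (length(muspGrid) < 1L || length(muaGrid) < 1L)
    stop("muspGrid and muaGrid must be non-empty")
  vals <- array(NA_real_,
    dim = c(length(muspGrid), length(muaGrid), length(separations)))
  rMax <- max(separations) + ringHalfwidth + 1
  for (i in seq_along(muspGrid)) {
    med <- TransportMedium(musp = muspGrid[i], g = g, n = n, slab = slab)
    rec <- runWhiteMC(med, nPhotons = nPhotons, seed = seed + i - 1,
      rMax = rMax)
    vals[i, , ] <- rescaleAbsorption(rec, muaGrid, separations,
      ringHalfwidth)
  }
  new("ReflectanceLUT", muspGrid = muspGrid, muaGrid = muaGrid,
    separations = separations, values = vals,
    metadata = list(g = g, n = n, slab = slab, nPhotons = nPhotons,
      seed = seed, ringHalfwidth = ringHalfwidth,
      version = as.character(utils::packageVersion("swirprobe"))))
}

#' @describeIn ReflectanceLUT-class Reduced-scattering grid (mm^-1).
#' @param x A `ReflectanceLUT`.
#' @export
setMethod("muspGrid", "ReflectanceLUT", function(x) x@muspGrid)

#' @describeIn ReflectanceLUT-class Absorption grid (mm^-1).
#' @export
setMethod("muaGrid", "ReflectanceLUT", function(x) x@muaGrid)

#' @describeIn ReflectanceLUT-class Tabulated separations (mm).
#' @export
setMethod("separations", "ReflectanceLUT", function(x) x@separations)

#' @describeIn ReflectanceLUT-class The `[musp, mua, separation]` Rd array.
#' @export
setMethod("lutValues", "ReflectanceLUT", function(x) x@values)

setMethod("show", "ReflectanceLUT", function(object) {
  cat(sprintf(
    "ReflectanceLUT: %d musp x %d mua x %d separations (g = %g, n = %g)\n",
    length(object@muspGrid), length(object@muaGrid),
    length(object@separations), object@metadata$g, object@metadata$n))
  cat(sprintf("  musp %g-%g mm^-1, mua %g-%g mm^-1, %g photons/node\n",
    min(object@muspGrid), max(object@muspGrid), min(object@muaGrid),
    max(object@muaGrid), object@metadata$nPhotons))
})

.axisCoord <- function(grid, q, axis, logScale = FALSE) {
  tol <- 1e-9 * max(abs(grid))
  if (any(q < grid[1] - tol) || any(q > grid[length(grid)] + tol)) {
    bad <- q[q < grid[1] - tol | q > grid[length(grid)] + tol][1L]
    stop("query ", format(bad), " outside the ", axis, " grid [",
      format(grid[1]), ", ", format(grid[length(grid)]),
      "]; no extrapolation", call. = FALSE)
  }
  q <- pmin(pmax(q, grid[1]), grid[length(grid)])
  i <- findInterval(q, grid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(grid) - 1L)
  if (logScale) {
    t <- (log(q) - log(grid[i])) / (log(grid[i + 1L]) - log(grid[i]))
  } else {
    t <- (q - grid[i]) / (grid[i + 1L] - grid[i])
  }
  list(i = i, t = t)
}

#' Interpolate a reflectance look-up table
#'
#' Bilinear interpolation of tabulated Rd, linear in reduced scattering and
#' in the logarithm of absorption (the Rd-vs-mua decay is near-exponential,
#' so log-mua interpolation tracks the grid well). Queries are exact at
#' grid nodes; out-of-bounds queries raise an error naming the offending
#' axis rather than extrapolating. Degenerate single-point grids are
#' matched exactly.
#'
#' @param lut A [ReflectanceLUT-class] object.
#' @param musp,mua Query optical properties in mm^-1 (vectors recycle to a
#'   common length).
#' @param separation One of the tabulated separations (scalar or vector).
#' @return Interpolated Rd value(s).
#' @export
setMethod("lutLookup",
  signature(lut = "ReflectanceLUT"),
  function(lut, musp, mua, separation) {
    n <- max(length(musp), length(mua), length(separation))
    musp <- rep_len(musp, n); mua <- rep_len(mua, n)
    separation <- rep_len(separation, n)
    k <- match(separation, lut@separations)
    if (anyNA(k))
      stop("separation ", separation[which(is.na(k))[1L]],
        " mm is not tabulated in this LUT", call. = FALSE)
    if (length(lut@muspGrid) == 1L) {
      if (any(abs(musp - lut@muspGrid) > 1e-9))
        stop("query outside the musp grid (single-point grid)",
          call. = FALSE)
      si <- rep_len(1L, n); st <- rep_len(0, n)
    } else {
      sc <- .axisCoord(lut@muspGrid, musp, "musp")
      si <- sc$i; st <- sc$t
    }
    if (length(lut@muaGrid) == 1L) {
      if (any(abs(mua - lut@muaGrid) > 1e-12))
        stop("query outside the mua grid (single-point grid)",
          call. = FALSE)
      ai <- rep_len(1L, n); at <- rep_len(0, n)
    } else {
      ac <- .axisCoord(lut@muaGrid, mua, "mua", logScale = TRUE)
      ai <- ac$i; at <- ac$t
    }
    v <- lut@values
    idx <- function(i, j) v[cbind(i, j, k)]
    i2 <- pmin(si + 1L, length(lut@muspGrid))
    j2 <- pmin(ai + 1L, length(lut@muaGrid))
    (1 - st) * (1 - at) * idx(si, ai) + st * (1 - at) * idx(i2, ai) +
      (1 - st) * at * idx(si, j2) + st * at * idx(i2, j2)
  })

#' Save or load a reflectance look-up table
#'
#' The LUT (grids, values, and build metadata: g, n, slab, photon budget,
#' seed, package version) is serialized to a single file; the round trip is
#' bit-exact.
#'
#' @param lut A [ReflectanceLUT-class] object.
#' @param file Path to write to or read from.
#' @return `readLUT()` returns the [ReflectanceLUT-class]; `saveLUT()`
#'   returns `file` invisibly.
#' @export
saveLUT <- function(lut, file) {
  stopifnot(is(lut, "ReflectanceLUT"))
  saveRDS(lut, file)
  invisible(file)
}

#' @rdname saveLUT
#' @export
readLUT <- function(file) {
  lut <- readRDS(file)
  if (!is(lut, "ReflectanceLUT"))
    stop("file does not contain a ReflectanceLUT")
  validObject(lut)
  lut
}
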