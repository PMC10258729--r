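#' Transport medium for the slab Monte Carlo
#'
#' Homogeneous optical properties of the simulated slab. Internally the
#' photon random walk uses the scattering coefficient
#' \eqn{\mu_s = \mu_s'/(1-g)} with Henyey-Greenstein phase function; the
#' white (zero-absorption) scheme leaves absorption to a post-hoc
#' Beer-Lambert rescaling of path lengths.
#'
#' @slot musp Reduced scattering coefficient in mm^-1.
#' @slot g Scattering anisotropy (mean cosine), in `[0, 1)`. Default 0.7,
#'   typical of lipid-water emulsions.
#' @slot n Refractive index of the medium relative to air. Default 1.435
#'   (dense emulsions); use 1.33 for dilute aqueous suspensions.
#' @slot slab Slab dimensions in mm, `c(x, y, z)`. Default 60 x 60 x 100,
#'   large enough to approximate a semi-infinite medium; bottom and side
#'   boundaries absorb.
#' @aliases TransportMedium-class
#' @exportClass TransportMedium
setClass("TransportMedium",
  representation(musp = "numeric", g = "numeric", n = "numeric",
    slab = "numeric"),
  prototype(g = 0.7, n = 1.435, slab = c(60, 60, 100)))

setValidity("TransportMedium", function(object) {
  msg <- NULL
  if (object@musp <= 0) msg <- c(msg, "musp must be > 0")
  if (object@g < 0 || object@g >= 1) msg <- c(msg, "g must be in [0, 1)")
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (length(object@slab) != 3L || any(object@slab <= 0))
    msg <- c(msg, "slab must be three positive dimensions (mm)")
  if (is.null(msg)) TRUE else msg
})

#' @param musp,g,n,slab See slot descriptions.
#' @return `TransportMedium()` returns a `TransportMedium` object.
#' @rdname TransportMedium-class
#' @export
TransportMedium <- function(musp, g = 0.7, n = 1.435,
    slab = c(60, 60, 100)) {
  new("TransportMedium", musp = musp, g = g, n = n, slab = slab)
}

setMethod("show", "TransportMedium", function(object) {
  cat(sprintf(
    "TransportMedium: musp = %g mm^-1, g = %g, n = %g, slab %g x %g x %g mm\n",
    object@musp, object@g, object@n, object@slab[1], object@slab[2],
    object@slab[3]))
})

#' Run a white Monte Carlo slab simulation
#'
#' Simulates the steady-state random walk of photons launched as a pencil
#' beam normally incident on the top surface of a homogeneous slab, at zero
#' absorption ("white" Monte Carlo). Steps are sampled exponentially at
#' \eqn{\mu_s = \mu_s'/(1-g)}; scattering angles follow the
#' Henyey-Greenstein phase function; the top surface applies Fresnel
#' reflection for the index mismatch against air, recording the transmitted
#' fraction of the photon weight as an exit event; bottom and side
#' boundaries absorb. Deep photons undergo Russian roulette below weight
#' `1e-4` (survival probability 0.1) and are terminated at a total path
#' length of ten slab diagonals.
#'
#' @param medium A [TransportMedium-class] object.
#' @param nPhotons Number of photons to launch (>= 1).
#' @param seed Integer seed for the simulation's dedicated RNG; a fixed
#'   seed reproduces the exit records exactly.
#' @param rMax Exit events at radii beyond `rMax` mm are not recorded
#'   (they still count toward the escaped-weight summary). Default 30 mm.
#' @return A [S4Vectors::DataFrame] of exit records with columns
#'   `path_mm` (total path length in the medium), `radius_mm` (exit radial
#'   distance from the source) and `weight` (statistical weight at exit,
#'   in (0, 1]). Its `metadata()` holds the weight ledger: `launched`,
#'   `specular`, `escaped_top`, `lost_other`, `lost_roulette`,
#'   `lost_cutoff`, plus the medium and seed.
#' @seealso [rescaleAbsorption()], [buildLUT()]
#' @examples
#' med <- TransportMedium(musp = 1, g = 0, n = 1)
#' rec <- runWhiteMC(med, nPhotons = 500, seed = 1)
#' S4Vectors::metadata(rec)$escaped_top
#' @export
runWhiteMC <- function(medium, nPhotons, seed, rMax = 30) {
  stopifnot(is(medium, "TransportMedium"))
  validObject(medium)
  if (length(nPhotons) != 1L || nPhotons < 1)
    stop("nPhotons must be a single count >= 1")
  mus <- medium@musp / (1 - medium@g)
  maxPath <- 10 * sqrt(sum(medium@slab^2))
  res <- .mc_slab(mus, medium@g, medium@n,
    medium@slab[1] / 2, medium@slab[2] / 2, medium@slab[3],
    as.integer(nPhotons), maxPath, rMax, 1e-4, 0.1, as.double(seed))
  out <- S4Vectors::DataFrame(path_mm = res$path_mm,
    radius_mm = res$radius_mm, weight = res$weight)
  S4Vectors::metadata(out) <- list(
    launched = res$launched, specular = res$specular,
    escaped_top = res$escaped_top, lost_other = res$lost_other,
    lost_roulette = res$lost_roulette, lost_cutoff = res$lost_cutoff,
    musp = medium@musp, g = medium@g, n = medium@n, slab = medium@slab,
    seed = seed, rMax = rMax)
  out
}

#' Beer-Lambert absorption rescaling of white Monte Carlo records
#'
#' Converts zero-absorption exit records into spatially resolved diffuse
#' reflectance at one or more absorption levels: each recorded weight is
#' scaled by \eqn{e^{-\mu_a L}} with its path length L, binned into an
#' annular ring centered on each source-detector separation, and normalized
#' per launched photon and unit ring area.
#'
#' @param records Exit records from [runWhiteMC()].
#' @param mua Absorption coefficient(s) in mm^-1 (>= 0).
#' @param separations Ring centers in mm.
#' @param ringHalfwidth Ring half-width in mm (default 1.5). Rings are
#'   half-open `[s - hw, s + hw)` and must not overlap.
#' @return A matrix of Rd values, `length(mua)` rows x
#'   `length(separations)` columns (dimnames give the grids). At
#'   `mua = 0` this is the unscaled detected fraction per unit area.
#' @export
rescaleAbsorption <- function(records, mua, separations,
    ringHalfwidth = 1.5) {
  stopifnot(all(mua >= 0), all(separations > 0), ringHalfwidth > 0)
  seps <- separations
  if (length(seps) > 1L && any(diff(sort(seps)) < 2 * ringHalfwidth - 1e-12))
    stop("ring bins overlap: separations closer than twice the half-width")
  md <- S4Vectors::metadata(records)
  n <- md$launched
  if (is.null(n)) stop("records lack the launched-photon count metadata")
  rd <- matrix(0, nrow = length(mua), ncol = length(seps),
    dimnames = list(mua = format(mua), separation = format(seps)))
  for (k in seq_along(seps)) {
    lo <- seps[k] - ringHalfwidth
    hi <- seps[k] + ringHalfwidth
    inring <- records$radius_mm >= lo & records$radius_mm < hi
    area <- pi * (hi^2 - max(lo, 0)^2)
    if (!any(inring)) next
    L <- records$path_mm[inring]
    w <- records$weight[inring]
    rd[, k] <- drop(crossprod(exp(-outer(L, mua)), w)) / (n * area)
  }
  rd
}

#' Semi-infinite diffusion-theory diffuse reflectance
#'
#' Closed-form spatially resolved diffuse reflectance of a semi-infinite
#' homogeneous medium in the diffusion approximation with an extrapolated
#' boundary (isotropic point source at one transport mean free path, image
#' source across the extrapolated boundary; internal-reflection parameter
#' from the standard polynomial fit in the relative refractive index).
#' Valid in the high-albedo, large-separation regime; used in this package
#' as the independent physics check of the Monte Carlo transport.
#'
#' @param rho Radial source-detector distance(s) in mm.
#' @param mua,musp Absorption and reduced scattering coefficients, mm^-1.
#' @param n Refractive index of the medium relative to air.
#' @return Diffuse reflectance per unit area (mm^-2).
#' @export
diffusionRd <- function(rho, mua, musp, n = 1.0) {
  stopifnot(mua >= 0, musp > 0, n >= 1)
  mutp <- mua + musp
  z0 <- 1 / mutp
  D <- 1 / (3 * mutp)
  mueff <- sqrt(mua / D)
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

#' @describeIn diffusionRd Diffusion-theory Rd averaged over an annular
#'   ring, matching the detector convention of [rescaleAbsorption()].
#' @param separation Ring center in mm.
#' @param ringHalfwidth Ring half-width in mm.
#' @export
diffusionRdRing <- function(separation, mua, musp, n = 1.0,
    ringHalfwidth = 1.5) {
  lo <- separation - ringHalfwidth
  hi <- separation + ringHalfwidth
  area <- pi * (hi^2 - max(lo, 0)^2)
  f <- function(r) diffusionRd(r, mua, musp, n) * 2 * pi * r
  integrate(f, lo, hi)$value / area
}
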