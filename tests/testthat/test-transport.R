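test_that("white MC is reproducible for a fixed seed", {
  med <- TransportMedium(musp = 0.5)
  a <- runWhiteMC(med, nPhotons = 3000, seed = 42)
  b <- runWhiteMC(med, nPhotons = 3000, seed = 42)
  expect_identical(a$path_mm, b$path_mm)
  expect_identical(a$radius_mm, b$radius_mm)
  expect_identical(a$weight, b$weight)
  c <- runWhiteMC(med, nPhotons = 3000, seed = 43)
  expect_false(identical(a$path_mm, c$path_mm))
  expect_true(all(a$path_mm > 0))
  expect_true(all(a$weight > 0 & a$weight <= 1))
  expect_error(runWhiteMC(med, nPhotons = 0, seed = 1), "nPhotons")
})

test_that("energy is conserved at zero absorption", {
  # index-matched isotropic case: no roulette or cutoff ever triggers,
  # every photon ends at a boundary, so the ledger closes exactly
  med <- TransportMedium(musp = 1, g = 0, n = 1)
  rec <- runWhiteMC(med, nPhotons = 5000, seed = 7)
  md <- S4Vectors::metadata(rec)
  expect_equal(md$escaped_top + md$lost_other + md$lost_roulette +
    md$lost_cutoff + md$specular, md$launched, tolerance = 1e-12)
  expect_equal(md$lost_roulette, 0)
  # thick scattering slab: nearly all light returns through the top
  expect_gt(md$escaped_top / md$launched, 0.5)
  # mismatched-index case closes within the roulette tolerance
  med2 <- TransportMedium(musp = 1)
  rec2 <- runWhiteMC(med2, nPhotons = 5000, seed = 8)
  md2 <- S4Vectors::metadata(rec2)
  expect_equal(
    (md2$escaped_top + md2$lost_other + md2$lost_roulette +
      md2$lost_cutoff + md2$specular) / md2$launched, 1,
    tolerance = 0.02)
})

test_that("absorption rescaling applies Beer-Lambert weights", {
  # single synthetic record: L = 10 mm, w = 1 at radius 7 mm
  rec <- S4Vectors::DataFrame(path_mm = 10, radius_mm = 7, weight = 1)
  S4Vectors::metadata(rec) <- list(launched = 1)
  area <- pi * (8.5^2 - 5.5^2)
  rd <- rescaleAbsorption(rec, mua = 0.1, separations = 7)
  expect_equal(drop(rd), exp(-1) / area)
  # mua = 0 leaves the weight unchanged
  expect_equal(drop(rescaleAbsorption(rec, 0, 7)), 1 / area)
  # doubling mua never increases Rd (monotone over a real record set)
  med <- TransportMedium(musp = 1)
  rr <- runWhiteMC(med, nPhotons = 5000, seed = 3)
  m1 <- rescaleAbsorption(rr, c(0.01, 0.02, 0.04), c(7, 10, 13, 16))
  expect_true(all(diff(m1) < 0))
  # overlapping rings are refused
  expect_error(rescaleAbsorption(rr, 0.01, c(7, 8)), "overlap")
})

test_that("MC reflectance matches diffusion theory at high albedo", {
  # independent closed-form oracle: extrapolated-boundary point-source
  # diffusion solution for a semi-infinite medium, averaged over the
  # detector ring. Valid regime: musp >= 2, mua <= 0.01, rho >= 10 mm.
  lut <- ciLUT()
  md <- lut@metadata
  musps <- muspGrid(lut)
  muas <- muaGrid(lut)
  for (i in which(musps >= 2)) {
    for (j in which(muas <= 0.01)) {
      for (k in which(separations(lut) >= 10)) {
        dt <- diffusionRdRing(separations(lut)[k], muas[j], musps[i],
          n = md$n, ringHalfwidth = md$ringHalfwidth)
        expect_equal(lutValues(lut)[i, j, k], dt, tolerance = 0.15)
      }
    }
  }
})

test_that("per-ring standard error shrinks like one over sqrt(photons)", {
  med <- TransportMedium(musp = 0.5)
  rdAt <- function(n, seed) {
    rec <- runWhiteMC(med, nPhotons = n, seed = seed, rMax = 18)
    drop(rescaleAbsorption(rec, 0.01, 10))
  }
  seeds <- 1:12
  seSmall <- sd(vapply(seeds, function(s) rdAt(2000, s), numeric(1)))
  seBig <- sd(vapply(seeds, function(s) rdAt(8000, 100 + s), numeric(1)))
  # quadrupling the photon budget should halve the SE (about sqrt(4))
  expect_equal(seSmall / seBig, 2, tolerance = 0.8)
})
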