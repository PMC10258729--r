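test_that("Beer's-law mixing reproduces hand-computable examples", {
  tab <- fixtureTable()
  # empty sample absorbs nothing
  empty <- SampleComposition(water = 0, lipid = 0)
  expect_identical(absorptionAt(empty, 980, tab), 0)
  # pure water returns the table entry exactly
  pure <- SampleComposition(water = 100, lipid = 0)
  eW980 <- tab@entries$mua_per_unit_fraction_mm1[
    tab@entries$chromophore == "water" & tab@entries$wavelength_nm == 980]
  expect_identical(absorptionAt(pure, 980, tab), eW980)
  # D2O absorbs exactly one tenth of water: 50/50 mix gives 0.55 eps_w
  mix <- SampleComposition(water = 50, lipid = 0, d2o = 50)
  for (wl in c(980, 1200, 1300)) {
    eW <- absorptionAt(SampleComposition(100, 0), wl, tab)
    expect_equal(absorptionAt(mix, wl, tab), 0.55 * eW)
  }
})

test_that("absorption is linear in each volume fraction", {
  tab <- fixtureTable()
  for (wl in c(900, 980, 1300)) {
    base <- absorptionAt(SampleComposition(water = 20, lipid = 0), wl, tab)
    expect_equal(
      absorptionAt(SampleComposition(water = 40, lipid = 0), wl, tab),
      2 * base)
    sumAB <- absorptionAt(SampleComposition(water = 20, lipid = 30), wl,
      tab)
    expect_equal(sumAB,
      base + absorptionAt(SampleComposition(water = 0, lipid = 30), wl,
        tab))
  }
})

test_that("a missing table entry names the chromophore and wavelength", {
  tab <- fixtureTable()
  expect_error(
    absorptionAt(SampleComposition(water = 50, lipid = 50), 1111, tab),
    "water.*1111")
})

test_that("fixture table satisfies the spectral sanity constraints", {
  e <- fixtureTable()@entries
  w <- function(wl) e$mua_per_unit_fraction_mm1[
    e$chromophore == "water" & e$wavelength_nm == wl]
  l <- function(wl) e$mua_per_unit_fraction_mm1[
    e$chromophore == "lipid" & e$wavelength_nm == wl]
  # water absorption grows across the SWIR band
  expect_true(w(1300) > w(1200) && w(1200) > w(980))
  # lipid has its absorption peak near 1200 nm, slightly above water
  expect_true(l(1200) > l(980) && l(1200) > l(1300))
  expect_true(l(1200) > w(1200))
  expect_true(all(e$mua_per_unit_fraction_mm1 > 0))
})

test_that("scattering power law matches hand arithmetic", {
  expect_equal(scatteringAt(ScatteringPowerLaw(1, 0), 1300), 1.0)
  expect_equal(scatteringAt(ScatteringPowerLaw(5, 1.29), 980), 5.0)
  expect_equal(scatteringAt(ScatteringPowerLaw(2, 1), 490), 4.0)
  # monotone decreasing in wavelength for positive slope
  wl <- seq(900, 1300, by = 50)
  expect_true(all(diff(scatteringAt(ScatteringPowerLaw(3, 0.8), wl)) < 0))
})

test_that("probe geometries define the stable wavelength-major channels", {
  geom <- swirGeometry()
  expect_equal(nChannels(geom), 12L)
  ch <- channels(geom)
  expect_equal(ch$wavelength_nm[1:4], rep(980, 4))
  expect_equal(ch$separation_mm[1:4], c(7, 10, 13, 16))
  expect_equal(nChannels(nirGeometry()), 12L)
  expect_equal(nChannels(emulsionGeometry()), 9L)
  expect_equal(wavelengths(nirGeometry()), c(900, 930, 970))
  expect_error(ProbeGeometry(c(980, 980), c(7, 10)), "ascending")
  expect_error(ProbeGeometry(numeric(0), c(7)), "positive")
})

test_that("composition validity enforces fraction bounds", {
  expect_error(SampleComposition(water = -1, lipid = 0), "0, 100")
  expect_error(SampleComposition(water = 60, lipid = 60), "exceed")
  expect_silent(SampleComposition(water = 60, lipid = 40))
})

test_that("chromophore tables load from delimited text", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chromophore\twavelength_nm\tmua_per_unit_fraction_mm1\tsource",
    "water\t980\t0.05\ttest"), f)
  tab <- readChromophoreTable(f)
  expect_s4_class(tab, "ChromophoreTable")
  expect_equal(absorptionAt(SampleComposition(100, 0), 980, tab), 0.05)
})
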