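test_that("composition draws honor the mode constraints", {
  geom <- swirGeometry()
  cfg <- generatorConfig("sum100")
  d <- drawCompositions(5000, cfg, geom, seed = 1)
  expect_equal(d$water + d$lipid, rep(100, 5000))
  expect_true(all(d$d2o == 0))
  expect_true(all(d$A >= 0.2 & d$A <= 10))
  # d2o mode: water + lipid + d2o = 100, lipid small
  cfgD <- generatorConfig("d2o", fixedScattering = c(0.78, 0.56, 0.49),
    lipidMax = 2)
  dd <- drawCompositions(2000, cfgD, geom, seed = 2)
  expect_equal(dd$water + dd$lipid + dd$d2o, rep(100, 2000))
  expect_true(all(dd$lipid <= 2 & dd$lipid >= 0))
  expect_true(all(dd$d2o >= 0))
  expect_true(all(is.na(dd$A)))
  # fixed mode repeats one composition
  cfgF <- generatorConfig("fixed", fixedComposition = c(30, 70, 0))
  df <- drawCompositions(5, cfgF, geom, seed = 3)
  expect_equal(df$water, rep(30, 5))
})

test_that("scattering slope draws match the configured distribution", {
  # CLT check on the slope mean; rejection sampling only trims extreme
  # (A, b) pairs so the empirical mean stays near the nominal 1.29
  geom <- swirGeometry()
  d <- drawCompositions(1e5, generatorConfig("sum100"), geom, seed = 4)
  tol <- 3 * 0.52 / sqrt(1e5) + 0.02  # CLT band + small rejection bias
  expect_lt(abs(mean(d$b) - 1.29), tol)
  expect_lt(attr(d, "rejectionRate"), 0.1)
  # every accepted draw is forward-modelable at all probe wavelengths
  musp <- outer(d$A, rep(1, 3)) *
    outer(d$b, wavelengths(geom) / 980, function(b, l) l^(-b))
  expect_true(all(musp >= 0.2 & musp <= 10))
})

test_that("draws are reproducible and independent across seeds", {
  geom <- swirGeometry()
  cfg <- generatorConfig("sum100")
  a <- drawCompositions(100, cfg, geom, seed = 10)
  b <- drawCompositions(100, cfg, geom, seed = 10)
  expect_identical(a, b)
  c <- drawCompositions(100, cfg, geom, seed = 11)
  expect_false(identical(a$water, c$water))
})

test_that("forward model is deterministic and channel-stable", {
  lut <- ciLUT()
  tab <- fixtureTable()
  geom <- swirGeometry()
  comp <- data.frame(water = c(30, 30), lipid = c(70, 70), d2o = c(0, 0),
    A = c(2, 2), b = c(1, 1))
  rd <- forwardReflectance(comp, geom, lut, tab)
  expect_equal(ncol(rd), 12L)
  # identical compositions give identical vectors
  expect_equal(rd[1, ], rd[2, ])
  # repeated calls identical: no RNG leakage into the forward model
  expect_identical(forwardReflectance(comp, geom, lut, tab), rd)
  # more water absorbs more at 1300 nm (water-dominated channel)
  wet <- forwardReflectance(
    data.frame(water = 80, lipid = 20, d2o = 0, A = 2, b = 1),
    geom, lut, tab)
  dry <- forwardReflectance(
    data.frame(water = 20, lipid = 80, d2o = 0, A = 2, b = 1),
    geom, lut, tab)
  expect_true(all(wet[, grepl("1300", colnames(wet))] <
    dry[, grepl("1300", colnames(dry))]))
  # out-of-bounds optical properties name the channel
  expect_error(forwardReflectance(
    data.frame(water = 30, lipid = 70, d2o = 0, A = 12, b = 0),
    geom, lut, tab), "channel 980nm_7mm")
})

test_that("water/lipid relabeling with a swapped table mirrors the forward model", {
  lut <- ciLUT()
  tab <- fixtureTable()
  swapped <- tab
  e <- swapped@entries
  e$chromophore <- c(water = "lipid", lipid = "water")[e$chromophore]
  swapped@entries <- e
  geom <- swirGeometry()
  comp <- data.frame(water = 35, lipid = 65, d2o = 0, A = 3, b = 1.2)
  mirror <- data.frame(water = 65, lipid = 35, d2o = 0, A = 3, b = 1.2)
  expect_equal(forwardReflectance(comp, geom, lut, tab),
    forwardReflectance(mirror, geom, lut, swapped))
})

test_that("relative noise has the configured spread and a positive floor", {
  x <- rep(2e-4, 1e5)
  expect_identical(addNoise(x, 0), x)
  noisy <- addNoise(x, 0.05, seed = 6)
  expect_lt(abs(sd(noisy / x) - 0.05), 3 * 0.05 / sqrt(2 * 1e5))
  expect_lt(abs(mean(noisy / x) - 1), 3 * 0.05 / sqrt(1e5))
  expect_identical(addNoise(x, 0.05, seed = 6), noisy)
  # extreme noise cannot push values below the positive floor
  tiny <- addNoise(rep(1e-9, 1000), 5, seed = 7)
  expect_true(all(tiny > 0))
})

test_that("datasets carry labels, both assays, and round-trip exactly", {
  ds <- ciDataset(50, seed = 21)
  expect_s4_class(ds, "ReflectanceSet")
  expect_equal(dim(ds), c(12L, 50L))
  expect_equal(compositions(ds)$water + compositions(ds)$lipid,
    rep(100, 50))
  # noiseless assay is the deterministic forward model of the labels
  redo <- forwardReflectance(compositions(ds), swirGeometry(), ciLUT(),
    fixtureTable())
  expect_equal(unname(reflectanceMatrix(ds, "noiseless")), unname(redo))
  # noisy assay differs but is reproducible via the stored seeds
  expect_false(all(reflectanceMatrix(ds) ==
    reflectanceMatrix(ds, "noiseless")))
  ds2 <- ciDataset(50, seed = 21)
  expect_equal(reflectanceMatrix(ds2), reflectanceMatrix(ds))
  f <- tempfile(fileext = ".rds")
  saveRDS(ds, f)
  back <- readRDS(f)
  expect_identical(reflectanceMatrix(back), reflectanceMatrix(ds))
  expect_identical(compositions(back), compositions(ds))
})

test_that("a singleton dataset and SampleComposition forwarding work", {
  ds <- ciDataset(1, seed = 31)
  expect_equal(ncol(ds), 1L)
  comp <- SampleComposition(water = 60, lipid = 40,
    scattering = ScatteringPowerLaw(2, 1))
  rd <- forwardReflectance(comp, swirGeometry(), ciLUT(), fixtureTable())
  expect_equal(dim(rd), c(1L, 12L))
  expect_equal(absorptionAt(comp, 980, fixtureTable()),
    0.6 * 0.0465 + 0.4 * 0.0042)
})
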