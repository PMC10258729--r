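# Shared fixtures, built once per test run and memoized.
#
# The shared LUTs use a reduced photon budget (3e4 photons per
# reduced-scattering node); Monte Carlo noise at that budget is a few
# percent in the farthest ring, well inside the tolerances asserted on
# them.

.fixtureEnv <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, builder(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

# emulsion-medium LUT (g = 0.7, n = 1.435) over the full property grids
ciLUT <- function() .memo("ciLUT", function() {
  buildLUT(swirGeometry(), nPhotons = 3e4, seed = 101)
})

# dilute-suspension LUT (n = 1.33) over the narrow Intralipid musp range
d2oLUT <- function() .memo("d2oLUT", function() {
  buildLUT(swirGeometry(),
    muspGrid = exp(seq(log(0.2), log(1.5), length.out = 6)),
    nPhotons = 3e4, seed = 202, n = 1.33)
})

fixtureTable <- function() .memo("tab", defaultChromophoreTable)

# small labeled datasets on the shared LUT
ciDataset <- function(n, geometry = swirGeometry(), seed = 11,
    config = generatorConfig("sum100")) {
  makeDataset(n, config, geometry, ciLUT(), fixtureTable(), seed = seed)
}
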