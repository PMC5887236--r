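## Session-level cache of the expensive fixture runs so several test files
## can share one enumeration.

## regression blocks may fail under surrogate energies; never cut the run
## short because of them
options(testthat.progress.max_fails = 1000L)

.runCache <- new.env(parent = emptyenv())

cachedRun <- function(name, fun) {
  if (is.null(.runCache[[name]])) .runCache[[name]] <- fun()
  .runCache[[name]]
}

eqn1States <- function() {
  cachedRun("eqn1", function() {
    fx <- fixtureInterhalogen()
    enumerateIntermediates(fx$reactant, fx$config)
  })
}

claisenStates <- function() {
  cachedRun("claisen", function() {
    fx <- fixtureClaisen()
    enumerateIntermediates(fx$reactant, fx$config)
  })
}

hydroStates <- function() {
  cachedRun("hydro", function() {
    fx <- fixtureHydroformylation()
    enumerateIntermediates(fx$reactant, fx$config, product = fx$product)
  })
}

claisenPipeline <- function() {
  cachedRun("claisenPipe", function() {
    fx <- fixtureClaisen()
    runPipeline(fx$reactant, fx$product, fx$config, delta = fx$delta,
                eTol = fx$eTol, evaluator = bondEnergyEvaluator(),
                topq = fx$topq, states = claisenStates())
  })
}

hydroPipeline <- function() {
  cachedRun("hydroPipe", function() {
    fx <- fixtureHydroformylation()
    suppressWarnings(
      runPipeline(fx$reactant, fx$product, fx$config, delta = fx$delta,
                  eTol = fx$eTol, evaluator = bondEnergyEvaluator(),
                  topq = fx$topq, states = hydroStates()))
  })
}
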