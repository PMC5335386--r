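## Shared fixtures. Heavy multi-seed engine runs are memoised so the
## conservation audit and the condition comparisons reuse one set of runs.

unitCube <- function() boxMesh(c(0, 0, 0), c(1, 1, 1), role = "cube")

transporterQ10 <- function(...) transporterScheme(transporterParams(...),
                                                  applyQ10 = TRUE)

quickConfig <- function(...) simConfig(nIterations = 400, nMolecules = 200,
                                       recordStride = 1, ...)

## full-scale 30-seed runs for the three headline conditions
fullConditionRuns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- list(GLT = transporterQ10())
      cfg <- simConfig(recordStride = 1)
      run <- function(spec)
        runSeeds(buildScene(spec), sch, cfg, seeds = 1:30)
      cache <<- list(
        control = run(sceneSpec("control")),
        tfllr = run(sceneSpec("tfllr")),
        halfDensity = run(sceneSpec("control", transporterDensity = 5400)))
    }
    cache
  }
})
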