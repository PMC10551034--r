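# Shared host-guest campaign machinery for the heavier end-to-end tests.
# Study conditions: 56 umbrella windows, harmonic z-confinement
# kZ = 20 kcal/mol per metric-unit^2, 500-step equilibration ramp,
# 20000-step production ("long") vs its 1% ("short"), BAOAB at
# dt = 0.012, gamma = 1, 300 K.

hgCampaign <- function(toy, path, cvs, traj, nWindows = 56,
                       production = 20000, stride = 10, ramp = 500,
                       masterSeed = 1, kZ = 20) {
  wins <- buildWindows(path, nWindows, kZ = kZ, rampSteps = ramp,
                       productionSteps = production, masterSeed = masterSeed)
  wins <- assignInitialStructures(wins, cvs, path)
  runCampaign(toy@provider, path, wins, traj,
              list(dt = 0.012, gamma = 1, kT = toy@kT, stride = stride))
}

hgGuessPath <- function(toy, style, seed, nNodes = 12, sigma = 0.03) {
  traj <- generateGuessPath(toy, style, sigma = sigma, seed = seed)
  cvs <- projectTrajectory(traj, toy@extras$anchors)
  path <- buildPath(cvs, nNodes = nNodes,
                    metric = cvMetric(traj[[1]], toy@extras$anchors))
  list(traj = traj, cvs = cvs, path = path)
}

# Campaign seeded from the path's own nodes (used for refined paths,
# which have no generating trajectory).
hgCampaignFromPath <- function(toy, path, nWindows = 32, production = 5000,
                               stride = 5, ramp = 300, masterSeed = 1,
                               kZ = 20) {
  sNodes <- pathFE:::pathCVBatch(pathNodes(path), path)[, "s"]
  x0Fn <- function(w)
    toy@extras$initFn(pathNodes(path)[which.min(abs(sNodes - w@sCenter)), ])
  wins <- buildWindows(path, nWindows, kZ = kZ, rampSteps = ramp,
                       productionSteps = production, masterSeed = masterSeed)
  runCampaign(toy@provider, path, wins, x0Fn,
              list(dt = 0.012, gamma = 1, kT = toy@kT, stride = stride))
}

hgBarrier <- function(series, kT, nBins = 40) {
  sol <- solveWham(binSamples(series, nBins), kT = kT)
  profileStatistics(sol$profile, c(0, 0.15), c(0.85, 1))$barrier
}
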