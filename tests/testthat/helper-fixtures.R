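## Small fixtures shared across tests. Everything is generated in code.

simpleSchedule <- function(n = 6, durS = 300) buildSchedule(rep(durS, n))

## a TAC with prescribed mid-time point values (frame-averaged semantics are
## irrelevant for transform algebra tests, which act on the stored values)
tacFromValues <- function(schedule, values, label = "region") {
  timeActivityCurve(schedule, values, regionLabel = label)
}

## positive random TAC for property tests
randomPositiveTAC <- function(schedule, seed) {
  set.seed(seed)
  tacFromValues(schedule, stats::runif(nFrames(schedule), 0.5, 5))
}

defaultSim <- function(schedule = studyFrameSchedule(),
                       kin = defaultTissueKinetics(),
                       ref = defaultReferenceKinetics()) {
  input <- defaultPlasmaInput()
  list(kin = kin, ref = ref, input = input, schedule = schedule,
       striatum = simulateRegion(kin, input, schedule, "striatum"),
       cerebellum = simulateRegion(ref, input, schedule, "cerebellum"))
}

## long low-frequency protocol used for asymptotic oracle-equivalence checks
longSchedule <- function(totalMin = 960, frameS = 300) {
  buildSchedule(rep(frameS, totalMin * 60 / frameS))
}
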