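#' Construct a tri-exponential plasma input function
#'
#' @param A1 kBq/mL/min. @param A2,A3 kBq/mL.
#' @param lambda1,lambda2,lambda3 1/min, `lambda1 > lambda2 > lambda3 > 0`.
#' @param delay appearance delay, min.
#' @return a [PlasmaInput-class].
#' @export
plasmaInput <- function(A1, A2, A3, lambda1, lambda2, lambda3, delay = 0) {
  new("PlasmaInput", A1 = as.numeric(A1), A2 = as.numeric(A2),
      A3 = as.numeric(A3), lambda1 = as.numeric(lambda1),
      lambda2 = as.numeric(lambda2), lambda3 = as.numeric(lambda3),
      delay = as.numeric(delay))
}

#' Default simulator settings
#'
#' `defaultPlasmaInput()` is a bolus whose fast phase peaks near 90 kBq/mL at
#' about 45 s after appearance with a slow terminal phase (0.004/min), the
#' shape of a tail-vein bolus in a rat under peripheral enzyme blockade.
#' `defaultTissueKinetics()` (K1 = 0.1, k2 = 0.3, k3 = 0.03,
#' kLoss = 0.01 /min) and `defaultReferenceKinetics()` (K1r = 0.1,
#' k2r = 0.3 /min) produce striatum-to-cerebellum SUVr of about 2-2.7 over
#' 50-85 min with a slowly flattening late scan. All are configuration, not
#' constants.
#'
#' @return a [PlasmaInput-class], [TissueKinetics-class] or
#'   [ReferenceKinetics-class].
#' @export
defaultPlasmaInput <- function() {
  plasmaInput(A1 = 600, A2 = 30, A3 = 25, lambda1 = 4, lambda2 = 0.5,
              lambda3 = 0.004, delay = 0.5)
}

#' @rdname defaultPlasmaInput
#' @export
defaultTissueKinetics <- function() tissueKinetics(0.1, 0.3, 0.03, 0.01)

#' @rdname defaultPlasmaInput
#' @export
defaultReferenceKinetics <- function() referenceKinetics(0.1, 0.3)

#' Construct tissue kinetic parameters
#'
#' @param K1,k2,k3,kLoss rate constants in 1/min (see
#'   [TissueKinetics-class]).
#' @return a [TissueKinetics-class].
#' @export
tissueKinetics <- function(K1, k2, k3, kLoss) {
  new("TissueKinetics", K1 = as.numeric(K1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), kLoss = as.numeric(kLoss))
}

#' @rdname tissueKinetics
#' @param K1r,k2r reference-region rate constants in 1/min.
#' @export
referenceKinetics <- function(K1r, k2r) {
  new("ReferenceKinetics", K1r = as.numeric(K1r), k2r = as.numeric(k2r))
}

#' Evaluate the plasma input function
#'
#' @param input a [PlasmaInput-class].
#' @param tMin times in minutes from injection.
#' @return plasma activity concentration, kBq/mL (0 before the delay; any
#'   residual negative excursion is clipped at 0).
#' @export
plasmaInputCurve <- function(input, tMin) {
  stopifnot(is(input, "PlasmaInput"))
  tau <- pmax(tMin - input@delay, 0)
  cp <- .epEval(.epPlasma(input), tau)
  cp[tMin < input@delay] <- 0
  pmax(cp, 0)
}

## Target-tissue total activity as ep terms on tau = t - delay (minutes).
.epTarget <- function(kin, input) {
  cp <- .epPlasma(input)
  c1 <- .epScale(.epConvExp(cp, kin@k2 + kin@k3), kin@K1)
  if (kin@k3 == 0) return(c1)
  c2 <- .epScale(.epConvExp(c1, kin@kLoss), kin@k3)
  .epMerge(rbind(c1, c2))
}

.epReference <- function(kin, input) {
  .epScale(.epConvExp(.epPlasma(input), kin@k2r), kin@K1r)
}

#' @rdname simulateRegion
#' @export
setMethod("simulateRegion", "TissueKinetics",
  function(kin, input, schedule, regionLabel = "striatum") {
    stopifnot(is(input, "PlasmaInput"), is(schedule, "FrameSchedule"))
    act <- .epFrameAverage(.epTarget(kin, input), schedule@starts / 60,
                           (schedule@starts + schedule@durations) / 60,
                           input@delay)
    timeActivityCurve(schedule, act, regionLabel = regionLabel,
                      decayCorrected = TRUE)
  })

#' @rdname simulateRegion
#' @export
setMethod("simulateRegion", "ReferenceKinetics",
  function(kin, input, schedule, regionLabel = "cerebellum") {
    stopifnot(is(input, "PlasmaInput"), is(schedule, "FrameSchedule"))
    act <- .epFrameAverage(.epReference(kin, input), schedule@starts / 60,
                           (schedule@starts + schedule@durations) / 60,
                           input@delay)
    timeActivityCurve(schedule, act, regionLabel = regionLabel,
                      decayCorrected = TRUE)
  })

#' Add frame-weighted Gaussian measurement noise to a TAC
#'
#' Adds independent zero-mean Gaussian noise per frame with standard
#' deviation
#' \deqn{\sigma_i = s \sqrt{\max(A_i, 0) \cdot 2^{t_i / T_{1/2}} / \Delta_i}}
#' where \eqn{A_i} is the frame activity, \eqn{t_i} the frame mid-time,
#' \eqn{\Delta_i} the frame duration and \eqn{s} the noise scale. Simulated
#' activities are decay-corrected (as scanner output is); the
#' \eqn{2^{t/T_{1/2}}} factor reinstates the count loss from physical decay,
#' so late frames are noisier, as in real dynamic PET.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param noiseScale unitless scale, >= 0 (0 returns the input unchanged).
#' @param halfLifeS isotope half-life in seconds.
#' @param seed optional integer; when given, the RNG state is set for this
#'   call and restored afterwards, making the call reproducible in
#'   isolation.
#' @return a [TimeActivityCurve-class] with noisy activities (which may be
#'   negative; downstream operations propagate them unclipped).
#' @export
addNoise <- function(tac, noiseScale, halfLifeS = F18_HALF_LIFE_S,
                     seed = NULL) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (!is.finite(noiseScale) || noiseScale < 0)
    stop("noiseScale must be >= 0")
  if (noiseScale == 0) return(tac)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  mid <- midTimes(tac@schedule)
  sdv <- noiseScale * sqrt(pmax(tac@activity, 0) * 2^(mid / halfLifeS) /
                             tac@schedule@durations)
  initialize(tac, activity = tac@activity + stats::rnorm(length(sdv), 0, sdv))
}

#' Closed-form asymptotic endpoint values of the simulation model
#'
#' The exact large-time limits of the three graphical estimators for the
#' linear compartment model used by [simulateRegion()]:
#' \deqn{K_i = \frac{K_1 k_3}{k_2 + k_3} \cdot \frac{k_{2r}}{K_{1r}}}
#' (reference-normalized net influx, the Patlak slope for the irreversible
#' system, kLoss = 0),
#' \deqn{DVR = \frac{K_1}{k_2 + k_3}\left(1 + \frac{k_3}{k_{loss}}\right)
#'   \cdot \frac{k_{2r}}{K_{1r}}}
#' (ratio of total distribution volumes, the Logan slope), and
#' \deqn{EDVR = DVR - 1}
#' (the Logan slope after reference subtraction, since distribution volumes
#' are additive). When the reference matches the target's nondisplaceable
#' uptake (K1r/k2r = K1/k2) and kLoss is much smaller than k2, the EDVR
#' reduces to the familiar interpretation
#' \eqn{(k_3/k_{loss}) \cdot k_2/(k_2+k_3)}: the ratio of specific to
#' precursor distribution volumes reduced by the factor k2/(k2+k3).
#'
#' @param kin a [TissueKinetics-class]; `kLoss` must be positive for a
#'   finite DVR and EDVR (`Ki` describes the irreversible, kLoss = 0
#'   interpretation and never involves kLoss).
#' @param ref a [ReferenceKinetics-class].
#' @return named list with `Ki` (1/min), `DVR` and `EDVR` (unitless).
#' @export
analyticTargets <- function(kin, ref) {
  stopifnot(is(kin, "TissueKinetics"), is(ref, "ReferenceKinetics"))
  ki <- kin@K1 * kin@k3 * ref@k2r / ((kin@k2 + kin@k3) * ref@K1r)
  if (kin@k3 > 0 && kin@kLoss == 0)
    stop("kLoss is zero: the trapped pool has infinite distribution volume, DVR/EDVR undefined")
  dvr <- if (kin@k3 == 0) {
    kin@K1 / kin@k2 * ref@k2r / ref@K1r
  } else {
    kin@K1 / (kin@k2 + kin@k3) * (1 + kin@k3 / kin@kLoss) * ref@k2r / ref@K1r
  }
  list(Ki = ki, DVR = dvr, EDVR = dvr - 1)
}
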