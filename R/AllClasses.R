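#' @import methods
NULL

#' Physical half-life of fluorine-18 in seconds
#'
#' Standard physical constant (109.77 min), used as the default half-life for
#' decay correction and for the decay-weighted noise model.
#'
#' @format A length-one numeric, seconds.
#' @export
F18_HALF_LIFE_S <- 109.77 * 60

.GENOTYPES <- c("WT", "G51D/+", "G51D/G51D")

#' FrameSchedule: timing grid of a dynamic PET acquisition
#'
#' Frame start times and durations in seconds from injection. Frame mid-times
#' (start + duration/2) are the abscissa used by all kinetic analyses.
#'
#' @slot starts numeric, frame start times (s), strictly increasing.
#' @slot durations numeric, frame durations (s), all positive; frames must not
#'   overlap.
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"),
  validity = function(object) {
    s <- object@starts; d <- object@durations
    if (length(s) == 0L) return("schedule must contain at least one frame")
    if (length(s) != length(d)) return("starts and durations differ in length")
    if (!all(is.finite(s)) || !all(is.finite(d))) return("non-finite frame times")
    if (any(d <= 0)) return("all frame durations must be positive")
    if (length(s) > 1L) {
      if (any(diff(s) <= 0)) return("frame starts must be strictly increasing")
      if (any(s[-1L] < (s + d)[-length(s)] - 1e-9)) return("frames must not overlap")
    }
    TRUE
  })

#' TimeActivityCurve: region activity per frame
#'
#' Radioactivity concentration (kBq/mL) in one region for each frame of a
#' dynamic scan. Negative values are permitted (simulated noise must propagate
#' unclipped through SUV and graphical transforms, so that noise stays
#' symmetric and graphical slopes unbiased).
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, kBq/mL, one value per frame.
#' @slot regionLabel character scalar naming the region.
#' @slot decayCorrected logical; whether values are decay-corrected to a
#'   common reference time (scanner output convention).
#' @export
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", activity = "numeric",
                 regionLabel = "character", decayCorrected = "logical"),
  validity = function(object) {
    if (length(object@activity) != length(object@schedule@starts))
      return("activity length must equal the number of frames")
    if (!all(is.finite(object@activity))) return("activity must be finite")
    if (length(object@regionLabel) != 1L) return("regionLabel must be a scalar")
    if (length(object@decayCorrected) != 1L || is.na(object@decayCorrected))
      return("decayCorrected must be TRUE or FALSE")
    TRUE
  })

#' SUVCurve: standardized uptake values per frame
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot suv numeric, g/mL, one value per frame.
#' @export
setClass("SUVCurve",
  representation(schedule = "FrameSchedule", suv = "numeric"),
  validity = function(object) {
    if (length(object@suv) != length(object@schedule@starts))
      return("suv length must equal the number of frames")
    TRUE
  })

#' SubjectMeta: per-animal scan metadata
#'
#' @slot subjectId character scalar.
#' @slot genotype one of "WT", "G51D/+", "G51D/G51D".
#' @slot ageMonths numeric, months.
#' @slot weightKg numeric, kg, positive.
#' @slot injectedDoseMBq numeric, MBq decay-corrected to injection time,
#'   positive.
#' @export
setClass("SubjectMeta",
  representation(subjectId = "character", genotype = "character",
                 ageMonths = "numeric", weightKg = "numeric",
                 injectedDoseMBq = "numeric"),
  validity = function(object) {
    if (!object@genotype %in% .GENOTYPES)
      return(sprintf("genotype must be one of: %s", paste(.GENOTYPES, collapse = ", ")))
    if (!is.finite(object@weightKg) || object@weightKg <= 0)
      return("weightKg must be positive")
    if (!is.finite(object@injectedDoseMBq) || object@injectedDoseMBq <= 0)
      return("injectedDoseMBq must be positive")
    TRUE
  })

#' GraphicalFit: a fitted Patlak or Logan transform
#'
#' Ordinary least-squares fit of the transformed coordinates over the frames
#' whose mid-times fall inside the fit window. Slope and intercept are in the
#' transform's native units (time in seconds).
#'
#' @slot slope,intercept numeric, model-dependent units.
#' @slot rSquared numeric in [0, 1].
#' @slot nPoints integer, number of frames fitted (>= 2).
#' @slot tStarS,endS numeric, fit window bounds (s), inclusive on mid-times.
#' @slot x,y numeric, the transformed coordinates used in the fit.
#' @export
setClass("GraphicalFit",
  representation(slope = "numeric", intercept = "numeric", rSquared = "numeric",
                 nPoints = "integer", tStarS = "numeric", endS = "numeric",
                 x = "numeric", y = "numeric"),
  validity = function(object) {
    if (object@nPoints < 2L) return("a graphical fit needs at least 2 points")
    if (!is.na(object@rSquared) && (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
      return("rSquared must lie in [0, 1]")
    TRUE
  })

#' PatlakResult: reference-tissue Patlak analysis outcome
#'
#' @slot fit a [GraphicalFit-class]; the slope is in 1/s.
#' @slot Ki numeric, net influx rate constant in 1/min (slope * 60).
#' @export
setClass("PatlakResult",
  representation(fit = "GraphicalFit", Ki = "numeric"),
  validity = function(object)
    if (!is.finite(object@Ki)) "Ki must be finite" else TRUE)

#' LoganResult: reference-tissue Logan analysis outcome
#'
#' @slot fit a [GraphicalFit-class].
#' @slot DVR numeric, unitless distribution volume ratio (the slope).
#' @export
setClass("LoganResult",
  representation(fit = "GraphicalFit", DVR = "numeric"),
  validity = function(object)
    if (!is.finite(object@DVR)) "DVR must be finite" else TRUE)

#' EDVRResult: effective-DVR analysis outcome
#'
#' Logan reference-tissue analysis applied to the specific TAC
#' (striatum minus cerebellum). The inverse of the EDVR estimates the
#' effective dopamine turnover.
#'
#' @slot fit a [GraphicalFit-class].
#' @slot EDVR numeric, unitless (the slope).
#' @slot effectiveTurnover numeric, 1/EDVR.
#' @export
setClass("EDVRResult",
  representation(fit = "GraphicalFit", EDVR = "numeric",
                 effectiveTurnover = "numeric"),
  validity = function(object) {
    if (!is.finite(object@EDVR)) return("EDVR must be finite")
    if (object@EDVR != 0 &&
        abs(object@EDVR * object@effectiveTurnover - 1) > 1e-9)
      return("effectiveTurnover must equal 1/EDVR")
    TRUE
  })

#' PlasmaInput: tri-exponential bolus input function
#'
#' Feng-type model of the arterial tracer concentration after a bolus:
#' for t >= delay, with s = t - delay,
#' Cp(s) = (A1 s - A2 - A3) exp(-lambda1 s) + A2 exp(-lambda2 s)
#'       + A3 exp(-lambda3 s), and 0 before the delay. The parameterization is
#' continuous at onset (Cp(delay) = 0).
#'
#' @slot A1 numeric, kBq/mL/min. @slot A2,A3 numeric, kBq/mL.
#' @slot lambda1,lambda2,lambda3 numeric, 1/min, with
#'   lambda1 > lambda2 > lambda3 > 0.
#' @slot delay numeric, min, appearance delay (>= 0).
#' @export
setClass("PlasmaInput",
  representation(A1 = "numeric", A2 = "numeric", A3 = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
                 delay = "numeric"),
  validity = function(object) {
    with_slots <- c(object@A1, object@A2, object@A3, object@lambda1,
                    object@lambda2, object@lambda3, object@delay)
    if (!all(is.finite(with_slots))) return("all parameters must be finite")
    if (!(object@lambda1 > object@lambda2 && object@lambda2 > object@lambda3 &&
          object@lambda3 > 0))
      return("need lambda1 > lambda2 > lambda3 > 0")
    if (object@delay < 0) return("delay must be non-negative")
    s <- seq(0, 240, by = 0.05)
    cp <- (object@A1 * s - object@A2 - object@A3) * exp(-object@lambda1 * s) +
      object@A2 * exp(-object@lambda2 * s) + object@A3 * exp(-object@lambda3 * s)
    if (min(cp) < -1e-9 * max(abs(cp)))
      return("Cp(t) must be non-negative over the scan interval")
    TRUE
  })

#' TissueKinetics: two-tissue irreversible-plus-loss striatal model
#'
#' Rate constants of the linear target-tissue model
#' dC1/dt = K1 Cp - (k2 + k3) C1 (precursor pool) and
#' dC2/dt = k3 C1 - kLoss C2 (specific, trapped pool), with total tissue
#' activity C1 + C2. k3 is the AADC trapping step; kLoss is the slow egress
#' of metabolized tracer from the specific compartment.
#'
#' @slot K1 numeric, 1/min, plasma-to-precursor transfer (>= 0).
#' @slot k2 numeric, 1/min, precursor efflux (>= 0).
#' @slot k3 numeric, 1/min, trapping (>= 0); k2 + k3 must be positive.
#' @slot kLoss numeric, 1/min, specific-compartment egress (>= 0; must be
#'   positive for finite DVR/EDVR).
#' @export
setClass("TissueKinetics",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 kLoss = "numeric"),
  validity = function(object) {
    v <- c(object@K1, object@k2, object@k3, object@kLoss)
    if (!all(is.finite(v)) || any(v < 0)) return("rates must be finite and >= 0")
    if (object@k2 + object@k3 <= 0) return("k2 + k3 must be positive")
    TRUE
  })

#' ReferenceKinetics: one-tissue cerebellar model
#'
#' The cerebellum carries no specific dopaminergic signal and is modelled as a
#' single reversible compartment, dCr/dt = K1r Cp - k2r Cr.
#'
#' @slot K1r,k2r numeric, 1/min, both positive.
#' @export
setClass("ReferenceKinetics",
  representation(K1r = "numeric", k2r = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@K1r, object@k2r))) ||
        object@K1r <= 0 || object@k2r <= 0)
      return("K1r and k2r must be positive")
    TRUE
  })

#' CohortDesign: layout and effects of a simulated study cohort
#'
#' @slot genotypes character, genotype levels simulated.
#' @slot agesMonths numeric, age groups (months).
#' @slot nPerCell integer, animals per genotype-by-age cell (>= 1).
#' @slot effectMap data.frame with columns genotype, age_months, edvr_mult
#'   (multiplicative EDVR effect applied through kLoss) and lr_kloss_ratio
#'   (left/right kLoss ratio encoding striatal asymmetry); multipliers > 0.
#' @slot noiseScale numeric, unitless scale of the frame-duration/decay
#'   weighted Gaussian noise model.
#' @slot subjectCV numeric, coefficient of variation of the log-normal
#'   between-animal jitter on all rate constants.
#' @slot seed integer, RNG seed making the cohort fully reproducible.
#' @export
setClass("CohortDesign",
  representation(genotypes = "character", agesMonths = "numeric",
                 nPerCell = "integer", effectMap = "data.frame",
                 noiseScale = "numeric", subjectCV = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nPerCell < 1L) return("nPerCell must be >= 1")
    if (!all(object@genotypes %in% .GENOTYPES)) return("unknown genotype level")
    need <- c("genotype", "age_months", "edvr_mult", "lr_kloss_ratio")
    if (!all(need %in% names(object@effectMap)))
      return(sprintf("effectMap needs columns: %s", paste(need, collapse = ", ")))
    if (any(object@effectMap$edvr_mult <= 0) ||
        any(object@effectMap$lr_kloss_ratio <= 0))
      return("effect multipliers must be positive")
    if (object@noiseScale < 0) return("noiseScale must be >= 0")
    if (object@subjectCV < 0) return("subjectCV must be >= 0")
    TRUE
  })

#' Cohort: simulated subjects with TACs and metadata
#'
#' @slot meta data.frame, one row per subject (subject_id, genotype,
#'   age_months, weight_kg, injected_dose_MBq).
#' @slot tacs named list (by subject id) of named lists (by region) of
#'   [TimeActivityCurve-class] objects.
#' @slot truth data.frame of per-subject ground-truth kinetic parameters and
#'   analytic endpoint values (empty for cohorts read back from disk).
#' @slot design the [CohortDesign-class] used.
#' @export
setClass("Cohort",
  representation(meta = "data.frame", tacs = "list", truth = "data.frame",
                 design = "CohortDesign"),
  validity = function(object) {
    if (nrow(object@meta) != length(object@tacs))
      return("meta and tacs must describe the same subjects")
    if (!identical(sort(object@meta$subject_id), sort(names(object@tacs))))
      return("tacs must be named by subject_id")
    TRUE
  })

#' DynamicImage: 4D dynamic PET image
#'
#' @slot voxels 4D numeric array (x, y, z, frame), kBq/mL.
#' @slot voxelSizeMm numeric length 3, voxel edge lengths (mm), positive.
#' @slot schedule a [FrameSchedule-class]; its frame count must match the
#'   fourth array dimension.
#' @export
setClass("DynamicImage",
  representation(voxels = "array", voxelSizeMm = "numeric",
                 schedule = "FrameSchedule"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 4L) return("voxels must be a 4D array")
    if (dim(object@voxels)[4L] != length(object@schedule@starts))
      return("frame axis must match the schedule frame count")
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      return("voxelSizeMm must be 3 positive values")
    TRUE
  })

#' RegionMask: 3D volume-of-interest mask
#'
#' @slot voxels 3D logical array on the same grid as the image it is applied
#'   to; at least one voxel must be TRUE.
#' @slot label character scalar, e.g. "left_striatum", "right_striatum",
#'   "whole_striatum", "cerebellum".
#' @export
setClass("RegionMask",
  representation(voxels = "array", label = "character"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@voxels)) return("mask voxels must be logical")
    if (!any(object@voxels)) return("mask must contain at least one voxel")
    if (length(object@label) != 1L) return("label must be a scalar")
    TRUE
  })
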