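#' @rdname FrameSchedule-class
#' @param x,object an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("midTimes", function(x) standardGeneric("midTimes"))

#' @rdname TimeActivityCurve-class
#' @param x an object.
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("isDecayCorrected", function(x) standardGeneric("isDecayCorrected"))

#' Schedule accessor
#' @param x an object carrying a frame schedule.
#' @return the [FrameSchedule-class] of `x`.
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname SUVCurve-class
#' @param x an object.
#' @export
setGeneric("suv", function(x) standardGeneric("suv"))

#' @rdname GraphicalFit-class
#' @param x an object containing a graphical fit.
#' @export
setGeneric("graphicalFit", function(x) standardGeneric("graphicalFit"))

#' Simulate a noise-free regional time-activity curve
#'
#' Solves the linear compartment model exactly (closed-form
#' exponential-polynomial solution) for the given plasma input and returns the
#' frame-averaged tissue activity, i.e. the mean of the continuous solution
#' over each frame rather than point samples.
#'
#' @param kin a [TissueKinetics-class] (two-tissue striatal model) or
#'   [ReferenceKinetics-class] (one-tissue cerebellar model).
#' @param input a [PlasmaInput-class].
#' @param schedule a [FrameSchedule-class] (seconds).
#' @param regionLabel label recorded on the returned curve.
#' @return a decay-corrected [TimeActivityCurve-class].
#' @examples
#' tac <- simulateRegion(defaultTissueKinetics(), defaultPlasmaInput(),
#'                       buildSchedule(rep(300, 24)))
#' @export
setGeneric("simulateRegion",
  function(kin, input, schedule, regionLabel = "region")
    standardGeneric("simulateRegion"))
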