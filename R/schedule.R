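#' Build a contiguous frame schedule from frame durations
#'
#' Frames are laid end to end starting at the moment of injection (t = 0), the
#' convention of dynamic small-animal PET acquisitions.
#'
#' @param durations numeric vector of frame durations in seconds, all
#'   positive.
#' @return a [FrameSchedule-class].
#' @examples
#' sched <- buildSchedule(c(rep(30, 6), rep(60, 3), rep(120, 2), rep(300, 22)))
#' sum(frameDurations(sched))  # 7200 s, a 2-h scan
#' @export
buildSchedule <- function(durations) {
  if (length(durations) == 0L) stop("durations must be non-empty")
  if (!all(is.finite(durations)) || any(durations <= 0))
    stop("all frame durations must be positive")
  starts <- cumsum(c(0, durations[-length(durations)]))
  new("FrameSchedule", starts = as.numeric(starts),
      durations = as.numeric(durations))
}

#' The 2-hour study acquisition schedule
#'
#' 6 frames of 30 s, 3 frames of 60 s, 2 frames of 120 s and 22 frames of
#' 300 s: 33 contiguous frames spanning 7200 s.
#'
#' @return a [FrameSchedule-class] with 33 frames.
#' @export
studyFrameSchedule <- function() {
  buildSchedule(c(rep(30, 6), rep(60, 3), rep(120, 2), rep(300, 22)))
}

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@starts))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@starts)

#' @rdname FrameSchedule-class
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)

#' @rdname FrameSchedule-class
#' @export
setMethod("midTimes", "FrameSchedule", function(x) x@starts + x@durations / 2)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f-%.0f s (total %.0f s)\n",
              nFrames(object), object@starts[1L],
              object@starts[nFrames(object)] + object@durations[nFrames(object)],
              sum(object@durations)))
  invisible(NULL)
})

.sameSchedule <- function(a, b, tol = 1e-9) {
  length(a@starts) == length(b@starts) &&
    all(abs(a@starts - b@starts) <= tol) &&
    all(abs(a@durations - b@durations) <= tol)
}

#' Frames inside a graphical-analysis fit window
#'
#' Returns the indices of all frames whose mid-time lies in
#' `[tStarS, endS]`, inclusive at both ends. Mid-times are the standard
#' abscissa for frame-averaged data and match the grid used by
#' [cumulativeIntegral()].
#'
#' @param schedule a [FrameSchedule-class].
#' @param tStarS,endS window bounds in seconds, `tStarS < endS`.
#' @return integer vector of frame indices; an empty window is an error.
#' @export
fitWindowFrames <- function(schedule, tStarS, endS) {
  stopifnot(is(schedule, "FrameSchedule"))
  if (!is.finite(tStarS) || !is.finite(endS) || tStarS >= endS)
    stop("need tStarS < endS")
  mid <- midTimes(schedule)
  idx <- which(mid >= tStarS & mid <= endS)
  if (length(idx) == 0L)
    stop(sprintf("no frame mid-times inside [%g, %g] s", tStarS, endS))
  idx
}
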