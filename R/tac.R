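#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity numeric, kBq/mL, one value per frame.
#' @param regionLabel region name recorded on the curve.
#' @param decayCorrected whether the values are decay-corrected to a common
#'   reference time (TRUE for typical scanner output).
#' @return a [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, activity, regionLabel = "region",
                              decayCorrected = TRUE) {
  new("TimeActivityCurve", schedule = schedule,
      activity = as.numeric(activity), regionLabel = regionLabel,
      decayCorrected = decayCorrected)
}

#' Construct subject metadata
#'
#' @param subjectId subject identifier.
#' @param genotype one of "WT", "G51D/+", "G51D/G51D".
#' @param ageMonths age in months.
#' @param weightKg body weight in kg (positive).
#' @param injectedDoseMBq injected activity in MBq, decay-corrected to
#'   injection time (positive).
#' @return a [SubjectMeta-class].
#' @export
subjectMeta <- function(subjectId, genotype, ageMonths, weightKg,
                        injectedDoseMBq) {
  new("SubjectMeta", subjectId = as.character(subjectId), genotype = genotype,
      ageMonths = as.numeric(ageMonths), weightKg = as.numeric(weightKg),
      injectedDoseMBq = as.numeric(injectedDoseMBq))
}

#' @rdname TimeActivityCurve-class
#' @export
setMethod("activity", "TimeActivityCurve", function(x) x@activity)

#' @rdname TimeActivityCurve-class
#' @export
setMethod("regionLabel", "TimeActivityCurve", function(x) x@regionLabel)

#' @rdname TimeActivityCurve-class
#' @export
setMethod("isDecayCorrected", "TimeActivityCurve", function(x) x@decayCorrected)

#' @rdname schedule
#' @export
setMethod("schedule", "TimeActivityCurve", function(x) x@schedule)

#' @rdname schedule
#' @export
setMethod("schedule", "SUVCurve", function(x) x@schedule)

#' @rdname SUVCurve-class
#' @export
setMethod("suv", "SUVCurve", function(x) x@suv)

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s': %d frames, %sdecay-corrected\n",
              object@regionLabel, nFrames(object@schedule),
              if (object@decayCorrected) "" else "not "))
  cat(sprintf("  activity range %.3g to %.3g kBq/mL\n",
              min(object@activity), max(object@activity)))
  invisible(NULL)
})

#' Decay-correct (or un-correct) a time-activity curve
#'
#' `decayCorrect` rescales each frame by `2^((mid - toTimeS)/halfLifeS)`,
#' referring all activities to the common time `toTimeS` (typically
#' injection, 0 s). `decayUncorrect` applies the inverse and is the exact
#' round-trip inverse. Correction state is tracked on the object and
#' double application is an error.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param halfLifeS physical half-life in seconds (default fluorine-18,
#'   [F18_HALF_LIFE_S]).
#' @param toTimeS reference time in seconds (default 0, injection).
#' @return a [TimeActivityCurve-class] with the flag updated.
#' @export
decayCorrect <- function(tac, halfLifeS = F18_HALF_LIFE_S, toTimeS = 0) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (!is.finite(halfLifeS) || halfLifeS <= 0) stop("halfLifeS must be positive")
  if (tac@decayCorrected)
    stop("TAC is already decay-corrected; double correction refused")
  f <- 2^((midTimes(tac@schedule) - toTimeS) / halfLifeS)
  initialize(tac, activity = tac@activity * f, decayCorrected = TRUE)
}

#' @rdname decayCorrect
#' @export
decayUncorrect <- function(tac, halfLifeS = F18_HALF_LIFE_S, toTimeS = 0) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (!is.finite(halfLifeS) || halfLifeS <= 0) stop("halfLifeS must be positive")
  if (!tac@decayCorrected)
    stop("TAC is not decay-corrected; nothing to undo")
  f <- 2^((midTimes(tac@schedule) - toTimeS) / halfLifeS)
  initialize(tac, activity = tac@activity / f, decayCorrected = FALSE)
}

#' Running integral of a time-activity curve
#'
#' Trapezoidal integration on the frame mid-times, with an initial triangle
#' from (0, 0) to the first mid-point. This zero-anchored trapezoid rule is
#' the standard quadrature for graphical analysis and is exact for
#' piecewise-linear curves.
#'
#' @param tac a [TimeActivityCurve-class].
#' @return numeric vector, the integral (kBq s/mL) from time 0 to each frame
#'   mid-time.
#' @export
cumulativeIntegral <- function(tac) {
  stopifnot(is(tac, "TimeActivityCurve"))
  mid <- midTimes(tac@schedule)
  a <- tac@activity
  n <- length(a)
  seg <- c(mid[1L] * a[1L] / 2,
           if (n > 1L) diff(mid) * (a[-1L] + a[-n]) / 2)
  cumsum(seg)
}

#' Standardized uptake value curve
#'
#' SUV (g/mL) = activity concentration in the VOI (kBq/mL) divided by
#' injected dose (MBq) per body weight (kg). Negative activities (from
#' simulated noise) propagate unchanged; clipping would bias downstream
#' graphical slopes.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param meta a [SubjectMeta-class] supplying dose and weight.
#' @return an [SUVCurve-class].
#' @examples
#' sched <- buildSchedule(c(60, 60))
#' tac <- timeActivityCurve(sched, c(5, 5))
#' m <- subjectMeta("r1", "WT", 5, weightKg = 0.37, injectedDoseMBq = 18.5)
#' suv(computeSUV(tac, m))  # 0.1 g/mL per frame
#' @export
computeSUV <- function(tac, meta) {
  stopifnot(is(tac, "TimeActivityCurve"), is(meta, "SubjectMeta"))
  new("SUVCurve", schedule = tac@schedule,
      suv = tac@activity / (meta@injectedDoseMBq / meta@weightKg))
}

#' SUV ratio of a target region to a reference region
#'
#' Elementwise target/reference SUV per frame. Frames where the reference is
#' not positive are returned as NA with a warning rather than silently
#' divided.
#'
#' @param target,reference [SUVCurve-class] objects on the same schedule.
#' @return numeric vector of unitless SUVr values, one per frame.
#' @export
suvRatio <- function(target, reference) {
  stopifnot(is(target, "SUVCurve"), is(reference, "SUVCurve"))
  if (!.sameSchedule(target@schedule, reference@schedule))
    stop("target and reference must share a frame schedule")
  out <- target@suv / reference@suv
  bad <- !(reference@suv > 0)
  if (any(bad)) {
    warning(sprintf("reference SUV not positive in %d frame(s); returned NA",
                    sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Locate the pseudo-equilibrium window of an SUVr curve
#'
#' Finds the longest contiguous run of at least 3 frames whose local linear
#' slope magnitude does not exceed `slopeTol`. The local slope at each frame
#' is the least-squares slope over that frame and its immediate neighbours
#' (one-sided at the scan ends), on mid-times in minutes.
#'
#' @param suvr numeric vector of SUVr values, one per frame.
#' @param schedule the matching [FrameSchedule-class].
#' @param slopeTol slope tolerance in SUVr units per minute. The default
#'   0.02/min is roughly 1% per minute of a typical late-scan striatal SUVr.
#' @return named numeric `c(startS, endS)` spanning the detected window
#'   (frame start of its first frame to frame end of its last), or `NULL`
#'   when no run of 3 frames qualifies.
#' @export
findPseudoEquilibrium <- function(suvr, schedule, slopeTol = 0.02) {
  stopifnot(is(schedule, "FrameSchedule"))
  n <- nFrames(schedule)
  if (length(suvr) != n) stop("suvr length must match the schedule")
  if (n < 3L) stop("need at least 3 frames")
  midMin <- midTimes(schedule) / 60
  localSlope <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - 1L):min(n, i + 1L)
    stats::cov(midMin[j], suvr[j]) / stats::var(midMin[j])
  }, numeric(1))
  ok <- abs(localSlope) <= slopeTol
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  cand <- which(r$values & r$lengths >= 3L)
  if (length(cand) == 0L) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  i1 <- ends[best] - r$lengths[best] + 1L
  i2 <- ends[best]
  c(startS = schedule@starts[i1],
    endS = schedule@starts[i2] + schedule@durations[i2])
}

#' Read and write time-activity curves as CSV
#'
#' Long-format interchange: one row per frame per region with columns
#' `frame_start_s`, `frame_duration_s`, `mid_time_s`, `activity_kBq_per_mL`,
#' `region`, `subject_id`.
#'
#' @param tacs a named list of [TimeActivityCurve-class] objects (names are
#'   ignored; region labels come from the curves).
#' @param subjectId subject identifier written to every row.
#' @param path CSV file path.
#' @return `writeTACs` returns `path` invisibly; `readTACs` returns a named
#'   list of [TimeActivityCurve-class] per region (decay-corrected assumed,
#'   the scanner-output convention recorded by this interface).
#' @export
writeTACs <- function(tacs, subjectId, path) {
  rows <- lapply(tacs, function(tac) {
    s <- tac@schedule
    data.frame(frame_start_s = s@starts, frame_duration_s = s@durations,
               mid_time_s = midTimes(s),
               activity_kBq_per_mL = tac@activity,
               region = tac@regionLabel, subject_id = subjectId)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeTACs
#' @export
readTACs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "activity_kBq_per_mL",
            "region")
  if (!all(need %in% names(df)))
    stop(sprintf("TAC CSV must contain columns: %s", paste(need, collapse = ", ")))
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$frame_start_s), ]
    sched <- new("FrameSchedule", starts = d$frame_start_s,
                 durations = d$frame_duration_s)
    timeActivityCurve(sched, d$activity_kBq_per_mL,
                      regionLabel = d$region[1L], decayCorrected = TRUE)
  })
  out[unique(df$region)]
}
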