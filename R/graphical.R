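#' @rdname GraphicalFit-class
#' @export
setMethod("graphicalFit", "PatlakResult", function(x) x@fit)

#' @rdname GraphicalFit-class
#' @export
setMethod("graphicalFit", "LoganResult", function(x) x@fit)

#' @rdname GraphicalFit-class
#' @export
setMethod("graphicalFit", "EDVRResult", function(x) x@fit)

setMethod("show", "GraphicalFit", function(object) {
  cat(sprintf("GraphicalFit: slope %.4g, intercept %.4g, R^2 %.4f (%d frames, %g-%g s)\n",
              object@slope, object@intercept, object@rSquared,
              object@nPoints, object@tStarS, object@endS))
  invisible(NULL)
})

setMethod("show", "PatlakResult", function(object) {
  cat(sprintf("Patlak reference-tissue analysis: Ki = %.5f /min (R^2 %.4f)\n",
              object@Ki, object@fit@rSquared))
  invisible(NULL)
})

setMethod("show", "LoganResult", function(object) {
  cat(sprintf("Logan reference-tissue analysis: DVR = %.4f (R^2 %.4f)\n",
              object@DVR, object@fit@rSquared))
  invisible(NULL)
})

setMethod("show", "EDVRResult", function(object) {
  cat(sprintf("EDVR analysis: EDVR = %.4f, effective turnover = %.4f (R^2 %.4f)\n",
              object@EDVR, object@effectiveTurnover, object@fit@rSquared))
  invisible(NULL)
})

## OLS of y on x with R^2; unweighted by design (graphical analyses here are
## fitted without weights).
.graphicalOLS <- function(x, y, tStarS, endS) {
  fit <- stats::.lm.fit(cbind(1, x), y)
  cf <- fit$coefficients
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else NA_real_
  r2 <- if (is.na(r2)) r2 else min(max(r2, 0), 1)
  new("GraphicalFit", slope = cf[2L], intercept = cf[1L],
      rSquared = r2, nPoints = length(x), tStarS = as.numeric(tStarS),
      endS = as.numeric(endS), x = x, y = y)
}

.checkPair <- function(target, reference) {
  stopifnot(is(target, "TimeActivityCurve"), is(reference, "TimeActivityCurve"))
  if (!.sameSchedule(target@schedule, reference@schedule))
    stop("target and reference must share a frame schedule")
}

#' Patlak reference-tissue graphical analysis
#'
#' Fits the Patlak transform
#' \deqn{C_T(t)/C_R(t) = K_i \int_0^t C_R \, d\tau / C_R(t) + b}
#' by ordinary least squares over the frames whose mid-times lie in
#' `[tStarS, endS]`, the linear regime of irreversible tracer uptake. The
#' study protocol uses 60 min of data with t* = 10 min. Internal time is in
#' seconds; the influx rate constant Ki is reported in 1/min (the field's
#' convention).
#'
#' @param target striatal [TimeActivityCurve-class].
#' @param reference cerebellar [TimeActivityCurve-class] (same schedule);
#'   must be positive on every frame in the window.
#' @param tStarS,endS fit window in seconds (defaults 600 and 3600).
#' @return a [PatlakResult-class].
#' @export
patlakReference <- function(target, reference, tStarS = 600, endS = 3600) {
  .checkPair(target, reference)
  idx <- fitWindowFrames(target@schedule, tStarS, endS)
  if (length(idx) < 2L) stop("need at least 2 frames in the fit window")
  cr <- reference@activity
  bad <- idx[!(cr[idx] > 0)]
  if (length(bad) > 0L)
    stop(sprintf("reference activity not positive in window frame(s): %s",
                 paste(bad, collapse = ", ")))
  intR <- cumulativeIntegral(reference)
  x <- intR[idx] / cr[idx]            # s
  y <- target@activity[idx] / cr[idx] # unitless
  fit <- .graphicalOLS(x, y, tStarS, endS)
  new("PatlakResult", fit = fit, Ki = fit@slope * 60)
}

#' Logan reference-tissue graphical analysis
#'
#' Fits the Logan transform
#' \deqn{\int_0^t C_T d\tau / C_T(t) = DVR \cdot \int_0^t C_R d\tau / C_T(t) + b}
#' over the frames whose mid-times lie in `[tStarS, endS]`; the slope is the
#' distribution volume ratio of target to reference. The study protocol uses
#' 120 min of data with t* = 30 min. The transform is the variant without the
#' reference-efflux correction term; supplying `k2PrimePerMin` adds the
#' standard \eqn{C_R/(k_2' C_T)} term to the abscissa as an opt-in.
#'
#' @param target target [TimeActivityCurve-class]; must be positive on every
#'   frame in the window.
#' @param reference reference [TimeActivityCurve-class] (same schedule).
#' @param tStarS,endS fit window in seconds (defaults 1800 and 7200).
#' @param k2PrimePerMin optional reference-tissue efflux constant (1/min)
#'   enabling the corrected abscissa; `NULL` (default) omits the term.
#' @return a [LoganResult-class].
#' @export
loganReference <- function(target, reference, tStarS = 1800, endS = 7200,
                           k2PrimePerMin = NULL) {
  .checkPair(target, reference)
  idx <- fitWindowFrames(target@schedule, tStarS, endS)
  if (length(idx) < 2L) stop("need at least 2 frames in the fit window")
  ct <- target@activity
  bad <- idx[!(ct[idx] > 0)]
  if (length(bad) > 0L)
    stop(sprintf("target activity not positive in window frame(s): %s",
                 paste(bad, collapse = ", ")))
  intT <- cumulativeIntegral(target)
  intR <- cumulativeIntegral(reference)
  x <- intR[idx] / ct[idx]
  if (!is.null(k2PrimePerMin)) {
    if (!is.finite(k2PrimePerMin) || k2PrimePerMin <= 0)
      stop("k2PrimePerMin must be positive")
    x <- x + reference@activity[idx] / ((k2PrimePerMin / 60) * ct[idx])
  }
  y <- intT[idx] / ct[idx]
  fit <- .graphicalOLS(x, y, tStarS, endS)
  new("LoganResult", fit = fit, DVR = fit@slope)
}

#' Effective distribution volume ratio (EDVR)
#'
#' Subtracts the cerebellar TAC from the striatal TAC elementwise and applies
#' the Logan reference-tissue analysis to the resulting specific TAC against
#' the cerebellum. The slope is the EDVR; its inverse estimates the effective
#' dopamine turnover, so a lower EDVR means faster turnover. Early frames of
#' the specific TAC may be negative (pre-equilibrium); only frames inside the
#' fit window must be positive.
#'
#' @param striatum,cerebellum [TimeActivityCurve-class] objects on the same
#'   schedule.
#' @param tStarS,endS fit window in seconds (defaults 1800 and 7200).
#' @return an [EDVRResult-class].
#' @export
edvr <- function(striatum, cerebellum, tStarS = 1800, endS = 7200) {
  .checkPair(striatum, cerebellum)
  specific <- initialize(striatum,
                         activity = striatum@activity - cerebellum@activity,
                         regionLabel = paste0(striatum@regionLabel, "-specific"))
  idx <- fitWindowFrames(striatum@schedule, tStarS, endS)
  if (all(specific@activity[idx] <= 0))
    stop("no specific binding signal: striatum - cerebellum <= 0 over the whole fit window")
  res <- loganReference(specific, cerebellum, tStarS = tStarS, endS = endS)
  if (res@DVR == 0) stop("degenerate EDVR of exactly 0")
  new("EDVRResult", fit = res@fit, EDVR = res@DVR,
      effectiveTurnover = 1 / res@DVR)
}

#' Tabulate graphical-analysis results
#'
#' Flattens Patlak/Logan/EDVR results to the long-format row used by the
#' cohort endpoint exports.
#'
#' @param result a [PatlakResult-class], [LoganResult-class] or
#'   [EDVRResult-class].
#' @param subjectId,region identifiers recorded in the row.
#' @return a one-row data.frame with columns subject_id, region, model,
#'   slope, intercept, r_squared, t_star_s, end_s, Ki_per_min, DVR, EDVR,
#'   effective_turnover (inapplicable entries NA).
#' @export
resultRow <- function(result, subjectId = NA_character_,
                      region = NA_character_) {
  fit <- graphicalFit(result)
  data.frame(subject_id = subjectId, region = region,
             model = switch(class(result),
                            PatlakResult = "patlak", LoganResult = "logan",
                            EDVRResult = "edvr"),
             slope = fit@slope, intercept = fit@intercept,
             r_squared = fit@rSquared, t_star_s = fit@tStarS,
             end_s = fit@endS,
             Ki_per_min = if (is(result, "PatlakResult")) result@Ki else NA_real_,
             DVR = if (is(result, "LoganResult")) result@DVR else NA_real_,
             EDVR = if (is(result, "EDVRResult")) result@EDVR else NA_real_,
             effective_turnover = if (is(result, "EDVRResult"))
               result@effectiveTurnover else NA_real_,
             stringsAsFactors = FALSE)
}

#' Endpoint accessors
#'
#' @param x a graphical-analysis result object.
#' @return the scalar endpoint value.
#' @name endpoints
NULL

#' @rdname endpoints
#' @export
setGeneric("Ki", function(x) standardGeneric("Ki"))
#' @rdname endpoints
#' @export
setMethod("Ki", "PatlakResult", function(x) x@Ki)

#' @rdname endpoints
#' @export
setGeneric("DVR", function(x) standardGeneric("DVR"))
#' @rdname endpoints
#' @export
setMethod("DVR", "LoganResult", function(x) x@DVR)

#' @rdname endpoints
#' @export
setGeneric("EDVR", function(x) standardGeneric("EDVR"))
#' @rdname endpoints
#' @export
setMethod("EDVR", "EDVRResult", function(x) x@EDVR)

#' @rdname endpoints
#' @export
setGeneric("effectiveTurnover", function(x) standardGeneric("effectiveTurnover"))
#' @rdname endpoints
#' @export
setMethod("effectiveTurnover", "EDVRResult", function(x) x@effectiveTurnover)
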