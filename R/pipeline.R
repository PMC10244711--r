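#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with the study protocol as
#' defaults: Patlak over 10-60 min, Logan and EDVR over 30-120 min, the
#' fluorine-18 half-life, a right-contralateral side convention for the
#' asymmetry index, and alpha = 0.05 for the group statistics.
#'
#' @param patlakTStarS,patlakEndS Patlak fit window, seconds.
#' @param loganTStarS,loganEndS Logan fit window, seconds.
#' @param edvrTStarS,edvrEndS EDVR fit window, seconds.
#' @param halfLifeS isotope half-life, seconds.
#' @param contralateral which striatal side is treated as contralateral by
#'   [asymmetryIndex()]: "right" (default) or "left". The study animals are
#'   unlesioned, so the mapping is a convention; it is echoed in every
#'   report.
#' @param alpha significance level for group statistics.
#' @return a list of class `"dopaPipelineConfig"`.
#' @export
pipelineConfig <- function(patlakTStarS = 600, patlakEndS = 3600,
                           loganTStarS = 1800, loganEndS = 7200,
                           edvrTStarS = 1800, edvrEndS = 7200,
                           halfLifeS = F18_HALF_LIFE_S,
                           contralateral = c("right", "left"),
                           alpha = 0.05) {
  contralateral <- match.arg(contralateral)
  for (w in list(c(patlakTStarS, patlakEndS), c(loganTStarS, loganEndS),
                 c(edvrTStarS, edvrEndS)))
    if (!all(is.finite(w)) || w[1L] >= w[2L])
      stop("every fit window needs tStar < end")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(patlakTStarS = patlakTStarS, patlakEndS = patlakEndS,
                 loganTStarS = loganTStarS, loganEndS = loganEndS,
                 edvrTStarS = edvrTStarS, edvrEndS = edvrEndS,
                 halfLifeS = halfLifeS, contralateral = contralateral,
                 alpha = alpha),
            class = "dopaPipelineConfig")
}

#' @export
print.dopaPipelineConfig <- function(x, ...) {
  cat(sprintf(paste0("dopaPET pipeline config: Patlak %g-%g s, Logan %g-%g s, ",
                     "EDVR %g-%g s, contralateral = %s, alpha = %g\n"),
              x$patlakTStarS, x$patlakEndS, x$loganTStarS, x$loganEndS,
              x$edvrTStarS, x$edvrEndS, x$contralateral, x$alpha))
  invisible(x)
}

.whole_striatum_tac <- function(left, right) {
  ## simulated cohorts carry no VOI volumes; the whole-striatum curve is the
  ## unweighted mean of the two sides (equal-volume assumption)
  initialize(left, activity = (left@activity + right@activity) / 2,
             regionLabel = "whole_striatum")
}

#' Fit kinetic endpoints for every subject of a cohort
#'
#' Runs Patlak (Ki), Logan (DVR) and EDVR analyses for the left, right and
#' whole striatum of each subject against its cerebellum, and computes the
#' left-right EDVR asymmetry index under the configured side convention.
#' Subjects with a missing region, or whose specific TAC cannot support a
#' fit (e.g. no positive specific signal in the EDVR window), are skipped
#' with a warning and counted in the `skipped` attribute. The computation is deterministic given its
#' inputs.
#'
#' @param cohort a [Cohort-class] (simulated or read from disk).
#' @param config a [pipelineConfig()].
#' @return data.frame with one row per subject and region
#'   (left/right/whole striatum): subject_id, genotype, age_months, region,
#'   Ki_per_min, DVR, EDVR, turnover, asymmetry (the per-subject asymmetry
#'   repeated on each of its rows), plus attributes `skipped` (count) and
#'   `contralateral`.
#' @export
fitCohort <- function(cohort, config = pipelineConfig()) {
  stopifnot(is(cohort, "Cohort"), inherits(config, "dopaPipelineConfig"))
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(cohort@meta))) {
    sid <- cohort@meta$subject_id[i]
    tacs <- cohort@tacs[[sid]]
    if (!all(c("left_striatum", "right_striatum", "cerebellum") %in%
               names(tacs))) {
      warning(sprintf("subject '%s' lacks a required region; skipped", sid))
      skipped <- skipped + 1L
      next
    }
    cer <- tacs$cerebellum
    striata <- list(left_striatum = tacs$left_striatum,
                    right_striatum = tacs$right_striatum,
                    whole_striatum = .whole_striatum_tac(tacs$left_striatum,
                                                         tacs$right_striatum))
    res <- tryCatch(
      lapply(striata, function(tac) {
        list(ki = patlakReference(tac, cer, config$patlakTStarS,
                                  config$patlakEndS),
             dvr = loganReference(tac, cer, config$loganTStarS,
                                  config$loganEndS),
             ed = edvr(tac, cer, config$edvrTStarS, config$edvrEndS))
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      ## e.g. a specific TAC without positive signal in the fit window
      warning(sprintf("subject '%s' not estimable (%s); skipped", sid,
                      conditionMessage(res)))
      skipped <- skipped + 1L
      next
    }
    edvrL <- res$left_striatum$ed@EDVR
    edvrR <- res$right_striatum$ed@EDVR
    asym <- if (config$contralateral == "right")
      asymmetryIndex(edvrR, edvrL) else asymmetryIndex(edvrL, edvrR)
    for (region in names(res))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, genotype = cohort@meta$genotype[i],
        age_months = cohort@meta$age_months[i], region = region,
        Ki_per_min = res[[region]]$ki@Ki, DVR = res[[region]]$dvr@DVR,
        EDVR = res[[region]]$ed@EDVR,
        turnover = res[[region]]$ed@effectiveTurnover,
        asymmetry = asym, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "contralateral") <- config$contralateral
  out
}

#' Group statistics over a cohort endpoint table
#'
#' For each age group: one-way ANOVA with Tukey HSD across genotypes on the
#' whole-striatum Ki, DVR and EDVR; a paired t test of left vs right EDVR
#' within each genotype; and normal Q-Q points for each whole-striatum
#' endpoint pooled across genotypes. Group cells too small to test are
#' listed under `insufficient` rather than failing the whole report.
#'
#' @param endpoints the data.frame from [fitCohort()].
#' @param config a [pipelineConfig()].
#' @return a nested list (class `"dopaGroupReport"`): one element per age
#'   with `anova` (per endpoint), `paired_lr_edvr` (per genotype), `qq`
#'   (per endpoint) and `insufficient`; the config is echoed in `$config`.
#' @export
reportGroups <- function(endpoints, config = pipelineConfig()) {
  stopifnot(is.data.frame(endpoints))
  if (length(unique(endpoints$genotype)) < 2L)
    stop("need at least 2 genotype groups to compare")
  ages <- sort(unique(endpoints$age_months))
  out <- list()
  for (age in ages) {
    sub <- endpoints[endpoints$age_months == age, ]
    whole <- sub[sub$region == "whole_striatum", ]
    ageRes <- list(anova = list(), paired_lr_edvr = list(), qq = list(),
                   insufficient = character(0))
    for (metric in c("Ki_per_min", "DVR", "EDVR")) {
      groups <- split(whole[[metric]], whole$genotype)
      groups <- groups[vapply(groups, length, 1L) > 0L]
      if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
        ageRes$insufficient <- c(ageRes$insufficient,
                                 sprintf("anova:%s", metric))
      } else {
        ageRes$anova[[metric]] <- anovaTukey(groups, alpha = config$alpha)
      }
      if (nrow(whole) >= 3L) ageRes$qq[[metric]] <- qqPoints(whole[[metric]])
    }
    for (gt in unique(sub$genotype)) {
      l <- sub$EDVR[sub$genotype == gt & sub$region == "left_striatum"]
      r <- sub$EDVR[sub$genotype == gt & sub$region == "right_striatum"]
      if (length(l) < 2L || length(l) != length(r)) {
        ageRes$insufficient <- c(ageRes$insufficient,
                                 sprintf("paired:%s", gt))
      } else {
        ageRes$paired_lr_edvr[[gt]] <- pairedT(l, r)
      }
    }
    out[[sprintf("age_%gm", age)]] <- ageRes
  }
  structure(list(by_age = out, config = unclass(config)),
            class = "dopaGroupReport")
}

#' @export
print.dopaGroupReport <- function(x, ...) {
  for (age in names(x$by_age)) {
    cat("==", age, "==\n")
    for (metric in names(x$by_age[[age]]$anova)) {
      a <- x$by_age[[age]]$anova[[metric]]
      cat(sprintf("  %s: F = %.3g, p = %.3g; significant pairs: %s\n",
                  metric, a$F_statistic, a$p_value,
                  if (any(a$pairwise$significant))
                    paste(a$pairwise$pair[a$pairwise$significant],
                          collapse = ", ") else "none"))
    }
    for (gt in names(x$by_age[[age]]$paired_lr_edvr)) {
      p <- x$by_age[[age]]$paired_lr_edvr[[gt]]
      cat(sprintf("  L/R EDVR %s: t(%d) = %.3g, p = %.3g\n", gt,
                  p$degrees_of_freedom, p$t_statistic, p$p_value))
    }
  }
  invisible(x)
}

#' Write pipeline outputs
#'
#' `writeEndpoints` writes the per-subject endpoint table as CSV;
#' `writeReport` serializes a group report (with the full config echo) as
#' JSON.
#'
#' @param endpoints data.frame from [fitCohort()].
#' @param report a `"dopaGroupReport"` from [reportGroups()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEndpoints <- function(endpoints, path) {
  utils::write.csv(endpoints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEndpoints
#' @export
writeReport <- function(report, path) {
  stopifnot(inherits(report, "dopaGroupReport"))
  strip <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
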