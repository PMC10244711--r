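.COHORT_REGIONS <- c("left_striatum", "right_striatum", "cerebellum")

#' Effect maps for simulated cohorts
#'
#' `defaultEffectMap()` encodes the study-like phenotype: a 0.7 multiplicative
#' EDVR effect (applied through a raised kLoss) in 16-month homozygotes, and
#' a left/right kLoss ratio of 1.2 (left striatum turning over faster, hence
#' lower left EDVR and a positive right-referenced asymmetry) in 5- and
#' 16-month homozygotes. `nullEffectMap()` sets every multiplier to 1
#' (no group differences), the configuration used for type-I-error checks.
#'
#' @param genotypes,agesMonths factor levels of the design grid.
#' @return data.frame with columns genotype, age_months, edvr_mult,
#'   lr_kloss_ratio.
#' @export
defaultEffectMap <- function(genotypes = c("WT", "G51D/+", "G51D/G51D"),
                             agesMonths = c(5, 11, 16)) {
  em <- expand.grid(genotype = genotypes, age_months = agesMonths,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  em$edvr_mult <- 1
  em$lr_kloss_ratio <- 1
  em$edvr_mult[em$genotype == "G51D/G51D" & em$age_months == 16] <- 0.7
  em$lr_kloss_ratio[em$genotype == "G51D/G51D" & em$age_months %in% c(5, 16)] <- 1.2
  em
}

#' @rdname defaultEffectMap
#' @export
nullEffectMap <- function(genotypes = c("WT", "G51D/+", "G51D/G51D"),
                          agesMonths = c(5, 11, 16)) {
  em <- defaultEffectMap(genotypes, agesMonths)
  em$edvr_mult <- 1
  em$lr_kloss_ratio <- 1
  em
}

#' Construct a cohort design
#'
#' The default design mirrors the study layout: 3 genotypes by 3 ages
#' (5, 11, 16 months) with 4 animals per cell, 36 subjects in total, with
#' the default effect map, 10% between-animal log-normal variability on all
#' rate constants and measurement-noise scale 0.1.
#'
#' @param genotypes genotype levels.
#' @param agesMonths age groups, months.
#' @param nPerCell animals per genotype-by-age cell.
#' @param effectMap see [defaultEffectMap()].
#' @param noiseScale unitless noise scale, see [addNoise()].
#' @param subjectCV between-animal coefficient of variation of the rate
#'   constants (log-normal, so rates stay positive).
#' @param seed integer RNG seed.
#' @return a [CohortDesign-class].
#' @export
cohortDesign <- function(genotypes = c("WT", "G51D/+", "G51D/G51D"),
                         agesMonths = c(5, 11, 16), nPerCell = 4,
                         effectMap = defaultEffectMap(genotypes, agesMonths),
                         noiseScale = 0.1, subjectCV = 0.1, seed = 1) {
  new("CohortDesign", genotypes = genotypes,
      agesMonths = as.numeric(agesMonths), nPerCell = as.integer(nPerCell),
      effectMap = effectMap, noiseScale = as.numeric(noiseScale),
      subjectCV = as.numeric(subjectCV), seed = as.integer(seed))
}

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %d genotypes x %d ages x %d per cell = %d subjects (seed %d)\n",
              length(object@genotypes), length(object@agesMonths),
              object@nPerCell,
              length(object@genotypes) * length(object@agesMonths) * object@nPerCell,
              object@seed))
  invisible(NULL)
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects, %d TACs (%s)\n", nrow(object@meta),
              sum(lengths(object@tacs)),
              paste(.COHORT_REGIONS, collapse = ", ")))
  invisible(NULL)
})

#' @rdname Cohort-class
#' @param x a [Cohort-class].
#' @export
cohortMeta <- function(x) { stopifnot(is(x, "Cohort")); x@meta }

#' @rdname Cohort-class
#' @export
cohortTruth <- function(x) { stopifnot(is(x, "Cohort")); x@truth }

#' @rdname Cohort-class
#' @param subjectId,region subject and region selectors.
#' @export
cohortTAC <- function(x, subjectId, region) {
  stopifnot(is(x, "Cohort"))
  sub <- x@tacs[[subjectId]]
  if (is.null(sub)) stop(sprintf("unknown subject '%s'", subjectId))
  tac <- sub[[region]]
  if (is.null(tac)) stop(sprintf("subject '%s' has no region '%s'", subjectId, region))
  tac
}

## log-normal multiplier with mean 1 and coefficient of variation cv
.lnJitter <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Simulate a full study-like cohort
#'
#' For every subject of the design, draws per-animal kinetic parameters:
#' a delivery multiplier shared by K1 and K1r, a nonspecific-efflux
#' multiplier shared by k2 and k2r, and independent multipliers for k3 and
#' kLoss, all log-normal around 1 with the design's coefficient of
#' variation. The shared rat-level factors reproduce how regional kinetics
#' co-vary within an animal, so the between-animal spread of the
#' reference-tissue endpoints stays close to the nominal CV. The generator
#' then applies the cell's effects
#' (the EDVR multiplier is implemented as a division of kLoss, since
#' EDVR scales inversely with kLoss; the left/right asymmetry as a
#' symmetric split of kLoss, left multiplied and right divided by the
#' square root of the ratio), simulates left striatum, right striatum and
#' cerebellum TACs with frame-weighted noise, and draws body weight
#' (0.37 kg, 10% CV) and injected dose (18.5 MBq, 38% CV, the study's
#' reported spread). Fully deterministic under the design seed.
#'
#' @param design a [CohortDesign-class].
#' @param kin base [TissueKinetics-class].
#' @param ref base [ReferenceKinetics-class].
#' @param input a [PlasmaInput-class].
#' @param schedule a [FrameSchedule-class].
#' @return a [Cohort-class]; its `truth` table records each subject's drawn
#'   rate constants and the analytic DVR/EDVR of both striatal sides.
#' @export
simulateCohort <- function(design, kin = defaultTissueKinetics(),
                           ref = defaultReferenceKinetics(),
                           input = defaultPlasmaInput(),
                           schedule = studyFrameSchedule()) {
  stopifnot(is(design, "CohortDesign"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(design@seed)

  gtCode <- c("WT" = "wt", "G51D/+" = "het", "G51D/G51D" = "hom")
  meta <- NULL; truth <- NULL; tacs <- list()
  for (age in design@agesMonths) for (gt in design@genotypes) {
    emRow <- design@effectMap[design@effectMap$genotype == gt &
                                design@effectMap$age_months == age, ]
    if (nrow(emRow) != 1L)
      stop(sprintf("effectMap must have exactly one row for (%s, %g m)", gt, age))
    for (i in seq_len(design@nPerCell)) {
      sid <- sprintf("%s_%02dm_r%d", gtCode[[gt]], age, i)
      ## between-animal variability: one delivery multiplier shared by K1 and
      ## K1r and one efflux multiplier shared by k2 and k2r (within a rat the
      ## nonspecific kinetics of striatum and cerebellum co-vary; this shared
      ## part is what the reference-tissue method cancels), plus independent
      ## jitter on the dopaminergic rates k3 and kLoss
      j <- .lnJitter(4L, design@subjectCV)
      kLossCell <- kin@kLoss * j[4L] / emRow$edvr_mult
      sides <- list(
        left_striatum = tissueKinetics(kin@K1 * j[1L], kin@k2 * j[2L],
                                       kin@k3 * j[3L],
                                       kLossCell * sqrt(emRow$lr_kloss_ratio)),
        right_striatum = tissueKinetics(kin@K1 * j[1L], kin@k2 * j[2L],
                                        kin@k3 * j[3L],
                                        kLossCell / sqrt(emRow$lr_kloss_ratio)))
      refS <- referenceKinetics(ref@K1r * j[1L], ref@k2r * j[2L])
      curves <- c(
        lapply(names(sides), function(side)
          simulateRegion(sides[[side]], input, schedule, regionLabel = side)),
        list(simulateRegion(refS, input, schedule,
                            regionLabel = "cerebellum")))
      names(curves) <- .COHORT_REGIONS
      curves <- lapply(curves, addNoise, noiseScale = design@noiseScale)
      tacs[[sid]] <- curves
      meta <- rbind(meta, data.frame(
        subject_id = sid, genotype = gt, age_months = age,
        weight_kg = 0.37 * .lnJitter(1L, 0.10),
        injected_dose_MBq = 18.5 * .lnJitter(1L, 0.38)))
      tgtL <- analyticTargets(sides$left_striatum, refS)
      tgtR <- analyticTargets(sides$right_striatum, refS)
      truth <- rbind(truth, data.frame(
        subject_id = sid, K1 = sides$left_striatum@K1,
        k2 = sides$left_striatum@k2, k3 = sides$left_striatum@k3,
        kLoss_left = sides$left_striatum@kLoss,
        kLoss_right = sides$right_striatum@kLoss,
        K1r = refS@K1r, k2r = refS@k2r,
        Ki_true = tgtL$Ki, DVR_true_left = tgtL$DVR,
        DVR_true_right = tgtR$DVR, EDVR_true_left = tgtL$EDVR,
        EDVR_true_right = tgtR$EDVR))
    }
  }
  rownames(meta) <- rownames(truth) <- NULL
  new("Cohort", meta = meta, tacs = tacs, truth = truth, design = design)
}

#' Write or read a cohort directory
#'
#' The on-disk layout is sufficient to re-run the downstream pipeline: one
#' TAC CSV per subject (see [writeTACs()]), a `manifest.csv` with the subject
#' metadata, and `design.json` echoing every design input including the seed.
#' Identical designs write byte-identical directories.
#'
#' @param cohort a [Cohort-class].
#' @param dir directory path (created if missing).
#' @return `writeCohort` returns `dir` invisibly; `readCohort` returns a
#'   [Cohort-class] (its `truth` table is empty: ground truth does not
#'   round-trip through the measurement-level files).
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort@meta, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  d <- cohort@design
  jsonlite::write_json(
    list(genotypes = d@genotypes, ages_months = d@agesMonths,
         n_per_cell = d@nPerCell, effect_map = d@effectMap,
         noise_scale = d@noiseScale, subject_cv = d@subjectCV, seed = d@seed),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (sid in cohort@meta$subject_id)
    writeTACs(cohort@tacs[[sid]], sid, file.path(dir, paste0(sid, "_tac.csv")))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest))
    stop(sprintf("'%s' is not a cohort directory (no manifest.csv)", dir))
  meta <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- cohortDesign(genotypes = dj$genotypes, agesMonths = dj$ages_months,
                         nPerCell = dj$n_per_cell, effectMap = dj$effect_map,
                         noiseScale = dj$noise_scale, subjectCV = dj$subject_cv,
                         seed = dj$seed)
  tacs <- lapply(meta$subject_id, function(sid) {
    f <- file.path(dir, paste0(sid, "_tac.csv"))
    if (!file.exists(f)) stop(sprintf("missing TAC file for subject '%s'", sid))
    readTACs(f)
  })
  names(tacs) <- meta$subject_id
  new("Cohort", meta = meta, tacs = tacs, truth = data.frame(),
      design = design)
}
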