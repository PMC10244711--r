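#' Construct a dynamic image / region mask
#'
#' @param voxels 4D numeric array (x, y, z, frame) in kBq/mL, or 3D logical
#'   array for masks.
#' @param voxelSizeMm voxel edge lengths (mm), length 3.
#' @param schedule a [FrameSchedule-class] matching the frame axis.
#' @return a [DynamicImage-class].
#' @export
dynamicImage <- function(voxels, voxelSizeMm, schedule) {
  new("DynamicImage", voxels = voxels, voxelSizeMm = as.numeric(voxelSizeMm),
      schedule = schedule)
}

#' @rdname dynamicImage
#' @param label region label.
#' @export
regionMask <- function(voxels, label) {
  new("RegionMask", voxels = voxels, label = label)
}

#' @rdname schedule
#' @export
setMethod("schedule", "DynamicImage", function(x) x@schedule)

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("DynamicImage: %dx%dx%d voxels (%.2gx%.2gx%.2g mm), %d frames\n",
              d[1L], d[2L], d[3L], object@voxelSizeMm[1L],
              object@voxelSizeMm[2L], object@voxelSizeMm[3L], d[4L]))
  invisible(NULL)
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d voxels\n", object@label,
              sum(object@voxels)))
  invisible(NULL)
})

#' Extract the mean time-activity curve of a VOI
#'
#' Per-frame mean of the voxels selected by the mask. The extraction is
#' linear in the image and independent of voxel order. Smoothing is never
#' applied here: display filtering must not feed quantification.
#'
#' @param image a [DynamicImage-class].
#' @param mask a [RegionMask-class] on the same spatial grid.
#' @return a [TimeActivityCurve-class] labelled by the mask.
#' @export
extractTAC <- function(image, mask) {
  stopifnot(is(image, "DynamicImage"), is(mask, "RegionMask"))
  d <- dim(image@voxels)
  if (!identical(d[1:3], dim(mask@voxels)))
    stop("image and mask grids differ")
  m <- matrix(image@voxels, nrow = prod(d[1:3]), ncol = d[4L])
  act <- colMeans(m[as.vector(mask@voxels), , drop = FALSE])
  timeActivityCurve(image@schedule, act, regionLabel = mask@label,
                    decayCorrected = TRUE)
}

#' Time-averaged 3D image over a scan window
#'
#' Duration-weighted mean of the frames whose mid-times fall inside
#' `[startS, endS]` (e.g. 0-120 min for a whole-scan display average).
#'
#' @param image a [DynamicImage-class].
#' @param startS,endS window bounds in seconds.
#' @return a 3D numeric array.
#' @export
meanFrameImage <- function(image, startS, endS) {
  stopifnot(is(image, "DynamicImage"))
  idx <- fitWindowFrames(image@schedule, startS, endS)
  w <- image@schedule@durations[idx]
  d <- dim(image@voxels)
  m <- matrix(image@voxels, nrow = prod(d[1:3]), ncol = d[4L])
  out <- as.vector(m[, idx, drop = FALSE] %*% (w / sum(w)))
  array(out, dim = d[1:3])
}

.gaussKernel <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  k / sum(k)
}

.conv1d <- function(x, k) {
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) / 2L
  y <- stats::convolve(c(numeric(r), x, numeric(r)), k, type = "filter")
  y
}

#' Separable 3D Gaussian smoothing
#'
#' Display-only filter (applied to averaged images for VOI drawing, never
#' before TAC extraction). The filter width is interpreted as full width at
#' half maximum by default (per-axis sigma = FWHM / (2 sqrt(2 ln 2)) /
#' voxel size); `kind = "sigma"` interprets it as sigma in mm directly.
#' Boundaries are zero-padded, so total intensity is conserved for signal
#' away from the edges.
#'
#' @param volume 3D numeric array.
#' @param fwhmMm filter width per axis (mm), length 1 or 3; 0 disables.
#' @param voxelSizeMm voxel edge lengths (mm), length 3.
#' @param kind "fwhm" (default) or "sigma".
#' @return a 3D numeric array of the same dimensions.
#' @export
gaussianSmooth <- function(volume, fwhmMm, voxelSizeMm,
                           kind = c("fwhm", "sigma")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(volume)) == 3L, length(voxelSizeMm) == 3L)
  fwhmMm <- rep_len(fwhmMm, 3L)
  if (any(fwhmMm < 0)) stop("filter widths must be >= 0")
  sigmaMm <- if (kind == "fwhm") fwhmMm / (2 * sqrt(2 * log(2))) else fwhmMm
  sigmaVox <- sigmaMm / voxelSizeMm
  out <- volume
  d <- dim(volume)
  for (axis in 1:3) {
    k <- .gaussKernel(sigmaVox[axis])
    if (length(k) == 1L) next
    out <- apply(out, setdiff(1:3, axis), .conv1d, k = k)
    ## apply() returns the convolved axis first; restore the layout
    out <- aperm(array(out, dim = c(d[axis], d[setdiff(1:3, axis)])),
                 order(c(axis, setdiff(1:3, axis))))
  }
  out
}

#' Standardized-uptake-value image
#'
#' Duration-weighted frame average over the window, divided voxelwise by
#' injected dose per body weight (the same normalization as [computeSUV()]).
#'
#' @param image a [DynamicImage-class].
#' @param meta a [SubjectMeta-class].
#' @param startS,endS averaging window in seconds.
#' @return a 3D numeric array in g/mL.
#' @export
suvImage <- function(image, meta, startS, endS) {
  stopifnot(is(meta, "SubjectMeta"))
  meanFrameImage(image, startS, endS) /
    (meta@injectedDoseMBq / meta@weightKg)
}

#' Paint a spherical-region voxel phantom
#'
#' Builds a 4D image in which the voxels of each spherical region carry that
#' region's TAC exactly (background 0) together with masks that match the
#' painted voxels, so that [extractTAC()] is an exact round trip. The
#' default geometry loosely mimics two striatal foci plus a cerebellar
#' region. Regions must not overlap.
#'
#' @param regionTacs named list of [TimeActivityCurve-class] objects sharing
#'   one schedule; names become mask labels.
#' @param centersMm numeric matrix (regions x 3) of sphere centres in mm.
#' @param radiiMm sphere radii in mm, one per region.
#' @param dim integer length 3, grid size in voxels.
#' @param voxelSizeMm voxel edge lengths in mm, length 3.
#' @return list with `image` (a [DynamicImage-class]) and `masks` (a named
#'   list of [RegionMask-class]).
#' @export
makePhantom <- function(regionTacs, centersMm, radiiMm,
                        dim = c(32L, 32L, 16L), voxelSizeMm = c(0.4, 0.4, 0.4)) {
  stopifnot(is.list(regionTacs), length(regionTacs) >= 1L)
  if (is.null(names(regionTacs)) || any(names(regionTacs) == ""))
    stop("regionTacs must be a named list")
  centersMm <- rbind(centersMm)
  if (nrow(centersMm) != length(regionTacs) ||
      length(radiiMm) != length(regionTacs))
    stop("need one centre and radius per region")
  sched <- regionTacs[[1L]]@schedule
  for (tac in regionTacs)
    if (!.sameSchedule(tac@schedule, sched))
      stop("all region TACs must share one schedule")
  ## voxel centres in mm
  cx <- (seq_len(dim[1L]) - 0.5) * voxelSizeMm[1L]
  cy <- (seq_len(dim[2L]) - 0.5) * voxelSizeMm[2L]
  cz <- (seq_len(dim[3L]) - 0.5) * voxelSizeMm[3L]
  masks <- list()
  painted <- array(FALSE, dim)
  vox <- array(0, c(dim, nFrames(sched)))
  nvox <- prod(dim)
  for (r in seq_along(regionTacs)) {
    dx2 <- outer(outer((cx - centersMm[r, 1L])^2,
                       (cy - centersMm[r, 2L])^2, `+`),
                 (cz - centersMm[r, 3L])^2, `+`)
    inside <- dx2 <= radiiMm[r]^2
    if (!any(inside))
      stop(sprintf("region '%s' covers no voxel", names(regionTacs)[r]))
    if (any(inside & painted))
      stop(sprintf("region '%s' overlaps another region", names(regionTacs)[r]))
    painted <- painted | inside
    act <- regionTacs[[r]]@activity
    idx <- which(inside)
    for (f in seq_along(act)) vox[idx + (f - 1L) * nvox] <- act[f]
    masks[[names(regionTacs)[r]]] <- regionMask(inside, names(regionTacs)[r])
  }
  list(image = dynamicImage(vox, voxelSizeMm, sched), masks = masks)
}

#' NIfTI input/output for dynamic images and masks
#'
#' 4D images are stored as NIfTI-1 (gzipped accepted) with the frame
#' schedule as a sidecar JSON holding `frame_starts_s` and
#' `frame_durations_s`; masks are stored as 0/1 NIfTI volumes.
#'
#' @param image a [DynamicImage-class].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param scheduleJson sidecar JSON path; defaults to `path` with the NIfTI
#'   extension replaced by `_frames.json`.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
writeDynamicImage <- function(image, path, scheduleJson = NULL) {
  stopifnot(is(image, "DynamicImage"))
  if (is.null(scheduleJson)) scheduleJson <- .sidecarPath(path)
  nii <- RNifti::asNifti(image@voxels)
  RNifti::pixdim(nii) <- c(image@voxelSizeMm, 1)
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(list(frame_starts_s = image@schedule@starts,
                            frame_durations_s = image@schedule@durations),
                       scheduleJson, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", "_frames.json", path)
}

#' @rdname writeDynamicImage
#' @export
readDynamicImage <- function(path, scheduleJson = NULL) {
  if (is.null(scheduleJson)) scheduleJson <- .sidecarPath(path)
  nii <- RNifti::readNifti(path)
  sj <- jsonlite::read_json(scheduleJson, simplifyVector = TRUE)
  sched <- new("FrameSchedule", starts = as.numeric(sj$frame_starts_s),
               durations = as.numeric(sj$frame_durations_s))
  vox <- array(as.numeric(nii), dim = dim(nii))
  dynamicImage(vox, RNifti::pixdim(nii)[1:3], sched)
}

#' @rdname writeDynamicImage
#' @param mask a [RegionMask-class].
#' @export
writeRegionMask <- function(mask, path) {
  stopifnot(is(mask, "RegionMask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask@voxels),
                                           dim(mask@voxels))), path)
  invisible(path)
}

#' @rdname writeDynamicImage
#' @param label label for the mask read back.
#' @export
readRegionMask <- function(path, label) {
  nii <- RNifti::readNifti(path)
  regionMask(array(as.numeric(nii) != 0, dim(nii)), label)
}
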