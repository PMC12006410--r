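## End-to-end pullback analysis and aggregate reporting.

#' Analyze a full pullback
#'
#' Runs the complete pipeline — read, segment, lumen center and quadrant
#' partition, classify with calibration, morphometrics — and aggregates a
#' [PullbackReport-class]: stent boundaries, minimal lumen diameter,
#' uncovered-strut counts and the tissue composition of analyzed quadrants
#' within the stent interval (`not_analyzable` fraction reported
#' separately). Deterministic given the models and configuration. When
#' `outputDir` is given, a per-quadrant CSV, a report JSON and per-frame
#' mask PNGs are written.
#'
#' @param input A pullback: directory/zip path (see [readPullback()]), a
#'   [PhantomPullback-class], or a list of [OCTFrame-class].
#' @param segModel A [SegModel-class].
#' @param clsModel A [QuadModel-class].
#' @param calibration A [CalibrationConfig-class].
#' @param id Pullback identifier used in outputs.
#' @param nRays Rays per frame for morphometrics.
#' @param outputDir Optional output directory.
#' @return A [PullbackReport-class].
#' @export
analyzePullback <- function(input, segModel, clsModel,
                            calibration = calibrationConfig(),
                            id = "pullback", nRays = 360L,
                            outputDir = NULL) {
  if (!is(segModel, "SegModel") || !is(clsModel, "QuadModel"))
    stop("invalid model handles", call. = FALSE)
  frames <- if (is.character(input)) readPullback(input)
            else if (is(input, "PhantomPullback")) pullbackFrames(input)
            else input
  if (!length(frames)) stop("empty pullback", call. = FALSE)
  spacing <- frames[[1]]@spacing

  masks <- vector("list", length(frames))
  morph <- vector("list", length(frames))
  recs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    masks[[i]] <- segmentFrame(segModel, frames[[i]])
    fm <- frameMorphometrics(masks[[i]], spacingMm = spacing[1],
                             nRays = nRays)
    prof <- fm$profile
    half <- nRays %/% 2
    d <- prof$lumenRadiusMm[seq_len(half)] +
      prof$lumenRadiusMm[seq_len(half) + half]
    fm$minDiameterMm <- suppressWarnings(min(d, na.rm = TRUE))
    fm$profile <- NULL
    morph[[i]] <- data.frame(frame = i - 1L, fm)
    recs[[i]] <- predictQuadrants(clsModel, frames[[i]], masks[[i]],
                                  calibration, frameIndex = i - 1L)
  }
  frameMorpho <- do.call(rbind, morph)
  records <- do.call(rbind, recs)

  sb <- stentBoundaries(masks)
  stentR <- if (sb$detected) c(sb$start, sb$end) else integer(0)
  rep <- new("PullbackReport", id = id, nFrames = length(frames),
             stentRange = as.integer(stentR), stentDetected = sb$detected,
             frameMorpho = frameMorpho, records = records,
             composition = numeric(0), mld = list(),
             uncovered = 0L,
             flags = ifelse(frameMorpho$degenerate,
                            "degenerate: no lumen", ""),
             provenance = list(calibration = list(
               temperature = calibration@temperature,
               weights = calibration@weights, tta = calibration@tta),
               segSeed = segModel@seed, clsSeed = clsModel@seed,
               overrides = list()))
  rep <- recomputeAggregates(rep)

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeQuadrantRecords(reportRecordsTable(rep),
                         file.path(outputDir, "quadrant_records.csv"))
    writeReportJSON(rep, file.path(outputDir, "report.json"))
    for (i in seq_along(masks))
      writeMaskPNG(masks[[i]],
                   file.path(outputDir, sprintf("mask_%03d.png", i - 1L)))
  }
  rep
}

## Stent-interval-scoped aggregates: composition, MLD, uncovered counts.
recomputeAggregates <- function(rpt) {
  inStent <- if (rpt@stentDetected)
    rpt@records$frame >= rpt@stentRange[1] &
      rpt@records$frame <= rpt@stentRange[2]
  else rep(TRUE, nrow(rpt@records))
  sub <- rpt@records[inStent, ]
  analyzed <- sub$predicted != "not_analyzable"
  comp <- if (any(analyzed)) {
    tab <- table(factor(sub$predicted[analyzed], levels = .TISSUES))
    as.numeric(tab) / sum(tab)
  } else rep(NA_real_, 3)
  names(comp) <- .TISSUES
  comp <- c(comp, not_analyzable = mean(!analyzed))
  rpt@composition <- comp

  fmIn <- if (rpt@stentDetected)
    rpt@frameMorpho$frame >= rpt@stentRange[1] &
      rpt@frameMorpho$frame <= rpt@stentRange[2]
  else rep(TRUE, nrow(rpt@frameMorpho))
  fm <- rpt@frameMorpho[fmIn, ]
  ok <- is.finite(fm$minDiameterMm)
  rpt@mld <- if (any(ok)) {
    i <- fm$frame[ok][which.min(fm$minDiameterMm[ok])]
    list(frame = as.integer(i),
         diameter_mm = min(fm$minDiameterMm[ok]))
  } else list()
  rpt@uncovered <- as.integer(sum(fm$uncoveredStrutCount))
  rpt
}

#' Override the stent interval of a report
#'
#' Recomputes every stent-interval-scoped aggregate (tissue composition,
#' minimal-lumen-diameter localization, uncovered-strut count) under a
#' manually corrected interval; the override is logged in the report's
#' provenance. The input report is returned unchanged on an invalid
#' interval (an error is raised).
#'
#' @param report A [PullbackReport-class].
#' @param startFrame,endFrame 0-based inclusive interval with
#'   `0 <= startFrame <= endFrame < nFrames`.
#' @return The updated [PullbackReport-class].
#' @export
manualStentOverride <- function(report, startFrame, endFrame) {
  startFrame <- as.integer(startFrame); endFrame <- as.integer(endFrame)
  if (is.na(startFrame) || is.na(endFrame) || startFrame > endFrame ||
      startFrame < 0L || endFrame >= report@nFrames)
    stop("invalid stent interval [", startFrame, ", ", endFrame, "]",
         call. = FALSE)
  report@stentRange <- c(startFrame, endFrame)
  report@stentDetected <- TRUE
  report@provenance$overrides <-
    c(report@provenance$overrides,
      list(list(what = "stentRange", start = startFrame, end = endFrame)))
  recomputeAggregates(report)
}

## Per-quadrant records in label-table-compatible form.
reportRecordsTable <- function(rpt) {
  r <- rpt@records
  data.frame(pullback_id = rpt@id, frame_index = r$frame,
             quadrant_index = r$quadrant, rater_id = "model",
             class = r$predicted,
             r[, .CLASSES], confidence = r$confidence,
             degenerate = r$degenerate)
}

#' Write a pullback report as JSON
#'
#' @param report A [PullbackReport-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeReportJSON <- function(report, path) {
  out <- list(
    schema = "neoquant-report/1",
    id = report@id, nFrames = report@nFrames,
    stentDetected = report@stentDetected,
    stentRange = report@stentRange,
    stentLengthMm = if (report@stentDetected)
      (report@stentRange[2] - report@stentRange[1] + 1L) * 0.2 else NULL,
    composition = as.list(report@composition),
    mld = report@mld, uncoveredStruts = report@uncovered,
    frameMorphometrics = report@frameMorpho[
      setdiff(names(report@frameMorpho), "profile")],
    flags = report@flags, provenance = report@provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
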