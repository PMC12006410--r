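## Readers and writers: pullbacks (PNG/TIFF directories or zip archives),
## label masks (palette PNG: 0 background, 1 lumen, 2 neointima, 3 strut),
## per-quadrant label tables (CSV) and pullback manifests (JSON).

readOneImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("tiff package unavailable")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)),
    error = function(e)
      stop(sprintf("format error reading '%s': %s", basename(path),
                   conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]   # grayscale channel
  img
}

#' Read a pullback from a directory or zip archive of frame images
#'
#' Frames are ordered by natural filename sort (so `frame_2` precedes
#' `frame_10` regardless of zero padding), intensities are min-max
#' normalized per pullback to `[0,1]`, and missing spacing metadata is
#' filled from `spacing` with a warning when a manifest is absent.
#'
#' @param path Directory of PNG/TIFF frames (a `manifest.json` written by
#'   [writePullback()] is honoured for spacing), or a `.zip` of such
#'   frames.
#' @param spacing Default `(row mm/px, col mm/px, inter-frame mm)` used when
#'   no manifest provides it.
#' @return List of [OCTFrame-class], indices 0-based in pullback order.
#' @export
readPullback <- function(path, spacing = c(0.01, 0.01, 0.2)) {
  cleanup <- NULL
  if (length(path) == 1L && grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("pullback_zip_")
    members <- tryCatch(utils::unzip(path, exdir = exdir),
                        error = function(e)
                          stop("format error: cannot unzip '", path, "'",
                               call. = FALSE))
    if (!length(members)) stop("empty-input: zip contains no files",
                               call. = FALSE)
    path <- exdir
    cleanup <- exdir
  }
  if (!dir.exists(path)) stop("format error: '", path,
                              "' is not a readable directory", call. = FALSE)
  on.exit(if (!is.null(cleanup)) unlink(cleanup, recursive = TRUE))

  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("mask", basename(files), ignore.case = TRUE)]
  if (!length(files)) stop("empty-input: no frame images under '", path, "'",
                           call. = FALSE)
  files <- naturalSort(files)

  manifest <- file.path(path, "manifest.json")
  if (file.exists(manifest)) {
    mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    if (!is.null(mf$spacing)) spacing <- as.numeric(mf$spacing)
  } else {
    warning("no spacing metadata found; using defaults (",
            paste(spacing, collapse = ", "), ") mm", call. = FALSE)
  }

  imgs <- lapply(files, readOneImage)
  lo <- min(vapply(imgs, min, numeric(1)))
  hi <- max(vapply(imgs, max, numeric(1)))
  rng <- if (hi > lo) hi - lo else 1
  lapply(seq_along(imgs), function(i)
    OCTFrame((imgs[[i]] - lo) / rng, index = i - 1L, spacing = spacing))
}

#' Write a phantom pullback as a PNG stack with ground truth
#'
#' Emits `frame_NNN.png` (grayscale), `mask_NNN.png` (label palette scaled
#' to 0/85/170/255 for visibility; recover labels with [readMaskPNG()]) and
#' a JSON manifest recording spacing, seed, stent interval, annotation
#' flags and quadrant labels.
#'
#' @param pullback A [PhantomPullback-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writePullback <- function(pullback, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- pullbackTruths(pullback)
  for (i in seq_along(truths)) {
    t <- truths[[i]]
    png::writePNG(octImage(t),
                  file.path(dir, sprintf("frame_%03d.png", i - 1L)))
    writeMaskPNG(truthMask(t),
                 file.path(dir, sprintf("mask_%03d.png", i - 1L)))
  }
  sp <- truths[[1]]@spec
  manifest <- list(
    nFrames = length(truths),
    spacing = c(sp@pixelSpacing, sp@pixelSpacing, pullback@frameSpacing),
    seed = pullback@seed,
    stentRange = pullback@stentRange,
    annotated = pullback@annotated,
    quadrantLabels = lapply(truths, quadrantLabels))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = FALSE, digits = NA)
  invisible(mpath)
}

#' @describeIn writePullback write one label mask as a palette PNG.
#' @param mask An [OCTMask-class].
#' @param path Output PNG path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(maskLabels(mask) * 85 / 255, path)
  invisible(path)
}

#' @describeIn writePullback read a palette PNG back into an
#'   [OCTMask-class] (exact round trip).
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  OCTMask(matrix(as.integer(round(m * 255 / 85)), nrow = nrow(m)))
}

#' Read a per-quadrant label table
#'
#' The CSV must carry the five columns `pullback_id`, `frame_index`,
#' `quadrant_index`, `rater_id`, `class`. Class strings are normalized to
#' the canonical vocabulary (case, surrounding whitespace and the
#' "homogenous"/"heterogenous" spellings are tolerated); unknown classes
#' and quadrant indices outside 1..4 raise validation errors.
#'
#' @param path CSV path.
#' @return `data.frame` with validated, normalized columns.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pullback_id", "frame_index", "quadrant_index", "rater_id",
            "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  if (!all(df$quadrant_index %in% 1:4))
    stop("validation error: quadrant_index must be in {1,2,3,4}",
         call. = FALSE)
  df$class <- normalizeClassLabel(df$class)
  df
}

#' Write per-quadrant records to CSV
#'
#' Lossless counterpart of [readLabels()]: writing then reading yields
#' identical rows.
#'
#' @param records Non-empty `data.frame` with the five label-table columns
#'   (extra columns such as probabilities and confidence are preserved).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeQuadrantRecords <- function(records, path) {
  if (!nrow(records)) stop("no records to write", call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
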