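#' @import methods
#' @importFrom stats quantile sd median setNames predict
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Segmentation mask for one OCT frame
#'
#' A per-pixel label map over the four structural classes: 0 background,
#' 1 lumen, 2 neointima, 3 stent strut. Same shape as the source frame.
#'
#' @slot labels Integer matrix of labels in `{0,1,2,3}`.
#' @export
setClass("OCTMask", representation(labels = "matrix"))

setValidity("OCTMask", function(object) {
  v <- unique(as.vector(object@labels))
  if (!all(v %in% 0:3)) return("mask labels must be in {0,1,2,3}")
  TRUE
})

#' Construct a segmentation mask
#'
#' @param labels Integer matrix with values 0 (background), 1 (lumen),
#'   2 (neointima), 3 (strut).
#' @return An [OCTMask-class] object.
#' @export
OCTMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("OCTMask", labels = labels)
}

#' @describeIn OCTMask-class extract the label matrix.
#' @param x An `OCTMask`.
#' @export
maskLabels <- function(x) x@labels

setMethod("show", "OCTMask", function(object) {
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = names(.MASK_LEVELS)))
  cat(sprintf("OCTMask %dx%d | %s\n", nrow(object@labels),
              ncol(object@labels),
              paste(names(tab), tab, sep = "=", collapse = " ")))
})

#' One OCT cross-sectional frame
#'
#' @slot image Numeric matrix, intensities in `[0,1]`, row 1 at top.
#' @slot index 0-based position along the pullback.
#' @slot spacing Physical spacing `(row mm/px, col mm/px, inter-frame mm)`.
#' @export
setClass("OCTFrame", representation(image = "matrix", index = "integer",
                                    spacing = "numeric"))

setValidity("OCTFrame", function(object) {
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (min(object@image) < -1e-9 || max(object@image) > 1 + 1e-9)
    return("image intensities must lie in [0,1]")
  TRUE
})

#' Construct an OCT frame
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param index 0-based frame index.
#' @param spacing Numeric length-3: row and column pixel spacing (mm) and
#'   inter-frame spacing (mm).
#' @return An [OCTFrame-class].
#' @export
OCTFrame <- function(image, index = 0L, spacing = c(0.01, 0.01, 0.2)) {
  new("OCTFrame", image = image, index = as.integer(index),
      spacing = as.numeric(spacing))
}

#' @describeIn OCTFrame-class extract the intensity matrix.
#' @param x An `OCTFrame` (or [PhantomTruth-class]).
#' @export
setGeneric("octImage", function(x) standardGeneric("octImage"))

#' @rdname OCTFrame-class
#' @export
setMethod("octImage", "OCTFrame", function(x) x@image)

setMethod("show", "OCTFrame", function(object) {
  cat(sprintf("OCTFrame #%d %dx%d, %.4g mm/px, frame pitch %.3g mm\n",
              object@index, nrow(object@image), ncol(object@image),
              object@spacing[1], object@spacing[3]))
})

#' Generative description of one synthetic phantom frame
#'
#' The geometry of an annular stented-vessel cross-section: a (near-)circular
#' lumen, a neointima annulus whose thickness and tissue class are piecewise
#' constant over equal angular sectors (clockwise from 12 o'clock), strut
#' reflectors on the vessel wall, and an optional side-branch opening.
#'
#' @slot imageSize Pixels per side of the square frame.
#' @slot pixelSpacing Physical pixel size, mm.
#' @slot lumenCenter `(row, col)` subpixel lumen center.
#' @slot lumenRadius Lumen radius, px.
#' @slot thickness Per-sector neointima thickness, px (>= 0).
#' @slot tissueSectors Per-sector tissue class (one of the three tissue
#'   classes); same length as `thickness`.
#' @slot strutAngles Clockwise angles (degrees from 12 o'clock) of strut
#'   centers.
#' @slot strutCovered Logical per strut: `TRUE` = embedded under neointima,
#'   `FALSE` = uncovered (protrudes into the lumen).
#' @slot strutRadius Strut disc radius, px.
#' @slot sideBranch Angular interval `c(from, to)` in degrees of a
#'   side-branch opening, or `numeric(0)` for none.
#' @slot noiseLevel Speckle intensity scale.
#' @slot seed Integer RNG seed for texture rendering.
#' @export
setClass("PhantomSpec", representation(
  imageSize = "integer", pixelSpacing = "numeric", lumenCenter = "numeric",
  lumenRadius = "numeric", thickness = "numeric", tissueSectors = "character",
  strutAngles = "numeric", strutCovered = "logical", strutRadius = "numeric",
  sideBranch = "numeric", noiseLevel = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  n <- object@imageSize
  if (n < 32L) return("imageSize must be >= 32")
  if (object@lumenRadius <= 0) return("lumenRadius must be > 0")
  if (any(object@thickness < 0)) return("neointima thickness must be >= 0")
  if (length(object@tissueSectors) != length(object@thickness))
    return("tissueSectors and thickness must have the same length")
  if (!all(object@tissueSectors %in% .TISSUES))
    return("tissueSectors must be drawn from the three tissue classes")
  if (length(object@strutAngles) != length(object@strutCovered))
    return("strutAngles and strutCovered must have the same length")
  if (length(object@sideBranch) %in% c(0L, 2L) == FALSE)
    return("sideBranch must be numeric(0) or c(from, to) degrees")
  margin <- object@strutRadius + 3
  extent <- object@lumenRadius + max(object@thickness, 0) + margin
  lo <- min(object@lumenCenter); hi <- max(object@lumenCenter)
  if (lo - extent < 0 || hi + extent > n + 1)
    return("lumen, neointima annulus and struts do not fit inside the frame")
  if (any(object@strutCovered)) {
    sect <- sectorIndex(object@strutAngles[object@strutCovered],
                        length(object@thickness))
    if (any(object@thickness[sect] < 2 * object@strutRadius + 3))
      return(paste("covered struts require neointima thickness >=",
                   "2*strutRadius + 3 px at the strut angle"))
  }
  TRUE
})

## Sector index (1-based) of clockwise angles for nSectors equal sectors.
sectorIndex <- function(thetaDeg, nSectors) {
  pmin(floor((thetaDeg %% 360) / (360 / nSectors)) + 1L, nSectors)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %dpx @%.3g mm/px | lumen r=%.1f px at ",
                     "(%.1f,%.1f) | %d sectors | %d struts (%d uncovered)",
                     "%s | seed %d\n"),
              object@imageSize, object@pixelSpacing, object@lumenRadius,
              object@lumenCenter[1], object@lumenCenter[2],
              length(object@thickness), length(object@strutAngles),
              sum(!object@strutCovered),
              if (length(object@sideBranch)) " | side branch" else "",
              object@seed))
})

#' Rendered phantom frame with exact ground truth
#'
#' @slot image Rendered grayscale frame in `[0,1]`.
#' @slot mask Exact [OCTMask-class].
#' @slot quadrantLabels Character(4): the class of quadrants Q1..Q4 after the
#'   severity rule and structural (uncovered strut / side branch) overrides.
#' @slot spec The generating [PhantomSpec-class].
#' @export
setClass("PhantomTruth", representation(
  image = "matrix", mask = "OCTMask", quadrantLabels = "character",
  spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  if (length(object@quadrantLabels) != 4)
    return("quadrantLabels must have length 4")
  if (!all(object@quadrantLabels %in% .CLASSES))
    return("quadrantLabels outside the class vocabulary")
  if (!identical(dim(object@image), dim(object@mask@labels)))
    return("image and mask shapes differ")
  TRUE
})

#' @rdname PhantomTruth-class
#' @param x A `PhantomTruth`.
#' @export
setMethod("octImage", "PhantomTruth", function(x) x@image)

#' @describeIn PhantomTruth-class extract the ground-truth mask.
#' @export
truthMask <- function(x) x@mask

#' @describeIn PhantomTruth-class extract the four quadrant labels.
#' @export
quadrantLabels <- function(x) x@quadrantLabels

#' @describeIn PhantomTruth-class extract the generating spec.
#' @export
truthSpec <- function(x) x@spec

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth %dx%d | quadrants: %s\n",
              nrow(object@image), ncol(object@image),
              paste(object@quadrantLabels, collapse = ", ")))
})

#' A synthetic pullback: a frame sequence with stent interval metadata
#'
#' @slot truths List of [PhantomTruth-class], ordered by pullback position.
#' @slot stentRange 0-based first and last stented frame, or `integer(0)` if
#'   the pullback carries no stent.
#' @slot frameSpacing Inter-frame spacing, mm (0.2 mm, i.e. 5 frames per mm).
#' @slot annotated Logical per frame: marked for every-1-mm manual
#'   annotation (every fifth frame).
#' @slot seed Generator seed.
#' @export
setClass("PhantomPullback", representation(
  truths = "list", stentRange = "integer", frameSpacing = "numeric",
  annotated = "logical", seed = "integer"))

setValidity("PhantomPullback", function(object) {
  n <- length(object@truths)
  if (n < 1) return("pullback needs >= 1 frame")
  if (length(object@annotated) != n)
    return("annotated flags must match frame count")
  if (length(object@stentRange) == 2L) {
    if (object@stentRange[1] > object@stentRange[2] ||
        object@stentRange[1] < 0 || object@stentRange[2] >= n)
      return("stentRange outside [0, n_frames)")
  } else if (length(object@stentRange) != 0L)
    return("stentRange must be integer(0) or length 2")
  TRUE
})

#' @describeIn PhantomPullback-class number of frames.
#' @param x A `PhantomPullback`.
#' @export
setMethod("length", "PhantomPullback", function(x) length(x@truths))

#' @describeIn PhantomPullback-class extract one frame's truth.
#' @param i Frame position (1-based list index).
#' @export
setMethod("[[", "PhantomPullback", function(x, i) x@truths[[i]])

#' @describeIn PhantomPullback-class list of all truths.
#' @export
pullbackTruths <- function(x) x@truths

#' @describeIn PhantomPullback-class 0-based stented frame interval
#'   (or `integer(0)`).
#' @export
stentRange <- function(x) x@stentRange

#' @describeIn PhantomPullback-class logical annotation flags (every 1 mm).
#' @export
annotatedFrames <- function(x) x@annotated

setMethod("show", "PhantomPullback", function(object) {
  sr <- if (length(object@stentRange)) {
    sprintf("stent frames %d..%d", object@stentRange[1], object@stentRange[2])
  } else "no stent"
  cat(sprintf("PhantomPullback: %d frames @ %.2g mm pitch | %s | %d annotated\n",
              length(object@truths), object@frameSpacing, sr,
              sum(object@annotated)))
})

#' Lumen-centered quadrant partition of a frame
#'
#' Every pixel is assigned to one of four 90-degree quadrants rotating
#' clockwise from 12 o'clock about the lumen center: Q1 spans 12-3 o'clock,
#' Q2 3-6, Q3 6-9, Q4 9-12 (half-open angular intervals).
#'
#' @slot center `(row, col)` dividing point (subpixel).
#' @slot map Integer matrix of quadrant indices 1..4.
#' @slot degenerate `TRUE` when the center came from a lumen-free fallback.
#' @export
setClass("QuadrantPartition", representation(
  center = "numeric", map = "matrix", degenerate = "logical"))

setValidity("QuadrantPartition", function(object) {
  if (!all(object@map %in% 1:4)) return("quadrant map values must be 1..4")
  TRUE
})

#' @describeIn QuadrantPartition-class the quadrant index map.
#' @param x A `QuadrantPartition`.
#' @export
quadrantMap <- function(x) x@map

#' @describeIn QuadrantPartition-class the dividing center `(row, col)`.
#' @export
partitionCenter <- function(x) x@center

setMethod("show", "QuadrantPartition", function(object) {
  cat(sprintf("QuadrantPartition %dx%d about (%.1f, %.1f)%s\n",
              nrow(object@map), ncol(object@map), object@center[1],
              object@center[2],
              if (object@degenerate) " [degenerate center]" else ""))
})

#' Calibration configuration for quadrant predictions
#'
#' Houses the temperature of the sharpening step (exponent `1/T`), the
#' self/neighbour fusion weights, and the test-time augmentation set.
#'
#' @slot temperature Positive sharpening temperature `T`; probabilities are
#'   raised to `1/T` and renormalized (`T < 1` sharpens).
#' @slot weights `(w_self, w_neighbor)` with `w_self + 2*w_neighbor = 1`.
#' @slot tta Character vector of augmentation names; `"identity"` is always
#'   included. Supported: `"identity"`, `"hflip"`, `"gain_up"`, `"gain_down"`.
#' @export
setClass("CalibrationConfig", representation(
  temperature = "numeric", weights = "numeric", tta = "character"))

setValidity("CalibrationConfig", function(object) {
  if (object@temperature <= 0) return("temperature must be > 0")
  if (length(object@weights) != 2 || any(object@weights < 0))
    return("weights must be two nonnegative values")
  if (abs(object@weights[1] + 2 * object@weights[2] - 1) > 1e-9)
    return("weights must satisfy w_self + 2*w_neighbor = 1")
  ok <- c("identity", "hflip", "gain_up", "gain_down")
  if (!all(object@tta %in% ok))
    return(paste("unknown TTA transform; supported:",
                 paste(ok, collapse = ", ")))
  TRUE
})

#' @rdname CalibrationConfig-class
#' @param temperature Sharpening temperature `T`; the neutral default 1
#'   leaves probabilities unchanged. Fit it on validation data with
#'   [fitTemperature()] — with an already well-calibrated base model the
#'   fitted value is typically near or above 1 (softening), whereas an
#'   overconfident deep model calls for `T < 1`.
#' @param weights Fusion weights `(w_self, w_neighbor)`. The default
#'   `c(0.8, 0.1)` keeps the quadrant's own evidence dominant; heavier
#'   neighbour mixing degrades per-quadrant accuracy. Fit on validation
#'   frames with [fitCalibration()].
#' @param tta Augmentation set; rotations are excluded by design because they
#'   would break the fixed 12-o'clock quadrant frame.
#' @return A validated `CalibrationConfig`.
#' @export
calibrationConfig <- function(temperature = 1, weights = c(0.8, 0.1),
                              tta = c("identity", "hflip", "gain_up",
                                      "gain_down")) {
  new("CalibrationConfig", temperature = as.numeric(temperature),
      weights = as.numeric(weights), tta = unique(c("identity", tta)))
}

setMethod("show", "CalibrationConfig", function(object) {
  cat(sprintf("CalibrationConfig: T=%.3g, w=(%.3g, %.3g), TTA={%s}\n",
              object@temperature, object@weights[1], object@weights[2],
              paste(object@tta, collapse = ", ")))
})

#' Trained pixelwise segmentation model
#'
#' Opaque handle around the fitted model, its configuration snapshot and
#' seed. Applying it to a frame of any size yields a mask of the same shape.
#'
#' @slot fit The fitted model object.
#' @slot config Training configuration snapshot.
#' @slot seed Training seed.
#' @slot history Per-epoch/round validation metrics logged during training.
#' @export
setClass("SegModel", representation(fit = "ANY", config = "list",
                                    seed = "integer", history = "data.frame"))

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel (%s), %d features, seed %d\n",
              class(object@fit)[1], length(object@config$features),
              object@seed))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat("  final validation Dice:",
        paste(sprintf("%s=%.3f", names(last)[-1], unlist(last[-1])),
              collapse = " "), "\n")
  }
})

#' Trained quadrant tissue classifier
#'
#' @slot fit The fitted softmax network.
#' @slot center,scale Feature standardization parameters.
#' @slot classes Class labels in output order.
#' @slot config Training configuration snapshot.
#' @slot seed Training seed.
#' @slot metrics Validation metrics (per-class F1, confusion matrix).
#' @export
setClass("QuadModel", representation(
  fit = "ANY", center = "numeric", scale = "numeric", classes = "character",
  config = "list", seed = "integer", metrics = "list"))

setMethod("show", "QuadModel", function(object) {
  cat(sprintf("QuadModel (%s) over %d features, classes: %s, seed %d\n",
              class(object@fit)[1], length(object@center),
              paste(object@classes, collapse = ", "), object@seed))
  if (!is.null(object@metrics$accuracy))
    cat(sprintf("  validation accuracy %.3f\n", object@metrics$accuracy))
})

#' Aggregate analysis of one pullback
#'
#' @slot id Pullback identifier.
#' @slot nFrames Number of frames analyzed.
#' @slot stentRange Detected (or overridden) 0-based stent interval;
#'   `integer(0)` when no stent was detected.
#' @slot stentDetected Whether a stent interval was found.
#' @slot frameMorpho Per-frame morphometrics (`data.frame`).
#' @slot records Per-quadrant classification records (`data.frame`).
#' @slot composition Named fractions of analyzed (non-`not_analyzable`)
#'   quadrants per tissue class within the stent interval, plus the
#'   `not_analyzable` fraction reported separately.
#' @slot mld Minimal lumen diameter: `list(frame, diameter_mm)`.
#' @slot uncovered Total uncovered strut components over stented frames.
#' @slot flags Character vector of per-frame degeneracy flags.
#' @slot provenance List: seed, config echo, manual overrides.
#' @export
setClass("PullbackReport", representation(
  id = "character", nFrames = "integer", stentRange = "integer",
  stentDetected = "logical", frameMorpho = "data.frame",
  records = "data.frame", composition = "numeric", mld = "list",
  uncovered = "integer", flags = "character", provenance = "list"))

setMethod("show", "PullbackReport", function(object) {
  sr <- if (object@stentDetected)
    sprintf("stent %d..%d", object@stentRange[1], object@stentRange[2])
  else "no stent detected"
  cat(sprintf("PullbackReport '%s': %d frames, %s\n", object@id,
              object@nFrames, sr))
  if (length(object@composition)) {
    cat("  composition:",
        paste(sprintf("%s=%.2f", names(object@composition),
                      object@composition), collapse = " "), "\n")
  }
  if (length(object@mld))
    cat(sprintf("  MLD %.3f mm at frame %d | uncovered struts: %d\n",
                object@mld$diameter_mm, object@mld$frame, object@uncovered))
})
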