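## Lumen-center computation and the clockwise-from-12-o'clock quadrant
## partition, plus the 224x224 quadrant crops fed to the tissue classifier.

#' Lumen center of a segmentation mask
#'
#' Centroid (mean row, mean col) of the lumen pixels of a postprocessed
#' mask. When the mask contains no lumen the image center is returned and
#' the result is flagged degenerate (attribute `degenerate`).
#'
#' @param mask An [OCTMask-class].
#' @return Numeric `(row, col)` with attribute `degenerate`.
#' @export
lumenCenter <- function(mask) {
  lab <- maskLabels(mask)
  idx <- which(lab == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    ctr <- (dim(lab) + 1) / 2
    attr(ctr, "degenerate") <- TRUE
    return(ctr)
  }
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  attr(ctr, "degenerate") <- FALSE
  ctr
}

#' Partition a frame into four lumen-centered quadrants
#'
#' Assigns every pixel (at its center) to one of four 90-degree quadrants by
#' its clockwise angle from 12 o'clock about `center`: Q1 spans 12-3
#' o'clock, Q2 3-6, Q3 6-9, Q4 9-12, with half-open angular intervals
#' `[90(q-1), 90q)` so boundary pixels resolve deterministically (a pixel
#' directly above the center is Q1; directly right is Q2).
#'
#' @param shape `(rows, cols)` of the frame.
#' @param center `(row, col)` dividing point; must lie inside the image.
#' @return A [QuadrantPartition-class].
#' @export
partitionQuadrants <- function(shape, center) {
  shape <- as.integer(shape)
  if (center[1] < 0.5 || center[1] > shape[1] + 0.5 ||
      center[2] < 0.5 || center[2] > shape[2] + 0.5)
    stop("center outside image bounds", call. = FALSE)
  dr <- matrix(seq_len(shape[1]) - center[1], shape[1], shape[2])
  dc <- matrix(seq_len(shape[2]) - center[2], shape[1], shape[2],
               byrow = TRUE)
  theta <- clockAngle(dr, dc)
  map <- matrix(pmin(floor(theta / 90) + 1L, 4L), shape[1], shape[2])
  storage.mode(map) <- "integer"
  deg <- isTRUE(attr(center, "degenerate"))
  new("QuadrantPartition", center = as.numeric(center), map = map,
      degenerate = deg)
}

#' Crop one quadrant to a fixed-size classifier input
#'
#' Extracts the axis-aligned bounding box of quadrant `q`'s pixels with
#' pixels outside the quadrant zeroed, then resizes bilinearly to
#' `outSize x outSize` (default 224, the classification network's input
#' size). The resized wedge-membership mask is attached as attribute
#' `wedge` for downstream feature computation.
#'
#' @param frame An [OCTFrame-class] or a numeric image matrix.
#' @param partition A [QuadrantPartition-class] for the frame.
#' @param q Quadrant index 1..4.
#' @param outSize Output side length in pixels.
#' @return `outSize x outSize` numeric matrix in `[0,1]`.
#' @export
cropQuadrant <- function(frame, partition, q, outSize = 224L) {
  stopifnot(q %in% 1:4)
  img <- if (is(frame, "OCTFrame")) octImage(frame) else frame
  if (!identical(dim(img), dim(partition@map)))
    stop("frame and partition shapes differ", call. = FALSE)
  inQ <- partition@map == q
  if (!any(inQ))
    stop(sprintf("quadrant %d is empty for this center", q), call. = FALSE)
  idx <- which(inQ, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  subQ <- inQ[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sub[!subQ] <- 0
  out <- EBImage::resize(sub, w = outSize, h = outSize)
  wedge <- EBImage::resize(subQ + 0, w = outSize, h = outSize) > 0.5
  out <- clamp01(out)
  attr(out, "wedge") <- wedge
  out
}

#' Most-severe-class reduction for a quadrant
#'
#' A quadrant containing uncovered struts or a side-branch opening is
#' `not_analyzable`, overriding any tissue; otherwise the most severe tissue
#' present is scored, ordered homogeneous < heterogeneous <
#' neoatherosclerosis.
#'
#' @param tissues Character vector of tissue classes present (may be empty
#'   if a structural flag is set).
#' @param uncoveredStrut Logical: quadrant contains an uncovered strut.
#' @param sideBranch Logical: quadrant contains a side-branch opening.
#' @return One class label.
#' @export
#' @examples
#' severityLabel(c("homogeneous", "neoatherosclerosis"))
#' severityLabel("homogeneous", uncoveredStrut = TRUE)
severityLabel <- function(tissues, uncoveredStrut = FALSE,
                          sideBranch = FALSE) {
  if (uncoveredStrut || sideBranch) return("not_analyzable")
  if (!length(tissues)) stop("no tissues and no structural flag",
                             call. = FALSE)
  tissues <- normalizeClassLabel(tissues)
  if (any(tissues == "not_analyzable"))
    stop("not_analyzable is structural, not a tissue input", call. = FALSE)
  .TISSUES[max(match(tissues, .TISSUES))]
}
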