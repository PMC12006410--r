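## Per-frame and per-pullback vessel morphometrics from segmentation masks:
## ray-cast lumen radius and neointimal thickness profiles, minimal lumen
## diameter, uncovered-strut detection, stent boundary localization.
##
## Ray casting samples the nearest label at 0.5 px steps (no interpolation
## of categorical labels), clockwise from 12 o'clock.

## Sample mask labels along one ray; returns the labels and step distances.
castRay <- function(lab, center, thetaDeg, step = 0.5) {
  n1 <- nrow(lab); n2 <- ncol(lab)
  phi <- thetaDeg * pi / 180
  dr <- -cos(phi); dc <- sin(phi)
  maxT <- sqrt(n1^2 + n2^2)
  t <- seq(0, maxT, by = step)
  r <- round(center[1] + t * dr)
  c <- round(center[2] + t * dc)
  ok <- r >= 1 & r <= n1 & c >= 1 & c <= n2
  t <- t[ok]
  list(t = t, lab = lab[cbind(r[ok], c[ok])])
}

#' Radial lumen/neointima profile of one frame
#'
#' Casts `nRays` rays clockwise from 12 o'clock about `center`. Per ray,
#' the lumen radius is the distance to the last lumen pixel and the
#' neointimal thickness is the contiguous wall run (neointima, with
#' embedded struts counted as wall) immediately beyond the lumen boundary.
#' Rays whose lumen run reaches the image border (no boundary, e.g. a
#' side-branch opening) and rays with no lumen at all report `NA`.
#'
#' @param mask Postprocessed [OCTMask-class].
#' @param center `(row, col)`; default [lumenCenter()] of the mask.
#' @param nRays Number of rays (default 360, i.e. 1 degree).
#' @param spacingMm Pixel size in mm used to scale the outputs.
#' @return `data.frame(angle, lumenRadiusMm, neointimaThicknessMm)`; all
#'   `NA` (with attribute `degenerate`) when the mask has no lumen.
#' @export
radialProfile <- function(mask, center = NULL, nRays = 360L,
                          spacingMm = 0.01) {
  lab <- maskLabels(mask)
  if (is.null(center)) center <- lumenCenter(mask)
  angles <- (seq_len(nRays) - 1L) * 360 / nRays
  out <- data.frame(angle = angles, lumenRadiusMm = NA_real_,
                    neointimaThicknessMm = NA_real_)
  if (isTRUE(attr(center, "degenerate")) || !any(lab == 1L)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  for (i in seq_len(nRays)) {
    ray <- castRay(lab, center, angles[i])
    lum <- which(ray$lab == 1L)
    if (!length(lum)) next
    last <- max(lum)
    if (last == length(ray$lab)) next            # lumen reaches border
    ## midpoint boundary estimate: the true boundary lies between the last
    ## lumen sample and the next step, so add half a sampling step
    out$lumenRadiusMm[i] <- (ray$t[last] + 0.25) * spacingMm
    j <- last + 1L
    run <- 0L
    while (j <= length(ray$lab) && ray$lab[j] %in% c(2L, 3L)) {
      run <- run + 1L
      j <- j + 1L
    }
    ## pure-strut runs (an uncovered strut against the boundary) are not wall
    hasNeo <- run > 0L && any(ray$lab[(last + 1L):(last + run)] == 2L)
    out$neointimaThicknessMm[i] <- if (hasNeo) run * 0.5 * spacingMm else 0
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Morphometrics of one frame
#'
#' @param mask Postprocessed [OCTMask-class].
#' @param spacingMm Pixel size (mm).
#' @param nRays Rays for the radial profile.
#' @return `list`: mean/min/max lumen radius (mm), mean/max neointimal
#'   thickness (mm), lumen and neointima areas (mm^2), strut counts, and
#'   the per-ray profile.
#' @export
frameMorphometrics <- function(mask, spacingMm = 0.01, nRays = 360L) {
  lab <- maskLabels(mask)
  prof <- radialProfile(mask, nRays = nRays, spacingMm = spacingMm)
  struts <- uncoveredStruts(mask)
  pxArea <- spacingMm^2
  r <- prof$lumenRadiusMm; th <- prof$neointimaThicknessMm
  list(meanLumenRadiusMm = mean(r, na.rm = TRUE),
       minLumenRadiusMm = suppressWarnings(min(r, na.rm = TRUE)),
       maxLumenRadiusMm = suppressWarnings(max(r, na.rm = TRUE)),
       meanNeointimaThicknessMm = mean(th, na.rm = TRUE),
       maxNeointimaThicknessMm = suppressWarnings(max(th, na.rm = TRUE)),
       lumenAreaMm2 = sum(lab == 1L) * pxArea,
       neointimaAreaMm2 = sum(lab == 2L) * pxArea,
       strutCount = struts$total, uncoveredStrutCount = struts$uncovered,
       profile = prof,
       degenerate = isTRUE(attr(prof, "degenerate")))
}

#' Minimal lumen diameter along a pullback
#'
#' Per frame, the diameter is the minimum over angles of the sum of
#' opposing-ray lumen radii (`radius(theta) + radius(theta + 180)`), which
#' is robust to an off-center reference point. Returns the frame minimizing
#' it within the stent interval (ties resolved to the lowest frame index).
#'
#' @param masks List of postprocessed [OCTMask-class], pullback order.
#' @param spacingMm Pixel size (mm).
#' @param stentInterval 0-based `c(first, last)` stent interval; default
#'   detected with [stentBoundaries()]; pass `c(0, length(masks) - 1)` to
#'   search the whole pullback.
#' @param nRays Rays per frame (even).
#' @return `list(frame, diameterMm)` with `frame` 0-based.
#' @export
minimalLumenDiameter <- function(masks, spacingMm = 0.01,
                                 stentInterval = NULL, nRays = 360L) {
  if (is.null(stentInterval)) {
    sb <- stentBoundaries(masks)
    if (!sb$detected)
      stop("no stented frames with lumen", call. = FALSE)
    stentInterval <- c(sb$start, sb$end)
  }
  idx <- (stentInterval[1]:stentInterval[2]) + 1L
  half <- nRays / 2
  best <- NULL
  for (i in idx) {
    prof <- radialProfile(masks[[i]], nRays = nRays, spacingMm = spacingMm)
    r <- prof$lumenRadiusMm
    if (all(is.na(r))) next
    d <- r[seq_len(half)] + r[seq_len(half) + half]
    dmin <- suppressWarnings(min(d, na.rm = TRUE))
    if (!is.finite(dmin)) next
    if (is.null(best) || dmin < best$diameterMm - 1e-12)
      best <- list(frame = i - 1L, diameterMm = dmin)
  }
  if (is.null(best))
    stop("no stented frames with lumen", call. = FALSE)
  best
}

#' Detect uncovered stent struts in one frame
#'
#' Struts are connected components of the strut label. A strut is uncovered
#' iff its 1-px dilation touches lumen pixels and the neointima run between
#' its luminal face and the lumen along its centroid ray does not exceed
#' `coverThreshold` pixels (default 0: direct lumen contact).
#'
#' @param mask Postprocessed [OCTMask-class].
#' @param coverThreshold Maximum tolerated neointima run (px).
#' @return `list(total, uncovered, flags)` with one logical flag per strut
#'   component.
#' @export
uncoveredStruts <- function(mask, coverThreshold = 0) {
  lab <- maskLabels(mask)
  str <- lab == 3L
  if (!any(str)) return(list(total = 0L, uncovered = 0L, flags = logical(0)))
  comp <- EBImage::bwlabel(str)
  nComp <- max(comp)
  lum <- lab == 1L
  ctr <- lumenCenter(mask)
  brush <- EBImage::makeBrush(3, "box")
  flags <- vapply(seq_len(nComp), function(k) {
    m <- comp == k
    touches <- any((EBImage::dilate(m + 0, brush) > 0) & lum)
    if (!touches) return(FALSE)
    if (coverThreshold <= 0) return(TRUE)
    ## neointima run between lumen boundary and strut face on the centroid ray
    idx <- which(m, arr.ind = TRUE)
    cen <- colMeans(idx)
    th <- clockAngle(cen[1] - ctr[1], cen[2] - ctr[2])
    ray <- castRay(lab, ctr, th)
    lumLast <- suppressWarnings(max(which(ray$lab == 1L)))
    strFirst <- suppressWarnings(min(which(ray$lab == 3L)))
    if (!is.finite(lumLast) || !is.finite(strFirst) || strFirst <= lumLast)
      return(TRUE)
    run <- sum(ray$lab[lumLast:strFirst] == 2L) * 0.5
    run <= coverThreshold
  }, logical(1))
  list(total = nComp, uncovered = sum(flags), flags = flags)
}

#' Locate the stented segment of a pullback
#'
#' Per-frame strut pixel counts are median-filtered (window 3) and
#' thresholded at `max(minCount, 10%)` of the median nonzero smoothed
#' count; the first and last frame passing the threshold bound the stent.
#' A pullback in which no frame passes reports `detected = FALSE` rather
#' than raising.
#'
#' @param masks List of [OCTMask-class], pullback order.
#' @param minCount Absolute floor of the strut-pixel threshold (default 5).
#' @return `list(detected, start, end, counts)`, frames 0-based.
#' @export
stentBoundaries <- function(masks, minCount = 5) {
  counts <- vapply(masks, function(m) sum(maskLabels(m) == 3L), numeric(1))
  sm <- if (length(counts) >= 3) stats::runmed(counts, 3) else counts
  nz <- sm[sm > 0]
  if (!length(nz))
    return(list(detected = FALSE, start = NA_integer_, end = NA_integer_,
                counts = counts))
  thr <- max(minCount, 0.1 * median(nz))
  pass <- which(sm >= thr)
  if (!length(pass))
    return(list(detected = FALSE, start = NA_integer_, end = NA_integer_,
                counts = counts))
  list(detected = TRUE, start = min(pass) - 1L, end = max(pass) - 1L,
       counts = counts)
}
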