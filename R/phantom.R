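## Synthetic stented-vessel phantom generator.
##
## Geometry is defined in polar coordinates about the lumen center with the
## clockwise-from-12-o'clock angle convention used everywhere in the package.
## Thickness and tissue class are piecewise constant over equal angular
## sectors, which keeps per-pixel mask membership exactly reproducible by a
## brute-force distance/angle oracle.

#' Construct a phantom frame specification
#'
#' Builds and validates a [PhantomSpec-class]. Tissue classes can be given
#' per quadrant (length 4, expanded to sectors) or per sector directly.
#' Requesting `"not_analyzable"` for a quadrant places an uncovered strut at
#' that quadrant's bisector (if none is there already), since the class is
#' defined structurally: a quadrant with uncovered struts or a side-branch
#' opening.
#'
#' @param imageSize Pixels per side (square frame). Default 512.
#' @param pixelSpacing Physical pixel size in mm. Default 0.01 mm/px.
#' @param lumenCenter `(row, col)` subpixel lumen center; default the image
#'   center.
#' @param lumenRadius Lumen radius in px.
#' @param thickness Neointima thickness in px: scalar or per-sector vector
#'   (recycled to `nSectors`).
#' @param tissue Tissue classes: length 1, 4 (per quadrant) or `nSectors`
#'   (per sector). `"not_analyzable"` allowed only in the per-quadrant form.
#' @param nSectors Number of equal angular sectors (multiple of 4).
#' @param strutAngles Clockwise strut-center angles in degrees; `NULL` to
#'   place `nStruts` uniformly.
#' @param nStruts Number of struts when `strutAngles` is `NULL`.
#' @param strutCovered Logical, recycled per strut. Covered struts are
#'   embedded in the neointima; uncovered ones protrude into the lumen with
#'   no neointima over them.
#' @param strutRadius Strut disc radius in px.
#' @param sideBranch Angular interval `c(from, to)` degrees of a side-branch
#'   opening, or `NULL`.
#' @param noiseLevel Speckle intensity scale.
#' @param seed Integer seed for texture rendering.
#' @return A validated [PhantomSpec-class].
#' @export
#' @examples
#' sp <- phantomSpec(imageSize = 96, lumenRadius = 22, thickness = 10,
#'                   tissue = "homogeneous", nStruts = 4, seed = 1)
#' ph <- generatePhantomFrame(sp)
#' table(maskLabels(truthMask(ph)))
phantomSpec <- function(imageSize = 512L, pixelSpacing = 0.01,
                        lumenCenter = NULL, lumenRadius = imageSize / 5,
                        thickness = imageSize / 12,
                        tissue = "homogeneous", nSectors = 8L,
                        strutAngles = NULL, nStruts = 0L,
                        strutCovered = TRUE,
                        strutRadius = 3, sideBranch = NULL,
                        noiseLevel = 0.08, seed = 1L) {
  imageSize <- as.integer(imageSize)
  nSectors <- as.integer(nSectors)
  if (nSectors %% 4L != 0L)
    stop("nSectors must be a multiple of 4", call. = FALSE)
  if (is.null(lumenCenter))
    lumenCenter <- rep((imageSize + 1) / 2, 2)
  thickness <- rep_len(as.numeric(thickness), nSectors)

  tissue <- normalizeClassLabel(tissue)
  forcedNA <- logical(4)
  if (length(tissue) == 1L) tissue <- rep(tissue, 4L)
  if (length(tissue) == 4L) {
    forcedNA <- tissue == "not_analyzable"
    tissue[forcedNA] <- "homogeneous"   # rendered texture under the override
    tissue <- rep(tissue, each = nSectors / 4L)
  }
  if (length(tissue) != nSectors)
    stop("tissue must have length 1, 4 or nSectors", call. = FALSE)
  if (any(tissue == "not_analyzable"))
    stop("not_analyzable is structural; request it per quadrant", call. = FALSE)

  if (is.null(strutAngles)) {
    nStruts <- as.integer(nStruts)
    strutAngles <- if (nStruts > 0)
      (seq_len(nStruts) - 0.5) * 360 / nStruts else numeric(0)
  }
  strutCovered <- rep_len(as.logical(strutCovered), length(strutAngles))
  if (length(strutAngles) && any(strutCovered) && all(thickness == 0))
    stop("invalid spec: covered struts require nonzero neointima",
         call. = FALSE)

  ## structural guarantee for requested not_analyzable quadrants
  for (q in which(forcedNA)) {
    qiv <- c((q - 1) * 90, q * 90)
    inQ <- strutAngles >= qiv[1] & strutAngles < qiv[2] & !strutCovered
    branchInQ <- !is.null(sideBranch) &&
      anglesOverlap(sideBranch, qiv)
    if (!any(inQ) && !branchInQ) {
      strutAngles <- c(strutAngles, (q - 0.5) * 90)
      strutCovered <- c(strutCovered, FALSE)
    }
  }

  new("PhantomSpec", imageSize = imageSize,
      pixelSpacing = as.numeric(pixelSpacing),
      lumenCenter = as.numeric(lumenCenter),
      lumenRadius = as.numeric(lumenRadius), thickness = thickness,
      tissueSectors = tissue, strutAngles = as.numeric(strutAngles %% 360),
      strutCovered = strutCovered, strutRadius = as.numeric(strutRadius),
      sideBranch = if (is.null(sideBranch)) numeric(0)
                   else as.numeric(sideBranch),
      noiseLevel = as.numeric(noiseLevel), seed = as.integer(seed))
}

## TRUE when the angular interval [a1, a2) (degrees, may wrap) overlaps
## [b1, b2).
anglesOverlap <- function(a, b) {
  grid <- seq(0, 359.5, by = 0.5)
  inA <- angleIn(grid, a); inB <- angleIn(grid, b)
  any(inA & inB)
}

angleIn <- function(theta, iv) {
  a <- iv[1] %% 360; b <- iv[2] %% 360
  th <- theta %% 360
  if (iv[2] - iv[1] >= 360) rep(TRUE, length(th))
  else if (a <= b) th >= a & th < b
  else th >= a | th < b
}

#' Render a phantom frame with exact ground truth
#'
#' Renders the grayscale image, the exact segmentation mask and the four
#' quadrant labels for a [PhantomSpec-class]. Deterministic for a fixed
#' seed. The mask is exact by construction: a pixel is lumen iff its radius
#' is below the lumen boundary, neointima iff it falls inside the annulus of
#' its angular sector, strut iff inside a strut disc (struts override tissue
#' labels); uncovered struts protrude into the lumen and carry no neointima
#' over them, and a side-branch opening interrupts the annulus.
#'
#' Tissue textures encode the OCT appearance of the classes: homogeneous =
#' uniform single-scale speckle; heterogeneous = two-scale speckle under a
#' patchy gain field; neoatherosclerosis = bright superficial rim with
#' strong depth attenuation leaving a signal-poor core.
#'
#' @param spec A valid [PhantomSpec-class].
#' @return A [PhantomTruth-class].
#' @export
generatePhantomFrame <- function(spec) {
  validObject(spec)
  n <- spec@imageSize
  geom <- phantomGeometry(spec)
  mask <- geom$mask
  img <- withSeed(spec@seed, renderPhantomImage(spec, geom))
  labels <- quadrantTruthLabels(spec)
  new("PhantomTruth", image = img, mask = OCTMask(mask),
      quadrantLabels = labels, spec = spec)
}

## Exact geometric membership (no RNG): returns the label mask plus the
## polar grids and per-pixel annulus bookkeeping reused by the renderer.
phantomGeometry <- function(spec) {
  n <- spec@imageSize
  pg <- polarGrid(n, spec@lumenCenter)
  nS <- length(spec@thickness)
  sect <- sectorIndex(pg$theta, nS)
  thick <- matrix(spec@thickness[sect], n, n)

  ## side branch interrupts the annulus
  if (length(spec@sideBranch))
    thick[angleIn(pg$theta, spec@sideBranch)] <- 0

  ## uncovered struts carry no neointima over them: zero the annulus in a
  ## narrow angular window around each uncovered strut
  halfwin <- pmax(6, 2.5 * spec@strutRadius / spec@lumenRadius * 180 / pi)
  for (k in seq_along(spec@strutAngles)) {
    if (!spec@strutCovered[k])
      thick[angleIn(pg$theta, spec@strutAngles[k] + c(-halfwin, halfwin))] <- 0
  }

  R <- spec@lumenRadius
  lumen <- pg$r < R
  neo <- pg$r >= R & pg$r < R + thick

  mask <- matrix(0L, n, n)
  mask[lumen] <- 1L
  mask[neo] <- 2L

  ## struts override; record centers for rendering and truth flags
  strutRC <- strutCenters(spec)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (k in seq_len(nrow(strutRC))) {
    d2 <- (rows - strutRC[k, 1])^2 + (cols - strutRC[k, 2])^2
    mask[d2 <= spec@strutRadius^2] <- 3L
  }

  list(mask = mask, r = pg$r, theta = pg$theta, thick = thick, R = R,
       struts = strutRC, sect = sect)
}

## Strut center (row, col, radius) per strut. Covered struts sit embedded in
## the annulus; uncovered struts protrude luminal to the boundary.
strutCenters <- function(spec) {
  nK <- length(spec@strutAngles)
  out <- matrix(numeric(0), 0, 3)
  if (!nK) return(out)
  nS <- length(spec@thickness)
  R <- spec@lumenRadius
  out <- matrix(0, nK, 3)
  for (k in seq_len(nK)) {
    th <- spec@strutAngles[k]
    tk <- spec@thickness[sectorIndex(th, nS)]
    sr <- spec@strutRadius
    ## covered: embedded with >= 3 px of neointima on the luminal side so
    ## neither the strut nor its blooming ring touches the lumen;
    ## uncovered: protrudes inward
    rad <- if (spec@strutCovered[k]) {
      gap <- min(max(tk / 2 - sr, 3), tk - 2 * sr)
      R + gap + sr
    } else R - 1.2 * sr
    phi <- th * pi / 180
    out[k, ] <- c(spec@lumenCenter[1] - rad * cos(phi),
                  spec@lumenCenter[2] + rad * sin(phi), rad)
  }
  out
}

## Texture rendering; called under the spec seed.
renderPhantomImage <- function(spec, geom) {
  n <- spec@imageSize
  nz <- spec@noiseLevel
  img <- 0.04 * abs(speckleField(n, 0.8))           # dark background
  img[geom$mask == 1L] <- 0.03 + 0.25 * nz * abs(speckleField(n, 0.6))[geom$mask == 1L]

  depth <- geom$r - geom$R                           # px beyond lumen boundary
  neo <- geom$mask == 2L

  sp1 <- speckleField(n, 1.2)                        # fine speckle
  sp2 <- speckleField(n, 4)                          # coarse speckle
  gain <- speckleField(n, 8)                         # patchy gain field

  tex <- matrix(0, n, n)
  tisByPix <- matrix(spec@tissueSectors[geom$sect], n, n)

  ## homogeneous: uniform light reflection, single-scale fine speckle
  hom <- neo & tisByPix == "homogeneous"
  tex[hom] <- 0.62 * (1 + 1.8 * nz * sp1[hom])

  ## heterogeneous: focal backscattering variation — strong bimodal gain
  ## patches on top of two-scale speckle
  het <- neo & tisByPix == "heterogeneous"
  g <- 0.55 + 0.75 * (gain > 0.2)
  tex[het] <- 0.55 * g[het] * (1 + 2 * nz * sp1[het] + 3.5 * nz * sp2[het])

  ## neoatherosclerosis: bright superficial rim, rapid depth attenuation
  ## into a signal-poor core (lipid/foam-cell appearance)
  nac <- neo & tisByPix == "neoatherosclerosis"
  prof <- 0.8 * exp(-pmax(depth - 1.5, 0) / 2.8) + 0.03
  tex[nac] <- prof[nac] * (1 + 1.2 * nz * sp1[nac])

  ## tissue backscatter never saturates; only metal struts do
  img[neo] <- pmin(tex[neo], 0.92)

  ## struts: specular metallic reflectors, brighter than any tissue. A
  ## 1-px blooming ring at full strut brightness bleeds past the true
  ## boundary (the classic OCT strut artifact): the image cannot tell ring
  ## from strut, which is what keeps the tiny strut class the hardest to
  ## match — without planting strut-like signal away from real struts.
  strutPx <- geom$mask == 3L
  if (any(strutPx)) {
    bloom <- EBImage::dilate(strutPx + 0, EBImage::makeBrush(3, "box")) > 0
    img[bloom] <- 0.97 + 0.3 * nz * abs(sp1[bloom])
  }

  ## radial shadows behind struts (image only, mask untouched)
  for (k in seq_len(nrow(geom$struts))) {
    th <- spec@strutAngles[k]
    halfw <- (spec@strutRadius / geom$struts[k, 3]) * 180 / pi * 1.3
    sh <- geom$r > geom$struts[k, 3] + spec@strutRadius &
      angleIn(geom$theta, th + c(-halfw, halfw)) & geom$mask != 3L
    img[sh] <- img[sh] * 0.3
  }
  clamp01(img)
}

## Quadrant ground-truth labels: tissues present in each quadrant reduced by
## the severity rule, overridden structurally by uncovered struts or a
## side-branch opening. Structural features are attributed by their angular
## pixel extent, not just their center: a strut straddling a quadrant edge
## makes both quadrants not analyzable (>= 2 degrees of strut visible); a
## side branch must open into a quadrant by >= 5 degrees to count.
quadrantTruthLabels <- function(spec) {
  nS <- length(spec@thickness)
  perQ <- nS / 4L
  overlapDeg <- function(iv, qiv) {
    grid <- seq(0, 359.75, by = 0.25)
    sum(angleIn(grid, iv) & angleIn(grid, qiv)) * 0.25
  }
  sr <- spec@strutRadius
  uncAngles <- spec@strutAngles[!spec@strutCovered]
  rk <- max(spec@lumenRadius - 1.2 * sr, sr)
  wk <- asin(min(1, sr / rk)) * 180 / pi
  vapply(1:4, function(q) {
    sectors <- ((q - 1L) * perQ + 1L):(q * perQ)
    present <- unique(spec@tissueSectors[sectors][spec@thickness[sectors] > 0])
    if (!length(present)) present <- "homogeneous"   # bare quadrant
    qiv <- c((q - 1) * 90, q * 90)
    unc <- any(vapply(uncAngles, function(a)
      overlapDeg(a + c(-wk, wk), qiv) >= 2, logical(1)))
    br <- length(spec@sideBranch) > 0 &&
      overlapDeg(spec@sideBranch, qiv) >= 5
    severityLabel(present, uncoveredStrut = unc, sideBranch = br)
  }, character(1))
}

#' Generate a synthetic pullback
#'
#' Produces a sequence of phantom frames with per-frame randomized geometry
#' and tissue classes, a configurable stent interval outside which frames
#' contain no struts, a fixed inter-frame spacing of 0.2 mm (five frames per
#' millimetre), and annotation flags marking every fifth frame (the every-
#' 1-mm manual scoring convention).
#'
#' @param nFrames Number of frames (>= 1).
#' @param seed Integer seed; drives all per-frame randomization.
#' @param imageSize Pixels per side of each frame.
#' @param stentFrames 0-based `c(first, last)` stented frame interval;
#'   default the whole pullback; `NULL` for an unstented pullback.
#' @param pixelSpacing mm per pixel.
#' @param pUncovered Probability that a strut in a stented frame is
#'   uncovered.
#' @param pSideBranch Probability that a frame shows a side-branch opening.
#' @param nStrutsRange Integer range of strut counts per stented frame.
#' @param overrides Optional list keyed by 1-based frame position of named
#'   lists overriding `phantomSpec()` arguments for that frame (e.g.
#'   `list("7" = list(lumenRadius = 12))` for a stenotic frame).
#' @return A [PhantomPullback-class].
#' @export
#' @examples
#' pb <- generatePullback(6, seed = 3, imageSize = 96,
#'                        stentFrames = c(1, 4))
#' sum(annotatedFrames(pb))
generatePullback <- function(nFrames, seed = 1L, imageSize = 512L,
                             stentFrames = c(0L, nFrames - 1L),
                             pixelSpacing = 0.01, pUncovered = 0.15,
                             pSideBranch = 0.1, nStrutsRange = c(6L, 9L),
                             overrides = list()) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) stop("nFrames must be >= 1", call. = FALSE)
  if (!is.null(stentFrames)) {
    stentFrames <- as.integer(stentFrames)
    if (length(stentFrames) != 2L || stentFrames[1] > stentFrames[2] ||
        stentFrames[1] < 0L || stentFrames[2] >= nFrames)
      stop("invalid spec: stent interval outside [0, n_frames)",
           call. = FALSE)
  }

  truths <- withSeed(seed, {
    lapply(seq_len(nFrames), function(i) {
      idx0 <- i - 1L
      stented <- !is.null(stentFrames) &&
        idx0 >= stentFrames[1] && idx0 <= stentFrames[2]
      radius <- stats::runif(1, 0.16, 0.24) * imageSize
      center <- (imageSize + 1) / 2 +
        stats::runif(2, -0.04, 0.04) * imageSize
      thick <- stats::runif(8, 0.4, 1.4) * imageSize / 14
      ## tissue classes are angularly coherent within a frame, as in real
      ## vessels: a dominant per-frame class with occasional deviations
      dominant <- sample(.TISSUES, 1, prob = c(0.5, 0.3, 0.2))
      tissue <- ifelse(stats::runif(4) < 0.65, dominant,
                       sample(.TISSUES, 4, replace = TRUE,
                              prob = c(0.5, 0.3, 0.2)))
      nStruts <- if (stented)
        sample(seq(nStrutsRange[1], nStrutsRange[2]), 1) else 0L
      covered <- if (nStruts) stats::runif(nStruts) > pUncovered else logical(0)
      strutR <- max(2.5, imageSize / 170)
      ## covered struts must be embeddable in the annulus
      if (any(covered)) thick <- pmax(thick, 2 * strutR + 3.5)
      branch <- if (stats::runif(1) < pSideBranch) {
        a <- stats::runif(1, 0, 360); c(a, a + stats::runif(1, 25, 50))
      } else NULL
      args <- list(imageSize = imageSize, pixelSpacing = pixelSpacing,
                   lumenCenter = center, lumenRadius = radius,
                   thickness = pmax(thick, 2.5), tissue = tissue,
                   strutAngles = if (nStruts)
                     sort(stats::runif(nStruts, 0, 360)) else NULL,
                   nStruts = 0L, strutCovered = covered,
                   strutRadius = strutR,
                   sideBranch = branch,
                   seed = sample.int(.Machine$integer.max, 1))
      ov <- overrides[[as.character(i)]]
      if (!is.null(ov)) args[names(ov)] <- ov
      generatePhantomFrame(do.call(phantomSpec, args))
    })
  })

  annotated <- (seq_len(nFrames) %% 5L) == 0L
  if (!any(annotated)) annotated[nFrames] <- TRUE
  new("PhantomPullback", truths = truths,
      stentRange = if (is.null(stentFrames)) integer(0) else stentFrames,
      frameSpacing = 0.2, annotated = annotated, seed = as.integer(seed))
}

#' Convert phantom truths to plain OCT frames
#'
#' Strips ground truth, yielding the [OCTFrame-class] sequence a reader
#' would produce for the same pullback.
#'
#' @param pullback A [PhantomPullback-class].
#' @return List of [OCTFrame-class].
#' @export
pullbackFrames <- function(pullback) {
  lapply(seq_along(pullback@truths), function(i) {
    t <- pullback@truths[[i]]
    OCTFrame(t@image, index = i - 1L,
             spacing = c(t@spec@pixelSpacing, t@spec@pixelSpacing,
                         pullback@frameSpacing))
  })
}
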