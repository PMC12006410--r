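## Pixelwise 4-class segmentation (background / lumen / neointima / strut).
##
## The model is pluggable behind the SegModel handle; the default desk-scale
## model is a random forest over multiscale intensity/texture features per
## pixel, trained with stratified per-class pixel sampling (the
## inverse-imbalance device that keeps the tiny strut class from
## collapsing). Forest prediction runs single-threaded with a fixed seed so
## results are bit-reproducible.

.SEG_FEATURES <- c("intensity", "smooth2", "smooth6", "sd2", "sd6",
                   "detail", "radial")

## Per-pixel feature matrix for one image.
segFeatures <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  s2 <- EBImage::gblur(img, sigma = 2)
  s6 <- EBImage::gblur(img, sigma = 6)
  dr <- matrix(seq_len(n1) - (n1 + 1) / 2, n1, n2)
  dc <- matrix(seq_len(n2) - (n2 + 1) / 2, n1, n2, byrow = TRUE)
  rad <- sqrt(dr^2 + dc^2) / (min(n1, n2) / 2)
  cbind(intensity = as.vector(img), smooth2 = as.vector(s2),
        smooth6 = as.vector(s6), sd2 = as.vector(localSD(img, 2)),
        sd6 = as.vector(localSD(img, 6)),
        detail = as.vector(abs(img - s2)), radial = as.vector(rad))
}

#' Train the pixelwise segmenter
#'
#' Fits the default desk-scale model (a probability random forest over
#' multiscale texture features) on frame/mask pairs. Pixels are sampled
#' stratified by class (up to `config$pixelsPerClass` per class per frame)
#' to counter the extreme lumen/strut imbalance. Deterministic for a fixed
#' seed. Per-class Dice on a held-out validation split of the training
#' frames is logged in the handle's history.
#'
#' @param frames List of [OCTFrame-class] (or image matrices).
#' @param masks List of [OCTMask-class], same length and shapes.
#' @param config Named list of settings; recognized entries (with defaults):
#'   `numTrees` (150), `pixelsPerClass` (350), `valFraction` (0.15),
#'   `minNodeSize` (5).
#' @param seed Integer training seed.
#' @return A [SegModel-class] handle.
#' @export
trainSegmenter <- function(frames, masks, config = list(), seed = 1L) {
  if (!length(frames)) stop("empty training set", call. = FALSE)
  if (length(frames) != length(masks))
    stop("frame and mask counts differ", call. = FALSE)
  cfg <- utils::modifyList(
    list(numTrees = 150L, pixelsPerClass = 350L, valFraction = 0.15,
         minNodeSize = 5L), config)
  imgs <- lapply(frames, function(f)
    if (is(f, "OCTFrame")) octImage(f) else f)
  labs <- lapply(masks, function(m)
    if (is(m, "OCTMask")) maskLabels(m) else m)
  for (i in seq_along(imgs))
    if (!identical(dim(imgs[[i]]), dim(labs[[i]])))
      stop("frame/mask shape mismatch at position ", i, call. = FALSE)
  if (length(unique(unlist(lapply(labs, unique)))) < 2L)
    stop("training masks contain fewer than 2 classes", call. = FALSE)

  nVal <- max(0L, round(cfg$valFraction * length(imgs)))
  fit <- withSeed(seed, {
    valIdx <- if (nVal > 0) sample(seq_along(imgs), nVal) else integer(0)
    trIdx <- setdiff(seq_along(imgs), valIdx)
    if (!length(trIdx)) { trIdx <- seq_along(imgs); valIdx <- integer(0) }

    sampleFrame <- function(i) {
      X <- segFeatures(imgs[[i]])
      y <- as.vector(labs[[i]])
      keep <- unlist(lapply(unique(y), function(k) {
        w <- which(y == k)
        if (length(w) > cfg$pixelsPerClass)
          sample(w, cfg$pixelsPerClass) else w
      }))
      list(X = X[keep, , drop = FALSE], y = y[keep])
    }
    tr <- lapply(trIdx, sampleFrame)
    X <- do.call(rbind, lapply(tr, `[[`, "X"))
    y <- factor(unlist(lapply(tr, `[[`, "y")), levels = 0:3)
    rf <- ranger::ranger(
      x = as.data.frame(X), y = droplevels(y),
      num.trees = cfg$numTrees, probability = TRUE,
      min.node.size = cfg$minNodeSize,
      seed = seed, num.threads = 1L)
    list(rf = rf, valIdx = valIdx)
  })

  model <- new("SegModel", fit = fit$rf,
               config = c(cfg, list(features = .SEG_FEATURES)),
               seed = as.integer(seed),
               history = data.frame())
  if (length(fit$valIdx)) {
    dices <- vapply(fit$valIdx, function(i) {
      pred <- segmentFrame(model, imgs[[i]])
      maskDice(pred, OCTMask(labs[[i]]))
    }, numeric(3))
    model@history <- data.frame(round = 1L, t(rowMeans(dices)))
  }
  model
}

#' Segment one frame
#'
#' Predicts per-pixel class probabilities, takes the argmax (ties resolved
#' to the lowest class index) and applies [postprocessMask()].
#'
#' @param model A [SegModel-class].
#' @param frame An [OCTFrame-class] or image matrix in `[0,1]`.
#' @param postprocess Apply mask postprocessing (default `TRUE`).
#' @return An [OCTMask-class] with the frame's shape.
#' @export
segmentFrame <- function(model, frame, postprocess = TRUE) {
  img <- if (is(frame, "OCTFrame")) octImage(frame) else frame
  X <- segFeatures(img)
  pr <- predict(model@fit, as.data.frame(X), num.threads = 1L,
                seed = model@seed)$predictions
  ## columns are the trained class levels; expand to the full label set
  full <- matrix(0, nrow(pr), 4L,
                 dimnames = list(NULL, as.character(0:3)))
  full[, colnames(pr)] <- pr
  lab <- max.col(full, ties.method = "first") - 1L
  raw <- OCTMask(matrix(as.integer(lab), nrow(img), ncol(img)))
  if (postprocess) postprocessMask(raw, imageSize = nrow(img)) else raw
}

#' Postprocess a raw segmentation mask
#'
#' Reduces the lumen to its largest connected component with holes filled
#' (struts and neointima inside a filled hole keep their labels), removes
#' strut components smaller than `minStrutArea` pixels, and leaves the
#' neointima unchanged. Never introduces labels absent from the raw mask
#' (other than background).
#'
#' @param raw An [OCTMask-class].
#' @param minStrutArea Minimum strut component area in px; default 5 at
#'   512x512, scaled by `(imageSize/512)^2`.
#' @param imageSize Reference size used for the strut-area scaling.
#' @return A postprocessed [OCTMask-class].
#' @export
postprocessMask <- function(raw, minStrutArea = NULL,
                            imageSize = nrow(maskLabels(raw))) {
  lab <- maskLabels(raw)
  checkMaskValues(lab)
  if (is.null(minStrutArea))
    minStrutArea <- max(1, round(5 * (imageSize / 512)^2))

  out <- lab
  lum <- lab == 1L
  if (any(lum)) {
    comp <- EBImage::bwlabel(lum)
    sizes <- tabulate(comp[comp > 0])
    keep <- which.max(sizes)
    main <- comp == keep
    filled <- EBImage::fillHull(main) > 0
    out[lum] <- 0L                               # drop minor lumen blobs
    newLum <- filled & !(lab == 3L) & !(lab == 2L)
    out[newLum] <- 1L
  }

  str <- lab == 3L
  if (any(str)) {
    comp <- EBImage::bwlabel(str)
    sizes <- tabulate(comp[comp > 0])
    drop <- which(sizes < minStrutArea)
    if (length(drop)) out[str & comp %in% drop] <- 0L
  }
  OCTMask(out)
}
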