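## Metrics and protocols: Dice, classification metrics, Fleiss kappa,
## equal-count reliability curves, patient-grouped k-fold splits.

#' Dice overlap of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`, in `[0,1]`; 1 means complete overlap, 0 none.
#' When both masks are empty the score is defined as 1 (flagged via the
#' `bothEmpty` attribute): frames with absent neointima are the canonical
#' low-score edge case and a defined value avoids NaN propagation.
#'
#' @param a,b Logical (or 0/1) matrices of the same shape.
#' @return Numeric Dice score with attribute `bothEmpty`.
#' @export
diceScore <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) {
    out <- 1
    attr(out, "bothEmpty") <- TRUE
    return(out)
  }
  out <- 2 * sum(a & b) / (sa + sb)
  attr(out, "bothEmpty") <- FALSE
  out
}

#' Per-class Dice between two label masks
#'
#' @param pred,truth [OCTMask-class] objects (or integer label matrices).
#' @param classes Integer labels to score (default the three foreground
#'   classes 1 = lumen, 2 = neointima, 3 = strut).
#' @return Named numeric vector of Dice scores.
#' @export
maskDice <- function(pred, truth, classes = 1:3) {
  p <- if (is(pred, "OCTMask")) maskLabels(pred) else pred
  t <- if (is(truth, "OCTMask")) maskLabels(truth) else truth
  out <- vapply(classes, function(k) as.numeric(diceScore(p == k, t == k)),
                numeric(1))
  names(out) <- names(.MASK_LEVELS)[match(classes, .MASK_LEVELS)]
  out
}

#' Accuracy, macro-F1 and confusion matrix for quadrant labels
#'
#' Accuracy is the fraction of equal labels; macro-F1 is the unweighted mean
#' of per-class F1 scores, with classes absent from both truth and
#' prediction excluded from the average. The confusion matrix is 4x4 in the
#' canonical class order, rows = truth, columns = prediction.
#'
#' @param truth,pred Character vectors of class labels (free-form spellings
#'   are normalized).
#' @return `list(accuracy, macroF1, confusion)`.
#' @export
classificationMetrics <- function(truth, pred) {
  if (!length(truth) || length(truth) != length(pred))
    stop("truth and pred must be equal-length and non-empty", call. = FALSE)
  truth <- factor(normalizeClassLabel(truth), levels = .CLASSES)
  pred <- factor(normalizeClassLabel(pred), levels = .CLASSES)
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- vapply(.CLASSES, function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    if (tp + fp + fn == 0) return(NA_real_)   # absent everywhere
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(accuracy = acc, macroF1 = mean(f1, na.rm = TRUE),
       confusion = unclass(cm))
}

#' Fleiss kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning each of `N` items to
#' one of `k` categories: `kappa = (Pbar - Pe) / (1 - Pe)` with per-item
#' agreement averaged over items and expected agreement from the marginal
#' category proportions. When every rating falls in a single category the
#' expected agreement is 1 and kappa is undefined; `NA` is returned with
#' attribute `undefined = TRUE`.
#'
#' @param ratings Items x categories matrix of rating counts; every row must
#'   sum to the same number of raters (>= 2), and there must be >= 2 items.
#' @return Kappa, or flagged `NA` when undefined.
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  N <- nrow(ratings)
  if (N < 2L) stop("need >= 2 items", call. = FALSE)
  n <- sum(ratings[1, ])
  if (n < 2L) stop("need >= 2 raters", call. = FALSE)
  if (!all(rowSums(ratings) == n))
    stop("every item must have the same number of ratings", call. = FALSE)
  p <- colSums(ratings) / (N * n)
  Pbar <- mean((rowSums(ratings^2) - n) / (n * (n - 1)))
  Pe <- sum(p^2)
  if (1 - Pe < .Machine$double.eps) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- (Pbar - Pe) / (1 - Pe)
  attr(out, "undefined") <- FALSE
  out
}

#' Equal-count reliability curve
#'
#' Sorts samples by predicted confidence and splits them into `nBins`
#' equal-count bins (sizes differing by at most 1; ties broken by stable
#' sort order). Each bin reports its mean confidence, empirical accuracy
#' (true predictions / bin size) and size. The weighted mean of bin
#' accuracies equals the overall accuracy by construction.
#'
#' @param confidences Numeric in `[0,1]`.
#' @param correct Logical correctness flags, same length.
#' @param nBins Number of bins (default 10).
#' @return `data.frame(bin, meanConfidence, accuracy, size)`.
#' @export
calibrationCurve <- function(confidences, correct, nBins = 10L) {
  n <- length(confidences)
  if (n != length(correct))
    stop("confidences and correct must be equal length", call. = FALSE)
  if (n < nBins) stop("fewer samples than bins", call. = FALSE)
  if (any(confidences < -1e-9 | confidences > 1 + 1e-9))
    stop("confidences must lie in [0,1]", call. = FALSE)
  ord <- order(confidences)                      # stable in R
  conf <- confidences[ord]
  corr <- as.logical(correct)[ord]
  ## bin sizes differ by <= 1: first (n %% nBins) bins get the extra sample
  base <- n %/% nBins
  sizes <- rep(base, nBins) + c(rep(1L, n %% nBins),
                                rep(0L, nBins - n %% nBins))
  stopifnot(sum(sizes) == n)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(
    bin = seq_len(nBins),
    meanConfidence = vapply(seq_len(nBins), function(b)
      mean(conf[starts[b]:ends[b]]), numeric(1)),
    accuracy = vapply(seq_len(nBins), function(b)
      mean(corr[starts[b]:ends[b]]), numeric(1)),
    size = sizes)
}

#' Expected calibration error
#'
#' Size-weighted mean absolute gap between bin confidence and bin accuracy
#' over an equal-count reliability curve.
#'
#' @inheritParams calibrationCurve
#' @return Numeric ECE in `[0,1]`.
#' @export
expectedCalibrationError <- function(confidences, correct, nBins = 10L) {
  cc <- calibrationCurve(confidences, correct, nBins)
  sum(cc$size * abs(cc$meanConfidence - cc$accuracy)) / sum(cc$size)
}

#' Patient-grouped k-fold assignment
#'
#' Assigns frames to `k` folds such that all frames of a patient share a
#' fold (no information leak across folds) and fold frame-counts are as
#' balanced as the patient grouping allows: patients are taken
#' largest-first and greedily assigned to the currently smallest fold.
#' `seed` shuffles patients before sorting so ties break reproducibly but
#' not systematically.
#'
#' @param patientIds Character/factor patient id per frame.
#' @param k Number of folds (default 5); must not exceed the number of
#'   distinct patients.
#' @param seed Integer seed.
#' @return Integer fold index (1..k) per frame.
#' @export
patientKFold <- function(patientIds, k = 5L, seed = 1L) {
  patientIds <- as.character(patientIds)
  patients <- unique(patientIds)
  if (k > length(patients))
    stop("k exceeds the number of distinct patients", call. = FALSE)
  counts <- table(patientIds)[patients]
  ord <- withSeed(seed, sample(seq_along(patients)))
  patients <- patients[ord]; counts <- counts[ord]
  ord2 <- order(-as.integer(counts))             # largest-first, stable
  patients <- patients[ord2]; counts <- counts[ord2]
  foldSize <- numeric(k)
  foldOf <- setNames(integer(length(patients)), patients)
  for (i in seq_along(patients)) {
    f <- which.min(foldSize)
    foldOf[patients[i]] <- f
    foldSize[f] <- foldSize[f] + counts[i]
  }
  unname(foldOf[patientIds])
}
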