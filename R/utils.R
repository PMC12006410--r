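## Internal helpers shared across modules.

## Canonical class order used everywhere (probability vectors, confusion
## matrices, CSV output). Severity for the scoring rule is the order of
## .TISSUES; not_analyzable is assigned structurally, never by severity.
.CLASSES <- c("not_analyzable", "homogeneous", "heterogeneous",
              "neoatherosclerosis")
.TISSUES <- c("homogeneous", "heterogeneous", "neoatherosclerosis")

## Mask label encoding: 0 background, 1 lumen, 2 neointima, 3 strut.
.MASK_LEVELS <- c(background = 0L, lumen = 1L, neointima = 2L, strut = 3L)

#' Tissue class labels
#'
#' Returns the canonical class vocabulary used throughout the package, in the
#' fixed order probability vectors and confusion matrices are laid out:
#' `not_analyzable`, `homogeneous`, `heterogeneous`, `neoatherosclerosis`.
#'
#' @return Character vector of the four class labels.
#' @export
tissueClasses <- function() .CLASSES

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Natural sort: numeric runs inside filenames compare numerically, so
## frame_2 < frame_10 regardless of zero padding.
naturalSort <- function(x) {
  if (length(x) < 2L) return(x)
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  n <- max(lengths(toks))
  keys <- lapply(seq_len(n), function(i) {
    tk <- vapply(toks, function(t) if (i <= length(t)) t[i] else "",
                 character(1))
    num <- suppressWarnings(as.numeric(tk))
    if (all(!is.na(num) | tk == "")) {
      num[tk == ""] <- -Inf
      num
    } else tk
  })
  x[do.call(order, keys)]
}

## Clockwise angle (degrees, [0, 360)) from 12 o'clock, at pixel centers.
## Row 0/1 at top, so "up" is decreasing row; clockwise passes through
## increasing col at 90 degrees.
clockAngle <- function(drow, dcol) {
  (atan2(dcol, -drow) * 180 / pi) %% 360
}

## Polar coordinate grids for an image of side n about `center` (row, col).
polarGrid <- function(n, center) {
  dr <- matrix(seq_len(n) - center[1], n, n)
  dc <- matrix(seq_len(n) - center[2], n, n, byrow = TRUE)
  list(r = sqrt(dr^2 + dc^2), theta = clockAngle(dr, dc))
}

## Unit-variance smoothed noise field (speckle building block).
speckleField <- function(n, sigma) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (sigma > 0) z <- EBImage::gblur(z, sigma = sigma)
  s <- stats::sd(z)
  if (s < .Machine$double.eps) return(matrix(0, n, n))
  z / s
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Local standard deviation of an image at gaussian scale sigma.
localSD <- function(img, sigma) {
  m <- EBImage::gblur(img, sigma = sigma)
  m2 <- EBImage::gblur(img^2, sigma = sigma)
  sqrt(pmax(m2 - m^2, 0))
}

## Normalize free-text class labels ("Homogenous ", "NEOATHEROSCLEROSIS")
## to the canonical vocabulary; unknown strings raise a validation error.
normalizeClassLabel <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ -]+", "_", y)
  y[y == "homogenous"] <- "homogeneous"
  y[y == "heterogenous"] <- "heterogeneous"
  y[y %in% c("not_analysable", "notanalyzable", "na_quadrant")] <-
    "not_analyzable"
  bad <- setdiff(unique(y), .CLASSES)
  if (length(bad))
    stop("unknown class label(s): ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(.CLASSES, collapse = ", "), call. = FALSE)
  y
}

## Stop unless all mask values are legal labels.
checkMaskValues <- function(labels) {
  u <- unique(as.vector(labels))
  if (!all(u %in% .MASK_LEVELS))
    stop("mask contains illegal labels: ",
         paste(setdiff(u, .MASK_LEVELS), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
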