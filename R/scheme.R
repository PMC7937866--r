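#' Default brain IVIM b-value grid
#'
#' The 17 b-values, 0 to 2500 s/mm^2, of the reference brain protocol.
#' @return numeric vector of length 17.
#' @export
defaultBValues <- function() {
  c(0, 100, 200, 300, 400, 500, 600, 700, 800, 1000, 1200, 1400,
    1600, 1800, 2000, 2250, 2500)
}

#' Default MPG direction set
#'
#' The six motion-probing-gradient directions of the reference protocol,
#' unit-normalized, one per column.
#' @return 3 x 6 numeric matrix.
#' @export
defaultDirections <- function() {
  g <- cbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1),
             c(1, -1, 0), c(0, 1, -1), c(-1, 0, 1))
  sweep(g, 2, sqrt(colSums(g^2)), "/")
}

#' Build an acquisition scheme
#'
#' Expands a b-value grid and a direction set into the per-frame scheme of
#' a 4D series, direction-major: all b-values of direction 1, then
#' direction 2, and so on, with b = 0 acquired once per direction block.
#'
#' @param bGrid b-values acquired in each direction block, s/mm^2.
#' @param directions 3 x nDir matrix of MPG directions (normalized
#'   internally).
#' @return an [AcquisitionScheme-class] with `length(bGrid) * nDir` frames.
#' @examples
#' ivimScheme()  # 17 b-values x 6 directions = 102 frames
#' @export
ivimScheme <- function(bGrid = defaultBValues(),
                       directions = defaultDirections()) {
  directions <- as.matrix(directions)
  nrm <- sqrt(colSums(directions^2))
  if (any(nrm == 0)) stop("direction vectors must be non-zero")
  directions <- sweep(directions, 2, nrm, "/")
  nDir <- ncol(directions)
  b <- rep(bGrid, nDir)
  g <- directions[, rep(seq_len(nDir), each = length(bGrid)), drop = FALSE]
  new("AcquisitionScheme", bValues = b, directions = g)
}

#' Decompose a scheme into per-direction series
#'
#' Groups the frames of a scheme by MPG direction and orders each group by
#' b-value, validating that every direction was acquired on the same
#' b-grid. b = 0 frames carrying the zero vector are assigned to the
#' direction block of the nearest following diffusion-weighted frame.
#'
#' @param scheme an [AcquisitionScheme-class] object.
#' @return list with `bGrid` (the common increasing b-grid),
#'   `nDirections`, `directions` (3 x nDir matrix of unique directions)
#'   and `frameIndex` (matrix bGrid x nDir giving, for each direction and
#'   b, the frame number in the 4D series).
#' @export
seriesLayout <- function(scheme) {
  b <- scheme@bValues
  g <- scheme@directions
  n <- length(b)
  key <- rep(NA_integer_, n)
  uniq <- list()
  for (i in seq_len(n)) {
    v <- g[, i]
    if (sqrt(sum(v^2)) < 1e-8) next  # zero vector: b0 frame, fill later
    hit <- NA_integer_
    for (j in seq_along(uniq)) {
      # gradient polarity is irrelevant to diffusion weighting
      if (min(sum((uniq[[j]] - v)^2), sum((uniq[[j]] + v)^2)) < 1e-8) {
        hit <- j; break
      }
    }
    if (is.na(hit)) {
      uniq[[length(uniq) + 1L]] <- v
      hit <- length(uniq)
    }
    key[i] <- hit
  }
  # zero-vector frames inherit the next (else previous) labelled frame
  for (i in which(is.na(key))) {
    after <- which(!is.na(key) & seq_len(n) > i)
    before <- which(!is.na(key) & seq_len(n) < i)
    key[i] <- if (length(after)) key[after[1]] else key[rev(before)[1]]
  }
  nDir <- length(uniq)
  if (nDir == 0) stop("scheme has no diffusion-weighted frames")
  bGrid <- sort(unique(b[key == 1]))
  frameIndex <- matrix(NA_integer_, length(bGrid), nDir)
  for (d in seq_len(nDir)) {
    idx <- which(key == d)
    bd <- b[idx]
    if (!identical(sort(bd), bGrid))
      stop("direction ", d, " was not acquired on the common b-grid")
    frameIndex[, d] <- idx[order(bd)]
  }
  list(bGrid = bGrid, nDirections = nDir,
       directions = do.call(cbind, uniq), frameIndex = frameIndex)
}
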