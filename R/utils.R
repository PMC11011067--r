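# internal helpers shared across modules

# Run code with a locally seeded RNG stream, restoring the caller's stream
# afterwards so that simulator calls do not perturb user-level randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Deterministic derived seeds kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

#' Exact Euclidean distance to a pixel set
#'
#' Distance from every pixel of a binary image to the nearest `TRUE` pixel,
#' computed with an exact separable (lower-envelope) squared distance
#' transform. Distances are exact Euclidean pixel distances, so results
#' agree with a brute-force nearest-pixel search.
#'
#' @param target logical matrix; pixels to measure distance to.
#' @return numeric matrix of distances (0 on `target` pixels). If `target`
#'   has no `TRUE` pixel, all distances are `Inf`.
#' @export
edt_distance <- function(target) {
  stopifnot(is.matrix(target))
  mode(target) <- "logical"
  if (!any(target)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  sqrt(.edt_sq(target))
}

# labels (of an integer label matrix) having at least one pixel 8-adjacent
# to, or on, pixels where `outside` is TRUE (the image frame counts as
# outside when frame = TRUE)
labels_touching <- function(lab, outside, frame = FALSE) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- outside
  if (frame) {
    out[1, ] <- TRUE; out[nr, ] <- TRUE; out[, 1] <- TRUE; out[, nc] <- TRUE
  }
  # dilate `out` by one pixel (8-connectivity) via shifts
  d <- out
  d[-1, ] <- d[-1, ] | out[-nr, ]
  d[-nr, ] <- d[-nr, ] | out[-1, ]
  d[, -1] <- d[, -1] | out[, -nc]
  d[, -nc] <- d[, -nc] | out[, -1]
  d[-1, -1] <- d[-1, -1] | out[-nr, -nc]
  d[-nr, -nc] <- d[-nr, -nc] | out[-1, -1]
  d[-1, -nc] <- d[-1, -nc] | out[-nr, -1]
  d[-nr, -1] <- d[-nr, -1] | out[-1, -nc]
  sort(unique(lab[d & lab > 0L]))
}

# bounding-box crop of a label with a pixel margin; returns row/col ranges
bbox_crop <- function(mask, margin = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  list(
    rows = max(1L, r[1] - margin):min(nrow(mask), r[2] + margin),
    cols = max(1L, c[1] - margin):min(ncol(mask), c[2] + margin)
  )
}

# separable Gaussian smoothing (reflecting boundaries, direct convolution)
gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  u <- (-h):h
  g <- exp(-u^2 / (2 * sigma^2))
  g / sum(g)
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gauss_kernel(sigma)
  .conv_sep(img, g, g)
}

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  as.matrix(x)
}
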