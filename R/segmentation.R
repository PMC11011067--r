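# Nucleus and cell segmentation ---------------------------------------------
#
# Nuclei: smooth -> global Otsu threshold -> morphological closing (keeps
# the lobes of a multilobed nucleus as one object) -> hole filling ->
# distance-transform watershed with a high merge tolerance (splits touching
# nuclei, not lobes) -> size filter.
#
# Cells: seeded watershed grown from the nucleus labels over the membrane
# intensity (EBImage::propagate, i.e. the constrained seeded region growing
# used by common high-content pipelines), restricted to a foreground mask
# obtained by filling the thresholded membrane outline. When no membrane
# channel exists the smoothed ER channel serves as the landscape.

#' Project a z-stack to a single plane
#'
#' @param stack 3D array (x, y, z) or list of 2D slices.
#' @param method `"max"` (maximum-intensity projection, default) or
#'   `"mean"`.
#' @return 2D numeric matrix.
#' @export
project_stack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (is.list(stack)) stack <- array(unlist(stack),
                                     dim = c(dim(stack[[1]]), length(stack)))
  if (length(dim(stack)) == 2L) return(as.matrix(stack))
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("project_stack: need a non-empty stack")
  if (dim(stack)[3] == 1L) return(stack[, , 1])
  if (method == "max") {
    out <- stack[, , 1]
    for (z in 2:dim(stack)[3]) out <- pmax(out, stack[, , z])
    out
  } else {
    apply(stack, c(1, 2), mean)
  }
}

project_channel <- function(x, method = "max") {
  if (length(dim(x)) == 3L) project_stack(x, method) else as.matrix(x)
}

#' Segment nuclei from the nuclear channel
#'
#' @param nuclear 2D intensity matrix (project stacks first).
#' @param pixel_size_um micrometres per pixel.
#' @param sigma smoothing sigma, px.
#' @param min_area_um2 minimum nuclear area (default 50 um^2).
#' @param closing_radius radius (px) of the closing that keeps nuclear
#'   lobes merged.
#' @param watershed_tolerance merge tolerance of the distance-transform
#'   watershed; high values avoid splitting lobed nuclei.
#' @param threshold optional absolute intensity threshold overriding Otsu.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclear, pixel_size_um = ERSCREEN_PIXEL_SIZE_UM,
                           sigma = 2, min_area_um2 = 50, closing_radius = 2,
                           watershed_tolerance = 8, threshold = NULL) {
  x <- as_matrix(nuclear)
  mx <- max(x)
  if (mx <= 0) return(matrix(0L, nrow(x), ncol(x)))
  xs <- gauss_blur(x / mx, sigma)
  xs[xs < 0] <- 0; xs[xs > 1] <- 1
  thr <- if (is.null(threshold)) otsu_vector(as.vector(xs))
         else threshold / mx
  bw <- xs > thr
  if (!any(bw)) return(matrix(0L, nrow(x), ncol(x)))
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    bw <- as_matrix(EBImage::closing(EBImage::Image(bw), brush)) > 0
  }
  bw <- as_matrix(EBImage::fillHull(EBImage::Image(bw))) > 0
  dm <- EBImage::distmap(EBImage::Image(bw))
  lab <- as_matrix(EBImage::watershed(dm, tolerance = watershed_tolerance))
  storage.mode(lab) <- "integer"
  min_px <- min_area_um2 / pixel_size_um^2
  sizes <- tabulate(lab)
  drop <- which(sizes < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Segment cells by seeded watershed from nucleus labels
#'
#' @param membrane plasma-membrane intensity matrix, or `NULL` to fall back
#'   to the ER channel.
#' @param nucleus_labels integer label matrix from [segment_nuclei()];
#'   label ids are preserved per cell.
#' @param er ER intensity matrix (fallback landscape / foreground support).
#' @param sigma smoothing sigma, px.
#' @param lambda regularisation of [EBImage::propagate()] balancing image
#'   gradients against Euclidean distance.
#' @return integer cell label matrix sharing ids with `nucleus_labels`.
#' @export
segment_cells <- function(membrane, nucleus_labels, er = NULL, sigma = 2,
                          lambda = 1e-4) {
  nucleus_labels <- as_matrix(nucleus_labels)
  storage.mode(nucleus_labels) <- "integer"
  if (max(nucleus_labels) == 0L) {
    warning("segment_cells: no nuclei; returning empty cell map")
    return(matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels)))
  }
  landscape <- if (!is.null(membrane)) as_matrix(membrane) else as_matrix(er)
  if (is.null(landscape)) stop("segment_cells: need a membrane or ER channel")
  ls <- gauss_blur(landscape / max(landscape), sigma)
  ls[ls < 0] <- 0; ls[ls > 1] <- 1
  thr <- otsu_vector(as.vector(ls))
  if (!is.null(membrane)) {
    # fill the thresholded membrane outline to get the cell foreground
    fg <- as_matrix(EBImage::fillHull(EBImage::Image(ls > thr))) > 0
  } else {
    fg <- ls > 0.5 * thr
    fg <- as_matrix(EBImage::fillHull(EBImage::closing(
      EBImage::Image(fg), EBImage::makeBrush(5, "disc")))) > 0
  }
  if (!is.null(er)) {
    # restrict the foreground to pixels with ER content: the filled
    # membrane hull of closely apposed cells can span the dark pocket
    # between them, which would otherwise be annexed into a cell region
    # and scored as huge spurious "polygons". Smoothing at the cell scale
    # lifts inter-tubule gaps well above the background pockets.
    # the factor is low on purpose: inter-tubule gaps carry cytosolic ER
    # and must survive, while the pockets are near the read-noise floor
    es <- gauss_blur(as_matrix(er), sigma)
    med_fg <- median(es[fg])
    if (is.finite(med_fg) && med_fg > 0) fg <- fg & es > 0.25 * med_fg
  }
  fg <- fg | nucleus_labels > 0L
  lab <- as_matrix(EBImage::propagate(EBImage::Image(ls),
                                      EBImage::Image(nucleus_labels),
                                      mask = EBImage::Image(fg),
                                      lambda = lambda))
  storage.mode(lab) <- "integer"
  lab
}

#' Labels touching the field border
#'
#' Objects on image borders are excluded from the analysis.
#'
#' @param labels integer label matrix.
#' @return sorted integer vector of border-touching labels.
#' @export
border_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  setdiff(sort(unique(c(labels[1, ], labels[nr, ], labels[, 1],
                        labels[, nc]))), 0L)
}

#' Segment a whole field
#'
#' Projects any z-stacks, segments nuclei and cells and flags
#' border-touching labels.
#'
#' @param field a [field_image()] with at least `er` and `nucleus`
#'   channels.
#' @param projection `"max"` or `"mean"`.
#' @param ... passed to [segment_nuclei()].
#' @return a `segmented_field`: list with `cell_labels`, `nucleus_labels`,
#'   `border_excluded` (integer label ids), `er` (projected ER intensity)
#'   and `pixel_size_um`.
#' @export
segment_field <- function(field, projection = "max", ...) {
  stopifnot(inherits(field, "field_image"))
  er <- project_channel(field$channels$er, projection)
  nucch <- field$channels$nucleus
  if (is.null(nucch)) stop("I/O error: required channel missing: nucleus")
  nuc <- project_channel(nucch, projection)
  mem <- if (!is.null(field$channels$membrane))
    project_channel(field$channels$membrane, projection) else NULL
  nl <- segment_nuclei(nuc, pixel_size_um = field$pixel_size_um, ...)
  cl <- segment_cells(mem, nl, er = er)
  structure(list(cell_labels = cl, nucleus_labels = nl,
                 border_excluded = border_labels(cl), er = er,
                 pixel_size_um = field$pixel_size_um,
                 plate = field$plate, well = field$well,
                 field = field$field),
            class = "segmented_field")
}

#' Use simulator ground-truth masks as a segmentation
#'
#' Bypasses image segmentation by adopting the generator's exact label
#' maps; used to test the morphometrics stage in isolation.
#'
#' @param field a field synthesized with `keep_masks = TRUE` by
#'   [synthesize_field()].
#' @return a `segmented_field`.
#' @export
truth_segmentation <- function(field) {
  stopifnot(!is.null(field$cell_labels))
  structure(list(cell_labels = field$cell_labels,
                 nucleus_labels = field$nucleus_labels,
                 border_excluded = border_labels(field$cell_labels),
                 er = project_channel(field$image$channels$er),
                 pixel_size_um = field$image$pixel_size_um,
                 plate = field$image$plate, well = field$image$well,
                 field = field$image$field),
            class = "segmented_field")
}
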