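# Per-cell ER morphometrics --------------------------------------------------
#
# Two readouts per segmented cell:
#   * mean tubular-ER polygon area (um^2): the areas of the regions fully
#     enclosed by ER tubules within the peripheral tubular network — larger
#     polygons indicate a sparser network;
#   * % dense perinuclear ER: the percentage of the cytoplasm occupied by
#     high-intensity ER pixels within the perinuclear band — a proxy for
#     sheet ER.
# Plus nuclear area and circularity, which feed the transfection QC.

#' Morphometrics configuration
#'
#' @param band_fraction normalised radial cut-off of the perinuclear band
#'   (`d_nuc / (d_nuc + d_mem) <= band_fraction`), default 0.5.
#' @param dense_thresh_method `"peripheral"` (default): dense pixels exceed
#'   `dense_margin` times the `dense_quantile` quantile of the ER intensity
#'   in the peripheral cytoplasm (outside the band), so the threshold sits
#'   above tubule brightness whatever the absolute scale; or `"mad"`:
#'   median + `k_mad` * MAD of the whole cytoplasmic ER intensity.
#' @param dense_margin,dense_quantile parameters of the peripheral
#'   reference threshold.
#' @param k_mad multiplier of the MAD threshold variant.
#' @param tubule_sigma scale (px) of the ridge / smoothing filter used to
#'   binarise the tubular network.
#' @param tubule_enhance `"intensity"` (default; Otsu on the smoothed ER
#'   intensity within the peripheral region) or `"tubeness"` (Otsu on a
#'   Hessian ridge measure — more robust to slowly varying background).
#' @param min_polygon_area_um2 smallest polygon retained (default
#'   0.25 um^2).
#' @param projection z-projection rule, `"max"` or `"mean"`.
#' @export
morph_config <- function(band_fraction = 0.5,
                         dense_thresh_method = c("peripheral", "mad"),
                         dense_margin = 1.25, dense_quantile = 0.9,
                         k_mad = 2, tubule_sigma = 0.5,
                         tubule_enhance = c("intensity", "tubeness"),
                         min_polygon_area_um2 = 0.25,
                         projection = "max") {
  list(band_fraction = band_fraction,
       dense_thresh_method = match.arg(dense_thresh_method),
       dense_margin = dense_margin, dense_quantile = dense_quantile,
       k_mad = k_mad, tubule_sigma = tubule_sigma,
       tubule_enhance = match.arg(tubule_enhance),
       min_polygon_area_um2 = min_polygon_area_um2,
       projection = projection)
}

#' Perinuclear band of a cell
#'
#' Cytoplasm pixels whose normalised radial position
#' `d_nuc / (d_nuc + d_mem)` (exact Euclidean distance to the nucleus
#' vs. to the cell exterior) is at most `band_fraction`. `band_fraction`
#' 0 gives an empty band, 1 the entire cytoplasm.
#'
#' @param cell_mask,nucleus_mask logical matrices; the nucleus must lie
#'   inside the cell.
#' @param band_fraction cut-off in `[0, 1]`.
#' @return logical matrix (the band).
#' @export
perinuclear_band <- function(cell_mask, nucleus_mask, band_fraction = 0.5) {
  cell_mask <- as_matrix(cell_mask) > 0
  nucleus_mask <- as_matrix(nucleus_mask) > 0
  if (!any(nucleus_mask)) stop("geometry error: empty nucleus mask")
  if (any(nucleus_mask & !cell_mask))
    stop("geometry error: nucleus not inside cell")
  cyto <- cell_mask & !nucleus_mask
  if (band_fraction <= 0) return(matrix(FALSE, nrow(cell_mask), ncol(cell_mask)))
  if (band_fraction >= 1) return(cyto)
  d_nuc <- edt_distance(nucleus_mask)
  d_mem <- edt_distance(!cell_mask)
  band <- cyto & (d_nuc / (d_nuc + d_mem)) <= band_fraction
  band
}

#' Percentage of the cytoplasm occupied by dense perinuclear ER
#'
#' High-intensity ER pixels inside the perinuclear band, expressed as a
#' percentage of all cytoplasm pixels. The per-cell threshold is relative
#' (see [morph_config()]), so both readouts are invariant to rescaling the
#' ER channel.
#'
#' @param er ER intensity matrix.
#' @param cell_mask,nucleus_mask logical masks of one cell.
#' @param config a [morph_config()].
#' @return list with `dense_fraction_pct`, the `band` mask and the
#'   threshold used.
#' @export
dense_er_fraction <- function(er, cell_mask, nucleus_mask,
                              config = morph_config()) {
  er <- as_matrix(er)
  cell_mask <- as_matrix(cell_mask) > 0
  nucleus_mask <- as_matrix(nucleus_mask) > 0
  cyto <- cell_mask & !nucleus_mask
  if (!any(cyto)) stop("empty cytoplasm")
  band <- perinuclear_band(cell_mask, nucleus_mask, config$band_fraction)
  peripheral <- cyto & !band
  v_cyto <- er[cyto]
  thr <- if (config$dense_thresh_method == "peripheral" && any(peripheral)) {
    config$dense_margin * quantile(er[peripheral], config$dense_quantile,
                                   names = FALSE)
  } else {
    median(v_cyto) + config$k_mad * mad(v_cyto)
  }
  dense <- band & er > thr
  list(dense_fraction_pct = 100 * sum(dense) / sum(cyto),
       band = band, threshold = thr)
}

# Hessian ridge measure for bright tubules: -lambda2 (most negative
# eigenvalue of the Gaussian Hessian), clipped at zero.
hessian_tubeness <- function(img, sigma = 1) {
  n <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  u <- seq(-(n %/% 2), n %/% 2)
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -u / sigma^2 * g
  g2 <- (u^2 - sigma^2) / sigma^4 * g
  sep <- function(kr, kc) .conv_sep(img, kr, kc)
  ixx <- sep(g2, g); iyy <- sep(g, g2); ixy <- sep(g1, g1)
  tr <- ixx + iyy
  dt <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  l2 <- (tr - dt) / 2          # more negative eigenvalue
  pmax(-l2, 0)
}

#' Areas of the tubular-ER polygons of one cell
#'
#' Binarises the tubular network within the peripheral region (cytoplasm
#' outside the perinuclear band) and measures the connected components of
#' the non-tubule pixels that are fully enclosed — components touching the
#' peripheral-region boundary (dense band edge, cell edge or image frame)
#' are discarded, as are components below `min_polygon_area_um2`.
#'
#' @param er ER intensity matrix.
#' @param cell_mask logical cell mask.
#' @param peripheral_mask logical mask of the peripheral cytoplasm.
#' @param pixel_size_um micrometres per pixel.
#' @param config a [morph_config()].
#' @return numeric vector of polygon areas in um^2 (possibly empty).
#' @export
tubular_polygons <- function(er, cell_mask, peripheral_mask,
                             pixel_size_um = ERSCREEN_PIXEL_SIZE_UM,
                             config = morph_config()) {
  er <- as_matrix(er)
  cell_mask <- as_matrix(cell_mask) > 0
  peripheral_mask <- as_matrix(peripheral_mask) > 0
  if (!any(peripheral_mask)) return(numeric(0))
  enh <- if (config$tubule_enhance == "tubeness") {
    hessian_tubeness(er, config$tubule_sigma)
  } else if (config$tubule_sigma > 0) {
    gauss_blur(er, config$tubule_sigma)
  } else er
  v <- enh[peripheral_mask]
  rng <- range(v)
  if (diff(rng) <= 0) return(numeric(0))
  vn <- (v - rng[1]) / diff(rng)
  thr <- otsu_vector(vn)
  tub <- matrix(FALSE, nrow(er), ncol(er))
  tub[peripheral_mask] <- vn > thr
  gaps <- peripheral_mask & !tub
  lab <- as_matrix(EBImage::bwlabel(gaps))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(numeric(0))
  open_labels <- labels_touching(lab, !peripheral_mask, frame = TRUE)
  if (length(open_labels)) lab[lab %in% open_labels] <- 0L
  if (max(lab) == 0L) return(numeric(0))
  areas_px <- tabulate(lab)
  areas <- areas_px[areas_px > 0] * pixel_size_um^2
  areas[areas >= config$min_polygon_area_um2]
}

# Otsu threshold of a numeric vector in [0, 1] (histogram, 256 bins)
otsu_vector <- function(v, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  midpoints <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * midpoints)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  midpoints[which.max(between)]
}

#' Circularity of a binary mask
#'
#' `4 * pi * area / perimeter^2`, clipped to at most 1: 1 for a disk,
#' lower for elongated or lobed shapes. The perimeter estimator is the
#' half-pixel-offset smoothed boundary chain: the 8-connected outer
#' contour is traced, its vertex coordinates are smoothed with a circular
#' moving average (window 5) to remove digitisation staircase excess, the
#' closed polyline length is summed, and `pi` is added for the outward
#' half-pixel offset of pixel centres relative to the region boundary.
#'
#' @param mask logical matrix with one non-empty connected region.
#' @return circularity in `(0, 1]`.
#' @export
circularity <- function(mask) {
  mask <- as_matrix(mask) > 0
  a <- sum(mask)
  if (a == 0) stop("circularity: empty mask")
  p <- mask_perimeter(mask)
  min(4 * pi * a / p^2, 1)
}

# perimeter of the largest contour of a mask (see circularity() docs)
mask_perimeter <- function(mask, window = 5L) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) stop("circularity: no contour found")
  xy <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  n <- nrow(xy)
  if (n < window + 2L) {
    # tiny object: raw chain length plus offset
    d <- sqrt(rowSums((xy - xy[c(2:n, 1), ])^2))
    return(sum(d) + pi)
  }
  half <- window %/% 2L
  idx <- function(shift) ((seq_len(n) - 1L + shift) %% n) + 1L
  sx <- numeric(n); sy <- numeric(n)
  for (s in (-half):half) {
    sx <- sx + xy[idx(s), 1]
    sy <- sy + xy[idx(s), 2]
  }
  sx <- sx / window; sy <- sy / window
  dx <- sx - sx[c(2:n, 1)]; dy <- sy - sy[c(2:n, 1)]
  sum(sqrt(dx^2 + dy^2)) + pi
}

#' Measure one segmented cell
#'
#' Composes the perinuclear band, dense-ER fraction, tubular polygons and
#' nuclear shape into one record. Border-touching cells are refused:
#' objects on image borders are excluded from the analysis.
#'
#' @param seg a `segmented_field` (see [segment_field()]).
#' @param cell_id integer label of the cell.
#' @param config a [morph_config()].
#' @return one-row data.frame of class fields: `cell_id`, `n_polygons`,
#'   `mean_polygon_area_um2` (`NA` when no polygon), `dense_fraction_pct`,
#'   `nuclear_area_um2`, `nuclear_circularity`, `border_excluded`.
#' @export
measure_cell <- function(seg, cell_id, config = morph_config()) {
  if (cell_id %in% seg$border_excluded)
    stop("cell ", cell_id, " touches the field border and is excluded")
  measure_cell_impl(seg, cell_id, config, border = FALSE)
}

measure_cell_impl <- function(seg, cell_id, config, border) {
  cm_full <- seg$cell_labels == cell_id
  box <- bbox_crop(cm_full, margin = 2L)
  cm <- cm_full[box$rows, box$cols]
  nm <- seg$nucleus_labels[box$rows, box$cols] == cell_id
  er <- seg$er[box$rows, box$cols]
  px <- seg$pixel_size_um
  nuclear_area <- sum(nm) * px^2
  circ <- if (any(nm)) circularity(nm) else NA_real_
  if (!any(nm) || !any(cm & !nm)) {
    return(data.frame(cell_id = cell_id, n_polygons = NA_integer_,
                      mean_polygon_area_um2 = NA_real_,
                      dense_fraction_pct = NA_real_,
                      nuclear_area_um2 = nuclear_area,
                      nuclear_circularity = circ,
                      border_excluded = border))
  }
  dres <- dense_er_fraction(er, cm, nm, config)
  peripheral <- (cm & !nm) & !dres$band
  areas <- tubular_polygons(er, cm, peripheral, pixel_size_um = px,
                            config = config)
  data.frame(cell_id = cell_id,
             n_polygons = length(areas),
             mean_polygon_area_um2 = if (length(areas)) mean(areas) else NA_real_,
             dense_fraction_pct = dres$dense_fraction_pct,
             nuclear_area_um2 = nuclear_area,
             nuclear_circularity = circ,
             border_excluded = border)
}

#' Measure every cell of a segmented field
#'
#' Border-touching cells are listed with `border_excluded = TRUE` and `NA`
#' readouts; all others carry full morphometrics.
#'
#' @param seg a `segmented_field`.
#' @param config a [morph_config()].
#' @return data.frame, one row per cell, with plate/well/field identifiers.
#' @export
measure_field <- function(seg, config = morph_config()) {
  ids <- setdiff(sort(unique(as.vector(seg$cell_labels))), 0L)
  rows <- lapply(ids, function(id) {
    if (id %in% seg$border_excluded) {
      data.frame(cell_id = id, n_polygons = NA_integer_,
                 mean_polygon_area_um2 = NA_real_,
                 dense_fraction_pct = NA_real_,
                 nuclear_area_um2 = NA_real_,
                 nuclear_circularity = NA_real_,
                 border_excluded = TRUE)
    } else {
      measure_cell_impl(seg, id, config, border = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), n_polygons = integer(0),
                      mean_polygon_area_um2 = numeric(0),
                      dense_fraction_pct = numeric(0),
                      nuclear_area_um2 = numeric(0),
                      nuclear_circularity = numeric(0),
                      border_excluded = logical(0))
  }
  cbind(data.frame(plate = seg$plate, well = seg$well, field = seg$field),
        out)
}

#' @importFrom stats mad
NULL
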