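# Synthetic fluorescence-microscopy generator -------------------------------
#
# Emulates three channels of an adherent reporter cell line: a general-ER
# membrane marker (perinuclear dense annulus + peripheral tubular mesh), a
# nuclear stain (round or multilobed nuclei) and a plasma-membrane stain
# (cell outline). Every cell carries exact pixel-level ground truth taken
# before the noise model, so downstream segmentation and morphometrics can
# be validated without any acquired data.

#' Specification of one synthetic cell
#'
#' @param center `(x, y)` pixel position of the cell centre (may be `NULL`
#'   when the cell is rendered alone).
#' @param cell_radius cell radius in pixels.
#' @param nucleus_radius nominal nuclear radius in pixels (single-lobe
#'   radius; multilobed nuclei are unions of lobes of comparable size).
#' @param n_lobes number of nuclear lobes; 1 is a normal round nucleus,
#'   >= 2 the multilobed phenotype induced by INCENP knockdown.
#' @param tubule_spacing characteristic distance (px) between peripheral ER
#'   tubules; `Inf` suppresses the peripheral mesh entirely.
#' @param tubule_width drawn tubule width in px; must be < `tubule_spacing`.
#' @param dense_band_fraction fraction in `[0, 1]` of the cytoplasm radius
#'   `cell_radius - nucleus_radius` occupied by the dense perinuclear ER
#'   annulus.
#' @param dense_intensity_ratio brightness of dense ER relative to tubules
#'   (> 1).
#' @param seed integer seed controlling all randomness of this cell.
#' @param mesh `"voronoi"` (jittered seed points, irregular convex-ish
#'   faces) or `"hex"` (regular hexagonal lattice with closed-form face
#'   geometry, used for analytic tests).
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(center = NULL, cell_radius = 64, nucleus_radius = 19,
                      n_lobes = 1L, tubule_spacing = 8, tubule_width = 2,
                      dense_band_fraction = 0.25, dense_intensity_ratio = 3,
                      seed = 1L, mesh = c("voronoi", "hex")) {
  mesh <- match.arg(mesh)
  spec <- structure(list(
    center = center, cell_radius = cell_radius,
    nucleus_radius = nucleus_radius, n_lobes = as.integer(n_lobes),
    tubule_spacing = tubule_spacing, tubule_width = tubule_width,
    dense_band_fraction = dense_band_fraction,
    dense_intensity_ratio = dense_intensity_ratio,
    seed = as.integer(seed), mesh = mesh
  ), class = "cell_spec")
  validate_cell_spec(spec)
  spec
}

validate_cell_spec <- function(spec) {
  if (spec$nucleus_radius >= spec$cell_radius)
    stop("invalid cell_spec: nucleus_radius must be smaller than cell_radius")
  if (!is.infinite(spec$tubule_spacing) &&
      spec$tubule_spacing <= spec$tubule_width)
    stop("invalid cell_spec: tubule_spacing must exceed tubule_width")
  if (spec$dense_band_fraction < 0 || spec$dense_band_fraction > 1)
    stop("invalid cell_spec: dense_band_fraction must lie in [0, 1]")
  if (spec$dense_intensity_ratio <= 1)
    stop("invalid cell_spec: dense_intensity_ratio must exceed 1")
  if (spec$n_lobes < 1L) stop("invalid cell_spec: n_lobes must be >= 1")
  invisible(spec)
}

#' Noise model parameters
#'
#' Applied after compositing, in order: Gaussian blur (point-spread-function
#' proxy), Poisson shot noise on the photon scale, additive Gaussian read
#' noise, rounding to non-negative integer camera counts. With
#' `enabled = FALSE` the clean piecewise-constant render is returned
#' (scaled by `photon_scale`), which several geometric oracles rely on.
#'
#' @param sigma_blur blur standard deviation, px.
#' @param photon_scale expected photon count of a unit-intensity pixel.
#' @param read_sigma read-noise standard deviation, counts.
#' @param enabled logical; apply the noise model at all.
#' @export
noise_params <- function(sigma_blur = 1, photon_scale = 200, read_sigma = 3,
                         enabled = TRUE) {
  structure(list(sigma_blur = sigma_blur, photon_scale = photon_scale,
                 read_sigma = read_sigma, enabled = isTRUE(enabled)),
            class = "noise_params")
}

apply_noise <- function(img, noise, do_blur = TRUE) {
  if (!noise$enabled) return(img * noise$photon_scale)
  b <- img
  if (do_blur && noise$sigma_blur > 0)
    b <- gauss_blur(img, noise$sigma_blur)
  b[b < 0] <- 0
  counts <- matrix(0, nrow(b), ncol(b))
  pos <- which(b > 0)
  counts[pos] <- rpois(length(pos), noise$photon_scale * b[pos])
  counts <- counts + round(matrix(rnorm(length(b), 0, noise$read_sigma),
                                  nrow(b), ncol(b)))
  counts[counts < 0] <- 0
  counts
}

#' Multichannel field container
#'
#' @param channels named list of numeric matrices (or 3D arrays for
#'   z-stacks); names among `er`, `nucleus`, `membrane`.
#' @param pixel_size_um lateral pixel size, micrometres per pixel.
#' @param plate,well,field identifiers.
#' @export
field_image <- function(channels, pixel_size_um = ERSCREEN_PIXEL_SIZE_UM,
                        plate = NA_character_, well = NA_character_,
                        field = NA_integer_) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size_um > 0)
  dims <- lapply(channels, function(x) dim(x)[1:2])
  if (length(unique(dims)) != 1L)
    stop("all channels must share the same xy shape")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 plate = plate, well = well, field = as.integer(field)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %s px, channels: %s, %.3g um/px",
              paste(d, collapse = " x "),
              paste(names(x$channels), collapse = "/"), x$pixel_size_um))
  if (!is.na(x$well)) cat(sprintf("  [%s %s f%d]", x$plate, x$well, x$field))
  cat("\n")
  invisible(x)
}

# nucleus mask: disk or union of overlapping lobes (uses current RNG stream)
render_nucleus_mask <- function(spec, dx, dy) {
  rn <- spec$nucleus_radius
  if (spec$n_lobes == 1L) return(dx^2 + dy^2 <= rn^2)
  ang <- seq(0, 2 * pi, length.out = spec$n_lobes + 1L)[-1L] +
    runif(1, 0, 2 * pi) + runif(spec$n_lobes, -0.25, 0.25)
  # overlapping lobes around a small core: the union stays connected and
  # reaches ~2.5-3x the normal nuclear area (72 h of failed nuclear
  # fission leaves polyploid, grape-like nuclei)
  off <- 0.9 * rn
  lr <- 0.9 * rn * runif(spec$n_lobes, 0.92, 1.08)
  m <- dx^2 + dy^2 <= (0.5 * rn)^2
  for (k in seq_len(spec$n_lobes)) {
    m <- m | ((dx - off * cos(ang[k]))^2 + (dy - off * sin(ang[k]))^2 <= lr[k]^2)
  }
  m
}

# Grid-indexed mesh seeds around the cell centre. Seeds sit on a square
# (jittered, "voronoi") or hexagonal ("hex") lattice; because every
# pixel's nearest seeds lie in the 3x3 lattice neighbourhood of its own
# node, nearest/second-nearest distances are found in nine vectorised
# passes instead of a full pixel-by-seed scan.
mesh_grid <- function(spec, rmax) {
  s <- spec$tubule_spacing
  if (!is.finite(s)) return(NULL)
  hex <- spec$mesh == "hex"
  row_pitch <- if (hex) s * sqrt(3) / 2 else s
  m <- ceiling((rmax + 2 * s) / min(row_pitch, s)) + 1L
  n_side <- 2L * m + 1L
  jit <- if (hex) 0 else 0.35 * s
  jx <- matrix(runif(n_side^2, -jit, jit), n_side, n_side)
  jy <- matrix(runif(n_side^2, -jit, jit), n_side, n_side)
  list(s = s, hex = hex, row_pitch = row_pitch, m = m, n_side = n_side,
       jx = jx, jy = jy)
}

# nearest/second-nearest seed distance and nearest-seed label per pixel
mesh_nearest <- function(grid, u, v) {
  .mesh_nearest_cpp(u, v, grid$jx, grid$jy, grid$s, grid$row_pitch,
                    grid$hex, grid$m)
}

# Render one cell on a local canvas. Returns clean channels in relative
# intensity units plus exact ground-truth masks and face areas (px).
render_cell <- function(spec, dim = NULL, center = NULL) {
  validate_cell_spec(spec)
  R <- spec$cell_radius
  rn <- spec$nucleus_radius
  if (is.null(dim)) dim <- rep(2L * ceiling(R) + 7L, 2L)
  if (is.null(center)) center <- (dim + 1) / 2
  nr <- dim[1]; nc <- dim[2]
  dx <- matrix(seq_len(nr) - center[1], nr, nc)
  dy <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  r2 <- dx^2 + dy^2
  cell <- r2 <= R^2
  if (!any(cell)) stop("cell lies entirely outside the canvas")

  nucleus <- render_nucleus_mask(spec, dx, dy) & cell
  if (spec$n_lobes > 1L && 2.1 * rn >= R)
    stop("invalid cell_spec: multilobed nucleus does not fit inside the cell")

  wb <- spec$dense_band_fraction * (R - rn)
  cyto <- cell & !nucleus
  if (spec$n_lobes == 1L) {
    dense <- r2 > rn^2 & r2 <= (rn + wb)^2 & cell & !nucleus
    peripheral <- cyto & !dense & r2 > (rn + wb)^2
  } else {
    # the dense perinuclear ER wraps the nuclear envelope whatever its
    # shape: band of width wb around the lobed nucleus mask
    dn <- if (wb > 0 && any(nucleus)) edt_distance(nucleus) else NULL
    if (is.null(dn)) {
      dense <- matrix(FALSE, nr, nc)
      peripheral <- cyto
    } else {
      dense <- dn > 0 & dn <= wb & cell & !nucleus
      peripheral <- cyto & !dense & dn > wb
    }
  }

  tubule <- matrix(FALSE, nr, nc)
  face_label <- matrix(0L, nr, nc)
  face_areas_px <- numeric(0)
  grid <- mesh_grid(spec, rmax = R)
  if (!is.null(grid) && any(peripheral)) {
    idx <- which(peripheral)
    nn <- mesh_nearest(grid, dx[idx], dy[idx])
    on_tubule <- (nn$d2 - nn$d1) <= spec$tubule_width
    tubule[idx[on_tubule]] <- TRUE
    face_mask <- peripheral & !tubule
    face_label <- as_matrix(EBImage::bwlabel(face_mask))
    storage.mode(face_label) <- "integer"
    # enclosed faces only: drop components touching anything outside the
    # peripheral zone (dense band, nucleus lobes, cell edge, canvas frame)
    open_labels <- labels_touching(face_label, !peripheral, frame = TRUE)
    if (length(open_labels)) face_label[face_label %in% open_labels] <- 0L
    if (any(face_label > 0L)) {
      tb <- tabulate(face_label)
      keep <- which(tb > 0L)
      # renumber 1..n
      remap <- integer(max(face_label))
      remap[keep] <- seq_along(keep)
      face_label[face_label > 0L] <- remap[face_label[face_label > 0L]]
      face_areas_px <- tb[keep]
    }
  }

  er <- matrix(0, nr, nc)
  er[cyto] <- 0.08
  er[tubule] <- 1
  er[dense] <- spec$dense_intensity_ratio
  er[nucleus] <- 0.04
  nuc_ch <- matrix(0, nr, nc)
  nuc_ch[nucleus] <- 1
  mem <- matrix(0, nr, nc)
  mem[cell] <- 0.15
  rim <- r2 > (R - 1.5)^2 & r2 <= (R + 0.5)^2
  mem[rim] <- 1

  list(channels = list(er = er, nucleus = nuc_ch, membrane = mem),
       cell_mask = cell, nucleus_mask = nucleus, dense_mask = dense,
       face_label = face_label, face_areas_px = face_areas_px,
       cyto_px = sum(cyto), dense_px = sum(dense))
}

make_ground_truth <- function(spec, render, pixel_size_um) {
  px_area <- pixel_size_um^2
  structure(list(
    cell_mask = render$cell_mask,
    nucleus_mask = render$nucleus_mask,
    dense_mask = render$dense_mask,
    polygon_label = render$face_label,
    true_polygon_areas = render$face_areas_px * px_area,
    true_dense_fraction_pct = 100 * render$dense_px / render$cyto_px,
    true_nuclear_area_um2 = sum(render$nucleus_mask) * px_area,
    phenotype_label = if (spec$n_lobes > 1L) "multilobed" else "normal",
    border = FALSE,
    pixel_size_um = pixel_size_um
  ), class = "ground_truth")
}

# blur a clean multichannel render into a defocus series and apply noise;
# `focus` is the in-focus slice index of this object
noise_zstack <- function(channels, noise, z_slices, defocus_rate,
                         focus = (z_slices + 1) / 2) {
  lapply(channels, function(ch) {
    slices <- lapply(seq_len(z_slices), function(k) {
      off <- abs(k - focus)
      nk <- noise_params(sigma_blur = noise$sigma_blur * (1 + defocus_rate * off),
                         photon_scale = noise$photon_scale / (1 + 0.25 * off),
                         read_sigma = noise$read_sigma, enabled = noise$enabled)
      apply_noise(ch, nk)
    })
    array(unlist(slices), dim = c(dim(channels[[1]]), z_slices))
  })
}

# defocus series of clean channels (blur + attenuation only, no noise)
defocus_stack <- function(channels, noise, z_slices, defocus_rate, focus) {
  lapply(channels, function(ch) {
    slices <- lapply(seq_len(z_slices), function(k) {
      off <- abs(k - focus)
      s <- gauss_blur(ch, noise$sigma_blur * (1 + defocus_rate * off))
      s / (1 + 0.25 * off)
    })
    array(unlist(slices), dim = c(dim(ch), z_slices))
  })
}

#' Render one synthetic cell
#'
#' @param spec a [cell_spec()].
#' @param noise a [noise_params()] object.
#' @param pixel_size_um micrometres per pixel (default 0.28).
#' @param z_slices 1 for a single plane (default), or the number of optical
#'   slices of a defocus z-stack (e.g. 5).
#' @param defocus_rate per-slice blur growth rate for z-stacks.
#' @return list with elements `image` (a [field_image()]) and `truth`
#'   (a `ground_truth` with exact masks, per-polygon areas in um^2, the
#'   dense-ER percentage of the cytoplasm, and the phenotype label).
#' @export
synthesize_cell <- function(spec, noise = noise_params(),
                            pixel_size_um = ERSCREEN_PIXEL_SIZE_UM,
                            z_slices = 1L, defocus_rate = 0.6) {
  with_seed(spec$seed, {
    render <- render_cell(spec)
    truth <- make_ground_truth(spec, render, pixel_size_um)
    channels <- if (z_slices > 1L) {
      noise_zstack(render$channels, noise, z_slices, defocus_rate)
    } else {
      lapply(render$channels, apply_noise, noise = noise)
    }
    list(image = field_image(channels, pixel_size_um), truth = truth)
  })
}

#' Composite several cells into one field of view
#'
#' Cells are rendered independently from their specs (each from its own
#' seed), pasted onto a shared canvas and then passed through the noise
#' model once. Cells whose mask reaches the canvas frame are flagged
#' `border` in the ground truth; the specified cell placements must not
#' overlap.
#'
#' @param specs list of [cell_spec()]s, each with a `center`.
#' @param dim canvas size `(rows, cols)` in px.
#' @inheritParams synthesize_cell
#' @param field_seed seed for the field-level noise draw.
#' @param keep_masks retain per-field label maps in the ground truth.
#' @return list with `image` (a [field_image()]), `truth` (per-cell list of
#'   `ground_truth` objects without masks), and, when `keep_masks`, label
#'   maps `cell_labels`, `nucleus_labels` and the field `dense_mask`.
#' @export
synthesize_field <- function(specs, dim = c(448L, 448L),
                             noise = noise_params(),
                             pixel_size_um = ERSCREEN_PIXEL_SIZE_UM,
                             z_slices = 1L, defocus_rate = 0.6,
                             field_seed = 1L, keep_masks = TRUE) {
  stopifnot(length(specs) >= 1L)
  centers <- lapply(specs, `[[`, "center")
  if (any(vapply(centers, is.null, logical(1))))
    stop("every cell_spec needs a center for field compositing")
  for (i in seq_along(specs)) {
    for (j in seq_len(i - 1L)) {
      dd <- sqrt(sum((centers[[i]] - centers[[j]])^2))
      if (dd < specs[[i]]$cell_radius + specs[[j]]$cell_radius + 2)
        stop("overlapping cell placement between cells ", j, " and ", i)
    }
  }
  nr <- dim[1]; nc <- dim[2]
  nz <- max(1L, as.integer(z_slices))
  # each cell sits at its own height: its in-focus slice differs, which is
  # what makes the projection informative
  foci <- if (nz > 1L) with_seed(derive_seed(field_seed, 777L),
    sample(nz, length(specs), replace = length(specs) > nz)) else
    rep(1L, length(specs))
  er <- array(0, c(nr, nc, nz)); nuc <- array(0, c(nr, nc, nz))
  mem <- array(0, c(nr, nc, nz))
  cell_labels <- matrix(0L, nr, nc); nucleus_labels <- matrix(0L, nr, nc)
  dense_mask <- matrix(FALSE, nr, nc)
  truths <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    R <- ceiling(sp$cell_radius) + 3L
    cx <- sp$center[1]; cy <- sp$center[2]
    rows <- max(1L, floor(cx) - R):min(nr, ceiling(cx) + R)
    cols <- max(1L, floor(cy) - R):min(nc, ceiling(cy) + R)
    loc <- with_seed(sp$seed, {
      render_cell(sp, dim = c(length(rows), length(cols)),
                  center = c(cx - rows[1] + 1, cy - cols[1] + 1))
    })
    tr <- make_ground_truth(sp, loc, pixel_size_um)
    # border flag: mask reaches the canvas frame
    on_frame <- (rows[1] == 1L && any(loc$cell_mask[1, ])) ||
      (rows[length(rows)] == nr && any(loc$cell_mask[nrow(loc$cell_mask), ])) ||
      (cols[1] == 1L && any(loc$cell_mask[, 1])) ||
      (cols[length(cols)] == nc && any(loc$cell_mask[, ncol(loc$cell_mask)]))
    tr$border <- on_frame
    tr$cell_id <- i
    tr$center <- c(cx, cy)
    tr[c("cell_mask", "nucleus_mask", "dense_mask", "polygon_label")] <- NULL
    truths[[i]] <- tr
    # blur locally at paste time (cell supports are disjoint, so this
    # equals blurring the composited field) to keep field noise cheap
    if (nz == 1L) {
      if (noise$enabled && noise$sigma_blur > 0)
        loc$channels <- lapply(loc$channels, gauss_blur,
                               sigma = noise$sigma_blur)
      er[rows, cols, 1] <- pmax(er[rows, cols, 1], loc$channels$er)
      nuc[rows, cols, 1] <- pmax(nuc[rows, cols, 1], loc$channels$nucleus)
      mem[rows, cols, 1] <- pmax(mem[rows, cols, 1], loc$channels$membrane)
    } else {
      stk <- if (noise$enabled)
        defocus_stack(loc$channels, noise, nz, defocus_rate, foci[i])
      else lapply(loc$channels, function(ch)
        array(rep(ch, nz), c(dim(ch), nz)))
      er[rows, cols, ] <- pmax(er[rows, cols, ], stk$er)
      nuc[rows, cols, ] <- pmax(nuc[rows, cols, ], stk$nucleus)
      mem[rows, cols, ] <- pmax(mem[rows, cols, ], stk$membrane)
    }
    if (keep_masks) {
      cl <- cell_labels[rows, cols]; cl[loc$cell_mask] <- i
      cell_labels[rows, cols] <- cl
      nl <- nucleus_labels[rows, cols]; nl[loc$nucleus_mask] <- i
      nucleus_labels[rows, cols] <- nl
      dm <- dense_mask[rows, cols]
      dense_mask[rows, cols] <- dm | loc$dense_mask
    }
  }
  channels <- with_seed(field_seed, {
    lapply(list(er = er, nucleus = nuc, membrane = mem), function(arr) {
      for (z in seq_len(nz))
        arr[, , z] <- apply_noise(arr[, , z], noise, do_blur = FALSE)
      if (nz == 1L) arr[, , 1] else arr
    })
  })
  out <- list(image = field_image(channels, pixel_size_um), truth = truths)
  if (keep_masks) {
    out$cell_labels <- cell_labels
    out$nucleus_labels <- nucleus_labels
    out$dense_mask <- dense_mask
  }
  out
}

#' Draw random non-overlapping cell specs for one field
#'
#' Cell radii are log-normal around `cell_radius` (CV ~12%), nuclear radii
#' a log-normal fraction of the cell radius, tubule spacing and the dense
#' band log-normal around their (effect-scaled) means. Placement is
#' rejection sampling of non-overlapping circles; cells may touch the
#' field border. Fails with a placement error when the requested count
#' cannot be placed within the retry budget.
#'
#' @param n number of cells.
#' @param dim field size in px.
#' @param seed integer seed.
#' @param base named list of baseline parameters (see defaults in the code).
#' @param polygon_effect,dense_effect multiplicative condition effects on
#'   tubule spacing and dense-band fraction.
#' @param phenotype_rate probability that a cell carries a multilobed
#'   nucleus.
#' @param max_tries placement retry budget per cell.
#' @param strict error when not all `n` cells can be placed (default);
#'   with `strict = FALSE` the cells placed so far are returned with a
#'   warning (sparser field), which keeps long plate simulations running.
#' @return list of [cell_spec()]s.
#' @export
random_cell_specs <- function(n, dim = c(448L, 448L), seed = 1L,
                              base = list(), polygon_effect = 1,
                              dense_effect = 1, phenotype_rate = 0,
                              max_tries = 400L, strict = TRUE) {
  b <- modifyList(list(cell_radius = 64, nucleus_fraction = 0.30,
                       tubule_spacing = 8, tubule_width = 2,
                       dense_band_fraction = 0.25,
                       dense_intensity_ratio = 3,
                       radius_cv = 0.12, spacing_cv = 0.15,
                       dense_cv = 0.10), base)
  with_seed(seed, {
    specs <- list()
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n)) {
      R <- b$cell_radius * rlnorm(1, 0, b$radius_cv)
      margin <- 0.6 * R
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cx <- runif(1, margin, dim[1] - margin)
        cy <- runif(1, margin, dim[2] - margin)
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                radii + R + 6)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        if (strict)
          stop("placement error: could not fit ", n, " non-overlapping cells")
        warning("placed only ", length(specs), " of ", n, " cells",
                call. = FALSE)
        break
      }
      rn <- R * b$nucleus_fraction * rlnorm(1, 0, 0.08)
      rn <- min(rn, 0.45 * R)
      lobes <- if (runif(1) < phenotype_rate) sample(5:7, 1) else 1L
      specs[[i]] <- cell_spec(
        center = c(cx, cy), cell_radius = R, nucleus_radius = rn,
        n_lobes = lobes,
        tubule_spacing = b$tubule_spacing * polygon_effect * rlnorm(1, 0, b$spacing_cv),
        tubule_width = b$tubule_width,
        dense_band_fraction = min(0.9, b$dense_band_fraction * dense_effect *
                                    rlnorm(1, 0, b$dense_cv)),
        dense_intensity_ratio = b$dense_intensity_ratio * rlnorm(1, 0, 0.05),
        seed = derive_seed(seed, i, 7L)
      )
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, R)
    }
    specs
  })
}

#' Simulate a full screening plate
#'
#' Generates fields for every analysed well of a 96-well layout. Candidate
#' conditions take their multiplicative effects from `effects`
#' (`data.frame` with columns `condition`, `polygon_effect`, `dense_effect`
#' and optionally `phenotype_rate`); unlisted conditions, NTC wells and
#' untreated wells are simulated at the null effect (1, 1). INCENP wells
#' are simulated at `incenp_rate` multilobed phenotype rate.
#'
#' @param layout a [plate_layout()].
#' @param effects condition effect table (may be `NULL` for an all-null
#'   plate).
#' @param n_fields fields per well.
#' @param incenp_fields fields imaged in INCENP QC wells (default
#'   `3 * n_fields`: the efficiency gate needs ~100 scored nuclei for a
#'   stable percentage, so QC wells are scored over more fields).
#' @param ntc_fields fields imaged in NTC wells (default `2 * n_fields`:
#'   the pooled control enters every Dunnett comparison, so extra control
#'   cells benefit the whole screen; a full three-replicate screen would
#'   pool 9 NTC wells).
#' @param cells_per_field expected cells per field.
#' @param seed plate-level seed; all well/field/cell seeds derive from it.
#' @param noise a [noise_params()].
#' @param base baseline cell parameters, see [random_cell_specs()].
#' @param incenp_rate simulated INCENP phenotype rate (default 0.8).
#' @param baseline_rate spontaneous multilobed rate in all other wells
#'   (default 0: the multilobed construct models the strong INCENP
#'   knockdown phenotype, not ordinary spontaneous binucleation).
#' @param include_edge also simulate the untreated outer wells (off by
#'   default: they are excluded from analysis and only slow the run).
#' @param wells optional character vector restricting simulation to a
#'   subset of well coordinates (a partial plate run); control wells must
#'   be retained for downstream statistics.
#' @param dim field size in px.
#' @param on_field optional callback `function(field, info)` invoked with
#'   each synthesized field (`info` has `plate`, `well`, `field`,
#'   `condition`, `role`); when supplied, images are not retained, which
#'   keeps memory flat for whole-plate runs.
#' @param keep_masks keep per-field label maps (only when fields are
#'   retained).
#' @param plate_id plate identifier string.
#' @return list with `manifest` (one row per field), `truth` (one row per
#'   simulated cell: well, condition, true readouts, phenotype, border) and
#'   `fields` (list of synthesized fields, unless `on_field` was given).
#' @export
synthesize_screen_plate <- function(layout, effects = NULL, n_fields = 3L,
                                    incenp_fields = 3L * n_fields,
                                    ntc_fields = 2L * n_fields,
                                    cells_per_field = 9L, seed = 1L,
                                    noise = noise_params(), base = list(),
                                    incenp_rate = 0.8, baseline_rate = 0,
                                    include_edge = FALSE, dim = c(448L, 448L),
                                    on_field = NULL, keep_masks = FALSE,
                                    plate_id = "SIMPLATE", wells = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  wl <- layout$wells
  if (!is.null(wells)) wl <- wl[wl$well %in% wells, , drop = FALSE]
  if (!any(wl$role == "ntc"))
    stop("layout error: no NTC wells; downstream statistics require a control")
  if (!include_edge) wl <- wl[wl$role != "untreated_edge", , drop = FALSE]
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects), "condition" %in% names(effects))
    if (is.null(effects$phenotype_rate)) effects$phenotype_rate <- NA_real_
  }
  keep_fields <- is.null(on_field)
  fields_out <- if (keep_fields) list() else NULL
  manifest <- list(); truth_rows <- list()
  for (w in seq_len(nrow(wl))) {
    role <- wl$role[w]
    cond <- wl$condition[w]
    pe <- 1; de <- 1; rate <- baseline_rate
    if (role == "incenp") rate <- incenp_rate
    if (role == "candidate" && !is.null(effects) &&
        cond %in% effects$condition) {
      e <- effects[match(cond, effects$condition), ]
      pe <- e$polygon_effect; de <- e$dense_effect
      if (!is.na(e$phenotype_rate)) rate <- e$phenotype_rate
    }
    nf <- switch(role, incenp = incenp_fields, ntc = ntc_fields, n_fields)
    for (f in seq_len(nf)) {
      fseed <- derive_seed(seed, w, f)
      specs <- random_cell_specs(cells_per_field, dim = dim, seed = fseed,
                                 base = base, polygon_effect = pe,
                                 dense_effect = de, phenotype_rate = rate,
                                 strict = FALSE)
      fld <- synthesize_field(specs, dim = dim, noise = noise,
                              field_seed = derive_seed(fseed, 999L),
                              keep_masks = keep_masks || !keep_fields)
      fld$image$plate <- plate_id
      fld$image$well <- wl$well[w]
      fld$image$field <- f
      info <- list(plate = plate_id, well = wl$well[w], field = f,
                   condition = cond, role = role)
      manifest[[length(manifest) + 1L]] <- as.data.frame(info)
      for (tr in fld$truth) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          plate = plate_id, well = wl$well[w], field = f, cell_id = tr$cell_id,
          condition = cond, role = role,
          true_mean_polygon_area_um2 = if (length(tr$true_polygon_areas))
            mean(tr$true_polygon_areas) else NA_real_,
          true_n_polygons = length(tr$true_polygon_areas),
          true_dense_fraction_pct = tr$true_dense_fraction_pct,
          true_nuclear_area_um2 = tr$true_nuclear_area_um2,
          phenotype = tr$phenotype_label, border = tr$border
        )
      }
      if (keep_fields) {
        fields_out[[length(fields_out) + 1L]] <- fld
      } else {
        on_field(fld, info)
      }
    }
  }
  list(manifest = do.call(rbind, manifest),
       truth = do.call(rbind, truth_rows),
       fields = fields_out)
}
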