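# End-to-end pipeline --------------------------------------------------------

#' Measure every field of a simulated or stored plate
#'
#' Runs segmentation and per-cell morphometrics over the fields of a
#' plate, returning one tidy per-cell table annotated with well roles and
#' conditions.
#'
#' @param plate result of [synthesize_screen_plate()] with retained
#'   fields, or a manifest data.frame with a `file` column of TIFF paths.
#' @param layout the [plate_layout()].
#' @param config a [morph_config()].
#' @param segmentation `"image"` (default: full nucleus + cell
#'   segmentation) or `"truth"` (simulator masks; fields must retain
#'   masks).
#' @return per-cell data.frame (see [measure_field()]) with `condition`
#'   and `role` columns.
#' @export
measure_plate <- function(plate, layout, config = morph_config(),
                          segmentation = c("image", "truth")) {
  segmentation <- match.arg(segmentation)
  stopifnot(inherits(layout, "plate_layout"))
  tabs <- list()
  fields <- if (is.data.frame(plate)) {
    lapply(plate$file, read_field)
  } else plate$fields
  for (fld in fields) {
    seg <- if (segmentation == "truth") truth_segmentation(fld)
           else segment_field(if (inherits(fld, "field_image")) fld
                              else fld$image,
                              projection = config$projection)
    tabs[[length(tabs) + 1L]] <- measure_field(seg, config)
  }
  out <- do.call(rbind, tabs)
  idx <- match(out$well, layout$wells$well)
  out$condition <- layout$wells$condition[idx]
  out$role <- layout$wells$role[idx]
  out
}

# nuclear morphometrics only (for INCENP QC wells)
measure_nuclei_only <- function(image, config = morph_config()) {
  nuc <- project_channel(image$channels$nucleus, config$projection)
  nl <- segment_nuclei(nuc, pixel_size_um = image$pixel_size_um)
  ids <- setdiff(sort(unique(as.vector(nl))), 0L)
  bl <- border_labels(nl)
  px <- image$pixel_size_um
  rows <- lapply(ids, function(id) {
    m <- nl == id
    data.frame(cell_id = id, n_polygons = NA_integer_,
               mean_polygon_area_um2 = NA_real_,
               dense_fraction_pct = NA_real_,
               nuclear_area_um2 = sum(m) * px^2,
               nuclear_circularity = circularity(m),
               border_excluded = id %in% bl)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), n_polygons = integer(0),
               mean_polygon_area_um2 = numeric(0),
               dense_fraction_pct = numeric(0),
               nuclear_area_um2 = numeric(0),
               nuclear_circularity = numeric(0),
               border_excluded = logical(0))
  cbind(data.frame(plate = image$plate, well = image$well,
                   field = image$field), out)
}

#' Simulate, measure and analyse a whole screen
#'
#' Synthesizes a plate field by field (constant memory), measures each
#' field as it is produced, runs the INCENP transfection QC and, when the
#' plate passes, the screen statistics.
#'
#' @inheritParams synthesize_screen_plate
#' @param config a [morph_config()].
#' @param n_per_well cells sampled per well for the statistics.
#' @param alpha family-wise error rate of hit calling.
#' @param qc_threshold_pct transfection-efficiency gate (default 65).
#' @return list with `cells` (per-cell table), `truth`, `qc`
#'   (a `qc_report`), `screen` (an `er_screen`, `NULL` when QC fails) and
#'   `hits`.
#' @export
run_screen <- function(layout, effects = NULL, n_fields = 3L,
                       incenp_fields = 3L * n_fields,
                       ntc_fields = 2L * n_fields,
                       cells_per_field = 9L, seed = 1L,
                       noise = noise_params(), base = list(),
                       incenp_rate = 0.8, dim = c(448L, 448L),
                       config = morph_config(), n_per_well = 70,
                       alpha = 0.05, qc_threshold_pct = 65, wells = NULL) {
  tabs <- list()
  collect <- function(fld, info) {
    tab <- if (info$role == "incenp") {
      # QC wells only feed the nuclear phenotype: skip cell segmentation
      # and ER morphometrics
      measure_nuclei_only(fld$image, config)
    } else {
      seg <- segment_field(fld$image, projection = config$projection)
      measure_field(seg, config)
    }
    tab$condition <- info$condition
    tab$role <- info$role
    tabs[[length(tabs) + 1L]] <<- tab
  }
  sim <- synthesize_screen_plate(layout, effects = effects,
                                 n_fields = n_fields,
                                 incenp_fields = incenp_fields,
                                 ntc_fields = ntc_fields,
                                 cells_per_field = cells_per_field,
                                 seed = seed, noise = noise, base = base,
                                 incenp_rate = incenp_rate, dim = dim,
                                 on_field = collect, wells = wells,
                                 plate_id = layout$plate_id)
  cells <- do.call(rbind, tabs)
  qc <- qc_plate(cells, layout, threshold_pct = qc_threshold_pct)
  screen <- NULL
  hits <- NULL
  if (qc$pass) {
    screen <- analyze_screen(cells, n_per_well = n_per_well,
                             seed = derive_seed(seed, 4242L), alpha = alpha)
    hits <- call_hits(screen)
  } else {
    message("plate ", layout$plate_id,
            " failed transfection QC; excluded from hit calling")
  }
  list(cells = cells, truth = sim$truth, qc = qc, screen = screen,
       hits = hits)
}
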