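# INCENP transfection QC ------------------------------------------------------
#
# INCENP knockdown blocks complete nuclear fission, producing multilobed
# nuclei of enlarged area and irregular circularity — a visible reporter of
# transfection. Each plate carries two INCENP wells; the fraction of cells
# showing the phenotype estimates the plate's transfection efficiency,
# which must reach 65% for the plate to enter hit calling.

# Default classifier thresholds, derived by calibrate_nucleus_classifier()
# on the simulator's normal-nucleus population (97.5th area percentile,
# 2.5th circularity percentile; n = 600, seed 101). Regenerate with the
# calibration function after changing the generator geometry.
NUCLEUS_THRESHOLDS_DEFAULT <- list(area_um2 = 153.29552, circ = 0.994715)

#' Calibrate the multilobed-nucleus classifier
#'
#' Simulates normal (single-lobe) nuclei through the full segmentation and
#' measurement path and returns the 97.5th percentile of nuclear area and
#' the 2.5th percentile of circularity as classification thresholds.
#'
#' @param n number of simulated nuclei.
#' @param seed integer seed.
#' @param base baseline cell parameters, see [random_cell_specs()].
#' @param noise a [noise_params()].
#' @return list with `area_um2` and `circ` thresholds.
#' @export
calibrate_nucleus_classifier <- function(n = 600, seed = 101,
                                         base = list(),
                                         noise = noise_params()) {
  recs <- simulate_nucleus_records(n, seed = seed, base = base, noise = noise,
                                   phenotype_rate = 0)
  list(area_um2 = quantile(recs$nuclear_area_um2, 0.975, names = FALSE),
       circ = quantile(recs$nuclear_circularity, 0.025, names = FALSE))
}

# measured nuclear records of n simulated cells (segmentation + measurement)
simulate_nucleus_records <- function(n, seed = 1, base = list(),
                                     noise = noise_params(),
                                     phenotype_rate = 0) {
  per_field <- 4L
  rows <- list()
  f <- 0L
  while (sum(vapply(rows, nrow, integer(1))) < n) {
    f <- f + 1L
    specs <- random_cell_specs(per_field, dim = c(384L, 384L),
                               seed = derive_seed(seed, f),
                               base = base, phenotype_rate = phenotype_rate,
                               strict = FALSE)
    fld <- synthesize_field(specs, dim = c(384L, 384L), noise = noise,
                            field_seed = derive_seed(seed, f, 2L),
                            keep_masks = FALSE)
    nl <- segment_nuclei(fld$image$channels$nucleus,
                         pixel_size_um = fld$image$pixel_size_um)
    keep <- setdiff(seq_len(max(nl)), border_labels(nl))
    if (!length(keep)) next
    px <- fld$image$pixel_size_um
    truth_lab <- vapply(fld$truth, function(t) t$phenotype_label, character(1))
    centers <- lapply(fld$truth, `[[`, "center")
    out <- lapply(keep, function(id) {
      m <- nl == id
      # match detected nucleus to the generating cell by centroid
      idxs <- which(m, arr.ind = TRUE)
      cen <- colMeans(idxs)
      dd <- vapply(centers, function(cc) sum((cc - cen)^2), numeric(1))
      data.frame(nuclear_area_um2 = sum(m) * px^2,
                 nuclear_circularity = circularity(m),
                 phenotype = truth_lab[which.min(dd)])
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, out)
  }
  out <- do.call(rbind, rows)
  out[seq_len(n), ]
}

#' Classify a nucleus as normal or multilobed
#'
#' Multilobed requires both an enlarged area and an irregular (low)
#' circularity.
#'
#' @param nuclear_area_um2 nuclear area(s), um^2.
#' @param circ nuclear circularity value(s).
#' @param thresholds list with `area_um2` and `circ`
#'   (default: simulator-calibrated package values).
#' @return character vector, `"normal"` or `"multilobed"`.
#' @export
classify_nucleus <- function(nuclear_area_um2, circ,
                             thresholds = NUCLEUS_THRESHOLDS_DEFAULT) {
  if (any(!is.na(nuclear_area_um2) & nuclear_area_um2 <= 0))
    stop("classify_nucleus: non-positive nuclear area")
  ifelse(nuclear_area_um2 > thresholds$area_um2 & circ < thresholds$circ,
         "multilobed", "normal")
}

#' Phenotype fraction of one well
#'
#' @param cells per-cell records of one INCENP well (needs
#'   `nuclear_area_um2`, `nuclear_circularity`, `border_excluded`).
#' @param thresholds classifier thresholds, see [classify_nucleus()].
#' @return percentage of scored (non-border) cells classified multilobed.
#' @export
well_efficiency <- function(cells, thresholds = NUCLEUS_THRESHOLDS_DEFAULT) {
  scored <- cells[!cells$border_excluded & !is.na(cells$nuclear_area_um2), ]
  if (!nrow(scored)) stop("QC error: no scored cells in well")
  cls <- classify_nucleus(scored$nuclear_area_um2,
                          scored$nuclear_circularity, thresholds)
  100 * mean(cls == "multilobed")
}

#' Plate-level transfection QC
#'
#' Scores every INCENP well of a plate, averages their phenotype fractions
#' into the plate efficiency and gates at `threshold_pct` (inclusive).
#'
#' @param cells per-cell table of the plate (columns `well`,
#'   `nuclear_area_um2`, `nuclear_circularity`, `border_excluded`).
#' @param layout the [plate_layout()].
#' @param threshold_pct efficiency gate, default 65.
#' @param rule `"mean"` (default: mean across INCENP wells) or `"all"`
#'   (every INCENP well must individually reach the gate).
#' @param thresholds classifier thresholds.
#' @return a `qc_report`: per-well efficiencies, plate efficiency, pass
#'   flag.
#' @export
qc_plate <- function(cells, layout, threshold_pct = 65,
                     rule = c("mean", "all"),
                     thresholds = NUCLEUS_THRESHOLDS_DEFAULT) {
  rule <- match.arg(rule)
  stopifnot(inherits(layout, "plate_layout"))
  incenp_wells <- layout$wells$well[layout$wells$role == "incenp"]
  if (!length(incenp_wells))
    stop("configuration error: layout has no INCENP wells")
  eff <- vapply(incenp_wells, function(w) {
    wc <- cells[cells$well == w, ]
    if (!nrow(wc)) stop("QC error: no cells recorded for INCENP well ", w)
    well_efficiency(wc, thresholds)
  }, numeric(1))
  n_scored <- vapply(incenp_wells, function(w) {
    wc <- cells[cells$well == w, ]
    sum(!wc$border_excluded & !is.na(wc$nuclear_area_um2))
  }, numeric(1))
  plate_eff <- mean(eff)
  pass <- if (rule == "mean") plate_eff >= threshold_pct
          else all(eff >= threshold_pct)
  structure(list(plate_id = layout$plate_id,
                 well_efficiency_pct = eff, n_cells_scored = n_scored,
                 plate_efficiency_pct = plate_eff,
                 threshold_pct = threshold_pct, rule = rule, pass = pass),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> plate %s: efficiency %.1f%% (gate %.0f%%) — %s\n",
              x$plate_id, x$plate_efficiency_pct, x$threshold_pct,
              if (x$pass) "PASS" else "FAIL"))
  for (w in names(x$well_efficiency_pct))
    cat(sprintf("  %s: %.1f%% (%d cells)\n", w, x$well_efficiency_pct[[w]],
                as.integer(x$n_cells_scored[[w]])))
  invisible(x)
}

#' Gate a plate on its QC report
#'
#' @param report a `qc_report` from [qc_plate()].
#' @param threshold_pct efficiency gate (default 65; `>=` is inclusive).
#' @return logical pass/fail.
#' @export
gate_plate <- function(report, threshold_pct = 65) {
  stopifnot(inherits(report, "qc_report"))
  if (report$rule == "mean") report$plate_efficiency_pct >= threshold_pct
  else all(report$well_efficiency_pct >= threshold_pct)
}
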