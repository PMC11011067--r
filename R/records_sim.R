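# Record-level screen simulator ----------------------------------------------
#
# Draws per-cell morphometric records directly from the generative
# distributions, bypassing image synthesis and measurement. Used for
# statistical calibration (family-wise error, power, sampling arithmetic)
# where thousands of screens are needed and the imaging stages are
# exercised elsewhere.

#' Simulate a per-cell screen record table without images
#'
#' Cells are drawn i.i.d. within wells: mean polygon area log-normal
#' around the condition mean, dense-ER percentage normal (clipped to
#' `[0, 100]`).
#'
#' @param conditions character vector of condition names (must include
#'   `"NTC"`).
#' @param wells_per_condition named (or single) number of wells per
#'   condition; the control defaults to 9 wells as in a 3-plate screen.
#' @param cells_per_well cells recorded per well.
#' @param effects optional data.frame (`condition`, `polygon_effect`,
#'   `dense_effect`): multiplicative shift of the polygon-area mean and of
#'   the dense percentage.
#' @param base list with `polygon_mean` (um^2), `polygon_cv`, `dense_mean`
#'   (percent), `dense_sd` (points).
#' @param seed integer seed.
#' @return data.frame with `well`, `condition`, `mean_polygon_area_um2`,
#'   `dense_fraction_pct`, `border_excluded`.
#' @export
simulate_cell_records <- function(conditions, wells_per_condition = 3,
                                  cells_per_well = 70, effects = NULL,
                                  base = list(), seed = 1) {
  stopifnot("NTC" %in% conditions)
  b <- modifyList(list(polygon_mean = 5, polygon_cv = 0.45,
                       dense_mean = 30, dense_sd = 6), base)
  if (length(wells_per_condition) == 1L) {
    wells_per_condition <- setNames(rep(wells_per_condition,
                                        length(conditions)), conditions)
    wells_per_condition[["NTC"]] <- max(wells_per_condition[["NTC"]], 9)
  }
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) {
      pe <- 1; de <- 1
      if (!is.null(effects) && cond %in% effects$condition) {
        e <- effects[match(cond, effects$condition), ]
        pe <- e$polygon_effect; de <- e$dense_effect
      }
      for (w in seq_len(wells_per_condition[[cond]])) {
        n <- cells_per_well
        rows[[length(rows) + 1L]] <- data.frame(
          well = sprintf("%s_w%d", cond, w), condition = cond,
          mean_polygon_area_um2 = rlnorm(n, log(b$polygon_mean * pe),
                                         sqrt(log(1 + b$polygon_cv^2))),
          dense_fraction_pct = pmin(100, pmax(0,
            rnorm(n, b$dense_mean * de, b$dense_sd))),
          border_excluded = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
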