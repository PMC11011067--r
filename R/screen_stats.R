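# Screen-level statistics ----------------------------------------------------
#
# Per-well random sampling of cells, one-way ANOVA with Dunnett many-to-one
# post-tests against the pooled non-targeting control, star levels
# (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001), and direction-labelled
# biological interpretation of significant ER-readout changes.

#' Randomly sample cells per well
#'
#' Uniform sampling without replacement of at most `n_per_well` analysable
#' (non-border) cells from every well; wells with fewer cells contribute
#' all of them with a warning.
#'
#' @param cells per-cell table (needs columns `well` and
#'   `border_excluded`).
#' @param n_per_well cells sampled per well (default 70).
#' @param seed integer seed; the draw is deterministic given it.
#' @return the sampled subset of `cells`.
#' @export
sample_cells <- function(cells, n_per_well = 70, seed = 1) {
  stopifnot(is.data.frame(cells), "well" %in% names(cells))
  if ("border_excluded" %in% names(cells))
    cells <- cells[!cells$border_excluded, , drop = FALSE]
  wells <- unique(cells$well)
  with_seed(seed, {
    picks <- lapply(wells, function(w) {
      idx <- which(cells$well == w)
      if (!length(idx)) return(integer(0))
      if (length(idx) <= n_per_well) {
        if (length(idx) < n_per_well)
          warning("well ", w, " has only ", length(idx), " cells (< ",
                  n_per_well, "); using all", call. = FALSE)
        idx
      } else {
        sample(idx, n_per_well)
      }
    })
    cells[sort(unlist(picks)), , drop = FALSE]
  })
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Compares every condition against the control with the single-step
#' Dunnett procedure (equal-variance pooled estimate, two-sided,
#' multivariate-t critical distribution), reporting family-wise adjusted
#' p-values alongside the omnibus ANOVA.
#'
#' @param values numeric response per cell.
#' @param group condition per cell (character or factor).
#' @param control control condition name (default `"NTC"`), pooled across
#'   its wells.
#' @return list with `anova_f`, `anova_p` and `table`
#'   (condition, estimate = condition mean - control mean, t, adjusted p).
#' @export
dunnett_vs_control <- function(values, group, control = "NTC") {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group)[keep]
  if (!control %in% group) stop("control group '", control, "' missing")
  if (sum(group == control) < 2) stop("control group needs n >= 2")
  g <- factor(group)
  g <- stats::relevel(g, ref = control)
  if (nlevels(g) < 2) stop("need at least two groups")
  fit <- aov(values ~ g, data = data.frame(values = values, g = g))
  an <- summary(fit)[[1]]
  # sort comparisons in a canonical order so results do not depend on the
  # order conditions appear in the data
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  # the multivariate-t integration is randomised quasi-Monte-Carlo; pin the
  # stream locally so results are reproducible, and restore the caller's
  sm <- with_seed(20090625, summary(glht_fit,
                                    test = multcomp::adjusted("single-step")))
  comp_names <- sub(" - .*$", "", names(sm$test$coefficients))
  tab <- data.frame(condition = comp_names,
                    estimate = as.numeric(sm$test$coefficients),
                    t = as.numeric(sm$test$tstat),
                    p_adj = as.numeric(sm$test$pvalues),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$condition), ]
  rownames(tab) <- NULL
  list(anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       df_resid = fit$df.residual, table = tab)
}

#' Star level of a p-value
#'
#' `ns` p >= 0.05, `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
star_level <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

interpretation_label <- function(readout, direction) {
  if (direction == "unchanged") return("no detected change")
  if (readout == "mean_polygon_area_um2") {
    if (direction == "decreased") "more densely packed tubular ER network"
    else "less dense tubular ER network"
  } else {
    if (direction == "increased") "expansion of the dense sheet ER"
    else "contraction of the sheet ER"
  }
}

#' Analyse a screen's cell table
#'
#' Samples cells per well, runs one-way ANOVA + Dunnett against the pooled
#' NTC control for both ER readouts, assigns stars and directions and
#' derives the biological interpretation of each significant change.
#'
#' @param cells per-cell table (columns `well`, `condition`,
#'   `mean_polygon_area_um2`, `dense_fraction_pct`, `border_excluded`).
#'   Untreated edge wells and INCENP wells are dropped before analysis.
#' @param n_per_well cells sampled per well (default 70).
#' @param seed sampling seed.
#' @param alpha family-wise error rate of the hit calls (default 0.05,
#'   controlled across both readouts).
#' @param control control condition name.
#' @param unit `"cell"` (default; every sampled cell is an observation,
#'   mirroring per-cell screen analyses) or `"well"` (well means are the
#'   observations — robust to within-well pseudoreplication).
#' @param readouts readout columns to analyse.
#' @return an `er_screen` object; see [call_hits()], `print()` and
#'   `summary()`.
#' @export
analyze_screen <- function(cells, n_per_well = 70, seed = 1, alpha = 0.05,
                           control = "NTC",
                           unit = c("cell", "well"),
                           readouts = c("mean_polygon_area_um2",
                                        "dense_fraction_pct")) {
  unit <- match.arg(unit)
  stopifnot(all(c("well", "condition") %in% names(cells)),
            all(readouts %in% names(cells)))
  if ("role" %in% names(cells))
    cells <- cells[!cells$role %in% c("untreated_edge", "incenp"), ,
                   drop = FALSE]
  cells <- cells[cells$condition != "untreated" &
                   cells$condition != "INCENP", , drop = FALSE]
  sampled <- sample_cells(cells, n_per_well = n_per_well, seed = seed)
  results <- list()
  for (ro in readouts) {
    dat <- sampled[!is.na(sampled[[ro]]), ]
    vals <- if (unit == "well") {
      agg <- stats::aggregate(dat[[ro]],
                              by = list(condition = dat$condition,
                                        well = dat$well), FUN = mean)
      list(v = agg$x, g = agg$condition)
    } else list(v = dat[[ro]], g = dat$condition)
    dn <- dunnett_vs_control(vals$v, vals$g, control = control)
    grp_mean <- tapply(vals$v, vals$g, mean)
    grp_sem <- tapply(vals$v, vals$g, function(x) sd(x) / sqrt(length(x)))
    grp_n_cells <- tapply(dat[[ro]], dat$condition, length)
    tab <- dn$table
    tab$mean <- as.numeric(grp_mean[tab$condition])
    tab$sem <- as.numeric(grp_sem[tab$condition])
    tab$n <- as.integer(grp_n_cells[tab$condition])
    tab$control_mean <- as.numeric(grp_mean[[control]])
    tab$stars <- star_level(tab$p_adj)
    tab$direction <- ifelse(tab$stars == "ns", "unchanged",
                            ifelse(tab$estimate > 0, "increased", "decreased"))
    tab$interpretation <- vapply(seq_len(nrow(tab)), function(i)
      interpretation_label(ro, tab$direction[i]), character(1))
    tab$readout <- ro
    results[[ro]] <- list(anova_f = dn$anova_f, anova_p = dn$anova_p,
                          table = tab)
  }
  structure(list(results = results, readouts = readouts, alpha = alpha,
                 control = control, unit = unit, n_per_well = n_per_well,
                 seed = seed,
                 n_control = sum(sampled$condition == control),
                 n_conditions = length(setdiff(unique(sampled$condition),
                                               control)),
                 sampled = sampled),
            class = "er_screen")
}

#' Conditions table of a screen analysis
#'
#' @param screen an `er_screen` from [analyze_screen()].
#' @return data.frame with one row per condition and readout: mean, SEM,
#'   n, Dunnett-adjusted p, stars, direction, interpretation.
#' @export
conditions_table <- function(screen) {
  stopifnot(inherits(screen, "er_screen"))
  out <- do.call(rbind, lapply(screen$results, function(r) r$table))
  rownames(out) <- NULL
  out[c("readout", "condition", "n", "mean", "sem", "control_mean",
        "estimate", "t", "p_adj", "stars", "direction", "interpretation")]
}

#' Call hits against the control
#'
#' A condition is a hit on a readout when its Dunnett-adjusted p-value
#' falls below `alpha / n_readouts`, so that the family-wise error rate of
#' the whole screen (all conditions, both readouts) stays at `alpha`.
#'
#' @param screen an `er_screen`.
#' @param alpha family-wise error rate across the entire screen.
#' @return data.frame of hits (possibly empty) with direction and
#'   interpretation labels.
#' @export
call_hits <- function(screen, alpha = screen$alpha) {
  tab <- conditions_table(screen)
  cut_p <- alpha / length(screen$readouts)
  hits <- tab[tab$p_adj < cut_p, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @export
print.er_screen <- function(x, ...) {
  cat(sprintf("<er_screen> %d conditions vs %s (%d control cells), unit=%s\n",
              x$n_conditions, x$control, x$n_control, x$unit))
  for (ro in x$readouts) {
    r <- x$results[[ro]]
    cat(sprintf("  %s: ANOVA F=%.2f p=%.3g\n", ro, r$anova_f, r$anova_p))
  }
  h <- call_hits(x)
  cat(sprintf("  hits at family-wise alpha=%.3g: %d\n", x$alpha, nrow(h)))
  if (nrow(h))
    print(h[c("readout", "condition", "estimate", "p_adj", "stars",
              "direction")], digits = 3)
  invisible(x)
}

#' @export
summary.er_screen <- function(object, ...) {
  conditions_table(object)
}
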