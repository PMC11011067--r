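# shared fixtures: everything is generated in code at test time

# a small, fast cell spec (default geometry unless overridden)
quick_spec <- function(seed = 1, ...) {
  cell_spec(seed = seed, ...)
}

# measure the two ER readouts of a synthesized single cell using its own
# ground-truth masks (isolates morphometrics from segmentation)
measure_from_truth <- function(cellres, config = morph_config()) {
  tr <- cellres$truth
  er <- cellres$image$channels$er
  if (length(dim(er)) == 3L) er <- project_stack(er)
  d <- dense_er_fraction(er, tr$cell_mask, tr$nucleus_mask, config)
  peripheral <- (tr$cell_mask & !tr$nucleus_mask) & !d$band
  areas <- tubular_polygons(er, tr$cell_mask, peripheral,
                            pixel_size_um = tr$pixel_size_um,
                            config = config)
  list(dense_fraction_pct = d$dense_fraction_pct,
       polygon_areas = areas,
       mean_polygon_area = if (length(areas)) mean(areas) else NA_real_)
}

# rasterised disk / square masks for shape oracles
disk_mask <- function(r, pad = 4L) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- (n + 1) / 2
  dx <- matrix(seq_len(n) - c0, n, n)
  dy <- t(dx)
  dx^2 + dy^2 <= r^2
}

square_mask <- function(a, pad = 4L) {
  n <- a + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + a), (pad + 1):(pad + a)] <- TRUE
  m
}

# brute-force exact Euclidean distance from each pixel to the nearest
# TRUE pixel of `target` (chunked; independent of the package's EDT)
brute_distance <- function(target) {
  idx <- which(target, arr.ind = TRUE)
  out <- matrix(Inf, nrow(target), ncol(target))
  all_px <- expand.grid(i = seq_len(nrow(target)), j = seq_len(ncol(target)))
  step <- 2000L
  for (s in seq(1L, nrow(all_px), by = step)) {
    rows <- s:min(s + step - 1L, nrow(all_px))
    di <- outer(all_px$i[rows], idx[, 1], "-")
    dj <- outer(all_px$j[rows], idx[, 2], "-")
    out[cbind(all_px$i[rows], all_px$j[rows])] <-
      sqrt(apply(di^2 + dj^2, 1, min))
  }
  out
}

# layout + effect table of the simulated validation screen: two
# conditions with a denser tubular network and expanded dense ER, one
# with enlarged polygons, twenty null conditions
demo_screen_design <- function() {
  conds <- c(rep(c("HIT_DN1", "HIT_DN2", "HIT_UP1"), each = 3),
             rep(sprintf("NULL%02d", 1:20), each = 2), rep("FILLER", 6))
  layout <- default_screen_layout(candidates = conds)
  wells <- layout$wells$well[layout$wells$condition != "FILLER" &
                              layout$wells$role %in%
                                c("candidate", "ntc", "incenp")]
  effects <- data.frame(condition = c("HIT_DN1", "HIT_DN2", "HIT_UP1"),
                        polygon_effect = c(0.6, 0.6, 1.5),
                        dense_effect = c(1.4, 1.4, 1.0))
  list(layout = layout, wells = wells, effects = effects)
}
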