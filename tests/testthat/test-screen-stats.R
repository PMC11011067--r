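# per-well sampling, Dunnett statistics, hit calling

test_that("per-well sampling keeps at most 70 cells, deterministically", {
  cells <- simulate_cell_records(c("NTC", "GENE1"),
                                 wells_per_condition = c(NTC = 1, GENE1 = 2),
                                 cells_per_well = 200, seed = 1)
  s1 <- sample_cells(cells, n_per_well = 70, seed = 5)
  s2 <- sample_cells(cells, n_per_well = 70, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(table(s1$well) == 70))
  s3 <- sample_cells(cells, n_per_well = 70, seed = 6)
  expect_false(identical(rownames(s1), rownames(s3)))
  # exactly 70 cells -> all retained, no warning
  small <- cells[cells$well == "NTC_w1", ][1:70, ]
  expect_silent(sk <- sample_cells(small, n_per_well = 70, seed = 1))
  expect_identical(nrow(sk), 70L)
  # short wells contribute everything with a warning
  expect_warning(su <- sample_cells(small[1:40, ], n_per_well = 70),
                 "only 40")
  expect_identical(nrow(su), 40L)
})

test_that("three wells of 70 sampled cells give a 210-cell analysis set", {
  cells <- simulate_cell_records(c("NTC", "TARGET"),
                                 wells_per_condition = c(NTC = 9, TARGET = 3),
                                 cells_per_well = 90, seed = 2)
  sampled <- sample_cells(cells, n_per_well = 70, seed = 3)
  expect_identical(sum(sampled$condition == "TARGET"), 210L)
  expect_identical(sum(sampled$condition == "NTC"), 630L)
})

test_that("two-group Dunnett collapses to the equal-variance t-test", {
  set.seed(7)
  v <- c(rnorm(12, 10), rnorm(14, 10.8))
  g <- rep(c("NTC", "A"), c(12, 14))
  dn <- dunnett_vs_control(v, g)
  tt <- t.test(v[g == "A"], v[g == "NTC"], var.equal = TRUE)
  expect_lt(abs(dn$table$p_adj - tt$p.value), 1e-6)
})

test_that("adjusted p-values are invariant to row order", {
  set.seed(8)
  v <- rnorm(60)
  g <- rep(c("NTC", "A", "B"), each = 20)
  d1 <- dunnett_vs_control(v, g)
  perm <- sample(60)
  d2 <- dunnett_vs_control(v[perm], g[perm])
  expect_equal(d1$table, d2$table, tolerance = 1e-10)
})

test_that("Dunnett rejects unusable control groups", {
  expect_error(dunnett_vs_control(rnorm(10), rep("A", 10)), "missing")
  expect_error(dunnett_vs_control(c(1, 2, 3), c("NTC", "A", "A")),
               "n >= 2")
})

test_that("an 0.8-SD shift at screen sample sizes is always detected", {
  for (seed in 1:5) {
    cells <- simulate_cell_records(
      c("NTC", sprintf("G%02d", 1:20)), wells_per_condition = 3,
      cells_per_well = 70,
      effects = data.frame(condition = "G01", polygon_effect = 1,
                           dense_effect = 1.16), # 0.8 x dense_sd = 4.8 pts
      seed = seed)
    sc <- analyze_screen(cells, seed = seed)
    tab <- sc$results$dense_fraction_pct$table
    expect_lt(tab$p_adj[tab$condition == "G01"], 0.05)
  }
})

test_that("star levels follow the published cut-offs", {
  expect_identical(star_level(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
                   c("ns", "*", "**", "***", "****"))
  expect_identical(star_level(c(0.05, 0.01, 0.001, 1e-4)),
                   c("ns", "*", "**", "***"))
})

test_that("hit calls carry direction and ER interpretation labels", {
  eff <- data.frame(condition = c("DENSER", "SPARSER"),
                    polygon_effect = c(0.5, 1.8),
                    dense_effect = c(1.5, 0.6))
  cells <- simulate_cell_records(c("NTC", "DENSER", "SPARSER",
                                   sprintf("N%02d", 1:10)),
                                 wells_per_condition = 3,
                                 cells_per_well = 70, effects = eff,
                                 seed = 9)
  sc <- analyze_screen(cells, seed = 9)
  hits <- call_hits(sc)
  expect_true(all(c("DENSER", "SPARSER") %in% hits$condition))
  poly <- hits[hits$readout == "mean_polygon_area_um2", ]
  expect_identical(poly$direction[poly$condition == "DENSER"], "decreased")
  expect_match(poly$interpretation[poly$condition == "DENSER"],
               "densely packed")
  expect_identical(poly$direction[poly$condition == "SPARSER"], "increased")
  expect_match(poly$interpretation[poly$condition == "SPARSER"],
               "less dense")
  dense <- hits[hits$readout == "dense_fraction_pct", ]
  expect_match(dense$interpretation[dense$condition == "DENSER"],
               "expansion")
  expect_match(dense$interpretation[dense$condition == "SPARSER"],
               "contraction")
  # direction only for significant conditions
  tab <- conditions_table(sc)
  expect_true(all(tab$direction[tab$stars == "ns"] == "unchanged"))
  # well-level analysis mode runs and finds the strong effects too
  scw <- analyze_screen(cells, seed = 9, unit = "well")
  expect_true("DENSER" %in% call_hits(scw)$condition)
})
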