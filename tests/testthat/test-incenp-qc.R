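# INCENP multilobed-nucleus QC and plate gating

test_that("classification needs both enlarged area and low circularity", {
  thr <- list(area_um2 = 100, circ = 0.9)
  expect_identical(classify_nucleus(80, 0.98, thr), "normal")
  expect_identical(classify_nucleus(150, 0.95, thr), "normal")  # round, big
  expect_identical(classify_nucleus(80, 0.6, thr), "normal")    # small, lobed
  expect_identical(classify_nucleus(150, 0.6, thr), "multilobed")
  expect_error(classify_nucleus(-3, 0.5, thr), "non-positive")
})

test_that("classifier reaches 90% accuracy on a balanced synthetic set", {
  normal <- suppressWarnings(
    erscreen:::simulate_nucleus_records(100, seed = 51, phenotype_rate = 0))
  lobed <- suppressWarnings(
    erscreen:::simulate_nucleus_records(100, seed = 52, phenotype_rate = 1))
  both <- rbind(normal, lobed)
  cls <- classify_nucleus(both$nuclear_area_um2, both$nuclear_circularity)
  truth <- c(rep("normal", 100), rep("multilobed", 100))
  expect_gte(mean(cls == truth), 0.9)
})

test_that("well efficiency covers the trivial and simulated cases", {
  mk <- function(area, circ) data.frame(
    nuclear_area_um2 = area, nuclear_circularity = circ,
    border_excluded = FALSE)
  thr <- list(area_um2 = 100, circ = 0.9)
  expect_identical(well_efficiency(mk(rep(60, 50), rep(0.97, 50)), thr), 0)
  expect_identical(well_efficiency(mk(rep(200, 20), rep(0.5, 20)), thr), 100)
  empty <- data.frame(nuclear_area_um2 = numeric(0),
                      nuclear_circularity = numeric(0),
                      border_excluded = logical(0))
  expect_error(well_efficiency(empty), "no scored")
  # generator at 80% phenotype rate is reported near 80%
  sim <- suppressWarnings(
    erscreen:::simulate_nucleus_records(100, seed = 53,
                                        phenotype_rate = 0.8))
  expect_gte(mean(sim$phenotype == "multilobed") * 100,
             80 - 1.96 * sqrt(0.8 * 0.2 / 100) * 100)
  sim$border_excluded <- FALSE
  eff <- well_efficiency(sim)
  expect_lt(abs(eff - 80), 10)
})

test_that("the 65% plate gate is inclusive and monotone in its threshold", {
  mk_report <- function(effs) structure(
    list(plate_id = "P", well_efficiency_pct = effs,
         n_cells_scored = rep(50, length(effs)),
         plate_efficiency_pct = mean(effs), threshold_pct = 65,
         rule = "mean", pass = mean(effs) >= 65), class = "qc_report")
  expect_true(gate_plate(mk_report(c(70, 72))))
  expect_false(gate_plate(mk_report(c(60, 58))))
  expect_true(gate_plate(mk_report(c(65, 65))))
  r <- mk_report(c(62, 70))
  passes <- vapply(seq(50, 90, by = 5),
                   function(t) gate_plate(r, threshold_pct = t), logical(1))
  expect_true(all(diff(as.integer(passes)) <= 0))
  # "all wells" rule is stricter than the mean rule
  r$rule <- "all"
  expect_false(gate_plate(r, threshold_pct = 65))
})

test_that("plate QC errors on missing INCENP wells or empty wells", {
  lay <- default_screen_layout()
  cells <- data.frame(well = "B2", nuclear_area_um2 = 80,
                      nuclear_circularity = 0.97, border_excluded = FALSE)
  expect_error(qc_plate(cells, lay), "INCENP well")
  no_incenp <- lay$wells
  no_incenp$role[no_incenp$role == "incenp"] <- "candidate"
  no_incenp$condition[no_incenp$role == "candidate" &
                        no_incenp$condition == "INCENP"] <- "X"
  expect_error(plate_layout(no_incenp), "INCENP")
})
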