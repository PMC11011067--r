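# z-projection, nucleus and cell segmentation

test_that("projection handles trivial stacks and rejects empty input", {
  m <- matrix(runif(64), 8, 8)
  expect_identical(project_stack(array(m, c(8, 8, 1))), m)
  const <- array(rep(m, 5), c(8, 8, 5))
  expect_identical(project_stack(const), m)
  expect_equal(project_stack(const, method = "mean"), m)
  expect_error(project_stack(array(0, c(8, 8, 0))), "non-empty")
})

test_that("max projection of a defocus stack beats single slices on SNR", {
  # three cells at different heights: every single slice has some cells
  # out of focus, while the projection keeps each cell near its focus
  specs <- list(cell_spec(center = c(90, 90), seed = 61),
                cell_spec(center = c(90, 250), seed = 62),
                cell_spec(center = c(250, 170), seed = 63))
  fld <- synthesize_field(specs, dim = c(340L, 340L), z_slices = 5L,
                          field_seed = 64L)
  clean <- synthesize_field(specs, dim = c(340L, 340L),
                            noise = noise_params(enabled = FALSE),
                            field_seed = 64L, keep_masks = TRUE)
  tub <- clean$image$channels$er == 200
  gap <- clean$cell_labels > 0 & clean$image$channels$er == 16
  snr <- function(img) (mean(img[tub]) - mean(img[gap])) / sd(img[gap])
  stack <- fld$image$channels$er
  proj <- project_stack(stack)
  slice_snr <- vapply(seq_len(dim(stack)[3]),
                      function(z) snr(stack[, , z]), numeric(1))
  expect_gte(snr(proj), max(slice_snr))
})

test_that("nuclei are detected with high overlap against ground truth", {
  specs <- random_cell_specs(4, dim = c(416L, 416L), seed = 21,
                             strict = FALSE)
  fld <- synthesize_field(specs, dim = c(416L, 416L), field_seed = 22L,
                          keep_masks = TRUE)
  nl <- segment_nuclei(fld$image$channels$nucleus)
  truth <- fld$nucleus_labels
  non_border <- setdiff(seq_along(fld$truth), which(
    vapply(fld$truth, `[[`, logical(1), "border")))
  detected <- 0L
  for (id in non_border) {
    tm <- truth == id
    cand <- nl[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) next
    lab <- as.integer(names(sort(table(cand), decreasing = TRUE))[1])
    mm <- nl == lab
    iou <- sum(mm & tm) / sum(mm | tm)
    if (iou >= 0.8) detected <- detected + 1L
    expect_gte(iou, 0.8)
  }
  expect_identical(detected, length(non_border))
})

test_that("blank images yield no nuclei and no cells (with a warning)", {
  blank <- matrix(0, 64, 64)
  nl <- segment_nuclei(blank)
  expect_identical(max(nl), 0L)
  expect_warning(cl <- segment_cells(matrix(0, 64, 64), nl), "no nuclei")
  expect_identical(max(cl), 0L)
})

test_that("multilobed nuclei stay merged as one object", {
  sp <- cell_spec(n_lobes = 3L, seed = 23)
  fld <- synthesize_field(list(cell_spec(center = c(160, 160),
                                         n_lobes = 3L, seed = 23)),
                          dim = c(320L, 320L), keep_masks = TRUE)
  nl <- segment_nuclei(fld$image$channels$nucleus)
  expect_identical(max(nl), 1L)
})

test_that("cell masks recover ground truth and share nucleus labels", {
  fld <- synthesize_field(list(cell_spec(center = c(160, 160), seed = 24)),
                          dim = c(320L, 320L), keep_masks = TRUE)
  seg <- segment_field(fld$image)
  expect_identical(max(seg$cell_labels), 1L)
  tm <- fld$cell_labels == 1
  mm <- seg$cell_labels == 1
  expect_gte(sum(mm & tm) / sum(mm | tm), 0.9)
  # label consistency on nucleus pixels
  nuc_px <- seg$nucleus_labels > 0
  expect_identical(seg$cell_labels[nuc_px], seg$nucleus_labels[nuc_px])
})

test_that("adjacent cells are separated with one cell per nucleus", {
  specs <- list(cell_spec(center = c(105, 160), seed = 25),
                cell_spec(center = c(245, 160), seed = 26))
  fld <- synthesize_field(specs, dim = c(352L, 352L), keep_masks = TRUE)
  seg <- segment_field(fld$image)
  expect_identical(max(seg$cell_labels), 2L)
  for (id in 1:2) {
    tm <- fld$cell_labels == id
    cand <- seg$cell_labels[tm]; cand <- cand[cand > 0]
    best <- as.integer(names(sort(table(cand), decreasing = TRUE))[1])
    other <- setdiff(1:2, best)
    # the matched region must not bleed into the other truth cell
    expect_lt(sum(seg$cell_labels == best & fld$cell_labels ==
                    setdiff(1:2, id)) / sum(tm), 0.02)
  }
})

test_that("border-touching labels are excluded and others never touch", {
  specs <- list(cell_spec(center = c(20, 200), seed = 27),
                cell_spec(center = c(210, 200), seed = 28))
  fld <- synthesize_field(specs, dim = c(400L, 400L))
  seg <- segment_field(fld$image)
  expect_true(length(seg$border_excluded) >= 1)
  kept <- setdiff(seq_len(max(seg$cell_labels)), seg$border_excluded)
  for (id in kept) {
    m <- seg$cell_labels == id
    expect_false(any(m[1, ]) || any(m[nrow(m), ]) ||
                   any(m[, 1]) || any(m[, ncol(m)]))
  }
})
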