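test_that("pixel-to-cell conversion follows the circle-area normalization", {
  expect_equal(estimate_cell_count(0, "CD8", resolution_um_per_px = 0.346), 0)
  # one 8 um disk covers ~420 px at 0.346 um/px -> ~1 cell
  expect_equal(estimate_cell_count(420, "CD8", resolution_um_per_px = 0.346),
               420 * 0.346^2 / (pi * 16), tolerance = 1e-12)
  expect_equal(estimate_cell_count(420, "CD8", resolution_um_per_px = 0.346),
               1.0003, tolerance = 1e-3)
  # equal pixel areas: a macrophage counts 1/4 as much as a lymphocyte
  expect_equal(estimate_cell_count(1000, "CD163", resolution_um_per_px = 1),
               estimate_cell_count(1000, "CD8", resolution_um_per_px = 1) / 4)
  expect_error(estimate_cell_count(10, "CD99", resolution_um_per_px = 1), "unknown")
})

test_that("zone scores substitute directly into the ZS definition", {
  # one 8 um CD8 disk inside a PERI_NEG band -> ZS ~ cells / band area
  m <- two_bar_mask(120, 120, pos_cols = integer(0), neg_cols = 1, res = 1)
  m <- paint_disk(m, 60, 10, 4, "CD8")
  zm <- assign_zones(m, depth_um = 20, contact_um = 1.5)
  sc <- compute_zone_scores(m, zm, case_id = "t")
  rec <- sc[sc$class == "CD8" & sc$marker == "K17-" & sc$compartment == "peri", ]
  expect_equal(rec$cells, rec$pixels / (pi * 16), tolerance = 1e-12)
  expect_equal(rec$score_per_mm2, rec$cells / rec$zone_area_um2 * 1e6)
  expect_equal(rec$cells, 1, tolerance = 0.1)           # pixelated disk ~ one cell
  # no immune pixels anywhere -> all scores zero
  sc0 <- compute_zone_scores(two_bar_mask(), assign_zones(two_bar_mask(), 25, 1.5))
  expect_true(all(sc0$score_per_mm2 == 0))
})

test_that("scores omit zero-denominator records and respect marker swap", {
  m <- two_bar_mask(40, 40, pos_cols = 20, neg_cols = integer(0))
  zm <- assign_zones(m, depth_um = 10, contact_um = 1.5)
  sc <- compute_zone_scores(m, zm)
  expect_true(all(sc$marker == "K17+"))   # no NEG zones exist
  expect_equal(nrow(sc), 8)

  # odd bar separation -> no equidistant stroma pixels, so the swap is exact
  m2 <- two_bar_mask(60, 60, pos_cols = 20, neg_cols = 41)
  m2 <- paint_disk(m2, 30, 24, 3, "CD8")
  m2 <- paint_disk(m2, 12, 45, 5, "CD163")
  zm2 <- assign_zones(m2, depth_um = 10, contact_um = 1.5)
  sw <- swap_markers(m2)
  scA <- compute_zone_scores(m2, zm2)
  scB <- compute_zone_scores(sw, assign_zones(sw, depth_um = 10, contact_um = 1.5))
  flip <- function(x) ifelse(x == "K17+", "K17-", "K17+")
  merged <- merge(scA, transform(scB, marker = flip(marker)),
                  by = c("class", "marker", "compartment"))
  expect_equal(merged$score_per_mm2.x, merged$score_per_mm2.y)
})

test_that("zone scores are additive over disjoint zones of one label", {
  m <- two_bar_mask(60, 120, pos_cols = integer(0), neg_cols = c(20, 100), res = 1)
  m <- paint_disk(m, 30, 25, 3, "CD4")
  m <- paint_disk(m, 30, 95, 3, "CD4")
  zm <- assign_zones(m, depth_um = 10, contact_um = 1.5)
  sc <- compute_zone_scores(m, zm)
  rec <- sc[sc$class == "CD4" & sc$marker == "K17-" & sc$compartment == "peri", ]
  # halves of the image each hold one bar + one disk; merged totals must sum
  left <- label_mask(unclass(m)[, 1:60], 1)
  right <- label_mask(unclass(m)[, 61:120], 1)
  part <- lapply(list(left, right), function(mm) {
    compute_zone_scores(mm, assign_zones(mm, depth_um = 10, contact_um = 1.5))
  })
  pr <- dplyr::bind_rows(part)
  pr <- pr[pr$class == "CD4" & pr$marker == "K17-" & pr$compartment == "peri", ]
  expect_equal(sum(pr$cells), rec$cells)
  expect_equal(sum(pr$zone_area_um2), rec$zone_area_um2)
})

test_that("k disjoint disks are recovered within pixelation error", {
  res <- 0.346
  for (k in c(1, 5, 25)) {
    m <- blank_mask(320, 320, res = res)
    g <- unclass(m); g[, 1] <- CODE[["TUMOR_K17NEG"]]; m <- label_mask(g, res)
    centers <- expand.grid(row = seq(20, 300, by = 56), col = seq(20, 300, by = 56))
    for (i in seq_len(k)) {
      m <- paint_disk(m, centers$row[i], centers$col[i], 4 / res, "CD8")
    }
    px <- sum(unclass(m) == CODE[["CD8"]])
    est <- estimate_cell_count(px, "CD8", resolution_um_per_px = res)
    expect_equal(est, k, tolerance = 0.1)
  }
})

test_that("normalized ratios flag zero denominators and divide the rest", {
  rec <- tibble::tibble(
    case_id = rep(c("a", "b", "c"), each = 2),
    class = "CD8", compartment = "peri",
    marker = rep(c("K17+", "K17-"), 3),
    score_per_mm2 = c(100, 200, 0, 50, 80, 80))
  r <- normalized_ratios(rec)
  expect_equal(r$ratio[r$case_id == "a"], 2)
  expect_equal(r$status[r$case_id == "b"], "undefined_zero_denominator")
  expect_equal(r$ratio[r$case_id == "c"], 1)
  # missing pair -> skipped with warning
  expect_warning(normalized_ratios(rec[-1, ]), "skipped")
})

test_that("digital K17 score applies the 10% threshold inclusively", {
  g <- matrix(CODE[["TUMOR_K17NEG"]], 100, 100)
  g[1:10, 1:100] <- CODE[["TUMOR_K17POS"]]      # 1,000 of 10,000 px
  s <- digital_k17_score(label_mask(g, 1))
  expect_equal(s$k17_percent, 10)
  expect_equal(s$k17_status, "high")
  g2 <- matrix(CODE[["TUMOR_K17NEG"]], 10, 10)
  expect_equal(digital_k17_score(label_mask(g2, 1))$k17_percent, 0)
  expect_equal(digital_k17_score(label_mask(g2, 1))$k17_status, "low")
  g3 <- matrix(CODE[["TUMOR_K17POS"]], 10, 10)
  expect_equal(digital_k17_score(label_mask(g3, 1))$k17_percent, 100)
  expect_error(digital_k17_score(blank_mask()), "tumor")
})
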