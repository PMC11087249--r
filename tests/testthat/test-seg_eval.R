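test_that("dot dilation rasterizes disks by pixel-centre inclusion", {
  none <- dilate_dots(tibble::tibble(x = numeric(), y = numeric(), class = character()),
                      "CD8", 10, 0.346, c(50, 50))
  expect_false(any(none$mask))

  # one dot at 10 um diameter, 0.346 um/px: radius round(5/0.346) = 14 px;
  # exhaustive enumeration of integer offsets with di^2+dj^2 <= 14^2 gives 613
  one <- dilate_dots(tibble::tibble(x = 25, y = 25, class = "CD8"),
                     "CD8", 10, 0.346, c(51, 51))
  off <- expand.grid(di = -14:14, dj = -14:14)
  expect_equal(sum(one$mask), sum(off$di^2 + off$dj^2 <= 14^2))
  expect_equal(sum(one$mask), 613)

  # two dots 1 px apart merge into one blob in the union mask
  two <- dilate_dots(tibble::tibble(x = c(20, 21), y = c(20, 20), class = "CD8"),
                     "CD8", 5, 1, c(41, 41))
  expect_equal(max(label_components_8(two$mask)), 1)
  expect_length(two$disks, 2)

  expect_error(dilate_dots(tibble::tibble(x = 1, y = 1, class = "CD8"),
                           "CD8", 0, 1, c(10, 10)), "positive")
})

test_that("8-connected labelling merges diagonal touches", {
  b <- matrix(FALSE, 5, 5); b[2, 2] <- TRUE; b[3, 3] <- TRUE; b[5, 5] <- TRUE
  lab <- label_components_8(b)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
})

test_that("component matching follows the counting rules literally", {
  H <- 60; W <- 60; res <- 1
  dots <- tibble::tibble(x = c(10, 30, 50), y = c(10, 30, 50), class = "CD8")
  disks <- dilate_dots(dots, "CD8", 10, res, c(H, W))

  # prediction identical to the disks: k separated TPs, nothing else
  r <- component_match(disks$mask, disks)
  expect_equal(unlist(r), c(TP = 3L, FP = 0L, FN = 0L))

  # empty prediction: recall 0, PPV undefined, F1 0
  r0 <- component_match(matrix(FALSE, H, W), disks)
  expect_equal(unlist(r0), c(TP = 0L, FP = 0L, FN = 3L))
  s0 <- immunotopo:::score_counts(0, 0, 3)
  expect_true(is.na(s0$PPV))
  expect_equal(s0$recall, 0)
  expect_equal(s0$F1, 0)

  # one predicted component overlapping two disks: TP 1, FN 0 => recall 1
  # despite two dots (the component-counting asymmetry)
  dots2 <- tibble::tibble(x = c(20, 30), y = c(25, 25), class = "CD8")
  disks2 <- dilate_dots(dots2, "CD8", 6, res, c(H, W))
  pred <- matrix(FALSE, H, W); pred[26, 15:36] <- TRUE
  r2 <- component_match(pred, disks2)
  expect_equal(unlist(r2), c(TP = 1L, FP = 0L, FN = 0L))
  s2 <- immunotopo:::score_counts(r2$TP, r2$FP, r2$FN)
  expect_equal(s2$recall, 1)

  # a merged blob of two unmatched disks still counts FN per source dot
  r3 <- component_match(matrix(FALSE, H, W),
                        dilate_dots(tibble::tibble(x = c(20, 21), y = c(25, 25),
                                                   class = "CD8"),
                                    "CD8", 6, res, c(H, W)))
  expect_equal(r3$FN, 2L)

  expect_error(component_match(matrix(FALSE, 3, 3), disks), "extent")
})

test_that("shrinking the dilation never increases TP", {
  set.seed(55)
  H <- 80; W <- 80
  dots <- tibble::tibble(x = runif(12, 5, 75), y = runif(12, 5, 75), class = "CD8")
  pred <- matrix(FALSE, H, W)
  for (i in 1:12) {
    pred[round(dots$y[i]) + 1 + sample(-6:6, 1), round(dots$x[i]) + 1] <- TRUE
  }
  tp <- vapply(c(14, 10, 6, 2), function(diam) {
    component_match(pred, dilate_dots(dots, "CD8", diam, 1, c(H, W)))$TP
  }, integer(1))
  expect_true(all(diff(tp) <= 0))
})

test_that("evaluation micro-averages counts across patches", {
  # two patches with counts (3,1,0) and (1,1,2): sums (4,2,2) -> 0.667 each
  res <- 1; H <- 80; W <- 80
  mk_patch <- function(dot_xy, pred_xy) {
    dots <- tibble::tibble(x = dot_xy[, 1], y = dot_xy[, 2], class = "CD8",
                           annotator = "a1")
    g <- matrix(CODE[["STROMA"]], H, W)
    g[1, 1] <- CODE[["TUMOR_K17NEG"]]     # keep the mask a valid case
    m <- label_mask(g, res)
    for (i in seq_len(nrow(pred_xy))) m <- paint_disk(m, pred_xy[i, 2] + 1, pred_xy[i, 1] + 1, 2, "CD8")
    list(mask = m, dots = dots)
  }
  # patch 1: 3 dots all hit, 1 spurious component
  p1 <- mk_patch(cbind(c(10, 30, 50), c(10, 10, 10)),
                 cbind(c(10, 30, 50, 70), c(10, 10, 10, 60)))
  # patch 2: 3 dots, one hit, 1 spurious, 2 missed
  p2 <- mk_patch(cbind(c(10, 30, 50), c(40, 40, 40)),
                 cbind(c(10, 70), c(40, 70)))
  ev <- evaluate_detection(list(p1$mask, p2$mask), list(p1$dots, p2$dots),
                           classes = "CD8", diameters_um = 10)
  expect_equal(ev$TP, 4L); expect_equal(ev$FP, 2L); expect_equal(ev$FN, 2L)
  expect_equal(ev$PPV, 0.667, tolerance = 1e-3)
  expect_equal(ev$recall, 0.667, tolerance = 1e-3)
  expect_equal(ev$F1, 0.667, tolerance = 1e-3)

  # perfect patches give F1 = 1 and both diameters are reported side by side
  ev2 <- evaluate_detection(list(p1$mask), list(p1$dots[0, ]), classes = "CD8",
                            diameters_um = c(10, 5))
  expect_equal(nrow(ev2), 2)
  expect_setequal(ev2$dilation_diameter_um, c(10, 5))
  expect_error(evaluate_detection(list(), list()), "empty")
})
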