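# Fixtures are built in code; no binary files ship with the package.

CT <- class_table()
CODE <- setNames(CT$code, CT$role)

# A blank stroma mask with optional resolution.
blank_mask <- function(h = 20, w = 20, res = 1) {
  label_mask(matrix(CODE[["STROMA"]], h, w), res)
}

# Two parallel vertical tumor bars: K17+ at columns pos_cols, K17- at neg_cols.
two_bar_mask <- function(h = 60, w = 60, pos_cols = 5:8, neg_cols = 48:51, res = 1) {
  g <- matrix(CODE[["STROMA"]], h, w)
  g[, pos_cols] <- CODE[["TUMOR_K17POS"]]
  g[, neg_cols] <- CODE[["TUMOR_K17NEG"]]
  label_mask(g, res)
}

# Random small mask with scattered tumor pixels of both markers, for
# oracle-equivalence property tests.
random_tumor_mask <- function(h = 64, w = 64, n_pos = 40, n_neg = 40, res = 1) {
  g <- matrix(CODE[["STROMA"]], h, w)
  idx <- sample.int(h * w, n_pos + n_neg)
  g[idx[seq_len(n_pos)]] <- CODE[["TUMOR_K17POS"]]
  g[idx[n_pos + seq_len(n_neg)]] <- CODE[["TUMOR_K17NEG"]]
  label_mask(g, res)
}

# Paint a filled disk of an immune role onto a mask (centre row/col 1-based,
# radius in pixels; pixel centres within the radius are included).
paint_disk <- function(mask, row, col, radius_px, role) {
  g <- unclass(mask)
  h <- nrow(g); w <- ncol(g)
  rr <- floor(radius_px)
  off <- expand.grid(di = -rr:rr, dj = -rr:rr)
  off <- off[off$di^2 + off$dj^2 <= radius_px^2, ]
  ri <- row + off$di; cj <- col + off$dj
  ok <- ri >= 1 & ri <= h & cj >= 1 & cj <= w
  g[cbind(ri[ok], cj[ok])] <- CODE[[role]]
  label_mask(g, mask_resolution(mask), mask_class_table(mask))
}

# Swap the two tumor marker codes of a mask.
swap_markers <- function(mask) {
  g <- unclass(mask)
  pos <- g == CODE[["TUMOR_K17POS"]]
  neg <- g == CODE[["TUMOR_K17NEG"]]
  g[pos] <- CODE[["TUMOR_K17NEG"]]
  g[neg] <- CODE[["TUMOR_K17POS"]]
  label_mask(g, mask_resolution(mask), mask_class_table(mask))
}

# Small, fast synthetic configuration for pipeline-level tests: coarser
# resolution keeps physical areas (and hence cell counts) meaningful at a
# modest pixel count; lighter infiltrates keep the contact shell uncrowded.
fast_config <- function(...) {
  defaults <- list(image_hw_px = c(400, 400), resolution_um_per_px = 1,
                   n_nests = 5, nest_radius_um = c(28, 6),
                   base_intensity = c(CD4 = 100, CD8 = 250, CD16 = 75, CD163 = 150),
                   intra_fraction = 0.15)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
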