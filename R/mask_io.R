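#' Write a label mask to an indexed PNG or single-channel TIFF
#'
#' Codes are stored as 8-bit grey levels (bit-exact for codes 0..255). The
#' class table and resolution are serialized to a JSON sidecar at
#' `<path>.json` so that [read_label_mask()] can round-trip the mask without
#' further arguments.
#'
#' @param mask A [label_mask()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask")) abort("`mask` must be a label_mask")
  img <- unclass(mask) / 255
  attributes(img) <- list(dim = dim(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, where = path, bits.per.sample = 8L)
  } else {
    abort("unsupported extension: use .png, .tif or .tiff")
  }
  tab <- mask_class_table(mask)
  sidecar <- list(
    resolution_um_per_px = mask_resolution(mask),
    classes = setNames(as.list(tab$role), as.character(tab$code))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a label mask from an indexed PNG or single-channel TIFF
#'
#' Resolution and class table are taken from the JSON sidecar written by
#' [write_label_mask()] when present; explicit arguments override the
#' sidecar. When no sidecar exists the resolution must be given explicitly
#' (it is never silently defaulted).
#'
#' @param path Image path.
#' @param class_table Optional [class_table()] override.
#' @param resolution_um_per_px Optional resolution override.
#' @return A [label_mask()]. Unknown codes raise an error naming the code and
#'   its pixel count.
#' @export
read_label_mask <- function(path, class_table = NULL, resolution_um_per_px = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort("unsupported extension: use .png, .tif or .tiff")
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))

  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (is.null(resolution_um_per_px)) resolution_um_per_px <- sc$resolution_um_per_px
    if (is.null(class_table) && !is.null(sc$classes)) {
      class_table <- validate_class_table(tibble(
        code = as.integer(names(sc$classes)),
        role = unname(vapply(sc$classes, as.character, character(1)))
      ))
    }
  }
  if (is.null(resolution_um_per_px)) {
    abort("resolution not found: no sidecar and no `resolution_um_per_px` given")
  }
  if (is.null(class_table)) class_table <- immunotopo::class_table()
  label_mask(grid, resolution_um_per_px, class_table)
}

#' Read ROI polygons from a GeoJSON FeatureCollection
#'
#' Polygons are in pixel coordinates (x = column, y = row, 0-based); each
#' feature may carry a `case_id` property. Only exterior rings are used.
#'
#' @param path GeoJSON file.
#' @return Tibble with columns `roi_id`, `case_id`, and a list-column
#'   `ring` of two-column (x, y) coordinate matrices.
#' @export
read_rois <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  rows <- purrr::imap(feats, function(f, i) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) return(NULL)
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    colnames(ring) <- c("x", "y")
    tibble(roi_id = i,
           case_id = as.character(f$properties$case_id %||% NA_character_),
           ring = list(validate_ring(ring)))
  })
  dplyr::bind_rows(rows)
}

validate_ring <- function(ring) {
  # drop a repeated closing vertex; the tests below treat rings as closed
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) abort("ROI ring needs at least 3 distinct vertices")
  ring
}

# Even-odd ray casting with explicit boundary inclusion: a point exactly on a
# ring edge (within eps) counts as inside, independent of vertex order.
points_in_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary test: distance from point to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    # crossing test (half-open rule)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
  }
  inside | on_edge
}

#' Restrict a mask to regions of interest
#'
#' Pixels whose centre falls outside every ROI polygon are set to the
#' [excluded_code()] sentinel and drop out of all downstream denominators.
#' Pixel centres lie at integer coordinates (x = col, y = row, 0-based);
#' boundary pixels are included. Passing an empty ROI set is an error unless
#' `allow_empty = TRUE` explicitly opts out of restriction.
#'
#' @param mask A [label_mask()].
#' @param rois Tibble from [read_rois()], or a list of (x, y) ring matrices.
#' @param allow_empty If `TRUE`, an empty ROI set returns the mask unchanged.
#' @return A new [label_mask()] with out-of-ROI pixels excluded.
#' @export
apply_rois <- function(mask, rois, allow_empty = FALSE) {
  rings <- if (is.data.frame(rois)) rois$ring else rois
  if (length(rings) == 0) {
    if (allow_empty) return(mask)
    abort("empty ROI set; pass allow_empty = TRUE to process the full image")
  }
  H <- nrow(mask); W <- ncol(mask)
  for (ring in rings) {
    if (any(ring[, 1] < 0 | ring[, 1] > W - 1 | ring[, 2] < 0 | ring[, 2] > H - 1)) {
      abort("ROI vertex outside mask extent")
    }
  }
  px <- rep(0:(W - 1), each = H)   # column-major to match matrix layout
  py <- rep(0:(H - 1), times = W)
  keep <- rep(FALSE, H * W)
  for (ring in rings) keep <- keep | points_in_ring(px, py, ring)
  grid <- unclass(mask)
  grid[!keep] <- excluded_code()
  label_mask(grid, mask_resolution(mask), mask_class_table(mask))
}

#' Tile an extent into a grid of fixed-size patches
#'
#' Offsets along each axis run 0, stride, 2*stride, ... up to
#' `extent - patch_size`; when the remainder is not a multiple of the stride
#' one flush-end offset at `extent - patch_size` is appended so the patches
#' cover every pixel. A 1000 x 1000 region tiled with 400 px patches at
#' stride 200 yields the 4 x 4 = 16 overlapping patches used to augment
#' each training region of interest.
#'
#' @param extent_hw Integer vector `c(height, width)` in pixels.
#' @param patch_size_px Patch side length (square patches).
#' @param stride_px Stride between patch origins, >= 1.
#' @return Tibble with columns `row_off`, `col_off` (0-based origins), with
#'   attributes `patch_size_px` and `stride_px`.
#' @examples
#' nrow(tile_patches(c(1000, 1000), 400, 200))  # 16
#' @export
tile_patches <- function(extent_hw, patch_size_px, stride_px) {
  extent_hw <- as.integer(extent_hw)
  if (length(extent_hw) != 2L) abort("`extent_hw` must be c(height, width)")
  if (stride_px < 1) abort("`stride_px` must be >= 1")
  if (any(patch_size_px > extent_hw)) abort("patch size exceeds extent")
  axis_offsets <- function(extent) {
    last <- extent - patch_size_px
    offs <- seq(0L, last, by = as.integer(stride_px))
    if (offs[length(offs)] != last) offs <- c(offs, as.integer(last))
    offs
  }
  ro <- axis_offsets(extent_hw[1]); co <- axis_offsets(extent_hw[2])
  out <- tidyr::expand_grid(row_off = ro, col_off = co)
  attr(out, "patch_size_px") <- as.integer(patch_size_px)
  attr(out, "stride_px") <- as.integer(stride_px)
  out
}

#' Read pathologist dot annotations
#'
#' @param path CSV with columns `x`, `y`, `class`, `annotator` (x = column,
#'   y = row, 0-based pixel coordinates).
#' @param extent_hw Optional `c(height, width)`; when given, out-of-bounds
#'   points raise an error that names the offending row.
#' @return Tibble with those four columns.
#' @export
read_dot_annotations <- function(path, extent_hw = NULL) {
  dots <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            x = readr::col_double(), y = readr::col_double(),
                            class = readr::col_character(),
                            annotator = readr::col_character()))
  required <- c("x", "y", "class", "annotator")
  if (!all(required %in% names(dots))) {
    abort(paste0("dot annotation CSV must have columns: ", paste(required, collapse = ", ")))
  }
  oob <- dots$x < 0 | dots$y < 0
  if (!is.null(extent_hw)) {
    oob <- oob | dots$x > extent_hw[2] - 1 | dots$y > extent_hw[1] - 1
  }
  bad <- which(oob)
  if (length(bad)) abort(sprintf("dot annotation out of bounds at row %d", bad[1]))
  dots
}
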