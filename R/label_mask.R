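#' Construct a label mask
#'
#' A label mask is the pipeline's universal input: an H x W integer matrix of
#' pixel class codes plus the physical pixel resolution in micrometres per
#' pixel. Rows are image rows (y, top to bottom), columns are image columns
#' (x, left to right); pixel (row r, col c) is addressed 0-based in file
#' formats and annotations, with the pixel centre at continuous coordinates
#' (x = c, y = r).
#'
#' @param grid Integer matrix of class codes.
#' @param resolution_um_per_px Positive scalar, micrometres per pixel.
#'   The scanner resolution used throughout the source study is 0.346.
#' @param class_table A [class_table()]; defaults to codes 0..6.
#' @return An object of class `label_mask`: the integer matrix with
#'   attributes `resolution_um_per_px` and `class_table`.
#' @examples
#' m <- label_mask(matrix(0L, 4, 4), 0.346)
#' dim(m)
#' @export
label_mask <- function(grid, resolution_um_per_px = 0.346, class_table = immunotopo::class_table()) {
  if (!is.matrix(grid)) abort("`grid` must be a matrix")
  if (nrow(grid) < 1L || ncol(grid) < 1L) abort("mask extent must be at least 1x1")
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      is.na(resolution_um_per_px) || resolution_um_per_px <= 0) {
    abort("`resolution_um_per_px` must be a positive scalar")
  }
  storage.mode(grid) <- "integer"
  class_table <- validate_class_table(class_table)
  present <- unique(as.vector(grid))
  known <- c(class_table$code, excluded_code())
  bad <- setdiff(present, known)
  if (length(bad)) {
    counts <- vapply(bad, function(b) sum(grid == b), integer(1))
    abort(paste0("unknown class code(s) in mask: ",
                 paste(sprintf("%d (%d px)", bad, counts), collapse = ", ")))
  }
  structure(grid,
            resolution_um_per_px = as.numeric(resolution_um_per_px),
            class_table = class_table,
            class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  res <- attr(x, "resolution_um_per_px")
  cat(sprintf("<label_mask> %d x %d px @ %.4g um/px\n", nrow(x), ncol(x), res))
  tab <- attr(x, "class_table")
  cnt <- vapply(tab$code, function(cc) sum(x == cc), integer(1))
  info <- tibble(role = tab$role, code = tab$code, pixels = cnt)
  n_excl <- sum(x == excluded_code())
  print(info, n = Inf)
  if (n_excl > 0) cat(sprintf("excluded (outside ROI): %d px\n", n_excl))
  invisible(x)
}

#' Mask resolution in micrometres per pixel
#' @param mask A [label_mask()].
#' @return Numeric scalar.
#' @export
mask_resolution <- function(mask) attr(mask, "resolution_um_per_px")

#' Class table attached to a mask
#' @param mask A [label_mask()].
#' @return The mask's class table.
#' @export
mask_class_table <- function(mask) attr(mask, "class_table")

#' Tabulate pixel counts per role
#'
#' @param mask A [label_mask()].
#' @return Tibble with columns `role`, `code`, `pixels`.
#' @export
mask_pixel_counts <- function(mask) {
  tab <- mask_class_table(mask)
  tibble(role = tab$role, code = tab$code,
         pixels = vapply(tab$code, function(cc) sum(mask == cc), integer(1)))
}

role_grid <- function(mask, roles) {
  codes <- role_code(mask_class_table(mask), roles)
  matrix(as.vector(mask) %in% codes, nrow(mask), ncol(mask))
}
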