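#' Dilate dot annotations into disks
#'
#' Expands point labels of one class into a binary disk mask: each dot
#' becomes a disk of radius `round((diameter_um/2) / resolution)` pixels; a
#' pixel is included when its centre lies within that radius of the dot.
#' The evaluation protocol uses 10 um and 5 um diameters side by side to
#' probe the sensitivity of the scores to the dilation.
#'
#' @param dots Tibble with `x`, `y` (0-based pixel coordinates) and `class`.
#' @param class Class whose dots to dilate.
#' @param diameter_um Disk diameter in micrometres (> 0).
#' @param resolution_um_per_px Micrometres per pixel.
#' @param extent_hw `c(height, width)` of the target mask.
#' @return List: `mask` (H x W logical union of disks) and `disks` (list of
#'   per-dot pixel index vectors, used to count misses per source dot).
#' @export
dilate_dots <- function(dots, class, diameter_um, resolution_um_per_px, extent_hw) {
  if (diameter_um <= 0) abort("`diameter_um` must be positive")
  H <- extent_hw[1]; W <- extent_hw[2]
  sel <- dots[dots$class == class, , drop = FALSE]
  r_px <- round((diameter_um / 2) / resolution_um_per_px)
  off <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, , drop = FALSE]
  mask <- matrix(FALSE, H, W)
  disks <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    # dots are (x = col, y = row), 0-based; matrix indices are 1-based
    ri <- round(sel$y[i]) + 1L + off$di
    cj <- round(sel$x[i]) + 1L + off$dj
    ok <- ri >= 1 & ri <= H & cj >= 1 & cj <= W
    lin <- (cj[ok] - 1L) * H + ri[ok]
    disks[[i]] <- lin
    mask[lin] <- TRUE
  }
  list(mask = mask, disks = disks)
}

#' 8-connected component labelling
#'
#' Connected components of a binary matrix under 8-connectivity (edge and
#' diagonal adjacency). Built on 4-connected labelling with a union-find
#' merge of labels that touch diagonally.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components_8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab4 <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(m, dim = dim(m))))), nrow(m), ncol(m))
  n <- max(lab4)
  if (n <= 1) return(lab4)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  H <- nrow(m); W <- ncol(m)
  # diagonal neighbour pairs: down-right and down-left shifts
  pairs <- rbind(
    cbind(as.vector(lab4[-H, -W]), as.vector(lab4[-1, -1])),
    cbind(as.vector(lab4[-H, -1]), as.vector(lab4[-1, -W]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab4
  out[lab4 > 0] <- relabel[lab4[lab4 > 0]]
  out
}

#' Match predicted components against dilated dot disks
#'
#' Counts follow the evaluation protocol literally: TP is the number of
#' 8-connected components of the predicted class mask that overlap any
#' disk; FP is the number of components overlapping no disk; FN is the
#' number of source dots whose disk overlaps no predicted pixel (disks that
#' merged into one blob are still counted per source dot). Note the
#' protocol's asymmetry: one component overlapping several disks counts as
#' a single TP yet leaves no FN.
#'
#' @param pred_mask Logical/0-1 matrix of predicted pixels of one class.
#' @param disks Result of [dilate_dots()] (or a compatible list).
#' @return Tibble `TP`, `FP`, `FN`.
#' @export
component_match <- function(pred_mask, disks) {
  if (!all(dim(pred_mask) == dim(disks$mask))) abort("extent mismatch")
  lab <- label_components_8(pred_mask)
  n_comp <- max(lab)
  overlapping <- unique(lab[disks$mask & lab > 0])
  TP <- length(overlapping)
  FP <- n_comp - TP
  pred_any <- pred_mask != 0
  FN <- sum(vapply(disks$disks, function(px) !any(pred_any[px]), logical(1)))
  tibble(TP = TP, FP = FP, FN = as.integer(FN))
}

score_counts <- function(TP, FP, FN) {
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (is.na(ppv) && is.na(recall)) {
    NA_real_
  } else if (isTRUE(ppv == 0) || isTRUE(recall == 0) ||
             (is.na(ppv) && recall == 0) || (is.na(recall) && ppv == 0)) {
    0
  } else if (is.na(ppv) || is.na(recall)) {
    NA_real_
  } else {
    2 * ppv * recall / (ppv + recall)
  }
  tibble(PPV = ppv, recall = recall, F1 = f1)
}

#' Evaluate predicted masks against dot annotations
#'
#' Per class and dilation diameter, TP/FP/FN are counted per patch with
#' [component_match()], summed across patches, and PPV, recall and F1 are
#' computed once on the sums (micro-averaging), which keeps sparse cell
#' types in individual patches from destabilizing the scores.
#'
#' @param pred_masks List of [label_mask()]s (one per patch).
#' @param dots_list List of dot-annotation tibbles (one per patch).
#' @param classes Immune/tumor roles to evaluate; defaults to the classes
#'   present in the annotations.
#' @param diameters_um Dilation diameters, default `c(10, 5)`.
#' @return Tibble `class`, `dilation_diameter_um`, `TP`, `FP`, `FN`, `PPV`,
#'   `recall`, `F1`.
#' @export
evaluate_detection <- function(pred_masks, dots_list, classes = NULL,
                               diameters_um = c(10, 5)) {
  if (length(pred_masks) == 0) abort("patch list is empty")
  if (length(pred_masks) != length(dots_list)) abort("pred_masks and dots_list differ in length")
  if (is.null(classes)) {
    classes <- sort(unique(unlist(lapply(dots_list, function(d) d$class))))
  }
  grid <- tidyr::expand_grid(class = classes, dilation_diameter_um = diameters_um)
  purrr::pmap_dfr(grid, function(class, dilation_diameter_um) {
    counts <- purrr::map_dfr(seq_along(pred_masks), function(p) {
      mask <- pred_masks[[p]]
      disks <- dilate_dots(dots_list[[p]], class, dilation_diameter_um,
                           mask_resolution(mask), dim(mask))
      component_match(role_grid(mask, class), disks)
    })
    sums <- summarise(counts, TP = sum(.data$TP), FP = sum(.data$FP), FN = sum(.data$FN))
    dplyr::bind_cols(
      tibble(class = class, dilation_diameter_um = dilation_diameter_um),
      sums, score_counts(sums$TP, sums$FP, sums$FN))
  })
}
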