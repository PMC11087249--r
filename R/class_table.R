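#' Pixel class roles
#'
#' The seven semantic roles a pixel can carry in a multi-class mIHC
#' segmentation mask: stroma/background, K17-positive tumor, K17-negative
#' (panCK-positive) tumor, and the four immune phenotypes (CD4+ helper T
#' cells, CD8+ cytotoxic T cells, CD16+CD163- M1-like macrophages,
#' CD16+CD163+ M2-like macrophages). `CD16` always means CD16+/CD163- and
#' `CD163` means CD16+/CD163+.
#'
#' @return Character vector of the seven role names.
#' @export
mask_roles <- function() {
  c("STROMA", "TUMOR_K17POS", "TUMOR_K17NEG", "CD4", "CD8", "CD16", "CD163")
}

#' Roles that mark immune cells
#' @return Character vector of the four immune roles.
#' @export
immune_roles <- function() c("CD4", "CD8", "CD16", "CD163")

#' Roles that mark tumor epithelium
#' @return Character vector of the two tumor roles.
#' @export
tumor_roles <- function() c("TUMOR_K17POS", "TUMOR_K17NEG")

#' Sentinel code for pixels excluded by ROI restriction
#'
#' Pixels outside every region of interest are set to this code and enter no
#' downstream numerator or denominator.
#'
#' @return Integer scalar (255).
#' @export
excluded_code <- function() 255L

#' Build a class table mapping integer codes to roles
#'
#' A class table declares which integer code in a label mask encodes which
#' role. Codes must be unique, each of the seven roles must appear exactly
#' once, and by convention stroma is code 0.
#'
#' @param codes Named integer vector, names are roles from [mask_roles()],
#'   values the pixel codes. Defaults to codes 0..6 in [mask_roles()] order.
#' @return A tibble with columns `code` (integer) and `role` (character),
#'   class `immunotopo_class_table`.
#' @examples
#' class_table()
#' @export
class_table <- function(codes = setNames(0:6, mask_roles())) {
  codes <- as.integer(codes)
  names(codes) <- names(codes) %||% mask_roles()
  tab <- tibble(code = unname(codes), role = names(codes))
  validate_class_table(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_class_table <- function(tab) {
  if (!all(c("code", "role") %in% names(tab))) {
    abort("class table needs columns `code` and `role`")
  }
  if (anyDuplicated(tab$code)) abort("class table codes must be unique")
  missing <- setdiff(mask_roles(), tab$role)
  extra <- setdiff(tab$role, mask_roles())
  if (length(missing)) abort(paste0("class table missing roles: ",
                                    paste(missing, collapse = ", ")))
  if (length(extra)) abort(paste0("unknown roles: ", paste(extra, collapse = ", ")))
  if (anyDuplicated(tab$role)) abort("each role must appear exactly once")
  if (any(tab$code == excluded_code())) {
    abort(sprintf("code %d is reserved for ROI-excluded pixels", excluded_code()))
  }
  structure(tab, class = c("immunotopo_class_table", class(tibble())))
}

#' Look up the code for a role
#' @param tab A class table.
#' @param role Role name(s).
#' @return Integer code(s).
#' @export
role_code <- function(tab, role) {
  idx <- match(role, tab$role)
  if (anyNA(idx)) abort(paste0("unknown role: ", paste(role[is.na(idx)], collapse = ", ")))
  tab$code[idx]
}
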