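#' Immune cell geometry
#'
#' Average cell dimensions used to convert stained pixel area into cell
#' counts: lymphocytes (CD4, CD8) are approximated as 8 um diameter circles,
#' macrophages (CD16, CD163) as 16 um circles.
#'
#' @param diameters_um Named numeric vector of diameters per immune role.
#' @return Tibble `role`, `diameter_um`, `area_um2` (pi (d/2)^2).
#' @export
cell_geometry <- function(diameters_um = c(CD4 = 8, CD8 = 8, CD16 = 16, CD163 = 16)) {
  if (any(diameters_um <= 0)) abort("cell diameters must be positive")
  tibble(role = names(diameters_um),
         diameter_um = unname(diameters_um),
         area_um2 = pi * (unname(diameters_um) / 2)^2)
}

#' Estimate a cell count from a stained pixel count
#'
#' Pixels are converted to square micrometres via the resolution, then
#' normalized by the average single-cell area of the role:
#' `count = pixels * resolution^2 / (pi (d/2)^2)`.
#'
#' @param immune_pixel_count Non-negative pixel count.
#' @param role One of the immune roles.
#' @param geometry Table from [cell_geometry()].
#' @param resolution_um_per_px Micrometres per pixel.
#' @return Estimated (real-valued) cell count.
#' @examples
#' estimate_cell_count(420, "CD8", resolution_um_per_px = 0.346)  # ~1 cell
#' @export
estimate_cell_count <- function(immune_pixel_count, role, geometry = cell_geometry(),
                                resolution_um_per_px) {
  if (any(immune_pixel_count < 0)) abort("pixel count must be >= 0")
  idx <- match(role, geometry$role)
  if (anyNA(idx)) abort(paste0("unknown immune role: ", paste(role[is.na(idx)], collapse = ", ")))
  immune_pixel_count * resolution_um_per_px^2 / geometry$area_um2[idx]
}

#' Tumor/Stromal Zone Scores for one case
#'
#' For each immune class, marker side M (K17+/K17-) and compartment, the
#' score is the estimated immune-cell count divided by the zone area:
#' peritumoral numerator pixels are immune pixels labelled `PERI_M` and the
#' denominator is the full `PERI_M` band (immune pixels included - they are
#' stroma); intratumoral numerator pixels are immune pixels in the contact
#' shell `CONTACT_M` and the denominator is the `TUMOR_M` + `CONTACT_M`
#' area, so intra scores are densities over the marker's tumor territory.
#' Records whose denominator is zero are omitted. Scores are reported in
#' cells/mm^2.
#'
#' @param mask A [label_mask()].
#' @param zonemap Zone map from [assign_zones()] on the same mask.
#' @param geometry Table from [cell_geometry()].
#' @param case_id Identifier copied into the records.
#' @return Tibble `case_id`, `class`, `marker`, `compartment`, `pixels`,
#'   `area_um2`, `cells`, `zone_area_um2`, `score_per_mm2`.
#' @export
compute_zone_scores <- function(mask, zonemap, geometry = cell_geometry(),
                                case_id = "case") {
  if (!all(dim(mask) == dim(zonemap))) abort("mask and zone map shapes differ")
  res <- mask_resolution(mask)
  zl <- zone_labels()
  tab <- mask_class_table(mask)
  zvec <- as.vector(zonemap)
  mvec <- as.vector(unclass(mask))

  zone_px <- function(code) sum(zvec == code)
  immune_px_in <- function(role, zcode) {
    sum(mvec == role_code(tab, role) & zvec == zcode)
  }

  denom <- list(
    "K17+" = list(
      peri  = zone_px(zl[["PERI_POS"]]),
      intra = zone_px(zl[["TUMOR_POS"]]) + zone_px(zl[["CONTACT_POS"]])),
    "K17-" = list(
      peri  = zone_px(zl[["PERI_NEG"]]),
      intra = zone_px(zl[["TUMOR_NEG"]]) + zone_px(zl[["CONTACT_NEG"]]))
  )
  numer_zone <- list(
    "K17+" = list(peri = zl[["PERI_POS"]], intra = zl[["CONTACT_POS"]]),
    "K17-" = list(peri = zl[["PERI_NEG"]], intra = zl[["CONTACT_NEG"]])
  )

  grid <- tidyr::expand_grid(class = immune_roles(),
                             marker = c("K17+", "K17-"),
                             compartment = c("intra", "peri"))
  out <- purrr::pmap_dfr(grid, function(class, marker, compartment) {
    d_px <- denom[[marker]][[compartment]]
    if (d_px == 0) return(NULL)
    n_px <- immune_px_in(class, numer_zone[[marker]][[compartment]])
    cells <- estimate_cell_count(n_px, class, geometry, res)
    zone_area <- d_px * res^2
    tibble(case_id = case_id, class = class, marker = marker,
           compartment = compartment, pixels = n_px,
           area_um2 = n_px * res^2, cells = cells,
           zone_area_um2 = zone_area,
           score_per_mm2 = cells / zone_area * 1e6)
  })
  out
}

#' K17-negative / K17-positive score ratios
#'
#' Normalizes the K17-negative Tumor/Stromal Zone Score by the K17-positive
#' score per case, class and compartment (the presentation used for ranked
#' ratio plots). A zero K17-positive score makes the ratio undefined; such
#' records are flagged and excluded from plots but the underlying raw scores
#' remain in cohort statistics.
#'
#' @param records Tibble from [compute_zone_scores()] (one or many cases).
#' @return Tibble `case_id`, `class`, `compartment`, `zs_pos`, `zs_neg`,
#'   `ratio`, `status` (`valid` / `undefined_zero_denominator`).
#' @export
normalized_ratios <- function(records) {
  wide <- records %>%
    select("case_id", "class", "compartment", "marker", "score_per_mm2") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "score_per_mm2")
  if (!all(c("K17+", "K17-") %in% names(wide))) {
    wide[setdiff(c("K17+", "K17-"), names(wide))] <- NA_real_
  }
  incomplete <- is.na(wide[["K17+"]]) | is.na(wide[["K17-"]])
  if (any(incomplete)) {
    warn(sprintf("%d case/class/compartment record(s) lack a marker pair; skipped",
                 sum(incomplete)))
  }
  wide %>%
    filter(!is.na(.data[["K17+"]]) & !is.na(.data[["K17-"]])) %>%
    mutate(zs_pos = .data[["K17+"]], zs_neg = .data[["K17-"]],
           status = ifelse(.data$zs_pos == 0, "undefined_zero_denominator", "valid"),
           ratio = ifelse(.data$zs_pos == 0, NA_real_, .data$zs_neg / .data$zs_pos)) %>%
    select("case_id", "class", "compartment", "zs_pos", "zs_neg", "ratio", "status")
}

#' Digital K17 score of a mask
#'
#' Percentage of tumor pixels that are K17-positive; tumors at or above the
#' 10% threshold are classified K17-high.
#'
#' @param mask A [label_mask()] with at least one tumor pixel.
#' @param threshold_percent High/low cut, default 10.
#' @return One-row tibble `k17_percent`, `k17_status` (`high`/`low`).
#' @export
digital_k17_score <- function(mask, threshold_percent = 10) {
  pos <- sum(role_grid(mask, "TUMOR_K17POS"))
  neg <- sum(role_grid(mask, "TUMOR_K17NEG"))
  if (pos + neg == 0) abort("no tumor pixels in mask")
  pct <- 100 * pos / (pos + neg)
  tibble(k17_percent = pct,
         k17_status = ifelse(pct >= threshold_percent, "high", "low"))
}
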