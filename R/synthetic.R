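#' Configuration for the synthetic mask generator
#'
#' Describes a synthetic mIHC case: tumor-nest geometry, the K17-positive
#' fraction of nest area, and zone-dependent immune intensities. Immune
#' cells are placed by an inhomogeneous Poisson process whose intensity at a
#' stromal point is `base_intensity[role] * zone_modulation[role]` when the
#' nearest tumor boundary is K17-positive and `base_intensity[role]`
#' otherwise, so `zone_modulation < 1` models immune exclusion from
#' K17-positive influence territory. Defaults emulate a 1000 x 1000 px
#' region scanned at 0.346 um/px with moderately infiltrated stroma.
#'
#' @param image_hw_px `c(height, width)` in pixels.
#' @param resolution_um_per_px Micrometres per pixel.
#' @param n_nests Number of tumor nests.
#' @param nest_radius_um `c(mean, sd)` of nest radius in micrometres.
#' @param k17pos_fraction Fraction of each nest's area that is K17+ (0-1).
#' @param base_intensity Named vector, cells/mm^2 in K17-negative influence
#'   territory per immune role.
#' @param zone_modulation Named vector, multiplicative factor on the
#'   intensity in K17-positive influence territory.
#' @param intra_fraction Fraction of cells placed in contact with tumor.
#' @param depth_um Peritumoral band depth used for ground-truth bookkeeping.
#' @param contact_um Contact distance; default [default_contact_um()].
#' @param seed Default master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(image_hw_px = c(1000, 1000),
                             resolution_um_per_px = 0.346,
                             n_nests = 8,
                             nest_radius_um = c(30, 8),
                             k17pos_fraction = 0.5,
                             base_intensity = c(CD4 = 200, CD8 = 500, CD16 = 150, CD163 = 300),
                             zone_modulation = c(CD4 = 1, CD8 = 1, CD16 = 1, CD163 = 1),
                             intra_fraction = 0.3,
                             depth_um = 25,
                             contact_um = NULL,
                             seed = 1L) {
  cfg <- list(image_hw_px = as.integer(image_hw_px),
              resolution_um_per_px = resolution_um_per_px,
              n_nests = as.integer(n_nests),
              nest_radius_um = nest_radius_um,
              k17pos_fraction = k17pos_fraction,
              base_intensity = base_intensity[immune_roles()],
              zone_modulation = zone_modulation[immune_roles()],
              intra_fraction = intra_fraction,
              depth_um = depth_um,
              contact_um = contact_um %||% default_contact_um(resolution_um_per_px),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$base_intensity < 0) || anyNA(cfg$base_intensity)) {
    abort("base intensities must be named for all immune roles and >= 0")
  }
  if (any(cfg$zone_modulation < 0) || anyNA(cfg$zone_modulation)) {
    abort("zone modulations must be named for all immune roles and >= 0")
  }
  for (f in c("k17pos_fraction", "intra_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]"))
  }
  if (cfg$n_nests < 1) abort("`n_nests` must be >= 1")
  if (cfg$contact_um >= cfg$depth_um) abort("`contact_um` must be smaller than `depth_um`")
  structure(cfg, class = "synthetic_config")
}

#' Read / write a synthetic configuration as YAML
#' @param path YAML file path.
#' @return [read_synthetic_config()] returns a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$base_intensity <- unlist(raw$base_intensity)
  raw$zone_modulation <- unlist(raw$zone_modulation)
  do.call(synthetic_config, raw)
}

#' @rdname read_synthetic_config
#' @param config A `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  out <- unclass(config)
  out$base_intensity <- as.list(out$base_intensity)
  out$zone_modulation <- as.list(out$zone_modulation)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Expected immune densities implied by a configuration
#'
#' The analytic oracle for recovery tests: the Poisson intensity in each
#' marker's influence territory.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `class`, `marker`, `lambda_per_mm2`.
#' @export
expected_densities <- function(config) {
  tidyr::expand_grid(class = immune_roles(), marker = c("K17+", "K17-")) %>%
    mutate(lambda_per_mm2 = config$base_intensity[.data$class] *
             ifelse(.data$marker == "K17+", config$zone_modulation[.data$class], 1)) %>%
    mutate(lambda_per_mm2 = unname(.data$lambda_per_mm2))
}

rasterize_ellipse <- function(H, W, cy, cx, a, b, theta) {
  # evaluate only inside the bounding box of the ellipse
  r <- max(a, b)
  r1 <- max(1L, floor(cy - r)); r2 <- min(H, ceiling(cy + r))
  c1 <- max(1L, floor(cx - r)); c2 <- min(W, ceiling(cx + r))
  out <- matrix(FALSE, H, W)
  if (r1 > r2 || c1 > c2) return(out)
  rows <- rep(r1:r2, times = c2 - c1 + 1L)
  cols <- rep(c1:c2, each = r2 - r1 + 1L)
  u <- (cols - cx) * cos(theta) + (rows - cy) * sin(theta)
  v <- -(cols - cx) * sin(theta) + (rows - cy) * cos(theta)
  inside <- u^2 / a^2 + v^2 / b^2 <= 1
  out[(cols[inside] - 1L) * H + rows[inside]] <- TRUE
  out
}

#' Simulate one synthetic case
#'
#' Tumor nests are unions of overlapping random ellipses; each connected
#' nest is split into contiguous K17+/K17- subregions by a random chord so
#' the realized K17+ share tracks `k17pos_fraction` (within a few
#' percentage points of jitter). Immune cells are placed as filled disks of
#' role-specific diameter by an inhomogeneous Poisson process on the stroma
#' (intensity keyed to the marker of the nearest tumor boundary); a
#' configurable fraction is placed in the contact shell. Disks never
#' overwrite tumor pixels, and overlaps between cells are resolved by
#' rejection sampling (minimum centre distance = sum of radii); placement
#' failure after a bounded number of attempts raises an error advising
#' lower intensities.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param case_id Identifier for the truth table.
#' @param geometry Cell geometry, see [cell_geometry()].
#' @param max_attempts Rejection-sampling bound per cell.
#' @return List with `mask` (a [label_mask()]), `truth` (tibble `case_id`,
#'   `class`, `marker`, `compartment` in intra/peri/outside, `true_count`,
#'   `zone_area_um2`), and `cells` (per-cell placements).
#' @export
simulate_case <- function(config, seed = config$seed, case_id = "case_1",
                          geometry = cell_geometry(), max_attempts = 200L) {
  set.seed(seed)
  H <- config$image_hw_px[1]; W <- config$image_hw_px[2]
  res <- config$resolution_um_per_px
  tab <- class_table()

  # --- tumor nests ---
  tumor <- matrix(FALSE, H, W)
  r_mean_px <- config$nest_radius_um[1] / res
  r_sd_px <- config$nest_radius_um[2] / res
  margin <- max(2, r_mean_px)
  for (k in seq_len(config$n_nests)) {
    cy <- runif(1, margin, H - margin); cx <- runif(1, margin, W - margin)
    for (e in 1:2) {
      a <- max(3, rnorm(1, r_mean_px, r_sd_px))
      b <- max(3, rnorm(1, r_mean_px * 0.8, r_sd_px))
      th <- runif(1, 0, pi)
      oy <- rnorm(1, 0, r_mean_px * 0.3); ox <- rnorm(1, 0, r_mean_px * 0.3)
      tumor <- tumor | rasterize_ellipse(H, W, cy + oy, cx + ox, a, b, th)
    }
  }
  if (!any(tumor)) abort("no tumor generated; enlarge nests or image")

  # --- split each connected nest into K17+/K17- by a random chord ---
  comp <- EBImage::bwlabel(EBImage::Image(tumor * 1, dim = c(H, W)))
  comp <- matrix(EBImage::imageData(comp), H, W)
  grid <- matrix(role_code(tab, "STROMA"), H, W)
  for (cid in seq_len(max(comp))) {
    idx <- which(comp == cid)
    ri <- ((idx - 1L) %% H) + 1L
    ci <- ((idx - 1L) %/% H) + 1L
    phi <- runif(1, 0, pi)
    proj <- cos(phi) * ci + sin(phi) * ri
    target <- min(1, max(0, config$k17pos_fraction + runif(1, -0.04, 0.04)))
    n_pos <- round(target * length(idx))
    ord <- order(proj, decreasing = TRUE)
    grid[idx[ord[seq_len(n_pos)]]] <- role_code(tab, "TUMOR_K17POS")
    if (n_pos < length(idx)) {
      grid[idx[ord[(n_pos + 1):length(idx)]]] <- role_code(tab, "TUMOR_K17NEG")
    }
  }

  # --- generator-truth zone geometry ---
  d_pos <- dist_to_set(grid == role_code(tab, "TUMOR_K17POS")) * res
  d_neg <- dist_to_set(grid == role_code(tab, "TUMOR_K17NEG")) * res
  dmin <- pmin(d_pos, d_neg)
  pos_side <- d_pos <= d_neg + 1e-9
  stroma <- grid == role_code(tab, "STROMA")
  a_px_mm2 <- (res / 1000)^2

  stroma_idx <- which(stroma)
  side_at <- pos_side[stroma_idx]
  dmin_at <- dmin[stroma_idx]
  contact_pool <- stroma_idx[dmin_at <= config$contact_um]

  # --- immune cell placement ---
  acc_r <- numeric(0); acc_c <- numeric(0); acc_rad_px <- numeric(0)
  acc_role <- character(0)
  for (role in immune_roles()) {
    lam <- config$base_intensity[[role]] *
      ifelse(side_at, config$zone_modulation[[role]], 1)
    w <- lam * a_px_mm2
    total <- sum(w)
    if (total == 0) next
    n_cells <- rpois(1, total)
    if (n_cells == 0) next
    rad_px <- geometry$diameter_um[match(role, geometry$role)] / 2 / res
    w_contact <- w[match(contact_pool, stroma_idx)]
    use_contact_pool <- length(contact_pool) > 0 && sum(w_contact) > 0
    # batched candidate queues (alias sampling is O(pool + draws))
    draw_queue <- function(pool, wts, k) pool[sample.int(length(pool), k, replace = TRUE, prob = wts)]
    q_stroma <- draw_queue(stroma_idx, w, 2L * n_cells + 16L)
    q_contact <- if (use_contact_pool) draw_queue(contact_pool, w_contact, n_cells + 16L) else integer(0)
    for (cell in seq_len(n_cells)) {
      is_intra <- use_contact_pool && runif(1) < config$intra_fraction
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        # a saturated contact shell spills the cell into the open stroma
        if (is_intra && att > max_attempts / 2) is_intra <- FALSE
        if (is_intra) {
          if (length(q_contact) == 0) q_contact <- draw_queue(contact_pool, w_contact, n_cells + 16L)
          idx <- q_contact[1]; q_contact <- q_contact[-1]
        } else {
          if (length(q_stroma) == 0) q_stroma <- draw_queue(stroma_idx, w, 2L * n_cells + 16L)
          idx <- q_stroma[1]; q_stroma <- q_stroma[-1]
        }
        rr <- ((idx - 1L) %% H) + 1L
        cc <- ((idx - 1L) %/% H) + 1L
        if (length(acc_r) > 0) {
          d2 <- (acc_r - rr)^2 + (acc_c - cc)^2
          if (any(d2 < (acc_rad_px + rad_px)^2)) next
        }
        acc_r <- c(acc_r, rr); acc_c <- c(acc_c, cc)
        acc_rad_px <- c(acc_rad_px, rad_px); acc_role <- c(acc_role, role)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("rejection sampling failed; lower the immune intensities or enlarge the image")
      }
    }
  }
  cells <- if (length(acc_r)) {
    lin <- (acc_c - 1L) * H + acc_r
    tibble(class = acc_role, row = as.integer(acc_r), col = as.integer(acc_c),
           marker = ifelse(pos_side[lin], "K17+", "K17-"),
           compartment = dplyr::case_when(
             dmin[lin] <= config$contact_um ~ "intra",
             dmin[lin] <= config$depth_um ~ "peri",
             TRUE ~ "outside"))
  } else {
    tibble(class = character(), row = integer(), col = integer(),
           marker = character(), compartment = character())
  }

  # --- rasterize disks (clipped to stroma) ---
  if (nrow(cells) > 0) {
    for (role in unique(cells$class)) {
      sel <- cells[cells$class == role, ]
      r_px <- geometry$diameter_um[match(role, geometry$role)] / 2 / res
      rr <- floor(r_px)
      off <- expand.grid(di = -rr:rr, dj = -rr:rr)
      off <- off[off$di^2 + off$dj^2 <= r_px^2, , drop = FALSE]
      pi_ <- rep(sel$row, each = nrow(off)) + rep(off$di, times = nrow(sel))
      pj_ <- rep(sel$col, each = nrow(off)) + rep(off$dj, times = nrow(sel))
      ok <- pi_ >= 1 & pi_ <= H & pj_ >= 1 & pj_ <= W
      lin <- (pj_[ok] - 1L) * H + pi_[ok]
      lin <- lin[stroma[lin]]
      grid[lin] <- role_code(tab, role)
    }
  }

  # --- truth table ---
  area_tbl <- tibble(
    marker = rep(c("K17+", "K17-"), each = 3),
    compartment = rep(c("intra", "peri", "outside"), 2),
    zone_area_um2 = c(
      (sum(grid == role_code(tab, "TUMOR_K17POS")) +
         sum(stroma & dmin <= config$contact_um & pos_side)) * res^2,
      sum(stroma & dmin > config$contact_um & dmin <= config$depth_um & pos_side) * res^2,
      sum(stroma & dmin > config$depth_um & pos_side) * res^2,
      (sum(grid == role_code(tab, "TUMOR_K17NEG")) +
         sum(stroma & dmin <= config$contact_um & !pos_side)) * res^2,
      sum(stroma & dmin > config$contact_um & dmin <= config$depth_um & !pos_side) * res^2,
      sum(stroma & dmin > config$depth_um & !pos_side) * res^2))
  truth <- tidyr::expand_grid(class = immune_roles(),
                              marker = c("K17+", "K17-"),
                              compartment = c("intra", "peri", "outside")) %>%
    left_join(cells %>% count(.data$class, .data$marker, .data$compartment,
                              name = "true_count"),
              by = c("class", "marker", "compartment")) %>%
    mutate(true_count = ifelse(is.na(.data$true_count), 0L, .data$true_count)) %>%
    left_join(area_tbl, by = c("marker", "compartment")) %>%
    mutate(case_id = case_id) %>%
    select("case_id", "class", "marker", "compartment", "true_count", "zone_area_um2")

  list(mask = label_mask(grid, res, tab), truth = truth,
       cells = cells %>% mutate(case_id = case_id))
}

#' Simulate a synthetic cohort
#'
#' Per-case seeds are derived deterministically from the master seed. An
#' optional `effect` injects a K17-linked modulation into a fixed share of
#' cases (e.g. CD8 exclusion from K17-positive territory in 93% of tumors);
#' the generator records which cases carry it.
#'
#' @param config Baseline [synthetic_config()] (its `zone_modulation` is the
#'   no-effect value applied to cases without the effect).
#' @param n_cases Number of cases, >= 1.
#' @param seed Master seed.
#' @param effect Optional list `list(role =, modulation =, prevalence =)`.
#' @param geometry Cell geometry.
#' @return List of class `synthetic_cohort`: `cases` (list of
#'   [simulate_case()] results), `truth` (bound truth tables), `case_info`
#'   (tibble `case_id`, `seed`, `has_effect`), `config`, `effect`.
#' @export
simulate_cohort <- function(config, n_cases, seed = config$seed, effect = NULL,
                            geometry = cell_geometry()) {
  if (n_cases < 1) abort("`n_cases` must be >= 1")
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  has_effect <- rep(FALSE, n_cases)
  if (!is.null(effect)) {
    n_eff <- round(effect$prevalence * n_cases)
    has_effect[sample.int(n_cases, n_eff)] <- TRUE
  }
  case_ids <- sprintf("case_%03d", seq_len(n_cases))
  cases <- purrr::map(seq_len(n_cases), function(i) {
    cfg_i <- config
    if (has_effect[i]) {
      for (role in effect$role) cfg_i$zone_modulation[[role]] <- effect$modulation
    }
    simulate_case(cfg_i, seed = case_seeds[i], case_id = case_ids[i],
                  geometry = geometry)
  })
  structure(list(
    cases = cases,
    truth = purrr::map_dfr(cases, "truth"),
    case_info = tibble(case_id = case_ids, seed = case_seeds, has_effect = has_effect),
    config = config, effect = effect
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases, %d x %d px @ %g um/px\n",
              length(x$cases), x$config$image_hw_px[1], x$config$image_hw_px[2],
              x$config$resolution_um_per_px))
  if (!is.null(x$effect)) {
    cat(sprintf("effect: %s modulation %g in %d/%d cases\n",
                paste(x$effect$role, collapse = "+"), x$effect$modulation,
                sum(x$case_info$has_effect), length(x$cases)))
  }
  invisible(x)
}
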