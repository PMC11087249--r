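#' Pipeline configuration
#'
#' Bundles every parameter of an end-to-end cohort run. Exactly one input
#' source is used: a synthetic generator configuration, or a list of mask
#' paths for real data.
#'
#' @param synthetic A [synthetic_config()] (or `NULL` when `mask_paths` is
#'   given).
#' @param mask_paths Character vector of label-mask files (or `NULL`).
#' @param n_cases Number of synthetic cases.
#' @param depth_um Peritumoral band depth (default 25).
#' @param contact_um Contact distance; default derived from resolution.
#' @param effect Optional synthetic effect, see [simulate_cohort()].
#' @param null_reps Replicates for the randomization null (0 disables it).
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param write_zonemaps Write per-case QC zone-map PNGs under
#'   `out_dir/zonemaps/`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), mask_paths = NULL,
                            n_cases = 10, depth_um = 25, contact_um = NULL,
                            effect = NULL, null_reps = 0, seed = 1L,
                            out_dir = NULL, write_zonemaps = FALSE) {
  if (is.null(synthetic) == is.null(mask_paths)) {
    abort("exactly one of `synthetic` or `mask_paths` must be set")
  }
  res <- if (!is.null(synthetic)) synthetic$resolution_um_per_px else NULL
  if (is.null(contact_um) && !is.null(res)) contact_um <- default_contact_um(res)
  if (!is.null(contact_um) && (contact_um <= 0 || contact_um >= depth_um)) {
    abort("need depth_um > contact_um > 0")
  }
  structure(list(synthetic = synthetic, mask_paths = mask_paths,
                 n_cases = n_cases, depth_um = depth_um, contact_um = contact_um,
                 effect = effect, null_reps = null_reps, seed = as.integer(seed),
                 out_dir = out_dir, write_zonemaps = write_zonemaps),
            class = "pipeline_config")
}

#' Run the full cohort pipeline
#'
#' Simulates (or loads) a cohort of label masks, partitions each into K17
#' influence zones, computes Tumor/Stromal Zone Scores and ratio records,
#' runs the cohort statistics, and optionally the per-case randomization
#' null. Deterministic given the config seed. When `out_dir` is set, writes
#' `scores.csv`, `ratios.csv`, `cohort.csv`, optional `null.csv`, per-case
#' QC zone maps, and a `manifest.json` recording parameters and seeds.
#'
#' @param config A [pipeline_config()].
#' @return List of class `immunotopo_run`: `scores`, `ratios`, `cohort` (an
#'   `immunotopo_cohort`), `null` (tibble or `NULL`), `case_info`, `truth`
#'   (synthetic only), `config`.
#' @export
run_cohort <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  if (!is.null(config$synthetic)) {
    cohort <- simulate_cohort(config$synthetic, config$n_cases,
                              seed = config$seed, effect = config$effect)
    masks <- lapply(cohort$cases, `[[`, "mask")
    case_info <- cohort$case_info
    truth <- cohort$truth
  } else {
    masks <- lapply(config$mask_paths, read_label_mask)
    case_info <- tibble(case_id = basename(config$mask_paths),
                        seed = NA_integer_, has_effect = NA)
    truth <- NULL
  }
  case_ids <- case_info$case_id

  zonemaps <- lapply(masks, assign_zones,
                     depth_um = config$depth_um, contact_um = config$contact_um)
  scores <- purrr::map2_dfr(seq_along(masks), case_ids, function(i, cid) {
    compute_zone_scores(masks[[i]], zonemaps[[i]], case_id = cid)
  })
  ratios <- normalized_ratios(scores)
  cohort_res <- cohort_summary(scores)

  null_res <- NULL
  if (config$null_reps > 0) {
    null_res <- purrr::map_dfr(seq_along(masks), function(i) {
      randomization_null(masks[[i]], zonemaps[[i]],
                         scores %>% filter(.data$case_id == case_ids[i]),
                         n_reps = config$null_reps,
                         seed = if (is.na(case_info$seed[i])) config$seed + i else case_info$seed[i]) %>%
        mutate(case_id = case_ids[i], .before = 1)
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scores, file.path(config$out_dir, "scores.csv"))
    readr::write_csv(ratios, file.path(config$out_dir, "ratios.csv"))
    readr::write_csv(cohort_res$summary, file.path(config$out_dir, "cohort.csv"))
    if (!is.null(null_res)) readr::write_csv(null_res, file.path(config$out_dir, "null.csv"))
    if (!is.null(truth)) readr::write_csv(truth, file.path(config$out_dir, "truth.csv"))
    if (isTRUE(config$write_zonemaps)) {
      zd <- file.path(config$out_dir, "zonemaps")
      dir.create(zd, showWarnings = FALSE)
      for (i in seq_along(zonemaps)) write_zone_map(zonemaps[[i]], file.path(zd, paste0(case_ids[i], ".png")))
    }
    manifest <- list(package = "immunotopo",
                     version = as.character(utils::packageVersion("immunotopo")),
                     seed = config$seed, depth_um = config$depth_um,
                     contact_um = config$contact_um, n_cases = length(masks),
                     null_reps = config$null_reps,
                     case_seeds = case_info$seed,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(scores = scores, ratios = ratios, cohort = cohort_res,
                 null = null_res, case_info = case_info, truth = truth,
                 config = config),
            class = "immunotopo_run")
}

#' @export
print.immunotopo_run <- function(x, ...) {
  cat(sprintf("<immunotopo_run> %d cases\n", nrow(x$case_info)))
  print(x$cohort)
  invisible(x)
}

#' Write a zone map as an indexed PNG with a JSON legend
#'
#' @param zonemap Zone map from [assign_zones()].
#' @param path PNG output path; the legend goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(zonemap, path) {
  png::writePNG(unclass(zonemap) / 255, target = path)
  zl <- zone_labels()
  jsonlite::write_json(
    list(labels = setNames(as.list(names(zl)), as.character(zl)),
         depth_um = attr(zonemap, "depth_um"),
         contact_um = attr(zonemap, "contact_um"),
         resolution_um_per_px = attr(zonemap, "resolution_um_per_px")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
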