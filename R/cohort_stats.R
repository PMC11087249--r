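#' Paired t test on matched zone scores
#'
#' Classical paired t test of per-case differences `neg - pos`, two-sided.
#' Degenerate inputs are flagged rather than erroring: all differences
#' exactly zero gives `t = 0, p = 1`; a nonzero constant difference (zero
#' variance) gives `p = 0` with infinite `t`.
#'
#' @param scores_pos,scores_neg Equal-length numeric vectors, n >= 2, paired
#'   by case.
#' @return One-row tibble `n`, `mean_diff`, `t_statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @examples
#' paired_zs_test(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_zs_test <- function(scores_pos, scores_neg) {
  if (length(scores_pos) != length(scores_neg)) abort("paired vectors differ in length")
  n <- length(scores_pos)
  if (n < 2) abort("paired t test needs n >= 2")
  d <- scores_neg - scores_pos
  if (all(d == 0)) {
    return(tibble(n = n, mean_diff = 0, t_statistic = 0, df = n - 1,
                  p_value = 1, degenerate = TRUE))
  }
  if (sd(d) == 0) {
    return(tibble(n = n, mean_diff = mean(d),
                  t_statistic = sign(mean(d)) * Inf, df = n - 1,
                  p_value = 0, degenerate = TRUE))
  }
  ht <- t.test(scores_neg, scores_pos, paired = TRUE, alternative = "two.sided")
  tibble(n = n, mean_diff = unname(ht$estimate),
         t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, degenerate = FALSE)
}

#' Fraction of cases with higher K17-negative score
#'
#' Share of cases whose K17-negative zone score strictly exceeds the
#' K17-positive score (the cohort headline statistic, e.g. "higher in
#' K17-negative zones in 93% of tumors"). Cases with an undefined ratio are
#' excluded from numerator and denominator; exact ties count as not-higher.
#'
#' @param ratio_records Tibble from [normalized_ratios()], one class and
#'   compartment at a time (or grouped upstream).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_cases_higher <- function(ratio_records) {
  valid <- ratio_records %>% filter(.data$status == "valid")
  if (nrow(valid) == 0) abort("no valid ratio records")
  mean(valid$zs_neg > valid$zs_pos)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rank correlation with average ranks for ties; the two-sided p value uses
#' the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom (p = 0 at |rho| = 1).
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return One-row tibble `rho`, `p_value`, `n`, `degenerate` (`TRUE` when a
#'   vector is constant and rho is undefined).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("vectors differ in length")
  n <- length(x)
  if (n < 3) abort("spearman correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Cohort summary per immune class and compartment
#'
#' Combines the paired t test on raw scores and the fraction-of-cases
#' statistic for every immune class x compartment present in the score
#' records.
#'
#' @param records Multi-case tibble from [compute_zone_scores()].
#' @return Object of class `immunotopo_cohort`: a list with `summary` (one
#'   row per class/compartment: `class`, `compartment`, `n_cases`,
#'   `fraction_higher_in_neg`, `mean_diff`, `t_statistic`, `p_value`,
#'   `degenerate`), `ratios`, and `n_cases`.
#' @export
cohort_summary <- function(records) {
  ratios <- normalized_ratios(records)
  summ <- ratios %>%
    group_by(.data$class, .data$compartment) %>%
    dplyr::group_modify(function(df, key) {
      tt <- if (nrow(df) >= 2) {
        paired_zs_test(df$zs_pos, df$zs_neg)
      } else {
        tibble(mean_diff = df$zs_neg - df$zs_pos, t_statistic = NA_real_,
               p_value = NA_real_, degenerate = TRUE)
      }
      frac <- if (any(df$status == "valid")) fraction_cases_higher(df) else NA_real_
      tibble(n_cases = nrow(df),
             fraction_higher_in_neg = frac,
             mean_diff = tt$mean_diff, t_statistic = tt$t_statistic,
             p_value = tt$p_value, degenerate = tt$degenerate)
    }) %>%
    ungroup()
  structure(list(summary = summ, ratios = ratios,
                 n_cases = dplyr::n_distinct(ratios$case_id)),
            class = "immunotopo_cohort")
}

#' @export
print.immunotopo_cohort <- function(x, ...) {
  cat(sprintf("<immunotopo_cohort> %d cases\n", x$n_cases))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Randomization null for zone-score asymmetry
#'
#' Tests whether the observed K17-negative vs K17-positive score difference
#' could arise from immune cells placed at random in the tumor
#' microenvironment. Per replicate, each immune class's estimated cell
#' equivalents are re-placed (as disks of the class geometry) uniformly over
#' the pooled admissible territory of their compartment - contact pixels of
#' both markers for intratumoral cells, peritumoral band pixels of both
#' markers for peritumoral cells - keeping per-case totals fixed; zone
#' scores are recomputed from the re-placed pixels. The empirical p value
#' uses the add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n_reps)`
#' on the statistic `|ZS_neg - ZS_pos|`, so p is never exactly zero.
#'
#' @param mask A [label_mask()].
#' @param zonemap Zone map from [assign_zones()] on the same mask.
#' @param observed_records Tibble from [compute_zone_scores()] for the case.
#' @param n_reps Number of null replicates, >= 19.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param geometry Table from [cell_geometry()].
#' @return Tibble `class`, `compartment`, `observed_diff`, `p_value`,
#'   `n_reps`, `n_cells_placed`.
#' @export
randomization_null <- function(mask, zonemap, observed_records, n_reps = 199,
                               seed = 1L, geometry = cell_geometry()) {
  if (n_reps < 19) abort("`n_reps` must be >= 19")
  res <- mask_resolution(mask)
  zl <- zone_labels()
  zvec <- as.vector(zonemap)
  H <- nrow(mask); W <- ncol(mask)

  territory <- list(
    intra = which(zvec %in% c(zl[["CONTACT_POS"]], zl[["CONTACT_NEG"]])),
    peri  = which(zvec %in% c(zl[["PERI_POS"]], zl[["PERI_NEG"]]))
  )
  stromal <- zvec %in% c(zl[["CONTACT_POS"]], zl[["CONTACT_NEG"]],
                         zl[["PERI_POS"]], zl[["PERI_NEG"]], zl[["OUTSIDE_BAND"]])
  denom_px <- c(
    pos_intra = sum(zvec == zl[["TUMOR_POS"]]) + sum(zvec == zl[["CONTACT_POS"]]),
    neg_intra = sum(zvec == zl[["TUMOR_NEG"]]) + sum(zvec == zl[["CONTACT_NEG"]]),
    pos_peri = sum(zvec == zl[["PERI_POS"]]),
    neg_peri = sum(zvec == zl[["PERI_NEG"]])
  )

  obs <- observed_records %>%
    select("class", "marker", "compartment", "score_per_mm2", "cells") %>%
    tidyr::pivot_wider(names_from = "marker",
                       values_from = c("score_per_mm2", "cells"),
                       values_fill = 0)
  for (col in c("score_per_mm2_K17+", "score_per_mm2_K17-",
                "cells_K17+", "cells_K17-")) {
    if (!col %in% names(obs)) obs[[col]] <- 0
  }
  obs <- obs %>%
    mutate(observed_diff = abs(.data[["score_per_mm2_K17-"]] - .data[["score_per_mm2_K17+"]]),
           n_place = as.integer(round(.data[["cells_K17+"]] + .data[["cells_K17-"]])))

  disk_offsets <- function(role) {
    r_px <- geometry$diameter_um[match(role, geometry$role)] / 2 / res
    rr <- floor(r_px)
    g <- expand.grid(di = -rr:rr, dj = -rr:rr)
    g <- g[g$di^2 + g$dj^2 <= r_px^2, , drop = FALSE]
    as.matrix(g)
  }
  offsets <- lapply(setNames(immune_roles(), immune_roles()), disk_offsets)

  total_area <- sum(vapply(seq_len(nrow(obs)), function(i) {
    obs$n_place[i] * nrow(offsets[[obs$class[i]]])
  }, numeric(1)))
  if (total_area > length(territory$intra) + length(territory$peri)) {
    abort("admissible territory smaller than total cell area; null placement impossible")
  }

  set.seed(seed)
  exceed <- matrix(0L, nrow(obs), 1)
  for (rep_i in seq_len(n_reps)) {
    placed_px <- vector("list", nrow(obs))
    for (i in seq_len(nrow(obs))) {
      n_c <- obs$n_place[i]
      if (n_c == 0) { placed_px[[i]] <- integer(0); next }
      terr <- territory[[obs$compartment[i]]]
      if (length(terr) == 0) { placed_px[[i]] <- integer(0); next }
      centers <- terr[sample.int(length(terr), n_c, replace = TRUE)]
      off <- offsets[[obs$class[i]]]
      ci <- ((centers - 1L) %% H) + 1L
      cj <- ((centers - 1L) %/% H) + 1L
      pi_ <- rep(ci, each = nrow(off)) + rep(off[, 1], times = n_c)
      pj_ <- rep(cj, each = nrow(off)) + rep(off[, 2], times = n_c)
      ok <- pi_ >= 1 & pi_ <= H & pj_ >= 1 & pj_ <= W
      lin <- (pj_[ok] - 1L) * H + pi_[ok]
      lin <- unique(lin[stromal[lin]])     # clip to stroma, merge overlaps
      placed_px[[i]] <- lin
    }
    for (i in seq_len(nrow(obs))) {
      comp <- obs$compartment[i]
      px <- placed_px[[i]]
      zpx <- zvec[px]
      if (comp == "intra") {
        n_pos <- sum(zpx == zl[["CONTACT_POS"]]); n_neg <- sum(zpx == zl[["CONTACT_NEG"]])
        d_pos <- denom_px[["pos_intra"]]; d_neg <- denom_px[["neg_intra"]]
      } else {
        n_pos <- sum(zpx == zl[["PERI_POS"]]); n_neg <- sum(zpx == zl[["PERI_NEG"]])
        d_pos <- denom_px[["pos_peri"]]; d_neg <- denom_px[["neg_peri"]]
      }
      score <- function(n_px, d_px) {
        if (d_px == 0) return(NA_real_)
        estimate_cell_count(n_px, obs$class[i], geometry, res) / (d_px * res^2) * 1e6
      }
      s_pos <- score(n_pos, d_pos); s_neg <- score(n_neg, d_neg)
      if (is.na(s_pos) || is.na(s_neg)) next
      if (abs(s_neg - s_pos) >= obs$observed_diff[i]) exceed[i] <- exceed[i] + 1L
    }
  }
  tibble(class = obs$class, compartment = obs$compartment,
         observed_diff = obs$observed_diff,
         p_value = (1 + as.vector(exceed)) / (1 + n_reps),
         n_reps = n_reps, n_cells_placed = obs$n_place)
}
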