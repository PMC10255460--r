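#' Aggregate synchronization scores
#'
#' Mean, sample standard deviation and count of held-out R-squared per
#' group. Default grouping is per (eye feature, channel, band, quadrant,
#' condition), i.e. each subject-video session contributes one R-squared
#' to its condition's group. Groups of size 1 get `sd = NA` and are
#' flagged.
#'
#' @param results Session-level result tibble: the output of
#'   [run_sync_matrix()] joined with session labels (columns `empathic`,
#'   `quadrant`, ...), as produced by [run_pipeline()] or
#'   [cohort_sync()].
#' @param by Grouping columns.
#' @return Tibble with `mean_r2, std_r2, n, std_defined` per group.
#' @export
aggregate_sync <- function(results,
                           by = c("eye_feature", "channel", "band",
                                  "quadrant", "empathic")) {
  if (nrow(results) == 0) stop("no results to aggregate", call. = FALSE)
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      std_r2 = stats::sd(.data$r2[!is.na(.data$r2)]),
      n = sum(!is.na(.data$r2)),
      .groups = "drop") |>
    dplyr::mutate(std_defined = .data$n >= 2)
}

#' Welch t-test between empathic and non-empathic scores
#'
#' Two-tailed independent-samples t-test with unequal variances on
#' per-session R-squared values. Degenerate inputs (zero variance in
#' both groups) fall back to `t = 0, p = 1` when the means are equal
#' and `t = +/-Inf, p = 0` otherwise.
#'
#' @param emp,non Numeric vectors of R-squared values (length >= 2).
#' @return One-row tibble `t_stat, p_value, df`.
#' @export
compare_conditions <- function(emp, non) {
  emp <- emp[!is.na(emp)]; non <- non[!is.na(non)]
  if (length(emp) < 2 || length(non) < 2) {
    stop("both condition groups need at least 2 values", call. = FALSE)
  }
  if (stats::sd(emp) == 0 && stats::sd(non) == 0) {
    if (mean(emp) == mean(non)) {
      return(tibble::tibble(t_stat = 0, p_value = 1, df = NA_real_))
    }
    return(tibble::tibble(t_stat = sign(mean(emp) - mean(non)) * Inf,
                          p_value = 0, df = NA_real_))
  }
  tt <- stats::t.test(emp, non, var.equal = FALSE,
                      alternative = "two.sided")
  tibble::tibble(t_stat = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter))
}

#' Condition-level comparison of synchronization per triple
#'
#' For every (eye feature, channel, band, quadrant), compares the
#' empathic against the non-empathic sessions' R-squared: group means
#' and standard deviations, Welch t statistic and p value, and the
#' exclusion verdict of [apply_exclusion()]. An optional
#' Benjamini-Hochberg adjusted p value is reported alongside (the raw
#' p values remain the decision basis).
#'
#' @param results Session-level result tibble (see [aggregate_sync()]).
#' @param interval `"std"` (default): exclusion uses mean +/- 1 sd
#'   intervals; `"se"`: standard-error intervals.
#' @param bh_adjust Add a `p_bh` column (default `TRUE`).
#' @return Comparison tibble, one row per triple x quadrant, with
#'   columns `mean_emp, std_emp, n_emp, mean_non, std_non, n_non,
#'   t_stat, p_value, retained, retention_reason, hemisphere`.
#' @export
compare_sync <- function(results, interval = c("std", "se"),
                         bh_adjust = TRUE) {
  interval <- match.arg(interval)
  agg <- aggregate_sync(results)
  wide <- tidyr::pivot_wider(
    agg,
    id_cols = c("eye_feature", "channel", "band", "quadrant"),
    names_from = "empathic",
    values_from = c("mean_r2", "std_r2", "n"))
  names(wide) <- sub("_TRUE$", "_emp", names(wide))
  names(wide) <- sub("_FALSE$", "_non", names(wide))
  names(wide) <- sub("^mean_r2", "mean", names(wide))
  names(wide) <- sub("^std_r2", "std", names(wide))
  need <- c("mean_emp", "std_emp", "n_emp", "mean_non", "std_non", "n_non")
  missing <- setdiff(need, names(wide))
  if (length(missing) > 0) {
    stop("results lack one of the conditions; cannot compare ",
         "(missing: ", paste(missing, collapse = ", "), ")", call. = FALSE)
  }

  tests <- purrr::pmap_dfr(
    wide[, c("eye_feature", "channel", "band", "quadrant")],
    function(eye_feature, channel, band, quadrant) {
      sub <- results[results$eye_feature == eye_feature &
                       results$channel == channel &
                       results$band == band &
                       results$quadrant == quadrant, ]
      emp <- sub$r2[sub$empathic]
      non <- sub$r2[!sub$empathic]
      if (sum(!is.na(emp)) >= 2 && sum(!is.na(non)) >= 2) {
        compare_conditions(emp, non)
      } else {
        tibble::tibble(t_stat = NA_real_, p_value = NA_real_,
                       df = NA_real_)
      }
    })
  out <- dplyr::bind_cols(wide, tests)
  out <- apply_exclusion(out, interval = interval)
  out$hemisphere <- hemisphere_tag(out$eye_feature, out$channel)
  if (bh_adjust) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significance <- dplyr::case_when(
    is.na(out$p_value) ~ "",
    out$p_value < 0.01 ~ "*",
    out$p_value < 0.05 ~ "**",
    TRUE ~ ""
  )
  out
}

#' Apply the two exclusion criteria
#'
#' A triple is excluded when (1) the non-empathic mean R-squared is at
#' least the empathic mean, or (2) the two `mean +/- std` intervals
#' overlap. Both rules must pass for the triple to be retained. When a
#' standard deviation is unavailable (group of one) criterion 2 cannot
#' be evaluated and the triple is conservatively excluded with reason
#' `std_overlap`.
#'
#' @param comparison Comparison tibble with `mean_emp, std_emp,
#'   mean_non, std_non` columns (see [compare_sync()]).
#' @param interval `"std"` for mean +/- 1 sd intervals (default) or
#'   `"se"` for standard-error intervals (`std / sqrt(n)`).
#' @return The tibble with `retained` (logical) and `retention_reason`
#'   (`kept`, `non_empathic_higher`, `std_overlap`) columns.
#' @export
apply_exclusion <- function(comparison, interval = c("std", "se")) {
  interval <- match.arg(interval)
  half_emp <- comparison$std_emp
  half_non <- comparison$std_non
  if (interval == "se") {
    half_emp <- half_emp / sqrt(comparison$n_emp)
    half_non <- half_non / sqrt(comparison$n_non)
  }
  crit1 <- comparison$mean_non >= comparison$mean_emp
  overlap <- (comparison$mean_emp - half_emp) <=
    (comparison$mean_non + half_non) &
    (comparison$mean_non - half_non) <= (comparison$mean_emp + half_emp)
  crit2 <- is.na(overlap) | overlap   # unevaluable -> conservative exclusion
  comparison$retention_reason <- dplyr::case_when(
    crit1 ~ "non_empathic_higher",
    crit2 ~ "std_overlap",
    TRUE ~ "kept"
  )
  comparison$retained <- comparison$retention_reason == "kept"
  comparison
}

#' Quadrant-level report of retained synchronizations
#'
#' Groups the retained triples by valence-arousal quadrant and tags
#' each with its hemisphere relation (same / crossed / midline for
#' pupil features).
#'
#' @param comparisons Output of [compare_sync()] (after exclusion).
#' @return Tibble of retained triples with `quadrant` and `hemisphere`,
#'   ordered by quadrant and descending empathic mean.
#' @export
quadrant_report <- function(comparisons) {
  kept <- comparisons[comparisons$retained, ]
  if (nrow(kept) == 0) {
    warning("no retained triples; quadrant report is empty")
    return(kept)
  }
  kept$hemisphere <- hemisphere_tag(kept$eye_feature, kept$channel)
  kept[order(kept$quadrant, -kept$mean_emp),
       c("quadrant", "eye_feature", "channel", "band", "hemisphere",
         "mean_emp", "std_emp", "mean_non", "std_non", "t_stat",
         "p_value", "significance")]
}
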