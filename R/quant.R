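#' Median-center pooled channels on the log2 scale
#'
#' Aligns the four pooled channels by shifting each group's log2 intensities
#' so that every per-group median equals the grand median (defined as the
#' median of the per-group medians). The shift is a per-group constant, so
#' within-group rank order is preserved and all downstream ratios of
#' already-aligned data are unchanged.
#'
#' @param table A peptide table: tibble with columns `protein_id`,
#'   `peptide_id`, `group`, `log2_intensity`, `unique_assignment`.
#' @return The table with normalized `log2_intensity`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   protein_id = "P1", peptide_id = c("a", "a", "a", "a"),
#'   group = group_labels(), log2_intensity = c(10, 12, 11, 11),
#'   unique_assignment = TRUE
#' )
#' normalize_channels(tab)
normalize_channels <- function(table) {
  validate_peptide_table(table)
  missing <- setdiff(group_labels(), unique(table$group))
  if (length(missing) > 0) {
    stop("empty group(s) in peptide table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  med <- stats::aggregate(log2_intensity ~ group, data = table, FUN = stats::median)
  grand <- stats::median(med$log2_intensity)
  offset <- stats::setNames(grand - med$log2_intensity, med$group)
  table$log2_intensity <- table$log2_intensity + unname(offset[table$group])
  table
}

# per-peptide log2 ratios for one protein and one contrast; peptides must be
# uniquely assigned and measured in both groups
peptide_deltas <- function(table, protein_id, contrast) {
  rows <- table[table$protein_id == protein_id & table$unique_assignment, ]
  num <- rows[rows$group == contrast$numerator, c("peptide_id", "log2_intensity")]
  den <- rows[rows$group == contrast$denominator, c("peptide_id", "log2_intensity")]
  shared <- merge(num, den, by = "peptide_id", suffixes = c("_num", "_den"))
  stats::setNames(shared$log2_intensity_num - shared$log2_intensity_den,
                  shared$peptide_id)
}

#' Protein fold change for one contrast
#'
#' The log2 fold change of a protein is the mean of the per-peptide log2
#' ratios between the two groups, restricted to peptides that are uniquely
#' assigned to the protein and measured in both groups.
#'
#' @param table Normalized peptide table.
#' @param protein_id Protein identifier.
#' @param contrast One row of [canonical_contrasts()] (or any list with
#'   `numerator` and `denominator`).
#' @return One-row tibble with `protein_id`, `contrast`, `log2_fc`,
#'   `linear_ratio`, `percent_change`, `p_value`, `n_peptides`; or zero rows
#'   when no co-measured unique peptide exists.
#' @export
protein_fold_change <- function(table, protein_id, contrast) {
  deltas <- peptide_deltas(table, protein_id, contrast)
  if (length(deltas) == 0) {
    return(tibble::tibble(
      protein_id = character(), contrast = character(), log2_fc = double(),
      linear_ratio = double(), percent_change = double(), p_value = double(),
      n_peptides = integer()
    ))
  }
  fc <- mean(deltas)
  tibble::tibble(
    protein_id = protein_id,
    contrast = contrast$contrast %||% paste0(contrast$numerator, "/", contrast$denominator),
    log2_fc = fc,
    linear_ratio = 2^fc,
    percent_change = percent_change(fc),
    p_value = if (length(deltas) < 2) NA_real_ else protein_t_test(deltas),
    n_peptides = length(deltas)
  )
}

#' One-sample two-tailed t-test of peptide log2 ratios against zero
#'
#' Tests whether the mean per-peptide log2 ratio differs from 0, using
#' `n - 1` degrees of freedom. With fewer than two ratios, or zero sample
#' variance, the p-value is undefined and `NA` is returned (the protein is
#' untestable, not significant).
#'
#' @param deltas Numeric vector of per-peptide log2 ratios.
#' @return p-value in \[0, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' protein_t_test(c(0.2, 0.3, 0.25, 0.15))
protein_t_test <- function(deltas) {
  if (length(deltas) == 0) stop("no peptide ratios supplied", call. = FALSE)
  if (!all(is.finite(deltas))) stop("non-finite peptide ratio", call. = FALSE)
  n <- length(deltas)
  if (n < 2) return(NA_real_)
  s <- stats::sd(deltas)
  if (s == 0) return(NA_real_)
  tstat <- mean(deltas) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Quantify all proteins across the canonical contrasts
#'
#' Vectorized driver over [protein_fold_change()]: computes, for every
#' protein and contrast, the mean peptide-level log2 ratio, its linear-ratio
#' and percent-change forms, the one-sample t-test p-value, and the number of
#' peptides used. Proteins with a single usable peptide keep their fold
#' change but carry an undefined p-value.
#'
#' @param table Normalized peptide table.
#' @param contrasts Contrast definitions; defaults to [canonical_contrasts()].
#' @return Long tibble keyed by (`protein_id`, `contrast`).
#' @export
quantify_proteins <- function(table, contrasts = canonical_contrasts()) {
  validate_peptide_table(table)
  used <- dplyr::filter(table, .data$unique_assignment)
  res <- lapply(seq_len(nrow(contrasts)), function(i) {
    ctr <- contrasts[i, ]
    num <- dplyr::filter(used, .data$group == ctr$numerator)
    den <- dplyr::filter(used, .data$group == ctr$denominator)
    shared <- dplyr::inner_join(
      num[, c("protein_id", "peptide_id", "log2_intensity")],
      den[, c("protein_id", "peptide_id", "log2_intensity")],
      by = c("protein_id", "peptide_id"), suffix = c("_num", "_den")
    )
    shared$delta <- shared$log2_intensity_num - shared$log2_intensity_den
    out <- dplyr::summarise(
      dplyr::group_by(shared, .data$protein_id),
      log2_fc = mean(.data$delta),
      p_value = protein_t_test(.data$delta),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
    out$contrast <- ctr$contrast
    out
  })
  res <- dplyr::bind_rows(res)
  res$linear_ratio <- 2^res$log2_fc
  res$percent_change <- percent_change(res$log2_fc)
  dplyr::arrange(
    res[, c("protein_id", "contrast", "log2_fc", "linear_ratio",
            "percent_change", "p_value", "n_peptides")],
    .data$protein_id, match(.data$contrast, contrasts$contrast)
  )
}

#' Phospho-isoform fold change for one contrast
#'
#' Run-level quantification: the log2 ratio is computed run by run (pairing
#' the technical runs of the two groups by `run_id`) and averaged. The
#' spread across runs within each group is summarized by its coefficient of
#' variation (sd/mean of the linear intensities, `n - 1` denominator), and
#' the CV of the ratio is obtained by [propagate_cv()].
#'
#' @param table Phospho table: tibble with columns `protein_id`,
#'   `isoform_id`, `sites`, `run_id`, `group`, `intensity`.
#' @param isoform_id Isoform identifier.
#' @param contrast One row of [canonical_contrasts()].
#' @return One-row tibble with `isoform_id`, `protein_id`, `contrast`,
#'   `log2_fc`, `linear_ratio`, `percent_change`, `cv_fc`; zero rows when a
#'   run is missing in either group.
#' @export
phospho_fold_change <- function(table, isoform_id, contrast) {
  rows <- table[table$isoform_id == isoform_id, ]
  num <- rows[rows$group == contrast$numerator, ]
  den <- rows[rows$group == contrast$denominator, ]
  all_runs <- sort(unique(table$run_id))
  if (!setequal(num$run_id, all_runs) || !setequal(den$run_id, all_runs)) {
    return(tibble::tibble(
      isoform_id = character(), protein_id = character(), contrast = character(),
      log2_fc = double(), linear_ratio = double(), percent_change = double(),
      cv_fc = double()
    ))
  }
  num <- num[order(num$run_id), ]
  den <- den[order(den$run_id), ]
  ratios <- log2(num$intensity / den$intensity)
  fc <- mean(ratios)
  cv_num <- stats::sd(num$intensity) / mean(num$intensity)
  cv_den <- stats::sd(den$intensity) / mean(den$intensity)
  tibble::tibble(
    isoform_id = isoform_id,
    protein_id = rows$protein_id[1],
    contrast = contrast$contrast %||% paste0(contrast$numerator, "/", contrast$denominator),
    log2_fc = fc,
    linear_ratio = 2^fc,
    percent_change = percent_change(fc),
    cv_fc = propagate_cv(cv_num, cv_den)
  )
}

#' Quantify all phospho-isoforms across the canonical contrasts
#'
#' Vectorized driver over [phospho_fold_change()]. Isoforms missing a
#' technical run in either group of a contrast are dropped for that contrast.
#'
#' @inheritParams phospho_fold_change
#' @param contrasts Contrast definitions; defaults to [canonical_contrasts()].
#' @return Long tibble keyed by (`isoform_id`, `contrast`), carrying
#'   `protein_id` for category joins.
#' @export
quantify_phospho <- function(table, contrasts = canonical_contrasts()) {
  validate_phospho_table(table)
  n_runs <- length(unique(table$run_id))
  # per isoform x group: mean log2 intensity over runs, linear CV, run count
  grp <- dplyr::summarise(
    dplyr::group_by(table, .data$protein_id, .data$isoform_id, .data$group),
    mean_log2 = mean(log2(.data$intensity)),
    cv = stats::sd(.data$intensity) / mean(.data$intensity),
    n_runs_present = dplyr::n_distinct(.data$run_id),
    .groups = "drop"
  )
  res <- lapply(seq_len(nrow(contrasts)), function(i) {
    ctr <- contrasts[i, ]
    num <- dplyr::filter(grp, .data$group == ctr$numerator, .data$n_runs_present == n_runs)
    den <- dplyr::filter(grp, .data$group == ctr$denominator, .data$n_runs_present == n_runs)
    shared <- dplyr::inner_join(
      num[, c("protein_id", "isoform_id", "mean_log2", "cv")],
      den[, c("isoform_id", "mean_log2", "cv")],
      by = "isoform_id", suffix = c("_num", "_den")
    )
    tibble::tibble(
      isoform_id = shared$isoform_id,
      protein_id = shared$protein_id,
      contrast = ctr$contrast,
      # mean over runs of per-run log2 ratios equals the difference of
      # per-group mean log2 intensities because run pairing is by run_id
      log2_fc = shared$mean_log2_num - shared$mean_log2_den,
      cv_fc = propagate_cv(shared$cv_num, shared$cv_den)
    )
  })
  res <- dplyr::bind_rows(res)
  res$linear_ratio <- 2^res$log2_fc
  res$percent_change <- percent_change(res$log2_fc)
  dplyr::arrange(
    res[, c("isoform_id", "protein_id", "contrast", "log2_fc", "linear_ratio",
            "percent_change", "cv_fc")],
    .data$isoform_id, match(.data$contrast, contrasts$contrast)
  )
}

#' Propagate coefficients of variation through a ratio
#'
#' The relative variability of a ratio of two measured quantities is the
#' square root of the sum of squares of the individual CVs.
#'
#' @param cv_num,cv_den Nonnegative CVs of numerator and denominator.
#' @return `sqrt(cv_num^2 + cv_den^2)`, vectorized.
#' @export
#' @examples
#' propagate_cv(0.03, 0.04) # 0.05
propagate_cv <- function(cv_num, cv_den) {
  if (any(!is.finite(cv_num)) || any(!is.finite(cv_den))) {
    stop("CVs must be finite", call. = FALSE)
  }
  if (any(cv_num < 0) || any(cv_den < 0)) {
    stop("CVs must be nonnegative", call. = FALSE)
  }
  sqrt(cv_num^2 + cv_den^2)
}

#' Convert a log2 fold change to percent change
#'
#' @param log2_fc Numeric log2 fold change(s).
#' @return `100 * (2^log2_fc - 1)`.
#' @export
#' @examples
#' percent_change(1)   # +100
#' percent_change(0)   # 0
percent_change <- function(log2_fc) {
  if (any(!is.finite(log2_fc))) stop("log2 fold change must be finite", call. = FALSE)
  100 * (2^log2_fc - 1)
}
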