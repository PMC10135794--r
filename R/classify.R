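#' Classify one phospho-isoform by the 10% threshold rules
#'
#' Pooled phospho runs carry no biological replication, so calls are made on
#' effect size alone. An isoform is *affected* when its pain-contrast linear
#' ratio changes by at least `affected_threshold` (default 10%):
#' `|r_pain - 1| >= threshold`, boundary inclusive. An affected isoform is
#' *back-regulated* by a treatment when the treatment-contrast ratio also
#' changes by at least the threshold, in the direction opposite to the
#' pain-model change (i.e. back toward uninjured levels). A same-direction
#' change of at least the threshold is flagged as *further modulated*
#' instead. When `overshoot_allowed` is `FALSE`, a reversal that pushes
#' expression past the uninjured level no longer counts as back-regulation.
#'
#' @param quant Rows of [quantify_phospho()] output for a single isoform
#'   (one row per contrast).
#' @param cfg An [analysis_config()].
#' @return One-row classification tibble; see [classify_dataset()].
#' @export
classify_phospho <- function(quant, cfg = analysis_config()) {
  stopifnot(length(unique(quant$isoform_id)) <= 1)
  w <- quant_by_contrast(quant, "linear_ratio")
  rec <- empty_record(quant$isoform_id[1], quant$protein_id[1], "phospho_isoform")
  if (anyNA(w)) {
    rec$unclassifiable <- TRUE
    return(rec)
  }
  thr <- cfg$affected_threshold
  pain_dev <- w[["pain"]] - 1
  rec$affected <- at_least(abs(pain_dev), thr)
  if (rec$affected && pain_dev != 0) {
    rec$pain_direction <- if (pain_dev > 0) "up" else "down"
    for (trt in c("DTMP", "LR")) {
      dev <- w[[trt]] - 1
      big <- at_least(abs(dev), thr)
      opposite <- big && sign(dev) == -sign(pain_dev)
      if (opposite && !cfg$overshoot_allowed) {
        # final level relative to uninjured must stay on the pain side of 1
        final <- w[["pain"]] * w[[trt]]
        opposite <- sign(final - 1) == sign(pain_dev) || final == 1
      }
      rec[[paste0("backreg_", trt)]] <- opposite
      rec[[paste0("further_modulated_", trt)]] <- big && sign(dev) == sign(pain_dev)
    }
  }
  rec
}

#' Classify one protein by the significance-gated rules
#'
#' Protein quantification rests on peptide-level replication, so calls are
#' significance-gated: a protein is *affected* when its pain-contrast
#' one-sample t-test gives `p < alpha`; it is *back-regulated* by a treatment
#' when the treatment contrast is also significant with log2 fold change of
#' the opposite sign, and *further modulated* when significant with the same
#' sign. A protein whose pain-contrast p-value is undefined (single peptide
#' or zero variance) is unclassifiable.
#'
#' @param quant Rows of [quantify_proteins()] output for a single protein.
#' @param cfg An [analysis_config()].
#' @return One-row classification tibble; see [classify_dataset()].
#' @export
classify_protein <- function(quant, cfg = analysis_config()) {
  stopifnot(length(unique(quant$protein_id)) <= 1)
  fc <- quant_by_contrast(quant, "log2_fc")
  pv <- quant_by_contrast(quant, "p_value")
  rec <- empty_record(quant$protein_id[1], quant$protein_id[1], "protein")
  if (is.na(fc[["pain"]]) || is.na(pv[["pain"]])) {
    rec$unclassifiable <- TRUE
    return(rec)
  }
  rec$affected <- pv[["pain"]] < cfg$alpha
  if (rec$affected && fc[["pain"]] != 0) {
    rec$pain_direction <- if (fc[["pain"]] > 0) "up" else "down"
    for (trt in c("DTMP", "LR")) {
      sig <- !is.na(pv[[trt]]) && pv[[trt]] < cfg$alpha && !is.na(fc[[trt]]) &&
        fc[[trt]] != 0
      opposite <- sig && sign(fc[[trt]]) == -sign(fc[["pain"]])
      if (opposite && !cfg$overshoot_allowed) {
        final <- fc[["pain"]] + fc[[trt]]
        opposite <- sign(final) == sign(fc[["pain"]]) || final == 0
      }
      rec[[paste0("backreg_", trt)]] <- opposite
      rec[[paste0("further_modulated_", trt)]] <-
        sig && sign(fc[[trt]]) == sign(fc[["pain"]])
    }
  }
  rec
}

empty_record <- function(entity_id, protein_id, kind) {
  tibble::tibble(
    entity_id = entity_id, protein_id = protein_id,
    entity_kind = kind, pain_direction = "none",
    affected = FALSE, backreg_DTMP = FALSE, backreg_LR = FALSE,
    further_modulated_DTMP = FALSE, further_modulated_LR = FALSE,
    unclassifiable = FALSE
  )
}

# "at least" comparison robust to floating-point representation of the
# threshold (e.g. |0.90 - 1| evaluates just below 0.10): values within 1e-9
# of the boundary count as on it, honoring the inclusive rule
at_least <- function(x, thr) {
  x >= thr | abs(x - thr) < 1e-9
}

# named vector of one quant column across the three canonical contrasts,
# NA where the contrast is absent
quant_by_contrast <- function(quant, column) {
  out <- stats::setNames(rep(NA_real_, 3), canonical_contrasts()$contrast)
  vals <- stats::setNames(quant[[column]], quant$contrast)
  out[names(vals)] <- vals
  out
}

#' Classify every entity in a quantified dataset and summarize counts
#'
#' Applies the phospho threshold rules (see [classify_phospho()]) or the
#' protein significance rules (see [classify_protein()]) to every entity,
#' chosen by the columns present in `quants` (`cv_fc` marks phospho output,
#' `p_value` protein output), and tallies the counts the study design
#' reports: total entities, entities affected by the pain model, and
#' affected entities back-regulated by each treatment, with the
#' corresponding percentages (back-regulation percentages are relative to
#' the affected set, and undefined when nothing is affected). The
#' implementation is vectorized but decision-equivalent to applying the
#' per-entity classifiers one by one.
#'
#' @param quants Output of [quantify_phospho()] or [quantify_proteins()].
#' @param cfg An [analysis_config()].
#' @return List with `records` (one-row-per-entity tibble with columns
#'   `entity_id`, `protein_id`, `entity_kind`, `pain_direction`, `affected`,
#'   `backreg_DTMP`, `backreg_LR`, `further_modulated_DTMP`,
#'   `further_modulated_LR`, `unclassifiable`) and `summary` (named list:
#'   `n_total`, `n_affected`, `n_backreg_DTMP`, `n_backreg_LR`,
#'   `pct_affected`, `pct_backreg_DTMP`, `pct_backreg_LR`).
#' @export
classify_dataset <- function(quants, cfg = analysis_config()) {
  if (nrow(quants) == 0) stop("no quantifications to classify", call. = FALSE)
  phospho <- "cv_fc" %in% names(quants)
  records <- if (phospho) classify_phospho_bulk(quants, cfg)
             else classify_protein_bulk(quants, cfg)
  records <- dplyr::arrange(records, .data$entity_id)
  list(records = records, summary = count_summary(records))
}

# vectorized forms of the per-entity rules
classify_phospho_bulk <- function(quants, cfg) {
  r <- pivot_quants(quants, "isoform_id", "linear_ratio")
  rec <- empty_record(r$entity_id, r$protein_id, "phospho_isoform")
  ok <- !is.na(r$pain) & !is.na(r$DTMP) & !is.na(r$LR)
  rec$unclassifiable <- !ok
  thr <- cfg$affected_threshold
  pain_dev <- r$pain - 1
  rec$affected <- ok & at_least(abs(pain_dev), thr)
  act <- rec$affected & pain_dev != 0
  rec$pain_direction[act] <- ifelse(pain_dev[act] > 0, "up", "down")
  for (trt in c("DTMP", "LR")) {
    dev <- r[[trt]] - 1
    big <- at_least(abs(dev), thr)
    opp <- act & big & sign(dev) == -sign(pain_dev)
    if (!cfg$overshoot_allowed) {
      final <- r$pain * r[[trt]]
      opp <- opp & (sign(final - 1) == sign(pain_dev) | final == 1)
    }
    rec[[paste0("backreg_", trt)]] <- opp
    rec[[paste0("further_modulated_", trt)]] <-
      act & big & sign(dev) == sign(pain_dev)
  }
  rec
}

classify_protein_bulk <- function(quants, cfg) {
  fc <- pivot_quants(quants, "protein_id", "log2_fc")
  pv <- pivot_quants(quants, "protein_id", "p_value")
  rec <- empty_record(fc$entity_id, fc$protein_id, "protein")
  ok <- !is.na(fc$pain) & !is.na(pv$pain)
  rec$unclassifiable <- !ok
  rec$affected <- ok & pv$pain < cfg$alpha
  rec$affected[is.na(rec$affected)] <- FALSE
  act <- rec$affected & fc$pain != 0
  rec$pain_direction[act] <- ifelse(fc$pain[act] > 0, "up", "down")
  for (trt in c("DTMP", "LR")) {
    sig <- !is.na(pv[[trt]]) & pv[[trt]] < cfg$alpha & !is.na(fc[[trt]]) &
      fc[[trt]] != 0
    opp <- act & sig & sign(fc[[trt]]) == -sign(fc$pain)
    if (!cfg$overshoot_allowed) {
      final <- fc$pain + fc[[trt]]
      opp <- opp & (sign(final) == sign(fc$pain) | final == 0)
    }
    rec[[paste0("backreg_", trt)]] <- opp
    rec[[paste0("further_modulated_", trt)]] <-
      act & sig & sign(fc[[trt]]) == sign(fc$pain)
  }
  rec
}

# entity x contrast wide table of one quant column, with protein_id carried
pivot_quants <- function(quants, id_col, column) {
  wide <- tidyr::pivot_wider(
    tibble::tibble(entity_id = quants[[id_col]],
                   protein_id = quants$protein_id,
                   contrast = quants$contrast,
                   value = quants[[column]]),
    names_from = "contrast", values_from = "value"
  )
  for (ctr in canonical_contrasts()$contrast) {
    if (!ctr %in% names(wide)) wide[[ctr]] <- NA_real_
  }
  wide
}

#' Tally affected / back-regulated counts from classification records
#'
#' @param records Classification record tibble (see [classify_dataset()]).
#' @return Named list of counts and percentages; percentages over an empty
#'   affected set are `NA`.
#' @export
count_summary <- function(records) {
  n_total <- nrow(records)
  n_aff <- sum(records$affected)
  n_d <- sum(records$backreg_DTMP)
  n_l <- sum(records$backreg_LR)
  list(
    n_total = n_total,
    n_affected = n_aff,
    n_backreg_DTMP = n_d,
    n_backreg_LR = n_l,
    pct_affected = if (n_total > 0) 100 * n_aff / n_total else NA_real_,
    pct_backreg_DTMP = if (n_aff > 0) 100 * n_d / n_aff else NA_real_,
    pct_backreg_LR = if (n_aff > 0) 100 * n_l / n_aff else NA_real_
  )
}
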