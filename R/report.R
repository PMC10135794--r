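#' Tri-state heatmap matrix for protein results
#'
#' Encodes the protein expression figures numerically: per protein and
#' contrast the cell is `+1` for a significant increase (`p < alpha`,
#' positive log2 fold change), `-1` for a significant decrease, and `0` for
#' no significant change (including undefined p-values and exactly-zero fold
#' changes). Rows are ordered alphabetically by protein; columns are the
#' pain contrast then the two treatments.
#'
#' @param quants Output of [quantify_proteins()].
#' @param cfg An [analysis_config()].
#' @return Tibble with columns `entity_id`, `pain`, `DTMP`, `LR`.
#' @export
encode_protein_heatmap <- function(quants, cfg = analysis_config()) {
  cell <- ifelse(!is.na(quants$p_value) & quants$p_value < cfg$alpha,
                 sign(quants$log2_fc), 0)
  wide <- tidyr::pivot_wider(
    tibble::tibble(entity_id = quants$protein_id, contrast = quants$contrast,
                   cell = cell),
    names_from = "contrast", values_from = "cell"
  )
  for (ctr in canonical_contrasts()$contrast) {
    if (!ctr %in% names(wide)) wide[[ctr]] <- NA_real_
  }
  dplyr::arrange(wide[, c("entity_id", "pain", "DTMP", "LR")], .data$entity_id)
}

#' Percent-change heatmap matrix for phospho-isoforms
#'
#' Encodes the phospho heatmaps numerically: per isoform and contrast the
#' cell is the percent expression change. By default only the isoform with
#' the largest pain-contrast change per parent protein is kept, matching the
#' figures' top-isoform display rule.
#'
#' @param quants Output of [quantify_phospho()].
#' @param top_only Keep only the top isoform per protein (default `TRUE`).
#' @return Tibble with columns `entity_id`, `pain`, `DTMP`, `LR` (percent).
#' @export
encode_phospho_heatmap <- function(quants, top_only = TRUE) {
  keep <- if (top_only) select_top_isoforms(quants) else unique(quants$isoform_id)
  sub <- quants[quants$isoform_id %in% keep, ]
  wide <- tidyr::pivot_wider(
    tibble::tibble(entity_id = sub$isoform_id, contrast = sub$contrast,
                   cell = sub$percent_change),
    names_from = "contrast", values_from = "cell"
  )
  for (ctr in canonical_contrasts()$contrast) {
    if (!ctr %in% names(wide)) wide[[ctr]] <- NA_real_
  }
  dplyr::arrange(wide[, c("entity_id", "pain", "DTMP", "LR")], .data$entity_id)
}

#' Select the most pain-affected isoform of each phosphoprotein
#'
#' For every parent protein, returns the isoform with the largest absolute
#' percent change on the pain contrast; ties break lexicographically by
#' isoform id.
#'
#' @param quants Output of [quantify_phospho()].
#' @param per_protein Number of isoforms to keep per protein (default 1).
#' @return Character vector of isoform ids, ordered by protein id.
#' @export
select_top_isoforms <- function(quants, per_protein = 1L) {
  pain <- quants[quants$contrast == "pain", ]
  pain <- pain[order(pain$protein_id, -abs(pain$percent_change), pain$isoform_id), ]
  picked <- dplyr::slice_head(dplyr::group_by(pain, .data$protein_id),
                              n = per_protein)
  picked$isoform_id
}

#' Write the pipeline's canonical output files
#'
#' Writes `classification.tsv` (one row per entity with direction and all
#' flags), `category_rollup.tsv`, `heatmap.tsv` (numeric heatmap matrix),
#' and `summary.json` (counts, percentages, configuration echo, and seed
#' provenance). Percent values in TSVs carry one decimal place; log2 values
#' six significant digits.
#'
#' @param dir Output directory (created if absent).
#' @param records Classification record tibble.
#' @param summary Count summary list from [classify_dataset()].
#' @param rollup Rollup tibble from [rollup_by_category()], or `NULL`.
#' @param heatmap Heatmap tibble, or `NULL`.
#' @param cfg An [analysis_config()].
#' @param seed Seed used for any synthetic input, or `NULL`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_summary <- function(dir, records, summary, rollup = NULL, heatmap = NULL,
                          cfg = analysis_config(), seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(classification = file.path(dir, "classification.tsv"),
             summary = file.path(dir, "summary.json"))
  readr::write_tsv(records, paths[["classification"]])
  if (!is.null(rollup)) {
    paths[["rollup"]] <- file.path(dir, "category_rollup.tsv")
    readr::write_tsv(format_rollup(rollup), paths[["rollup"]])
  }
  if (!is.null(heatmap)) {
    paths[["heatmap"]] <- file.path(dir, "heatmap.tsv")
    hm <- heatmap
    for (ctr in c("pain", "DTMP", "LR")) hm[[ctr]] <- fmt_num(hm[[ctr]])
    readr::write_tsv(hm, paths[["heatmap"]])
  }
  js <- list(
    totals = summary[c("n_total", "n_affected", "n_backreg_DTMP", "n_backreg_LR")],
    percentages = lapply(
      summary[c("pct_affected", "pct_backreg_DTMP", "pct_backreg_LR")],
      function(p) if (is.na(p)) NULL else round_half_up(p, 1)
    ),
    config = unclass(cfg),
    seed = seed
  )
  if (!is.null(rollup)) js$category_rollup <- rollup
  jsonlite::write_json(js, paths[["summary"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(paths)
}

#' Read back a summary.json written by [write_summary()]
#'
#' @param path Path to `summary.json`.
#' @return The parsed list.
#' @export
read_summary <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

format_rollup <- function(rollup) {
  out <- rollup
  for (col in c("pct_affected", "pct_backreg_DTMP", "pct_backreg_LR")) {
    out[[col]] <- fmt_num(out[[col]], decimals = 1)
  }
  out
}

# percent columns: one decimal place; others: 6 significant digits
fmt_num <- function(x, decimals = NULL) {
  if (is.null(decimals)) signif(x, 6) else round_half_up(x, decimals)
}
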