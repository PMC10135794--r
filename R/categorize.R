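#' Category overlap (Venn) counts
#'
#' Computes exact set overlaps between groups of annotated proteins. A group
#' is defined by a set of category labels; a protein belongs to the group
#' when it carries at least one of them. The default grouping is the one
#' used for the matrisome overlap figure: structural, the combined
#' adhesion/junction class, and signaling.
#'
#' @param ann Annotation tibble (`protein_id`, `category`, `source`), one row
#'   per membership; see [read_annotation()].
#' @param groups Named list mapping group name to a character vector of
#'   category labels (all must be in [matrisome_categories()]).
#' @return List with `sizes` (named vector), `pairwise` (named vector, names
#'   like `"structural&signaling"`), `triple` (all-groups intersection; `NA`
#'   unless exactly 3 groups), and `n_union`.
#' @export
venn_counts <- function(ann,
                        groups = list(
                          structural = "structural",
                          adhesion_junction = c("adhesion", "junction"),
                          signaling = "signaling")) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  bad <- setdiff(unlist(groups), matrisome_categories())
  if (length(bad) > 0) {
    stop("unknown category name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  members <- lapply(groups, function(cats) {
    unique(ann$protein_id[ann$category %in% cats])
  })
  sizes <- vapply(members, length, integer(1))
  pair_names <- utils::combn(names(groups), 2, paste, collapse = "&")
  pairwise <- if (length(groups) >= 2) {
    stats::setNames(as.vector(utils::combn(seq_along(groups), 2, function(ij) {
      length(intersect(members[[ij[1]]], members[[ij[2]]]))
    })), pair_names)
  } else {
    stats::setNames(integer(0), character(0))
  }
  triple <- if (length(groups) == 3) {
    length(Reduce(intersect, members))
  } else {
    NA_integer_
  }
  list(sizes = sizes, pairwise = pairwise, triple = triple,
       n_union = length(unique(unlist(members))))
}

#' Roll classification results up by matrisome category
#'
#' Joins classification records to the category annotation and counts, for
#' every category, the number of entities, how many were affected by the
#' pain model, and how many of those were back-regulated by each treatment.
#' Phospho-isoforms inherit all categories of their parent protein; an
#' entity belonging to several categories is counted in each (category
#' totals therefore sum to more than the number of distinct entities
#' whenever the annotation overlaps). Back-regulation percentages are taken
#' relative to the affected set and rounded half-up to whole percent, the
#' convention used in the per-category tables.
#'
#' @param records Classification record tibble (see [classify_dataset()]).
#' @param ann Annotation tibble (`protein_id`, `category`, `source`).
#' @param level `"phospho_isoform"` or `"protein"`; inferred from the
#'   records when `NULL`.
#' @param categories Categories to report (default all four, so a category
#'   with no members yields a zero row with undefined percentages).
#' @return List with `rollup` (tibble: `category`, `level`, `n_total`,
#'   `n_proteins`, `n_affected`, `n_backreg_DTMP`, `n_backreg_LR`,
#'   `pct_affected`, `pct_backreg_DTMP`, `pct_backreg_LR`) and `unannotated`
#'   (entity ids whose protein has no annotation; excluded from the rollup).
#' @export
rollup_by_category <- function(records, ann, level = NULL,
                               categories = matrisome_categories()) {
  stopifnot(all(categories %in% matrisome_categories()))
  level <- level %||% unique(records$entity_kind)
  stopifnot(length(level) == 1)
  annotated <- records$protein_id %in% ann$protein_id
  unannotated <- records$entity_id[!annotated]
  kept <- records[annotated, ]
  joined <- dplyr::inner_join(kept, ann[, c("protein_id", "category")],
                              by = "protein_id",
                              relationship = "many-to-many")
  joined <- dplyr::distinct(joined, .data$entity_id, .data$category,
                            .keep_all = TRUE)
  pct <- function(num, den) ifelse(den > 0, round_half_up(100 * num / den), NA_real_)
  rollup <- lapply(categories, function(cat) {
    sub <- joined[joined$category == cat, ]
    n_total <- nrow(sub)
    n_aff <- sum(sub$affected)
    n_d <- sum(sub$backreg_DTMP)
    n_l <- sum(sub$backreg_LR)
    tibble::tibble(
      category = cat, level = level, n_total = n_total,
      n_proteins = dplyr::n_distinct(sub$protein_id),
      n_affected = n_aff, n_backreg_DTMP = n_d, n_backreg_LR = n_l,
      pct_affected = pct(n_aff, n_total),
      pct_backreg_DTMP = pct(n_d, n_aff),
      pct_backreg_LR = pct(n_l, n_aff)
    )
  })
  list(rollup = dplyr::bind_rows(rollup), unannotated = unannotated)
}
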