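# TSV readers/writers with validation. The sole tabular dialect is
# tab-separated UTF-8 with a header row and "." decimals; readr handles CRLF
# endings and trailing blank lines transparently.

#' Read and validate a peptide-level proteomic table
#'
#' Expected columns: `protein_id`, `peptide_id`, `group`, `log2_intensity`,
#' `unique_assignment`. Group labels must be among [group_labels()];
#' (`protein_id`, `peptide_id`, `group`) must be unique; intensities must be
#' finite. Violations raise an error naming the offending data lines.
#'
#' @param path Path to a TSV file.
#' @return A validated peptide tibble.
#' @export
read_peptide_table <- function(path) {
  tab <- read_tsv_strict(path, c("protein_id", "peptide_id", "group",
                                 "log2_intensity", "unique_assignment"),
                         readr::cols(
                           protein_id = readr::col_character(),
                           peptide_id = readr::col_character(),
                           group = readr::col_character(),
                           log2_intensity = readr::col_double(),
                           unique_assignment = readr::col_logical()
                         ))
  check_rows(tab, path, bad_group = !tab$group %in% group_labels(),
             non_finite_intensity = !is.finite(tab$log2_intensity),
             missing_flag = is.na(tab$unique_assignment),
             duplicate_key = duplicated(tab[, c("protein_id", "peptide_id", "group")]))
  tab
}

#' Read and validate a phospho-isoform table
#'
#' Expected columns: `protein_id`, `isoform_id`, `sites`, `run_id`, `group`,
#' `intensity`. Site lists are semicolon-separated strings like
#' `"S1126;T1164"` (residue letter + 1-based position). Intensities must be
#' positive; every group must carry the same set of at least two run ids.
#'
#' @param path Path to a TSV file.
#' @return A validated phospho tibble.
#' @export
read_phospho_table <- function(path) {
  tab <- read_tsv_strict(path, c("protein_id", "isoform_id", "sites",
                                 "run_id", "group", "intensity"),
                         readr::cols(
                           protein_id = readr::col_character(),
                           isoform_id = readr::col_character(),
                           sites = readr::col_character(),
                           run_id = readr::col_character(),
                           group = readr::col_character(),
                           intensity = readr::col_double()
                         ))
  check_rows(tab, path, bad_group = !tab$group %in% group_labels(),
             nonpositive_intensity = !is.finite(tab$intensity) | tab$intensity <= 0,
             bad_sites = !grepl("^[A-Z][0-9]+(;[A-Z][0-9]+)*$", tab$sites),
             duplicate_key = duplicated(tab[, c("isoform_id", "run_id", "group")]))
  validate_phospho_table(tab)
  tab
}

#' Read and validate a category annotation table
#'
#' Expected columns: `protein_id`, `categories` (semicolon-separated subset
#' of [matrisome_categories()], nonempty), `source` (`ontology` or
#' `literature`). The result is returned in long form, one row per
#' protein-category membership.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `protein_id`, `category`, `source`.
#' @export
read_annotation <- function(path) {
  tab <- read_tsv_strict(path, c("protein_id", "categories", "source"),
                         readr::cols(.default = readr::col_character()))
  check_rows(tab, path,
             empty_categories = is.na(tab$categories) | tab$categories == "",
             bad_source = !tab$source %in% c("ontology", "literature"),
             duplicate_protein = duplicated(tab$protein_id))
  long <- tidyr::separate_rows(tab, "categories", sep = ";")
  bad <- !long$categories %in% matrisome_categories()
  if (any(bad)) {
    stop("unknown category name(s) in ", path, ": ",
         paste(unique(long$categories[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(protein_id = long$protein_id, category = long$categories,
                 source = long$source)
}

#' Write an annotation tibble in the semicolon TSV dialect
#'
#' @param ann Long annotation tibble (`protein_id`, `category`, `source`).
#' @param path Destination TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  wide <- dplyr::summarise(
    dplyr::group_by(ann, .data$protein_id),
    categories = paste(sort(unique(.data$category)), collapse = ";"),
    source = .data$source[1],
    .groups = "drop"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write a peptide or phospho table as TSV
#'
#' @param table A peptide or phospho tibble.
#' @param path Destination TSV path.
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Parse a phospho-site string
#'
#' @param sites String like `"S1126"` or `"S33;T48"`.
#' @return Tibble with columns `residue` (single letter) and `position`
#'   (1-based integer).
#' @export
#' @examples
#' parse_phospho_sites("T1164;S1167")
parse_phospho_sites <- function(sites) {
  stopifnot(length(sites) == 1, is.character(sites))
  parts <- strsplit(sites, ";", fixed = TRUE)[[1]]
  ok <- grepl("^[A-Z][0-9]+$", parts)
  if (length(parts) == 0 || !all(ok)) {
    stop("malformed site string: ", sites, call. = FALSE)
  }
  tibble::tibble(
    residue = substr(parts, 1, 1),
    position = as.integer(substring(parts, 2))
  )
}

# shared strict TSV reader: checks header and parse problems with line numbers
read_tsv_strict <- function(path, required, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = col_types, progress = FALSE,
                         na = c("", "NA"))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("malformed rows in ", path, " at line(s) ",
         paste(utils::head(unique(probs$row), 10) + 1, collapse = ", "),
         call. = FALSE)
  }
  tab
}

# report validation failures with 1-based file line numbers (header is line 1)
check_rows <- function(tab, path, ...) {
  checks <- list(...)
  msgs <- character(0)
  for (name in names(checks)) {
    bad <- which(checks[[name]])
    if (length(bad) > 0) {
      msgs <- c(msgs, paste0(gsub("_", " ", name), " at line(s) ",
                             paste(utils::head(bad + 1, 10), collapse = ", ")))
    }
  }
  if (length(msgs) > 0) {
    stop("invalid rows in ", path, ": ", paste(msgs, collapse = "; "),
         call. = FALSE)
  }
  invisible(tab)
}

validate_peptide_table <- function(table) {
  required <- c("protein_id", "peptide_id", "group", "log2_intensity",
                "unique_assignment")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("peptide table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("peptide table is empty", call. = FALSE)
  if (any(!is.finite(table$log2_intensity))) {
    stop("peptide table contains non-finite intensities", call. = FALSE)
  }
  invisible(table)
}

validate_phospho_table <- function(table) {
  required <- c("protein_id", "isoform_id", "sites", "run_id", "group",
                "intensity")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("phospho table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("phospho table is empty", call. = FALSE)
  if (any(table$intensity <= 0 | !is.finite(table$intensity))) {
    stop("phospho intensities must be positive and finite", call. = FALSE)
  }
  runs_by_group <- tapply(table$run_id, table$group, function(r) sort(unique(r)))
  if (length(unique(vapply(runs_by_group, paste, character(1), collapse = ","))) != 1) {
    stop("groups carry different technical run sets", call. = FALSE)
  }
  if (length(runs_by_group[[1]]) < 2) {
    stop("at least two technical runs per group are required", call. = FALSE)
  }
  invisible(table)
}
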