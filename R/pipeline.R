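#' Reported benchmark compositions
#'
#' The classification counts printed in the study report — overall
#' phospho-isoform counts, the four per-category tables, and the ECM protein
#' reversal percentages — serve as planted compositions for synthetic
#' benchmark datasets. Each element is a named class-count vector suitable
#' for [planted_spec()] (built with [plant_composition()]).
#'
#' The phospho compositions are (total / affected / back-regulated by DTMP /
#' back-regulated by LR): overall 883/738/559/428, structural 69/56/46/29,
#' adhesion 111/92/75/59, junction 790/664/509/390, signaling
#' 394/325/237/197. The proteomic dataset comprises 186 ECM proteins with
#' 83% of pain-affected proteins reversed by DTMP and 67% by LR-SCS; the
#' affected count itself is not printed, so the proteomic composition plants
#' 100 affected proteins, realizing the stated percentages exactly
#' (83 and 67 reversed).
#'
#' @return Named list of class-count vectors.
#' @export
#' @examples
#' sum(benchmark_compositions()$phospho_overall) # 883
benchmark_compositions <- function() {
  list(
    phospho_overall = plant_composition(883, 738, 559, 428),
    phospho_structural = plant_composition(69, 56, 46, 29),
    phospho_adhesion = plant_composition(111, 92, 75, 59),
    phospho_junction = plant_composition(790, 664, 509, 390),
    phospho_signaling = plant_composition(394, 325, 237, 197),
    proteomic_ecm = plant_composition(186, 100, 83, 67)
  )
}

#' Venn overlap composition of the matrisome categories
#'
#' The reported overlap structure of the three functional classes — 48
#' structural, 112 adhesion/junction, 102 signaling proteins, with 4 in all
#' three classes, 69 shared between the adhesion/junction and signaling
#' classes, and 18 structural proteins co-identified in another class (split
#' 3 with adhesion/junction, 11 with signaling, 4 with both) — expressed as
#' arguments for [generate_annotation()].
#'
#' @return List with `n_structural`, `n_adhesion_junction`, `n_signaling`,
#'   `overlaps`.
#' @export
benchmark_venn_composition <- function() {
  list(
    n_structural = 48, n_adhesion_junction = 112, n_signaling = 102,
    overlaps = c(structural_adhesion_junction = 7, structural_signaling = 15,
                 adhesion_junction_signaling = 69, all_three = 4)
  )
}

#' Write a synthetic dataset plus its ground-truth sidecar
#'
#' Writes the generated table in the pipeline's TSV dialect together with
#' `truth.tsv` (`entity_id`, `planted_class`). Real datasets simply lack the
#' sidecar.
#'
#' @param dataset A `synthetic_dataset` from [generate_phospho_dataset()] or
#'   [generate_proteomic_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, named vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kind <- if ("isoform_id" %in% names(dataset$table)) "phospho" else "peptide"
  paths <- c(table = file.path(dir, paste0(kind, "_table.tsv")),
             truth = file.path(dir, "truth.tsv"))
  write_quant_table(dataset$table, paths[["table"]])
  readr::write_tsv(
    tibble::tibble(entity_id = dataset$truth$entity_id,
                   planted_class = dataset$truth$class),
    paths[["truth"]]
  )
  invisible(paths)
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML key-value file mirroring the [run_pipeline()] config:
#' input paths (`peptide_table`, `phospho_table`, `annotation`), output
#' directory (`out_dir`), and rule parameters (`affected_threshold`,
#' `alpha`, `overshoot_allowed`).
#'
#' @param path Path to a YAML config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Executes normalize, quantify, classify, categorize, and report for
#' whichever branches the configuration provides inputs for: the proteomic
#' branch (peptide table, significance-gated classification) and/or the
#' phospho branch (phospho table, threshold-gated classification). Stage
#' progress is logged to stderr; any validation failure aborts before
#' partial outputs are written.
#'
#' @param config Named list (or path to a YAML file, see
#'   [read_pipeline_config()]) with elements `peptide_table` and/or
#'   `phospho_table`, optional `annotation`, `out_dir` (required), and
#'   optional `affected_threshold`, `alpha`, `overshoot_allowed`, `seed`.
#' @return Invisibly, a named list of per-branch results (`records`,
#'   `summary`, `rollup`, `heatmap`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$out_dir)) stop("config lacks `out_dir`", call. = FALSE)
  if (is.null(config$peptide_table) && is.null(config$phospho_table)) {
    stop("config must name a peptide_table and/or a phospho_table", call. = FALSE)
  }
  cfg <- analysis_config(
    affected_threshold = config$affected_threshold %||% 0.10,
    alpha = config$alpha %||% 0.05,
    overshoot_allowed = config$overshoot_allowed %||% TRUE
  )
  # read everything up front so validation failures leave no partial outputs
  peptides <- phospho <- ann <- NULL
  if (!is.null(config$peptide_table)) {
    log_stage("read", "reading peptide table ", config$peptide_table)
    peptides <- read_peptide_table(config$peptide_table)
  }
  if (!is.null(config$phospho_table)) {
    log_stage("read", "reading phospho table ", config$phospho_table)
    phospho <- read_phospho_table(config$phospho_table)
  }
  if (!is.null(config$annotation)) {
    log_stage("read", "reading annotation ", config$annotation)
    ann <- read_annotation(config$annotation)
  }
  results <- list()
  if (!is.null(peptides)) {
    results$protein <- run_branch(
      quants = quantify_proteins(normalize_channels(peptides)),
      ann = ann, cfg = cfg, seed = config$seed,
      out_dir = file.path(config$out_dir, "protein"),
      heatmap_fun = function(q) encode_protein_heatmap(q, cfg),
      label = "protein"
    )
  }
  if (!is.null(phospho)) {
    results$phospho <- run_branch(
      quants = quantify_phospho(phospho),
      ann = ann, cfg = cfg, seed = config$seed,
      out_dir = file.path(config$out_dir, "phospho"),
      heatmap_fun = encode_phospho_heatmap,
      label = "phospho"
    )
  }
  invisible(results)
}

run_branch <- function(quants, ann, cfg, seed, out_dir, heatmap_fun, label) {
  log_stage("quantify", label, ": ",
            length(unique(quants[[1]])), " entities quantified")
  cls <- classify_dataset(quants, cfg)
  log_stage("classify", label, ": ", cls$summary$n_affected, " of ",
            cls$summary$n_total, " affected")
  rollup <- NULL
  if (!is.null(ann)) {
    roll <- rollup_by_category(cls$records, ann)
    rollup <- roll$rollup
    if (length(roll$unannotated) > 0) {
      log_stage("categorize", label, ": ", length(roll$unannotated),
                " unannotated entities excluded from rollups")
    }
  }
  heatmap <- heatmap_fun(quants)
  paths <- write_summary(out_dir, cls$records, cls$summary, rollup = rollup,
                         heatmap = heatmap, cfg = cfg, seed = seed)
  log_stage("report", label, ": wrote ", length(paths), " files to ", out_dir)
  list(records = cls$records, summary = cls$summary, rollup = rollup,
       heatmap = heatmap, paths = paths)
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}
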