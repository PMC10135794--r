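#' Planted effect classes recognized by the generators
#'
#' Each synthetic entity (protein or phospho-isoform) is assigned one class:
#' unaffected by the pain model, or affected up/down, optionally
#' back-regulated by DTMP, by LR-SCS, or by both. Back-regulation is only
#' defined for affected entities.
#'
#' @return Character vector of the nine class codes.
#' @export
planted_class_codes <- function() {
  c("unaffected",
    "affected_up", "affected_up_rev_DTMP", "affected_up_rev_LR",
    "affected_up_rev_both",
    "affected_down", "affected_down_rev_DTMP", "affected_down_rev_LR",
    "affected_down_rev_both")
}

#' Decode planted class counts into direction and reversal flags
#'
#' @param class_counts Named integer vector over [planted_class_codes()].
#' @return Tibble with columns `class`, `n`, `direction` (`up`/`down`/
#'   `none`), `rev_DTMP`, `rev_LR`.
#' @export
#' @examples
#' decode_class_counts(plant_composition(10, 6, 4, 2))
decode_class_counts <- function(class_counts) {
  dec <- decode_class(names(class_counts))
  dec$n <- as.integer(class_counts)
  dec[, c("class", "n", "direction", "rev_DTMP", "rev_LR")]
}

# decode a class code into direction / reversal flags
decode_class <- function(class) {
  tibble::tibble(
    class = class,
    direction = dplyr::case_when(
      grepl("^affected_up", class) ~ "up",
      grepl("^affected_down", class) ~ "down",
      TRUE ~ "none"
    ),
    rev_DTMP = grepl("rev_DTMP$|rev_both$", class),
    rev_LR = grepl("rev_LR$|rev_both$", class)
  )
}

#' Build planted class counts from marginal composition counts
#'
#' Converts a reported composition — total entities, entities affected by
#' the pain model, and affected entities back-regulated by each treatment —
#' into per-class counts. The two back-regulated sets are nested maximally
#' (every entity reversed by the scarcer treatment is also reversed by the
#' other), which is always feasible, and each cell is split between up- and
#' down-regulated classes by `prop_up`.
#'
#' @param n_total,n_affected,n_backreg_dtmp,n_backreg_lr Marginal counts.
#' @param prop_up Fraction of each affected cell planted as upregulated.
#' @return Named integer vector over [planted_class_codes()].
#' @export
#' @examples
#' plant_composition(883, 738, 559, 428)
plant_composition <- function(n_total, n_affected, n_backreg_dtmp,
                              n_backreg_lr, prop_up = 0.5) {
  stopifnot(n_total >= n_affected, n_affected >= n_backreg_dtmp,
            n_affected >= n_backreg_lr, n_backreg_dtmp >= 0, n_backreg_lr >= 0)
  both <- min(n_backreg_dtmp, n_backreg_lr)
  d_only <- n_backreg_dtmp - both
  l_only <- n_backreg_lr - both
  none <- n_affected - both - d_only - l_only
  split_ud <- function(n) {
    up <- as.integer(round_half_up(n * prop_up))
    c(up = up, down = n - up)
  }
  counts <- c(unaffected = n_total - n_affected)
  for (cell in list(c("", none), c("_rev_DTMP", d_only), c("_rev_LR", l_only),
                    c("_rev_both", both))) {
    ud <- split_ud(as.integer(cell[2]))
    counts[paste0("affected_up", cell[1])] <- ud[["up"]]
    counts[paste0("affected_down", cell[1])] <- ud[["down"]]
  }
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  counts
}

#' Specification of a synthetic dataset with planted ground truth
#'
#' Collects the free parameters of the generators. Planted linear ratios sit
#' a multiplicative `margin` beyond the 10% decision boundary: upregulated
#' entities get a pain ratio of `1.10 * (1 + margin)` and downregulated ones
#' `0.90 / (1 + margin)`, so both fall strictly on the affected side for any
#' `margin > 0`; back-regulating treatments apply the same placement in the
#' opposite direction, while non-planted treatment effects are exactly null.
#' Measurement noise is multiplicative log-normal: each observed intensity is
#' the planted abundance times `2^e`, `e ~ Normal(0, noise_sd)`.
#'
#' For proteomic data, `scatter_sd` sets a deterministic peptide-by-channel
#' response heterogeneity (a fixed, exactly centered pattern across a
#' protein's peptides, scaled per channel) that gives the one-sample t-test a
#' nonzero denominator even when `noise_sd = 0`; planted shifts are
#' calibrated against it (see [generate_proteomic_dataset()]).
#'
#' @param class_counts Named integer vector over [planted_class_codes()]
#'   (see [plant_composition()]).
#' @param margin Fraction > 0; how far planted ratios sit beyond the 0.10
#'   boundary (default 0.05).
#' @param noise_sd Log2-scale standard deviation of multiplicative noise per
#'   peptide/run measurement (default 0 = noiseless).
#' @param scatter_sd Log2-scale standard deviation of the deterministic
#'   peptide response heterogeneity (proteomic only; default 0.1).
#' @param peptides_per_protein Integer range (length 2) for peptides per
#'   protein; lower bound must be >= 2 when any affected class is planted.
#' @param isoforms_per_protein Integer range for phospho-isoforms per parent
#'   protein (default 4..15).
#' @param n_runs Technical runs per group, phospho only (default 2).
#' @param alpha Significance level the proteomic shift calibration targets
#'   (default 0.05).
#' @param pain_shift_log2 Optional fixed log2 pain-contrast shift for
#'   affected proteins, overriding the calibrated shift (proteomic only).
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(class_counts, margin = 0.05, noise_sd = 0,
                         scatter_sd = 0.1,
                         peptides_per_protein = c(4L, 10L),
                         isoforms_per_protein = c(4L, 15L),
                         n_runs = 2L, alpha = 0.05,
                         pain_shift_log2 = NULL, seed = 1L) {
  if (is.null(names(class_counts)) ||
      !all(names(class_counts) %in% planted_class_codes())) {
    stop("class_counts must be named with planted class codes; see ",
         "planted_class_codes()", call. = FALSE)
  }
  if (anyDuplicated(names(class_counts))) {
    stop("duplicated class code in class_counts", call. = FALSE)
  }
  if (any(class_counts < 0) || any(class_counts != round(class_counts))) {
    stop("class_counts must be nonnegative integers", call. = FALSE)
  }
  stopifnot(margin > 0, noise_sd >= 0, scatter_sd >= 0, n_runs >= 2,
            length(peptides_per_protein) == 2,
            peptides_per_protein[1] <= peptides_per_protein[2],
            length(isoforms_per_protein) == 2,
            isoforms_per_protein[1] >= 1,
            isoforms_per_protein[1] <= isoforms_per_protein[2])
  n_affected <- sum(class_counts[names(class_counts) != "unaffected"])
  if (n_affected > 0 && peptides_per_protein[1] < 2) {
    stop("peptides_per_protein lower bound must be >= 2 when affected ",
         "classes are planted (the t-test needs replication)", call. = FALSE)
  }
  structure(
    list(class_counts = class_counts, n_entities = sum(class_counts),
         margin = margin, noise_sd = noise_sd, scatter_sd = scatter_sd,
         peptides_per_protein = as.integer(peptides_per_protein),
         isoforms_per_protein = as.integer(isoforms_per_protein),
         n_runs = as.integer(n_runs), alpha = alpha,
         pain_shift_log2 = pain_shift_log2, seed = as.integer(seed)),
    class = "planted_spec"
  )
}

# planted linear ratios for direction x threshold placement; `sign` is +1 for
# a change up, -1 for down. Up ratios sit at (1+thr)(1+margin), down ratios at
# (1-thr)/(1+margin); both are beyond the |r-1| >= thr boundary for margin > 0
planted_ratio <- function(sign, margin, thr = 0.10) {
  ifelse(sign > 0, (1 + thr) * (1 + margin),
         ifelse(sign < 0, (1 - thr) / (1 + margin), 1))
}

# expand class counts into a per-entity truth table, in canonical class
# order (independent of the seed so truth labels never vary with it)
expand_truth <- function(spec, prefix) {
  codes <- intersect(planted_class_codes(), names(spec$class_counts))
  class <- rep(codes, times = spec$class_counts[codes])
  n <- length(class)
  tibble::tibble(
    entity_id = sprintf("%s%05d", prefix, seq_len(n)),
    class = class
  )
}

#' Generate a synthetic phospho-isoform dataset with planted truth
#'
#' Emulates the pooled phosphoproteomic design: one pooled channel per group,
#' each measured in `n_runs` technical runs. Group-level abundances are
#' placed so the pain-contrast ratio (NoSCS/NoSNI) and the treatment ratios
#' (DTMP/NoSCS, LRSCS/NoSCS) realize each isoform's planted class at a
#' `margin` beyond the 10% boundary (see [planted_spec()]); per-run
#' intensities add multiplicative log-normal noise. Isoforms are grouped into
#' parent proteins for category rollups and top-isoform selection.
#'
#' @param spec A [planted_spec()].
#' @return A list of class `synthetic_dataset` with elements `table` (a
#'   phospho table, see [quantify_phospho()]), `truth` (tibble `entity_id`,
#'   `class`), and `spec`.
#' @export
generate_phospho_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  truth <- expand_truth(spec, "ISO")
  n <- nrow(truth)
  if (n == 0) stop("spec plants no entities", call. = FALSE)
  dec <- decode_class(truth$class)
  pain_sign <- ifelse(dec$direction == "up", 1, ifelse(dec$direction == "down", -1, 0))
  r_pain <- planted_ratio(pain_sign, spec$margin)
  r_dtmp <- ifelse(dec$rev_DTMP, planted_ratio(-pain_sign, spec$margin), 1)
  r_lr <- ifelse(dec$rev_LR, planted_ratio(-pain_sign, spec$margin), 1)

  withr::with_seed(spec$seed, {
    # parent proteins: consecutive blocks of isoforms
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample_range(spec$isoforms_per_protein[1],
                                     spec$isoforms_per_protein[2], 1))
    }
    protein_idx <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
    protein_id <- sprintf("PPROT%04d", protein_idx)
    sites <- random_sites(n)
    base <- 2^stats::rnorm(n, mean = 17, sd = 1.5)
    abund <- cbind(NoSNI = base, NoSCS = base * r_pain,
                   DTMP = base * r_pain * r_dtmp,
                   LRSCS = base * r_pain * r_lr)
    runs <- sprintf("R%d", seq_len(spec$n_runs))
    grid <- expand.grid(i = seq_len(n), run_id = runs,
                        group = group_labels(), stringsAsFactors = FALSE)
    eps <- if (spec$noise_sd > 0) stats::rnorm(nrow(grid), 0, spec$noise_sd) else 0
    table <- tibble::tibble(
      protein_id = protein_id[grid$i],
      isoform_id = truth$entity_id[grid$i],
      sites = sites[grid$i],
      run_id = grid$run_id,
      group = grid$group,
      intensity = abund[cbind(grid$i, match(grid$group, colnames(abund)))] * 2^eps
    )
  })
  table <- dplyr::arrange(table, .data$isoform_id, .data$group, .data$run_id)
  structure(list(table = table, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

# uniform draw from lo..hi, safe when lo == hi (unlike sample(seq(lo, hi)))
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
}

# plausible phospho-site strings like "S1126" or "S33;T48"
random_sites <- function(n) {
  n_sites <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  vapply(n_sites, function(k) {
    pos <- sort(sample(1:1500, k))
    res <- sample(c("S", "T", "Y"), k, replace = TRUE, prob = c(0.8, 0.15, 0.05))
    paste0(res, pos, collapse = ";")
  }, character(1))
}

#' Generate a synthetic peptide-level proteomic dataset with planted truth
#'
#' Emulates the pooled proteomic design: each protein is measured through
#' `k` uniquely assigned peptides (k drawn from `peptides_per_protein`),
#' with one pooled channel per group. A protein planted as affected receives
#' a common log2 shift between the relevant groups; the shift is calibrated
#' so the one-sample t-test on peptide-level ratios is significant at the
#' spec's `alpha` given the deterministic peptide response heterogeneity and
#' the noise level:
#' `shift = t_crit * sd_delta / sqrt(k) * (1 + margin)`, where `sd_delta` is
#' the standard deviation of the per-peptide log2 ratios implied by
#' `scatter_sd` and `noise_sd`. Unaffected contrasts have exactly zero shift,
#' so with `noise_sd = 0` their peptide ratios average exactly to zero and
#' the t-statistic vanishes.
#'
#' @param spec A [planted_spec()].
#' @return A list of class `synthetic_dataset` with elements `table` (a
#'   peptide table, see [quantify_proteins()]), `truth`, and `spec`.
#' @export
generate_proteomic_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  truth <- expand_truth(spec, "PROT")
  n <- nrow(truth)
  if (n == 0) stop("spec plants no entities", call. = FALSE)
  dec <- decode_class(truth$class)
  pain_sign <- ifelse(dec$direction == "up", 1, ifelse(dec$direction == "down", -1, 0))

  # fixed per-channel coefficients of the deterministic peptide response
  # pattern; differences are nonzero for all three contrasts so every
  # contrast's t-test has a positive denominator
  coefs <- c(NoSNI = 0, NoSCS = 1, DTMP = 2, LRSCS = -1)
  coef_diff <- c(pain = 1, DTMP = 1, LR = 2) # |coef(num) - coef(den)|

  withr::with_seed(spec$seed, {
    k <- sample_range(spec$peptides_per_protein[1], spec$peptides_per_protein[2], n)
    base <- stats::rnorm(n, mean = 17, sd = 1.5)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ki <- k[i]
      # exactly centered unit-sd pattern across this protein's peptides
      z <- if (ki >= 2) as.numeric(scale(seq_len(ki))) else 0
      sd_delta <- sqrt((coef_diff * spec$scatter_sd)^2 + 2 * spec$noise_sd^2)
      tcrit <- stats::qt(1 - spec$alpha / 2, df = max(ki - 1, 1))
      shift <- tcrit * sd_delta / sqrt(ki) * (1 + spec$margin)
      d_pain <- if (pain_sign[i] == 0) 0 else
        pain_sign[i] * (spec$pain_shift_log2 %||% shift[["pain"]])
      d_dtmp <- if (dec$rev_DTMP[i]) -pain_sign[i] * shift[["DTMP"]] else 0
      d_lr <- if (dec$rev_LR[i]) -pain_sign[i] * shift[["LR"]] else 0
      level <- c(NoSNI = 0, NoSCS = d_pain, DTMP = d_pain + d_dtmp,
                 LRSCS = d_pain + d_lr)
      pep_off <- stats::rnorm(ki, 0, 1)
      grid <- expand.grid(pep = seq_len(ki), group = group_labels(),
                          stringsAsFactors = FALSE)
      eps <- if (spec$noise_sd > 0) stats::rnorm(nrow(grid), 0, spec$noise_sd) else 0
      rows[[i]] <- tibble::tibble(
        protein_id = truth$entity_id[i],
        peptide_id = sprintf("%s_pep%02d", truth$entity_id[i], grid$pep),
        group = grid$group,
        log2_intensity = base[i] + pep_off[grid$pep] + level[grid$group] +
          coefs[grid$group] * spec$scatter_sd * z[grid$pep] + eps,
        unique_assignment = TRUE
      )
    }
  })
  table <- dplyr::bind_rows(rows)
  table <- dplyr::arrange(table, .data$protein_id, .data$peptide_id, .data$group)
  structure(list(table = table, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' Generate a category annotation realizing requested Venn overlaps
#'
#' Builds a protein-to-category annotation whose three Venn classes —
#' structural, adhesion/junction (members split between the `adhesion` and
#' `junction` labels), and signaling — have exactly the requested sizes,
#' pairwise intersections, and triple intersection.
#'
#' @param n_structural,n_adhesion_junction,n_signaling Group sizes.
#' @param overlaps Named numeric vector with elements
#'   `structural_adhesion_junction`, `structural_signaling`,
#'   `adhesion_junction_signaling` (pairwise intersections, triple included)
#'   and `all_three`.
#' @param seed Integer seed (controls the adhesion/junction label split).
#' @return Annotation tibble with columns `protein_id`, `category`, `source`
#'   (one row per protein-category membership).
#' @export
#' @examples
#' ann <- generate_annotation(10, 10, 10,
#'   overlaps = c(structural_adhesion_junction = 2, structural_signaling = 2,
#'                adhesion_junction_signaling = 2, all_three = 1))
#' venn_counts(ann)$triple
generate_annotation <- function(n_structural, n_adhesion_junction, n_signaling,
                                overlaps, seed = 1L) {
  needed <- c("structural_adhesion_junction", "structural_signaling",
              "adhesion_junction_signaling", "all_three")
  if (!all(needed %in% names(overlaps))) {
    stop("overlaps must contain: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  ab <- overlaps[["structural_adhesion_junction"]]
  ac <- overlaps[["structural_signaling"]]
  bc <- overlaps[["adhesion_junction_signaling"]]
  abc <- overlaps[["all_three"]]
  region <- c(
    abc = abc, ab_only = ab - abc, ac_only = ac - abc, bc_only = bc - abc,
    a_only = n_structural - ab - ac + abc,
    b_only = n_adhesion_junction - ab - bc + abc,
    c_only = n_signaling - ac - bc + abc
  )
  if (any(region < 0) || any(region != round(region))) {
    stop("infeasible overlap specification (negative Venn region)", call. = FALSE)
  }
  membership <- list(
    abc = c("A", "B", "C"), ab_only = c("A", "B"), ac_only = c("A", "C"),
    bc_only = c("B", "C"), a_only = "A", b_only = "B", c_only = "C"
  )
  groups <- rep(names(region), times = region)
  n <- length(groups)
  ids <- sprintf("ANN%04d", seq_len(n))
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      memb <- membership[[groups[i]]]
      cats <- character(0)
      if ("A" %in% memb) cats <- c(cats, "structural")
      if ("B" %in% memb) {
        # combined adhesion/junction class: members carry one of the two
        # labels (junction-weighted, as junction proteins dominate the class)
        cats <- c(cats, sample(c("adhesion", "junction"), 1, prob = c(0.2, 0.8)))
      }
      if ("C" %in% memb) cats <- c(cats, "signaling")
      tibble::tibble(protein_id = ids[i], category = cats, source = "ontology")
    })
  })
  dplyr::bind_rows(rows)
}
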