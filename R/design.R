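#' Experimental groups of the four-arm pooled design
#'
#' The design has one pooled TMT channel per experimental arm: uninjured
#' controls (`NoSNI`), injured untreated animals (`NoSCS`), and injured
#' animals treated with differential target multiplexed programming (`DTMP`)
#' or conventional low-rate stimulation (`LRSCS`).
#'
#' @return Character vector of the four group labels, in canonical order.
#' @export
#' @examples
#' group_labels()
group_labels <- function() {
  c("NoSNI", "NoSCS", "DTMP", "LRSCS")
}

#' Canonical contrasts of the injury/treatment design
#'
#' Three ratios carry the analysis: the pain-model effect (untreated injured
#' over uninjured) and the two treatment effects (each therapy over untreated
#' injured).
#'
#' @return A tibble with columns `contrast`, `numerator`, `denominator`.
#' @export
#' @examples
#' canonical_contrasts()
canonical_contrasts <- function() {
  tibble::tibble(
    contrast    = c("pain", "DTMP", "LR"),
    numerator   = c("NoSCS", "DTMP", "LRSCS"),
    denominator = c("NoSNI", "NoSCS", "NoSCS")
  )
}

#' Matrisome functional categories
#'
#' @return Character vector of the four recognized category labels.
#' @export
matrisome_categories <- function() {
  c("structural", "adhesion", "junction", "signaling")
}

#' Analysis configuration
#'
#' Bundles the decision-rule parameters: the fractional change threshold used
#' for phospho-isoform calls (a linear ratio at least `affected_threshold`
#' away from 1), the significance level used for protein calls, and whether a
#' treatment reversal that overshoots past uninjured levels still counts as
#' back-regulation.
#'
#' @param affected_threshold Fractional change on the linear ratio scale
#'   (default 0.10, i.e. a ratio outside \[0.90, 1.10\]).
#' @param alpha Two-tailed significance level for protein-level calls
#'   (default 0.05).
#' @param overshoot_allowed If `TRUE` (default) a reversal larger than the
#'   original pain-model change still counts as back-regulation.
#' @return A list of class `analysis_config`.
#' @export
#' @examples
#' analysis_config()
#' analysis_config(affected_threshold = 0.2)
analysis_config <- function(affected_threshold = 0.10, alpha = 0.05,
                            overshoot_allowed = TRUE) {
  stopifnot(is.numeric(affected_threshold), length(affected_threshold) == 1,
            is.numeric(alpha), length(alpha) == 1,
            is.logical(overshoot_allowed), length(overshoot_allowed) == 1)
  if (!(affected_threshold > 0 && affected_threshold < 1)) {
    stop("`affected_threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(affected_threshold = affected_threshold, alpha = alpha,
         overshoot_allowed = overshoot_allowed),
    class = "analysis_config"
  )
}

# round-half-up at `digits` decimals; base round() is round-half-even, which
# does not reproduce printed values like 82% from 81.5
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  floor(x * pow + 0.5) / pow
}

`%||%` <- function(a, b) if (is.null(a)) b else a
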