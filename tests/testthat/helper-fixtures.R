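# fixture builders: all synthetic, generated in code at test time

# peptide table from named list group -> per-peptide log2 intensities
make_peptide_table <- function(intensities, protein_id = "P1",
                               unique_assignment = TRUE) {
  k <- length(intensities[[1]])
  dplyr::bind_rows(lapply(names(intensities), function(g) {
    tibble::tibble(
      protein_id = protein_id,
      peptide_id = sprintf("pep%02d", seq_len(k)),
      group = g,
      log2_intensity = intensities[[g]],
      unique_assignment = unique_assignment
    )
  }))
}

# phospho table from named list group -> per-run linear intensities
make_phospho_table <- function(intensities, isoform_id = "I1",
                               protein_id = "P1", sites = "S10") {
  dplyr::bind_rows(lapply(names(intensities), function(g) {
    v <- intensities[[g]]
    tibble::tibble(
      protein_id = protein_id, isoform_id = isoform_id, sites = sites,
      run_id = sprintf("R%d", seq_along(v)), group = g, intensity = v
    )
  }))
}

# phospho quant rows for one isoform from its three linear ratios
make_phospho_quant <- function(pain, DTMP, LR, isoform_id = "I1",
                               protein_id = "P1", cv = 0) {
  r <- c(pain = pain, DTMP = DTMP, LR = LR)
  tibble::tibble(
    isoform_id = isoform_id, protein_id = protein_id,
    contrast = names(r), log2_fc = unname(log2(r)), linear_ratio = unname(r),
    percent_change = unname(100 * (r - 1)), cv_fc = cv
  )
}

# protein quant rows from log2 fold changes and p-values
make_protein_quant <- function(fc, p, protein_id = "P1", n_peptides = 5L) {
  tibble::tibble(
    protein_id = protein_id, contrast = names(fc), log2_fc = unname(fc),
    linear_ratio = 2^unname(fc), percent_change = 100 * (2^unname(fc) - 1),
    p_value = unname(p[names(fc)]), n_peptides = n_peptides
  )
}

# random phospho quant table of n isoforms; ratios include values at and
# around the 10% decision boundary
random_phospho_quants <- function(n, seed) {
  withr::with_seed(seed, {
    pool <- c(stats::runif(7 * n, 0.5, 2.0),
              rep(c(0.90, 1.10, 1.0), length.out = 2 * n))
    ratios <- matrix(sample(pool, 3 * n), ncol = 3)
  })
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_phospho_quant(ratios[i, 1], ratios[i, 2], ratios[i, 3],
                       isoform_id = sprintf("I%04d", i),
                       protein_id = sprintf("P%03d", (i - 1) %/% 4 + 1))
  }))
}

# independent brute-force evaluation of the phospho decision rules, written
# directly from the rule statement (oracle for classify_dataset)
brute_phospho_rules <- function(r_pain, r_trt, thr = 0.10) {
  # rounding keeps the inclusive boundary exact under floating point
  # (|0.90 - 1| must count as a 10% change)
  affected <- round(abs(r_pain - 1), 9) >= thr
  list(
    affected = affected,
    backreg = affected & round(abs(r_trt - 1), 9) >= thr &
      sign(r_trt - 1) == -sign(r_pain - 1)
  )
}
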