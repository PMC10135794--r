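test_that("median centering aligns group medians and is idempotent and shift-invariant", {
  tab <- make_peptide_table(list(
    NoSNI = c(9, 10, 11), NoSCS = c(11, 12, 13),
    DTMP = c(10, 11, 12), LRSCS = c(10.5, 11, 11.5)
  ))
  norm <- normalize_channels(tab)
  med <- tapply(norm$log2_intensity, norm$group, median)
  # group medians {10, 12, 11, 11} -> offsets {+1, -1, 0, 0}, target 11
  expect_equal(as.numeric(med[group_labels()]), rep(11, 4))
  expect_equal(norm$log2_intensity[norm$group == "NoSNI"], c(10, 11, 12))

  # idempotence on already-aligned data
  expect_equal(normalize_channels(norm)$log2_intensity, norm$log2_intensity,
               tolerance = 1e-12)

  # constant per-group shift is removed exactly
  shifted <- tab
  shifted$log2_intensity[shifted$group == "NoSCS"] <-
    shifted$log2_intensity[shifted$group == "NoSCS"] + 3.7
  expect_equal(normalize_channels(shifted)$log2_intensity,
               norm$log2_intensity, tolerance = 1e-12)
})

test_that("normalize_channels rejects tables with an empty group", {
  tab <- make_peptide_table(list(NoSNI = c(10, 11), NoSCS = c(10, 11),
                                 DTMP = c(10, 11)))
  expect_error(normalize_channels(tab), "LRSCS")
})

test_that("protein fold change averages peptide-level log2 ratios", {
  base <- c(20, 21, 22)
  tab <- make_peptide_table(list(
    NoSNI = base, NoSCS = base + c(0.5, 0.7, 0.6),
    DTMP = base, LRSCS = base
  ))
  pain <- canonical_contrasts()[1, ]
  q <- protein_fold_change(tab, "P1", pain)
  expect_equal(q$log2_fc, 0.6)
  expect_equal(q$linear_ratio, 2^0.6, tolerance = 1e-12)
  expect_equal(q$n_peptides, 3L)

  # identical intensities -> zero fold change, unit ratio
  same <- make_peptide_table(list(NoSNI = base, NoSCS = base,
                                  DTMP = base, LRSCS = base))
  q0 <- protein_fold_change(same, "P1", pain)
  expect_equal(q0$log2_fc, 0)
  expect_equal(q0$linear_ratio, 1)
})

test_that("non-unique peptides are excluded from quantification", {
  base <- c(20, 21, 22, 23)
  tab <- make_peptide_table(list(
    NoSNI = base, NoSCS = base + 0.5, DTMP = base, LRSCS = base
  ))
  tab$unique_assignment[tab$peptide_id == "pep04"] <- FALSE
  q <- protein_fold_change(tab, "P1", canonical_contrasts()[1, ])
  expect_equal(q$n_peptides, 3L)
  q_all <- quantify_proteins(tab)
  expect_true(all(q_all$n_peptides == 3L))
})

test_that("one-sample t-test matches frozen values and contracts", {
  p <- protein_t_test(c(0.2, 0.3, 0.25, 0.15))
  expect_equal(p, 0.00607, tolerance = 1e-2)
  # deltas symmetric about zero: t = 0, p = 1
  expect_equal(protein_t_test(c(-0.4, 0.4)), 1)
  # single delta: untestable, not significant
  expect_true(is.na(protein_t_test(0.3)))
  # zero variance: untestable
  expect_true(is.na(protein_t_test(c(0.2, 0.2, 0.2))))
  expect_error(protein_t_test(numeric(0)), "no peptide")
})

test_that("t-test agrees with the reference implementation on random vectors", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      n <- sample(2:12, 1)
      deltas <- stats::rnorm(n, mean = stats::runif(1, -0.5, 0.5), sd = 0.2)
      expect_equal(protein_t_test(deltas), stats::t.test(deltas)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("CV propagation follows the root-sum-of-squares form", {
  expect_equal(propagate_cv(0.03, 0.04), 0.05)
  expect_equal(propagate_cv(0, 0.17), 0.17)
  expect_equal(propagate_cv(0.10, 0.10), sqrt(0.02), tolerance = 1e-12)
  expect_error(propagate_cv(-0.1, 0.1), "nonnegative")
  # symmetry, monotonicity, and dominance over each argument
  withr::with_seed(7, {
    a <- stats::runif(200, 0, 0.5); b <- stats::runif(200, 0, 0.5)
    expect_equal(propagate_cv(a, b), propagate_cv(b, a))
    expect_true(all(propagate_cv(a, b) >= pmax(a, b)))
    expect_true(all(propagate_cv(a + 0.01, b) > propagate_cv(a, b)))
  })
})

test_that("percent change converts the log2 scale to the rule scale", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(1), 100)
  expect_equal(percent_change(-0.152003), -10.0, tolerance = 1e-3)
  expect_error(percent_change(Inf), "finite")
})

test_that("phospho fold change pairs runs and propagates duplicate CVs", {
  # run ratios 1.2 and 1.3: mean log2 ratio = 0.320768, linear 1.24900
  tab <- make_phospho_table(list(
    NoSNI = c(100, 100), NoSCS = c(120, 130),
    DTMP = c(120, 130), LRSCS = c(120, 130)
  ))
  q <- phospho_fold_change(tab, "I1", canonical_contrasts()[1, ])
  expect_equal(q$log2_fc, mean(log2(c(1.2, 1.3))), tolerance = 1e-12)
  expect_equal(q$log2_fc, 0.320773, tolerance = 1e-6)
  expect_equal(q$linear_ratio, 1.24900, tolerance = 1e-5)
  # duplicate intensities {100, 120}: CV = sd/mean = 0.128565 (n-1 sd)
  cv_num <- sd(c(120, 130)) / mean(c(120, 130))
  cv_den <- sd(c(100, 100)) / mean(c(100, 100))
  expect_equal(sd(c(100, 120)) / mean(c(100, 120)), 0.128565, tolerance = 1e-5)
  expect_equal(q$cv_fc, sqrt(cv_num^2 + cv_den^2), tolerance = 1e-12)

  # identical runs across groups: zero fold change, zero CV
  flat <- make_phospho_table(list(NoSNI = c(100, 100), NoSCS = c(100, 100),
                                  DTMP = c(100, 100), LRSCS = c(100, 100)))
  q0 <- phospho_fold_change(flat, "I1", canonical_contrasts()[1, ])
  expect_equal(q0$log2_fc, 0)
  expect_equal(q0$cv_fc, 0)
})

test_that("quantify_phospho matches the single-isoform operation", {
  ds <- generate_phospho_dataset(planted_spec(
    plant_composition(12, 8, 5, 3), noise_sd = 0.1, seed = 3
  ))
  bulk <- quantify_phospho(ds$table)
  for (iso in unique(ds$table$isoform_id)[1:5]) {
    for (i in 1:3) {
      ctr <- canonical_contrasts()[i, ]
      single <- phospho_fold_change(ds$table, iso, ctr)
      row <- bulk[bulk$isoform_id == iso & bulk$contrast == ctr$contrast, ]
      expect_equal(row$log2_fc, single$log2_fc, tolerance = 1e-12)
      expect_equal(row$cv_fc, single$cv_fc, tolerance = 1e-12)
    }
  }
})

test_that("fold changes are antisymmetric under contrast reversal", {
  ds <- generate_phospho_dataset(planted_spec(
    plant_composition(10, 6, 4, 2), noise_sd = 0.2, seed = 11
  ))
  fwd <- canonical_contrasts()[1, ]
  rev <- tibble::tibble(contrast = "rev", numerator = fwd$denominator,
                        denominator = fwd$numerator)
  for (iso in unique(ds$table$isoform_id)[1:4]) {
    expect_equal(phospho_fold_change(ds$table, iso, fwd)$log2_fc,
                 -phospho_fold_change(ds$table, iso, rev)$log2_fc,
                 tolerance = 1e-12)
  }

  pt <- generate_proteomic_dataset(planted_spec(
    plant_composition(6, 3, 2, 1), noise_sd = 0.1, seed = 11
  ))
  for (prot in unique(pt$table$protein_id)[1:3]) {
    expect_equal(protein_fold_change(pt$table, prot, fwd)$log2_fc,
                 -protein_fold_change(pt$table, prot, rev)$log2_fc,
                 tolerance = 1e-12)
  }
})
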