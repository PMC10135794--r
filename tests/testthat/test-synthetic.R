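test_that("planted spec validates its inputs", {
  expect_error(planted_spec(c(5, 5)), "named")
  expect_error(planted_spec(c(unaffected = 5, bogus_class = 2)), "class code")
  expect_error(planted_spec(c(unaffected = -1)), "nonnegative")
  expect_error(planted_spec(c(unaffected = 5), margin = 0))
  expect_error(planted_spec(c(unaffected = 5), noise_sd = -0.1))
  expect_error(planted_spec(c(affected_up = 2), peptides_per_protein = c(1, 5)),
               "t-test needs replication")
  # single-peptide proteins are allowed when nothing is planted affected
  expect_s3_class(planted_spec(c(unaffected = 3), peptides_per_protein = c(1, 3)),
                  "planted_spec")
})

test_that("plant_composition realizes marginal counts with nested reversal sets", {
  cc <- plant_composition(883, 738, 559, 428)
  expect_equal(sum(cc), 883)
  dec <- decode_class_counts(cc)
  expect_equal(sum(dec$n[dec$direction != "none"]), 738)
  expect_equal(sum(dec$n[dec$rev_DTMP]), 559)
  expect_equal(sum(dec$n[dec$rev_LR]), 428)
  expect_error(plant_composition(10, 12, 0, 0))
  expect_error(plant_composition(10, 5, 6, 0))
})

test_that("same spec and seed give identical tables; seeds move noise, not truth", {
  spec <- planted_spec(plant_composition(20, 12, 8, 5), noise_sd = 0.1, seed = 42)
  a <- generate_phospho_dataset(spec)
  b <- generate_phospho_dataset(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)

  spec2 <- planted_spec(plant_composition(20, 12, 8, 5), noise_sd = 0.1, seed = 43)
  c <- generate_phospho_dataset(spec2)
  expect_identical(a$truth, c$truth)
  expect_false(isTRUE(all.equal(a$table$intensity, c$table$intensity)))

  pa <- generate_proteomic_dataset(spec)
  pb <- generate_proteomic_dataset(spec)
  expect_identical(pa$table, pb$table)
})

test_that("noiseless phospho datasets round-trip exactly through quant + classify", {
  # property over compositions and margins, including a margin small enough
  # to expose misplacement of down-regulated ratios
  cases <- list(
    list(cc = plant_composition(40, 30, 20, 10), margin = 0.01),
    list(cc = plant_composition(40, 30, 20, 10), margin = 0.30),
    list(cc = plant_composition(25, 25, 25, 25), margin = 0.05),
    list(cc = c(unaffected = 10L), margin = 0.05)
  )
  for (case in cases) {
    ds <- generate_phospho_dataset(planted_spec(case$cc, margin = case$margin,
                                                noise_sd = 0, seed = 1))
    cls <- classify_dataset(quantify_phospho(ds$table))
    dec <- decode_class_counts(case$cc)
    expect_equal(cls$summary$n_affected, sum(dec$n[dec$direction != "none"]))
    expect_equal(cls$summary$n_backreg_DTMP, sum(dec$n[dec$rev_DTMP]))
    expect_equal(cls$summary$n_backreg_LR, sum(dec$n[dec$rev_LR]))
    # per-entity agreement with the planted class, not just totals
    joined <- merge(cls$records, ds$truth, by.x = "entity_id", by.y = "entity_id")
    expect_equal(joined$affected, grepl("^affected", joined$class))
    expect_equal(joined$backreg_DTMP, grepl("rev_DTMP$|rev_both$", joined$class))
    expect_equal(joined$backreg_LR, grepl("rev_LR$|rev_both$", joined$class))
  }
})

test_that("all-unaffected noiseless phospho data has unit ratios everywhere", {
  ds <- generate_phospho_dataset(planted_spec(c(unaffected = 15L), seed = 2))
  q <- quantify_phospho(ds$table)
  expect_equal(q$linear_ratio, rep(1, nrow(q)))
  expect_equal(classify_dataset(q)$summary$n_affected, 0L)
})

test_that("noiseless proteomic datasets round-trip exactly through quant + classify", {
  cc <- plant_composition(30, 18, 12, 9)
  ds <- generate_proteomic_dataset(planted_spec(cc, noise_sd = 0, seed = 4))
  cls <- classify_dataset(quantify_proteins(ds$table))
  dec <- decode_class_counts(cc)
  expect_equal(cls$summary$n_affected, sum(dec$n[dec$direction != "none"]))
  expect_equal(cls$summary$n_backreg_DTMP, sum(dec$n[dec$rev_DTMP]))
  expect_equal(cls$summary$n_backreg_LR, sum(dec$n[dec$rev_LR]))
  joined <- merge(cls$records, ds$truth, by = "entity_id")
  expect_equal(joined$affected, grepl("^affected", joined$class))
  expect_equal(joined$backreg_DTMP, grepl("rev_DTMP$|rev_both$", joined$class))
  expect_equal(joined$backreg_LR, grepl("rev_LR$|rev_both$", joined$class))
})

test_that("an unaffected protein has exactly zero fold change in all contrasts", {
  ds <- generate_proteomic_dataset(planted_spec(c(unaffected = 1L), noise_sd = 0,
                                                seed = 6))
  q <- quantify_proteins(ds$table)
  expect_equal(q$log2_fc, rep(0, 3))
  # and p = 1 exactly: peptide ratios are a centered pattern
  expect_equal(q$p_value, rep(1, 3))
})

test_that("planted proteomic shifts are detected at the Monte-Carlo oracle rate", {
  # fixed shift 1.0 log2, k = 6 peptides, noise_sd = 0.1: detection across
  # generator seeds must match one-sample t-test power simulated directly
  n_seeds <- 200
  detected <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    ds <- generate_proteomic_dataset(planted_spec(
      c(affected_up = 1L), noise_sd = 0.1, peptides_per_protein = c(6, 6),
      pain_shift_log2 = 1.0, seed = s
    ))
    q <- quantify_proteins(ds$table)
    p <- q$p_value[q$contrast == "pain"]
    detected[s] <- !is.na(p) && p < 0.05 && q$log2_fc[q$contrast == "pain"] > 0
  }
  # independent oracle: simulate the generator's delta distribution directly
  z <- as.numeric(scale(1:6))
  power <- withr::with_seed(999, mean(replicate(1000, {
    deltas <- 1.0 + 0.1 * z + stats::rnorm(6, 0, 0.1 * sqrt(2))
    stats::t.test(deltas)$p.value < 0.05
  })))
  expect_gte(power, 0.99)
  expect_gte(mean(detected), 0.99)
})

test_that("noisy phospho recovery stays within two points of the planted fraction", {
  cc <- benchmark_compositions()$phospho_overall
  planted_frac <- 100 * 738 / 883
  recovered <- vapply(1:20, function(s) {
    ds <- generate_phospho_dataset(planted_spec(cc, margin = 0.05,
                                                noise_sd = 0.03, seed = s))
    classify_dataset(quantify_phospho(ds$table))$summary$pct_affected
  }, numeric(1))
  expect_lt(abs(mean(recovered) - planted_frac), 2)
})

test_that("annotation generator realizes requested marginals and overlaps", {
  vc <- benchmark_venn_composition()
  ann <- do.call(generate_annotation, vc)
  counts <- venn_counts(ann)
  expect_equal(unname(counts$sizes),
               c(vc$n_structural, vc$n_adhesion_junction, vc$n_signaling))
  expect_equal(unname(counts$pairwise), unname(vc$overlaps[1:3]))
  expect_equal(counts$triple, 4L)

  # disjoint: every protein in exactly one category
  disj <- generate_annotation(5, 5, 5, overlaps = c(
    structural_adhesion_junction = 0, structural_signaling = 0,
    adhesion_junction_signaling = 0, all_three = 0))
  expect_equal(nrow(disj), 15)
  expect_equal(max(table(disj$protein_id)), 1L)

  # degenerate full overlap: all proteins in all three classes
  full <- generate_annotation(10, 10, 10, overlaps = c(
    structural_adhesion_junction = 10, structural_signaling = 10,
    adhesion_junction_signaling = 10, all_three = 10))
  fc <- venn_counts(full)
  expect_equal(unname(fc$sizes), c(10, 10, 10))
  expect_equal(fc$triple, 10L)
  expect_equal(fc$n_union, 10L)

  expect_error(generate_annotation(5, 5, 5, overlaps = c(
    structural_adhesion_junction = 4, structural_signaling = 4,
    adhesion_junction_signaling = 0, all_three = 0)), "infeasible")
})

test_that("synthetic datasets carry matching truth sidecars", {
  ds <- generate_phospho_dataset(planted_spec(plant_composition(8, 4, 2, 2),
                                              seed = 3))
  expect_setequal(unique(ds$table$isoform_id), ds$truth$entity_id)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  truth <- readr::read_tsv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(truth$entity_id, ds$truth$entity_id)
  expect_equal(truth$planted_class, ds$truth$class)
})
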