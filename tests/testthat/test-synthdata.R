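small_spec <- function(...) {
  cohort_spec(n_healthy = 60, n_cld = 40, n_hcc = 60,
              n_peptides_per_group = c(20, 30, 50), ...)
}

test_that("generated catalogs reproduce requested partition sizes exactly", {
  g <- generate_serology_cohort(cohort_spec(
    n_healthy = 30, n_cld = 20, n_hcc = 30,
    n_peptides_per_group = c(59, 281, 1671), seed = 2))
  asn <- assign_groups(g$catalog, g$annotations)
  expect_equal(unname(as.vector(table(asn$group))), c(59, 281, 1671))
  g2 <- generate_serology_cohort(small_spec(seed = 3))
  asn2 <- assign_groups(g2$catalog, g2$annotations)
  expect_equal(unname(as.vector(table(asn2$group))), c(20, 30, 50))
})

test_that("serology generation is bit-identical under a fixed seed", {
  a <- generate_serology_cohort(small_spec(seed = 7))
  b <- generate_serology_cohort(small_spec(seed = 7))
  expect_identical(a, b)
  c_ <- generate_serology_cohort(small_spec(seed = 8))
  expect_false(identical(a$ebs, c_$ebs))
})

test_that("EBS values are non-negative and right-skewed with a zero mass", {
  g <- generate_serology_cohort(small_spec(seed = 9))
  expect_true(all(g$ebs >= 0))
  expect_gt(mean(g$ebs == 0), 0.2)
  nz <- g$ebs[g$ebs > 0]
  expect_gt(mean(nz), median(nz)) # right skew
})

test_that("null serology spec produces no diagnosis-EBS association", {
  pvals <- vapply(1:20, function(k) {
    g <- generate_serology_cohort(cohort_spec(
      n_healthy = 70, n_cld = 30, n_hcc = 100,
      n_peptides_per_group = c(20, 5, 5),
      ebs_location_shift = 0, diagnosis_or_per_ebs_unit = 1, seed = 100 + k))
    x <- rowMeans(g$ebs[, 1:20])
    fit <- fit_diagnosis_logistic(x, g$meta$diagnosis)
    fit$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_hcc = 0), "n_hcc")
  expect_error(cohort_spec(censor_rate = 1.2), "censor_rate")
  expect_error(cohort_spec(diagnosis_or_per_ebs_unit = -1),
               "diagnosis_or_per_ebs_unit")
  expect_error(cohort_spec(n_peptides_per_group = c(5, 5)), "triple")
  expect_error(expression_spec(n_tumors = 10, n_seropositive = 20),
               "n_seropositive")
  expect_error(mimicry_spec(mimic_identity_fraction = 0),
               "mimic_identity_fraction")
})

test_that("IP-MS generation is deterministic and the planted mimic is recoverable", {
  sp <- mimicry_spec(n_background_proteins = 250, seed = 11)
  a <- generate_ipms_tables(sp)
  b <- generate_ipms_tables(sp)
  expect_identical(a, b)
  expect_true(all(a$spiked_ids %in% a$surface_list))
  fun <- mimicry_funnel(a$intensities, a$surface_list, a$sequences,
                        ce1_query())
  expect_equal(fun$ranking$table$protein_id[1], "MIMIC01")
})

test_that("a 50-fold spike is excluded by the strict >100 filter", {
  a <- generate_ipms_tables(mimicry_spec(n_background_proteins = 100,
                                         enrichment_fold_spiked = 50,
                                         seed = 12))
  fc <- compute_fold_changes(a$intensities)
  enriched <- intersect_enriched(fc)
  expect_false(any(a$spiked_ids %in% enriched))
})

test_that("too-low identity fraction errors before generating sequences", {
  expect_error(generate_ipms_tables(mimicry_spec(mimic_identity_fraction = 0.01)),
               "empty mimic subsequence")
})

test_that("mimic sequences carry the planted identity fraction", {
  a <- generate_ipms_tables(mimicry_spec(n_background_proteins = 50,
                                         mimic_identity_fraction = 0.8,
                                         seed = 13))
  rep_ <- align_query(ce1_query(), a$sequences[["MIMIC01"]])
  expect_gte(rep_$n_identity, round(0.8 * nchar(ce1_query())))
})

test_that("expression generation is deterministic with coherent metadata", {
  sp <- expression_spec(seed = 21)
  a <- generate_expression_cohort(sp)
  expect_identical(a, generate_expression_cohort(sp))
  expect_equal(ncol(a$expr), 97L)
  expect_equal(sum(a$meta$seropositive), 48L)
  expect_true(all(c("ASPH", adcc_signature()) %in% rownames(a$expr)))
  expect_true(all(a$meta$ce1_score[a$meta$seropositive] > 0))
  expect_true(all(a$meta$ce1_score[!a$meta$seropositive] == 0))
})

test_that("null expression spec gives no seronegative correlation and no NK imbalance", {
  sero_p <- numeric(40); nk_p <- numeric(40)
  for (k in 1:40) {
    ex <- generate_expression_cohort(expression_spec(
      n_tumors = 200, n_seropositive = 100,
      adcc_asph_rho_pos = 0, adcc_asph_rho_neg = 0,
      nk_high_fraction_pos = 0.4, nk_high_fraction_neg = 0.4,
      seed = 300 + k))
    norm <- zscore_within_dataset(ex$expr, ex$meta$dataset)
    sc <- adcc_score(norm)
    sp_ <- stratified_asph_adcc(norm["ASPH", ], sc, ex$meta$seropositive)
    sero_p[k] <- sp_$p[sp_$stratum == "seronegative"]
    nk <- nk_stratify(ex$meta$nk_score)
    nk_p[k] <- serostatus_nk_chisq(nk, ex$meta$seropositive)$p_value
  }
  expect_gte(mean(sero_p > 0.05), 0.9)
  expect_gte(mean(nk_p > 0.05), 0.9)
})
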