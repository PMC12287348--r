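test_that("sim_config validates its inputs", {
  expect_s3_class(tiny_sim_config(), "sim_config")
  expect_error(tiny_sim_config(planted_pair_rate_ratio = 0.5), ">= 1")
  expect_error(tiny_sim_config(baseline_term_rate = 0.3,
                               planted_pair_rate_ratio = 6), "exceeds 1")
  expect_error(tiny_sim_config(n_planted_propsychotics = 20L,
                               n_planted_antipsychotics = 10L),
               "exceed the medication universe")
  expect_error(tiny_sim_config(frac_multi_med_reports = 1.5), "\\[0, 1\\]")
})

test_that("simulation is deterministic under a fixed seed and leaves the RNG alone", {
  cfg <- tiny_sim_config(seed = 42L)
  set.seed(99)
  before <- runif(1)
  set.seed(99); runif(1)
  s1 <- simulate_dataset(cfg)
  after <- runif(1)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$db, s2$db)
  expect_identical(s1$links, s2$links)
  expect_identical(s1$risk_rare, s2$risk_rare)
  expect_identical(s1$truth, s2$truth)
  # generator restored the caller's RNG stream
  set.seed(99); runif(1)
  expect_identical(after, runif(1))
  # a different seed changes the world
  expect_false(identical(s1$db, simulate_dataset(tiny_sim_config(seed = 43L))$db))
})

test_that("report structure honours the configuration", {
  cfg <- tiny_sim_config(seed = 7L)
  s <- simulate_reports(cfg)
  per_report <- s$db[, .(n_med = data.table::uniqueN(medication_id),
                         n_se = sum(term_role == "side_effect")),
                     by = report_id]
  expect_identical(nrow(per_report), cfg$n_reports)
  expect_true(all(per_report$n_se >= 1L))
  frac_multi <- mean(per_report$n_med > 1L)
  expect_lt(abs(frac_multi - cfg$frac_multi_med_reports), 0.05)
  expect_true(all(per_report$n_med <= 3L))
  # truth sets drawn from the configured universes
  expect_true(all(s$truth$propsychotic_meds %in% s$vocab$medications))
  expect_length(intersect(s$truth$propsychotic_meds,
                          s$truth$antipsychotic_meds), 0)
  expect_true(all(s$truth$triple_evidence_genes %in%
                    s$truth$mechanism_genes))
  expect_true(all(s$truth$triple_evidence_genes %in%
                    s$truth$risk_genes_rare))
  expect_true(all(s$truth$triple_evidence_genes %in%
                    s$truth$risk_genes_common))
})

test_that("planted pairs reproduce the analytic PRR expectation", {
  # closed-form oracle for the generative model, fallback term included:
  # P(term present) = p_t + P(no term drawn) * p_t / sum(p)
  cfg <- sim_config(n_reports = 50000L, n_medications = 100L,
                    n_genes = 50L, n_psychosis_terms = 5L,
                    n_other_terms = 195L, frac_multi_med_reports = 0,
                    n_planted_propsychotics = 2L,
                    planted_pair_rate_ratio = 6, baseline_term_rate = 0.01,
                    n_planted_antipsychotics = 0L, n_mechanism_genes = 0L,
                    target_link_density = 0, seed = 11L)
  base <- cfg$baseline_term_rate
  elev <- base * cfg$planted_pair_rate_ratio
  n_terms <- cfg$n_psychosis_terms + cfg$n_other_terms
  p_exposed <- c(rep(elev, cfg$n_psychosis_terms),
                 rep(base, cfg$n_other_terms))
  p_base <- rep(base, n_terms)
  present_prob <- function(p) p + prod(1 - p) * p / sum(p)
  pe <- present_prob(p_exposed)[1]     # psychosis term | planted med
  pb <- present_prob(p_base)[1]        # psychosis term | other med
  # comparator mixes the other planted meds with background meds
  n_p <- cfg$n_planted_propsychotics; n_m <- cfg$n_medications
  prr_expected <- pe / (((n_p - 1) * pe + (n_m - n_p) * pb) / (n_m - 1))

  s <- simulate_reports(cfg)
  stats <- disproportionality(s$db)
  planted <- stats[stats$medication_id %in% s$truth$propsychotic_meds &
                     grepl("^PSY", stats$term_id)]
  expect_identical(nrow(planted), n_p * cfg$n_psychosis_terms)
  mean_prr <- mean(planted$prr)
  expect_lt(abs(mean_prr - prr_expected) / prr_expected, 0.08)
  # the analytic value itself sits near the configured ratio of 6 (damped
  # slightly by the >= 1-term guarantee and the planted-med comparator mix)
  expect_gt(prr_expected, 5)
  expect_lt(prr_expected, 7)
  expect_gt(mean_prr, 5)
  expect_lt(mean_prr, 7)
})

test_that("a null configuration plants no PRR signal", {
  cfg <- tiny_sim_config(planted_pair_rate_ratio = 1, seed = 5L,
                         n_reports = 20000L)
  s <- simulate_reports(cfg)
  stats <- disproportionality(filter_single_med_reports(s$db))
  planted <- stats[stats$medication_id %in% s$truth$propsychotic_meds &
                     grepl("^PSY", stats$term_id) & is.finite(stats$prr)]
  expect_lt(abs(mean(planted$prr) - 1), 0.35)
})

test_that("target links concentrate on planted genes with opposing labels", {
  cfg <- tiny_sim_config(seed = 3L)
  s <- simulate_reports(cfg)
  links <- simulate_target_links(cfg, s$truth)
  expect_false(any(duplicated(links[, c("medication_id", "gene", "source")])))
  expect_true(all(is.na(links$action_label[links$source == "predicted"])))
  prop_opposed <- links[links$medication_id %in% s$truth$propsychotic_meds &
                          links$gene %in% s$truth$opposed_genes]
  anti_opposed <- links[links$medication_id %in% s$truth$antipsychotic_meds &
                          links$gene %in% s$truth$opposed_genes]
  expect_true(all(classify_action(prop_opposed$action_label) == "activating"))
  expect_setequal(unique(classify_action(anti_opposed$action_label)),
                  "inhibiting")
  # recount oracle: row count matches an independent recount of the table
  expect_identical(nrow(links),
                   nrow(unique(as.data.frame(links)[c("medication_id",
                                                      "gene", "source")])))
  # empty configuration produces an empty table
  cfg0 <- tiny_sim_config(target_link_density = 0,
                          n_planted_propsychotics = 0L,
                          n_planted_antipsychotics = 0L,
                          n_mechanism_genes = 0L,
                          n_planted_risk_genes_rare = 0L,
                          n_planted_risk_genes_common = 0L)
  truth0 <- simulate_reports(cfg0)$truth
  expect_identical(nrow(simulate_target_links(cfg0, truth0)), 0L)
})

test_that("planted propsychotics always link when targeting probability is 1", {
  # PLANTED_TARGET_PROB is fixed at 0.9; with enough mechanism genes every
  # planted medication gets >= 1 link with overwhelming probability, and the
  # guarantee is exact for the forced opposed labels when links exist
  cfg <- tiny_sim_config(seed = 13L, n_mechanism_genes = 10L)
  s <- simulate_reports(cfg)
  links <- simulate_target_links(cfg, s$truth)
  linked <- unique(links$medication_id)
  expect_true(all(s$truth$propsychotic_meds %in% linked))
})

test_that("risk tables are uniform under the null and planted under effect", {
  cfg0 <- tiny_sim_config(n_planted_risk_genes_rare = 0L,
                          n_planted_risk_genes_common = 0L,
                          risk_effect = 0, n_genes = 500L)
  # simulation oracle: KS vs Uniform(0,1) non-significant at alpha = 0.01 in
  # >= 95% of 100 seeded replicates
  ok <- vapply(1:100, function(i) {
    cfg_i <- tiny_sim_config(n_planted_risk_genes_rare = 0L,
                             n_planted_risk_genes_common = 0L,
                             risk_effect = 0, n_genes = 500L,
                             seed = 1000L + i)
    truth <- simulate_reports(cfg_i)$truth
    risk <- simulate_risk_tables(cfg_i, truth)
    stats::ks.test(risk$rare$p_value, "punif")$p.value > 0.01 &&
      stats::ks.test(risk$common$p_value, "punif")$p.value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # triple-evidence genes are forced below the hard thresholds
  cfg <- tiny_sim_config(seed = 21L)
  truth <- simulate_reports(cfg)$truth
  risk <- simulate_risk_tables(cfg, truth)
  expect_identical(nrow(risk$rare), cfg$n_genes)
  expect_identical(anyDuplicated(risk$rare$gene), 0L)
  tri <- truth$triple_evidence_genes
  expect_true(all(risk$rare$p_value[risk$rare$gene %in% tri] <
                    RARE_LOF_SIGNIFICANCE))
  expect_true(all(risk$common$p_value[risk$common$gene %in% tri] <
                    0.05 / cfg$n_genes))
  # planted genes are stochastically smaller
  planted <- risk$rare$p_value[risk$rare$gene %in% truth$risk_genes_rare]
  other <- risk$rare$p_value[!risk$rare$gene %in% truth$risk_genes_rare]
  expect_lt(median(planted), median(other))
})

test_that("written tables round-trip losslessly", {
  cfg <- tiny_sim_config(seed = 17L, n_reports = 300L)
  s <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(s, dir)
  db2 <- read_report_db(file.path(dir, "reports.tsv"))
  links2 <- read_target_links(file.path(dir, "links.tsv"))
  rare2 <- read_gene_risk(file.path(dir, "risk_rare.tsv"), "rare_lof")
  expect_equal(as.data.frame(db2), as.data.frame(s$db))
  expect_equal(as.data.frame(links2), as.data.frame(s$links))
  expect_equal(rare2$p_value, s$risk_rare$p_value, tolerance = 1e-12)
  truth2 <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  expect_setequal(truth2$triple_evidence_genes, s$truth$triple_evidence_genes)
})
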