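test_that("action labels collapse case-insensitively into directions", {
  expect_identical(classify_action("agonist"), "activating")
  expect_identical(classify_action("weak inhibitor"), "inhibiting")
  expect_identical(classify_action(" Antagonist "), "inhibiting")
  expect_identical(classify_action("binder"), "unknown")
  expect_identical(classify_action(NA_character_), "unknown")
  m <- action_label_map()
  expect_length(intersect(m$activating, m$inhibiting), 0)
})

test_that("moa_proportions divides by labeled class medications and deduplicates", {
  links <- data.table::data.table(
    medication_id = c("M1", "M2", "M3", "M4", "M1", "M1"),
    gene = c("G1", "G1", "G1", "G2", "G1", "G3"),
    source = "curated",
    action_label = c("agonist", "activator", "inducer", "inhibitor",
                     "stimulator", "binder")
  )
  res <- moa_proportions(paste0("M", 1:4), links)
  g1 <- res[res$gene == "G1" & res$direction == "activating"]
  # M1 carries two activating labels on G1 but counts once; denominator is
  # the 4 labeled class medications
  expect_identical(g1$n_class_with_direction, 3L)
  expect_equal(g1$proportion, 0.75)
  expect_identical(attr(res, "n_denominator"), 4L)
  # unknown-only medication still counts toward the denominator by default,
  # but not in strict mode
  links2 <- rbind(links, data.table::data.table(
    medication_id = "M5", gene = "G9", source = "curated",
    action_label = "binder"
  ))
  res_any <- moa_proportions(paste0("M", 1:5), links2)
  expect_identical(attr(res_any, "n_denominator"), 5L)
  res_strict <- moa_proportions(paste0("M", 1:5), links2,
                                denominator = "known_direction")
  expect_identical(attr(res_strict, "n_denominator"), 4L)
  # predicted links never contribute labels
  links3 <- data.table::copy(links)
  links3$source <- "predicted"
  expect_error(moa_proportions(paste0("M", 1:4), links3), "mechanism label")
  # brute-force recount oracle on a random table
  rl <- make_link_table(paste0("M", 1:10), paste0("G", 1:6),
                        label_frac = 0.7, seed = 44)
  cls <- paste0("M", 1:6)
  res_r <- moa_proportions(cls, rl)
  lab <- rl[rl$source == "curated" & !is.na(rl$action_label)]
  lab$dir <- classify_action(lab$action_label)
  denom <- length(unique(lab$medication_id[lab$medication_id %in% cls]))
  for (i in seq_len(nrow(res_r))) {
    n <- length(unique(lab$medication_id[
      lab$medication_id %in% cls & lab$gene == res_r$gene[i] &
        lab$dir == res_r$direction[i]]))
    expect_identical(res_r$n_class_with_direction[i], n)
    expect_equal(res_r$proportion[i], n / denom)
  }
})

test_that("moa permutation matches exhaustive enumeration on a small instance", {
  meds <- paste0("M", 1:6)
  links <- make_link_table(meds, paste0("G", 1:4), density = 0.8,
                           label_frac = 0.9, seed = 55)
  cls <- c("M1", "M2", "M3")
  lab <- links[links$source == "curated" & !is.na(links$action_label)]
  lab$dir <- classify_action(lab$action_label)
  labeled_meds <- sort(unique(lab$medication_id))
  cls_lab <- intersect(cls, labeled_meds)
  n <- length(cls_lab)
  bg <- labeled_meds

  res <- lapply(c("greater", "geq"), function(mode) {
    moa_enrichment(cls, bg, links,
                   config = permutation_config(20000L, seed = 7L,
                                               comparison = mode))
  })
  # exhaustive oracle over all C(|bg|, n) subsets
  directed <- unique(lab[lab$dir != "unknown",
                         c("medication_id", "gene", "dir")])
  genes <- sort(unique(directed$gene[directed$medication_id %in% cls_lab]))
  subsets <- utils::combn(bg, n, simplify = FALSE)
  for (mode_i in 1:2) {
    r <- res[[mode_i]]
    for (i in seq_len(nrow(r))) {
      obs <- r$n_class_with_direction[i]
      null_counts <- vapply(subsets, function(ss) {
        length(unique(directed$medication_id[
          directed$medication_id %in% ss & directed$gene == r$gene[i] &
            directed$dir == r$direction[i]]))
      }, numeric(1))
      exp_p <- if (mode_i == 1) mean(null_counts > obs)
               else mean(null_counts >= obs)
      se <- sqrt(exp_p * (1 - exp_p) / 20000)
      expect_lt(abs(r$empirical_p[i] - exp_p), 3 * se + 1e-12)
    }
  }
})

test_that("directions never observed are non-significant and swap symmetry holds", {
  links <- data.table::data.table(
    medication_id = c("M1", "M2", "M3", "M4", "M5", "M6"),
    gene = "G1", source = "curated",
    action_label = c("agonist", "agonist", "agonist", "inhibitor",
                     "inhibitor", "binder")
  )
  cfg <- permutation_config(5000L, seed = 3L)
  res <- moa_enrichment(c("M1", "M2"), paste0("M", 1:6), links, config = cfg)
  inh <- res[res$direction == "inhibiting"]
  expect_true(all(inh$n_class_with_direction == 0L))
  expect_false(any(inh$significant))
  # relabeling activating <-> inhibiting swaps the directions in the output
  swap <- c(agonist = "inhibitor", inhibitor = "agonist", binder = "binder")
  links_sw <- data.table::copy(links)
  links_sw$action_label <- unname(swap[links$action_label])
  res_sw <- moa_enrichment(c("M1", "M2"), paste0("M", 1:6), links_sw,
                           config = cfg)
  merged <- merge(res, res_sw,
                  by.x = c("gene", "direction"),
                  by.y = c("gene", "direction"))
  a <- res[res$direction == "activating"]
  i_sw <- res_sw[res_sw$direction == "inhibiting"]
  expect_equal(a$proportion, i_sw$proportion)
  expect_equal(a$empirical_p, i_sw$empirical_p)
})

test_that("shared target calls classify opposed, same and mixed relations", {
  mk <- function(gene, dir, sig) {
    data.table::data.table(gene = gene, direction = dir,
                           n_class_with_direction = 1L, proportion = 0.5,
                           empirical_p = ifelse(sig, 0.01, 0.5),
                           significant = sig)
  }
  r1 <- rbind(mk("G1", "activating", TRUE), mk("G1", "inhibiting", FALSE),
              mk("G2", "activating", TRUE), mk("G2", "inhibiting", TRUE),
              mk("G3", "activating", TRUE))
  r2 <- rbind(mk("G1", "inhibiting", TRUE),
              mk("G2", "inhibiting", TRUE),
              mk("G4", "activating", TRUE))
  out <- shared_target_calls(r1, r2)
  expect_identical(out$relation[out$gene == "G1"], "opposed")
  expect_identical(out$relation[out$gene == "G2"], "mixed")
  expect_false("G3" %in% out$gene) # no significant direction in class 2
  expect_false("G4" %in% out$gene)
  # disjoint gene sets give an empty result
  empty <- shared_target_calls(mk("G9", "activating", TRUE),
                               mk("G8", "activating", TRUE))
  expect_identical(nrow(empty), 0L)
  # same-direction case
  same <- shared_target_calls(mk("G5", "inhibiting", TRUE),
                              mk("G5", "inhibiting", TRUE))
  expect_identical(same$relation, "same")
})

test_that("planted opposed genes reach significance in the planted directions", {
  cfg <- tiny_sim_config(seed = 23L)
  s <- simulate_reports(cfg)
  links <- simulate_target_links(cfg, s$truth)
  meds <- s$vocab$medications
  bg_prop <- build_background(meds, s$truth$antipsychotic_meds, links,
                              require_moa = TRUE)
  bg_anti <- build_background(meds, s$truth$propsychotic_meds, links,
                              require_moa = TRUE)
  pc <- function(seed) permutation_config(5000L, seed = seed)
  res_p <- moa_enrichment(s$truth$propsychotic_meds, bg_prop, links,
                          config = pc(1L))
  res_a <- moa_enrichment(s$truth$antipsychotic_meds, bg_anti, links,
                          config = pc(2L))
  opp <- s$truth$opposed_genes
  act_p <- res_p[res_p$gene %in% opp & res_p$direction == "activating"]
  inh_a <- res_a[res_a$gene %in% opp & res_a$direction == "inhibiting"]
  expect_gte(mean(act_p$significant), 0.85)
  expect_gte(mean(inh_a$significant), 0.85)
  shared <- shared_target_calls(res_p, res_a)
  expect_gte(sum(shared$opposed & shared$gene %in% opp),
             0.8 * length(opp))
})
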