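#' Simulation configuration for the synthetic reporting world
#'
#' Builds and validates the configuration for the seeded synthetic-data
#' generators. The defaults describe a desk-scale spontaneous-reporting world:
#' 50,000 reports over 150 medications and 200 side-effect terms, with ten
#' planted "propsychotic" medications whose psychosis-term reporting rate is
#' six-fold the baseline rate, eight planted antipsychotics opposing them on a
#' shared set of mechanism genes, and planted risk genes whose gene-level
#' p-values are stochastically small.
#'
#' @param n_reports number of reports to simulate.
#' @param n_medications size of the medication universe.
#' @param n_genes size of the gene universe.
#' @param n_psychosis_terms number of psychosis side-effect terms.
#' @param n_other_terms number of non-psychosis side-effect terms.
#' @param frac_multi_med_reports fraction of reports carrying 2-3 medications
#'   (these exist only to exercise the single-medication filter).
#' @param n_planted_propsychotics medications planted with elevated
#'   psychosis-term reporting.
#' @param planted_pair_rate_ratio target ratio of the psychosis-term reporting
#'   rate for planted medications relative to `baseline_term_rate`; must be
#'   >= 1.
#' @param baseline_term_rate per-term inclusion probability for unplanted
#'   medication-term pairs.
#' @param n_planted_antipsychotics medications planted as the opposing
#'   (antipsychotic) class.
#' @param n_mechanism_genes genes preferentially targeted by the planted
#'   propsychotic class.
#' @param target_link_density background probability of a medication-gene
#'   link.
#' @param moa_label_coverage fraction of curated links that carry a
#'   mechanism-of-action label.
#' @param n_planted_risk_genes_rare,n_planted_risk_genes_common numbers of
#'   genes planted with stochastically small risk p-values in each risk class.
#' @param risk_effect exponent controlling how small planted risk p-values
#'   are: planted p = U^(1 + risk_effect) with U uniform; 0 recovers the
#'   uniform null.
#' @param seed master integer seed; all generators derive named sub-streams
#'   from it.
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_reports = 1000, n_medications = 20, seed = 7)
sim_config <- function(n_reports = 50000L,
                       n_medications = 150L,
                       n_genes = 500L,
                       n_psychosis_terms = 20L,
                       n_other_terms = 180L,
                       frac_multi_med_reports = 0.3,
                       n_planted_propsychotics = 10L,
                       planted_pair_rate_ratio = 6,
                       baseline_term_rate = 0.01,
                       n_planted_antipsychotics = 8L,
                       n_mechanism_genes = 30L,
                       target_link_density = 0.02,
                       moa_label_coverage = 0.7,
                       n_planted_risk_genes_rare = 40L,
                       n_planted_risk_genes_common = 40L,
                       risk_effect = 3,
                       seed = 1L) {
  cfg <- list(
    n_reports = as.integer(n_reports),
    n_medications = as.integer(n_medications),
    n_genes = as.integer(n_genes),
    n_psychosis_terms = as.integer(n_psychosis_terms),
    n_other_terms = as.integer(n_other_terms),
    frac_multi_med_reports = frac_multi_med_reports,
    n_planted_propsychotics = as.integer(n_planted_propsychotics),
    planted_pair_rate_ratio = planted_pair_rate_ratio,
    baseline_term_rate = baseline_term_rate,
    n_planted_antipsychotics = as.integer(n_planted_antipsychotics),
    n_mechanism_genes = as.integer(n_mechanism_genes),
    target_link_density = target_link_density,
    moa_label_coverage = moa_label_coverage,
    n_planted_risk_genes_rare = as.integer(n_planted_risk_genes_rare),
    n_planted_risk_genes_common = as.integer(n_planted_risk_genes_common),
    risk_effect = risk_effect,
    seed = as.integer(seed)
  )
  for (f in c("n_reports", "n_medications", "n_genes", "n_psychosis_terms",
              "n_other_terms", "n_planted_propsychotics",
              "n_planted_antipsychotics", "n_mechanism_genes",
              "n_planted_risk_genes_rare", "n_planted_risk_genes_common")) {
    assert_count(cfg[[f]], f)
  }
  for (f in c("frac_multi_med_reports", "baseline_term_rate",
              "target_link_density", "moa_label_coverage")) {
    assert_prob(cfg[[f]], f)
  }
  if (cfg$planted_pair_rate_ratio < 1) {
    stop("planted_pair_rate_ratio must be >= 1")
  }
  if (cfg$risk_effect < 0) stop("risk_effect must be >= 0")
  if (cfg$n_planted_propsychotics + cfg$n_planted_antipsychotics >
      cfg$n_medications) {
    stop("planted medication classes exceed the medication universe")
  }
  if (cfg$baseline_term_rate * cfg$planted_pair_rate_ratio > 1) {
    stop("baseline_term_rate * planted_pair_rate_ratio exceeds 1: ",
         "planted pair rate is not a probability")
  }
  if (cfg$n_mechanism_genes > cfg$n_genes ||
      cfg$n_planted_risk_genes_rare > cfg$n_genes ||
      cfg$n_planted_risk_genes_common > cfg$n_genes) {
    stop("planted gene sets exceed the gene universe")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic identifier universes (no RNG involved).
sim_vocab <- function(config) {
  list(
    medications = sprintf("M%03d", seq_len(config$n_medications)),
    genes = sprintf("G%04d", seq_len(config$n_genes)),
    psychosis_terms = sprintf("PSY%03d", seq_len(config$n_psychosis_terms)),
    other_terms = sprintf("ADR%03d", seq_len(config$n_other_terms))
  )
}

# Draw the planted ground truth (medication classes and gene sets) from the
# "reports" sub-stream so that simulate_reports() fully determines it.
draw_sim_truth <- function(config, vocab) {
  meds <- vocab$medications
  genes <- vocab$genes
  prop <- sort(sample(meds, config$n_planted_propsychotics))
  anti <- sort(sample(setdiff(meds, prop), config$n_planted_antipsychotics))
  mech <- sort(sample(genes, config$n_mechanism_genes))
  opposed <- if (length(mech)) {
    sort(sample(mech, max(1L, round(0.6 * length(mech)))))
  } else {
    character()
  }
  n_triple <- min(2L, length(mech), config$n_planted_risk_genes_rare,
                  config$n_planted_risk_genes_common)
  triple <- if (n_triple > 0) sort(sample(mech, n_triple)) else character()
  draw_risk_set <- function(n_total) {
    extra <- n_total - length(triple)
    sort(c(triple, sample(setdiff(genes, triple), extra)))
  }
  list(
    propsychotic_meds = prop,
    antipsychotic_meds = anti,
    mechanism_genes = mech,
    opposed_genes = opposed,
    risk_genes_rare = if (config$n_planted_risk_genes_rare > 0)
      draw_risk_set(config$n_planted_risk_genes_rare) else character(),
    risk_genes_common = if (config$n_planted_risk_genes_common > 0)
      draw_risk_set(config$n_planted_risk_genes_common) else character(),
    triple_evidence_genes = triple
  )
}

#' Simulate a spontaneous-reporting database with planted signal pairs
#'
#' Generates `n_reports` reports. A configured fraction carries 2-3
#' medications (to exercise the single-medication filter); the rest carry
#' exactly one. Side-effect terms are sampled independently per term: for
#' reports containing a planted propsychotic medication, each psychosis term
#' is included with probability `baseline_term_rate * planted_pair_rate_ratio`;
#' all other medication-term pairs use `baseline_term_rate`. Reports that draw
#' no term receive one fallback term sampled proportionally to their term-rate
#' vector, so every report carries at least one side-effect term. About half
#' of the reports additionally carry one indication term.
#'
#' The planted truth (medication classes and gene sets used by the other
#' generators) is drawn here from the `reports` sub-stream of the master seed,
#' so the whole world is a pure function of the configuration.
#'
#' @param config a [sim_config()].
#' @return a list with elements `db` (a `data.table` with columns `report_id`,
#'   `medication_id`, `term_id`, `term_role`; one row per report-item
#'   combination), `truth` (the planted ground truth sets), and `vocab`
#'   (the identifier universes).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vocab <- sim_vocab(config)
  n <- config$n_reports
  base <- config$baseline_term_rate
  elevated <- base * config$planted_pair_rate_ratio
  all_terms <- c(vocab$psychosis_terms, vocab$other_terms)
  n_terms <- length(all_terms)
  if (n_terms == 0L) stop("term universe is empty")

  with_seed(sub_seed(config$seed, "reports"), {
    truth <- draw_sim_truth(config, vocab)

    # medication assignment ------------------------------------------------
    is_multi <- stats::runif(n) < config$frac_multi_med_reports &
      config$n_medications >= 3L
    med1 <- sample(vocab$medications, n, replace = TRUE)
    med_dt <- data.table::data.table(report_id = seq_len(n),
                                     medication_id = med1)
    if (any(is_multi)) {
      idx <- which(is_multi)
      n_extra <- sample(1:2, length(idx), replace = TRUE) # 2-3 meds total
      extra <- lapply(seq_along(idx), function(i) {
        sample(setdiff(vocab$medications, med1[idx[i]]), n_extra[i])
      })
      med_dt <- rbind(med_dt, data.table::data.table(
        report_id = rep(idx, n_extra),
        medication_id = unlist(extra)
      ))
    }

    exposed <- med_dt[
      med_dt$medication_id %in% truth$propsychotic_meds, unique(report_id)]
    is_exposed <- logical(n)
    is_exposed[exposed] <- TRUE

    # side-effect term sampling -------------------------------------------
    pair_rep <- integer(0)
    pair_term <- character(0)
    psy <- vocab$psychosis_terms
    for (j in seq_len(n_terms)) {
      p <- if (all_terms[j] %in% psy) {
        ifelse(is_exposed, elevated, base)
      } else {
        rep(base, n)
      }
      hit <- which(stats::runif(n) < p)
      pair_rep <- c(pair_rep, hit)
      pair_term <- c(pair_term, rep(all_terms[j], length(hit)))
    }

    # fallback so every report carries >= 1 side-effect term
    empty <- setdiff(seq_len(n), unique(pair_rep))
    if (length(empty)) {
      w_base <- rep(base, n_terms)
      w_exp <- ifelse(all_terms %in% psy, elevated, base)
      emp_exposed <- is_exposed[empty]
      fb <- character(length(empty))
      if (any(!emp_exposed)) {
        fb[!emp_exposed] <- sample(all_terms, sum(!emp_exposed),
                                   replace = TRUE, prob = w_base)
      }
      if (any(emp_exposed)) {
        fb[emp_exposed] <- sample(all_terms, sum(emp_exposed),
                                  replace = TRUE, prob = w_exp)
      }
      pair_rep <- c(pair_rep, empty)
      pair_term <- c(pair_term, fb)
    }
    term_dt <- data.table::data.table(report_id = pair_rep, term_id = pair_term,
                                      term_role = "side_effect")

    # indication terms ------------------------------------------------------
    if (length(vocab$other_terms)) {
      ind_rep <- which(stats::runif(n) < 0.5)
      if (length(ind_rep)) {
        term_dt <- rbind(term_dt, data.table::data.table(
          report_id = ind_rep,
          term_id = sample(vocab$other_terms, length(ind_rep), replace = TRUE),
          term_role = "indication"
        ))
      }
    }

    db <- merge(med_dt, term_dt, by = "report_id", allow.cartesian = TRUE)
    data.table::setorder(db, report_id, medication_id, term_role, term_id)
    list(db = db[], truth = truth, vocab = vocab)
  })
}

# Mechanism-of-action label vocabulary used by the link generator; the two
# direction lists match action_label_map(), plus labels with no direction.
sim_label_pool <- function() {
  m <- action_label_map()
  list(activating = m$activating, inhibiting = m$inhibiting,
       unknown = c("binder", "ligand"))
}

# Probability that a planted class medication links to one of its planted
# genes; fixed by design (see the methods vignette).
PLANTED_TARGET_PROB <- 0.9

#' Simulate a medication-target gene link table
#'
#' Planted propsychotic medications link to the mechanism genes with
#' probability 0.9 (curated source), carrying activating labels on the
#' opposed-gene subset; planted antipsychotics link to the opposed genes with
#' inhibiting labels. All medication-gene pairs additionally receive sparse
#' background links at `target_link_density`, split evenly between curated and
#' predicted sources. Only curated links ever carry an action label; a
#' `moa_label_coverage` fraction of background curated links get a label drawn
#' uniformly from the action vocabulary (including direction-less labels such
#' as "binder").
#'
#' @param config a [sim_config()].
#' @param truth planted truth as returned by [simulate_reports()].
#' @return a `data.table` with columns `medication_id`, `gene`, `source`
#'   (`curated`/`predicted`) and `action_label` (`NA` when unlabeled), unique
#'   by (medication, gene, source).
#' @export
simulate_target_links <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  vocab <- sim_vocab(config)
  if (length(vocab$genes) == 0L) stop("gene universe is empty")
  pool <- sim_label_pool()
  with_seed(sub_seed(config$seed, "links"), {
    parts <- list()

    plant <- function(meds, genes, label_fun) {
      if (!length(meds) || !length(genes)) return(NULL)
      grid <- expand.grid(medication_id = meds, gene = genes,
                          stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(grid)) < PLANTED_TARGET_PROB
      grid <- grid[keep, , drop = FALSE]
      if (!nrow(grid)) return(NULL)
      data.table::data.table(
        medication_id = grid$medication_id, gene = grid$gene,
        source = "curated", action_label = label_fun(grid$gene)
      )
    }

    # propsychotics: activating on opposed genes, labels elsewhere by coverage
    parts$prop <- plant(truth$propsychotic_meds, truth$mechanism_genes,
      function(g) {
        lab <- rep(NA_character_, length(g))
        opp <- g %in% truth$opposed_genes
        if (any(opp)) {
          lab[opp] <- sample(pool$activating, sum(opp), replace = TRUE)
        }
        rest <- which(!opp & stats::runif(length(g)) < config$moa_label_coverage)
        if (length(rest)) {
          lab[rest] <- sample(unlist(pool), length(rest), replace = TRUE)
        }
        lab
      })

    # antipsychotics: inhibiting on the same opposed genes
    parts$anti <- plant(truth$antipsychotic_meds, truth$opposed_genes,
      function(g) sample(pool$inhibiting, length(g), replace = TRUE))

    # sparse uniform background links over the grid, excluding the planted
    # class-gene pairs so planted labels are never contradicted
    if (config$target_link_density > 0) {
      grid <- expand.grid(medication_id = vocab$medications,
                          gene = vocab$genes, stringsAsFactors = FALSE)
      planted_pair <- (grid$medication_id %in% truth$propsychotic_meds &
                         grid$gene %in% truth$mechanism_genes) |
        (grid$medication_id %in% truth$antipsychotic_meds &
           grid$gene %in% truth$opposed_genes)
      keep <- !planted_pair &
        stats::runif(nrow(grid)) < config$target_link_density
      grid <- grid[keep, , drop = FALSE]
      if (nrow(grid)) {
        src <- sample(c("curated", "predicted"), nrow(grid), replace = TRUE)
        lab <- rep(NA_character_, nrow(grid))
        lab_idx <- which(src == "curated" &
                           stats::runif(nrow(grid)) < config$moa_label_coverage)
        if (length(lab_idx)) {
          lab[lab_idx] <- sample(unlist(pool), length(lab_idx), replace = TRUE)
        }
        parts$background <- data.table::data.table(
          medication_id = grid$medication_id, gene = grid$gene,
          source = src, action_label = lab
        )
      }
    }

    links <- data.table::rbindlist(parts, use.names = TRUE)
    if (nrow(links) == 0L) {
      return(data.table::data.table(
        medication_id = character(), gene = character(),
        source = character(), action_label = character()
      ))
    }
    # planted rows first so their labels win the (med, gene, source) dedup
    links <- unique(links, by = c("medication_id", "gene", "source"))
    data.table::setorder(links, medication_id, gene, source)
    links[]
  })
}

#' Exome-wide significance threshold for the rare-LoF risk class
#' @export
RARE_LOF_SIGNIFICANCE <- 2.14e-6

#' Simulate gene-level risk p-value tables
#'
#' Non-planted genes draw p-values from Uniform(0, 1]. Planted risk genes draw
#' from the power-function family `p = U^(1 + risk_effect)` (stochastically
#' smaller; `risk_effect = 0` recovers the uniform null). Triple-evidence
#' genes are forced below the rare-class exome-wide significance threshold
#' (2.14e-6) and below half the Bonferroni cutoff `0.05 / n_genes` in the
#' common class, so they survive the downstream high-confidence calls by
#' construction.
#'
#' @param config a [sim_config()].
#' @param truth planted truth as returned by [simulate_reports()].
#' @return a list with `rare` and `common` `data.table`s (columns `gene`,
#'   `p_value`; one row per gene), each carrying a `risk_class` attribute.
#' @export
simulate_risk_tables <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  vocab <- sim_vocab(config)
  if (length(vocab$genes) == 0L) stop("gene universe is empty")
  with_seed(sub_seed(config$seed, "risk"), {
    draw <- function(planted, triple, forced_max) {
      p <- stats::runif(config$n_genes)
      names(p) <- vocab$genes
      idx <- names(p) %in% planted
      p[idx] <- p[idx]^(1 + config$risk_effect)
      if (length(triple)) {
        p[triple] <- stats::runif(length(triple), forced_max * 1e-3, forced_max)
      }
      p[p <= 0] <- .Machine$double.xmin
      data.table::data.table(gene = names(p), p_value = unname(p))
    }
    rare <- draw(truth$risk_genes_rare, truth$triple_evidence_genes,
                 RARE_LOF_SIGNIFICANCE * 0.99)
    common <- draw(truth$risk_genes_common, truth$triple_evidence_genes,
                   0.5 * 0.05 / config$n_genes)
    data.table::setattr(rare, "risk_class", "rare_lof")
    data.table::setattr(common, "risk_class", "common_snp")
    list(rare = rare, common = common)
  })
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulate_reports()], [simulate_target_links()]
#' and [simulate_risk_tables()] under the named sub-streams of the master
#' seed.
#'
#' @param config a [sim_config()].
#' @return a list with `db`, `links`, `risk_rare`, `risk_common`, `truth`,
#'   `vocab`, and `config`.
#' @export
simulate_dataset <- function(config) {
  rep_out <- simulate_reports(config)
  links <- simulate_target_links(config, rep_out$truth)
  risk <- simulate_risk_tables(config, rep_out$truth)
  list(db = rep_out$db, links = links, risk_rare = risk$rare,
       risk_common = risk$common, truth = rep_out$truth,
       vocab = rep_out$vocab, config = config)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Writes `reports.tsv`, `links.tsv`, `risk_rare.tsv`, `risk_common.tsv` and
#' `truth.json` under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reports = file.path(dir, "reports.tsv"),
    links = file.path(dir, "links.tsv"),
    risk_rare = file.path(dir, "risk_rare.tsv"),
    risk_common = file.path(dir, "risk_common.tsv"),
    truth = file.path(dir, "truth.json")
  )
  data.table::fwrite(sim$db, paths[["reports"]], sep = "\t")
  data.table::fwrite(sim$links, paths[["links"]], sep = "\t")
  data.table::fwrite(sim$risk_rare, paths[["risk_rare"]], sep = "\t")
  data.table::fwrite(sim$risk_common, paths[["risk_common"]], sep = "\t")
  jsonlite::write_json(sim$truth, paths[["truth"]], pretty = TRUE)
  invisible(paths)
}

#' Read tables written by [write_sim_dataset()]
#'
#' @param path file path.
#' @return a `data.table` with the stored schema.
#' @export
read_report_db <- function(path) {
  db <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("medication_id",
                                                          "term_id",
                                                          "term_role")))
  db
}

#' @rdname read_report_db
#' @export
read_target_links <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = c("", "NA"),
                    colClasses = "character")
}

#' @rdname read_report_db
#' @param risk_class risk class tag to attach (`rare_lof` or `common_snp`).
#' @export
read_gene_risk <- function(path, risk_class = NA_character_) {
  x <- data.table::fread(path, sep = "\t")
  data.table::setattr(x, "risk_class", risk_class)
  x
}
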