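#' Pipeline configuration
#'
#' Bundles the stage parameters for [run_pipeline()]. The pipeline either
#' simulates its inputs from `sim` or ingests previously written tables from
#' `input_dir` (exactly one must be supplied).
#'
#' @param sim a [sim_config()], or `NULL` when ingesting.
#' @param input_dir directory holding `reports.tsv`, `links.tsv`,
#'   `risk_rare.tsv`, `risk_common.tsv` and `truth.json` (as written by
#'   [write_sim_dataset()]), or `NULL` when simulating.
#' @param criteria a [signal_criteria()].
#' @param n_iterations permutation iterations per enrichment run.
#' @param alpha significance cutoff shared by the permutation tests.
#' @param comparison permutation comparison mode (see
#'   [permutation_config()]).
#' @param bonferroni_m Bonferroni denominator for the common-SNP
#'   high-confidence call; defaults to the unrestricted common-risk row
#'   count.
#' @param out_dir optional directory for per-stage TSV outputs and the JSON
#'   summary.
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            criteria = signal_criteria(),
                            n_iterations = 10000L, alpha = 0.05,
                            comparison = "greater", bonferroni_m = NULL,
                            out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either a simulation config or an input directory is required")
  }
  structure(list(sim = sim, input_dir = input_dir, criteria = criteria,
                 n_iterations = as.integer(n_iterations), alpha = alpha,
                 comparison = comparison, bonferroni_m = bonferroni_m,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim_cfg <- do.call(sim_config, sim_cfg[setdiff(names(sim_cfg), "")])
    simulate_dataset(sim_cfg)
  } else {
    dirp <- config$input_dir
    truth <- jsonlite::read_json(file.path(dirp, "truth.json"),
                                 simplifyVector = TRUE)
    db <- read_report_db(file.path(dirp, "reports.tsv"))
    links <- read_target_links(file.path(dirp, "links.tsv"))
    terms <- unique(db$term_id[db$term_role == "side_effect"])
    list(
      db = db, links = links,
      risk_rare = read_gene_risk(file.path(dirp, "risk_rare.tsv"),
                                 "rare_lof"),
      risk_common = read_gene_risk(file.path(dirp, "risk_common.tsv"),
                                   "common_snp"),
      truth = truth,
      vocab = list(
        medications = sort(unique(db$medication_id)),
        genes = sort(unique(links$gene)),
        psychosis_terms = sort(grep("^PSY", terms, value = TRUE)),
        other_terms = sort(grep("^PSY", terms, value = TRUE, invert = TRUE))
      ),
      config = NULL
    )
  }
}

#' Run the full convergence analysis end-to-end
#'
#' Stage order: single-medication filtering, disproportionality signal
#' calling (propsychotic definition), target-gene permutation for both
#' classes, mechanism-of-action permutation and shared-target comparison,
#' genetic risk enrichment and high-confidence calls, set-overlap validation,
#' and the final convergence report. Identical configuration and seed give an
#' identical summary. Before/after counts of every filter are recorded in the
#' summary.
#'
#' @param config a [pipeline_config()].
#' @return a list with per-stage result tables and a `summary` list of stage
#'   counts; when `out_dir` is set, stage TSVs and `summary.json` are
#'   written there as a side effect.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  truth <- inputs$truth
  vocab <- inputs$vocab
  links <- inputs$links
  seed <- config$seed

  pcfg <- function(stream) {
    permutation_config(n_iterations = config$n_iterations,
                       seed = sub_seed(seed, stream), alpha = config$alpha,
                       comparison = config$comparison)
  }

  # stage 1: single-medication filter -------------------------------------
  n_reports_in <- data.table::uniqueN(inputs$db$report_id)
  fdb <- filter_single_med_reports(inputs$db)
  n_reports_kept <- data.table::uniqueN(fdb$report_id)

  # stage 2: disproportionality signals ------------------------------------
  sig <- call_signals(fdb, psychosis_terms = vocab$psychosis_terms,
                      excluded_meds = truth$antipsychotic_meds,
                      criteria = config$criteria)
  propsychotics <- sig$propsychotics

  # stage 3: target-gene permutation ---------------------------------------
  meds_in_db <- sort(unique(fdb$medication_id))
  bg_prop <- build_background(meds_in_db, truth$antipsychotic_meds, links)
  bg_anti <- build_background(vocab$medications, propsychotics, links)
  linked_meds <- unique(links$medication_id)
  run_targets <- function(class_meds, background, stream) {
    if (length(intersect(class_meds, linked_meds)) == 0L ||
        length(background) == 0L) {
      return(NULL)
    }
    target_enrichment(class_meds, background, links, pcfg(stream))
  }
  tg_prop <- run_targets(propsychotics, bg_prop, "perm_prop")
  tg_anti <- run_targets(truth$antipsychotic_meds, bg_anti, "perm_anti")
  prop_target_genes <- if (is.null(tg_prop)) character() else
    sort(tg_prop$gene[tg_prop$significant])
  anti_target_genes <- if (is.null(tg_anti)) character() else
    sort(tg_anti$gene[tg_anti$significant])

  # stage 4: mechanism-of-action permutation -------------------------------
  map <- action_label_map()
  bg_prop_moa <- build_background(meds_in_db, truth$antipsychotic_meds,
                                  links, require_moa = TRUE)
  bg_anti_moa <- build_background(vocab$medications, propsychotics, links,
                                  require_moa = TRUE)
  labeled_meds <- unique(links$medication_id[!is.na(links$action_label) &
                                               links$action_label != ""])
  run_moa <- function(class_meds, background, stream) {
    if (length(intersect(class_meds, labeled_meds)) == 0L ||
        length(background) == 0L) {
      return(NULL)
    }
    moa_enrichment(class_meds, background, links, map, pcfg(stream))
  }
  moa_prop <- run_moa(propsychotics, bg_prop_moa, "moa_prop")
  moa_anti <- run_moa(truth$antipsychotic_meds, bg_anti_moa, "moa_anti")
  shared <- if (!is.null(moa_prop) && !is.null(moa_anti)) {
    shared_target_calls(moa_prop, moa_anti)
  } else {
    NULL
  }

  # stage 5: genetic risk enrichment and high-confidence calls -------------
  drugged <- drugged_genes(links, vocab$medications)
  rare_prep <- prepare_risk_table(inputs$risk_rare, drugged)
  data.table::setattr(rare_prep, "risk_class", "rare_lof")
  common_prep <- prepare_risk_table(inputs$risk_common, drugged)
  data.table::setattr(common_prep, "risk_class", "common_snp")
  run_enrich <- function(tab, targets, name) {
    if (length(intersect(targets, tab$gene)) == 0L ||
        all(tab$gene %in% targets)) {
      return(NULL)
    }
    risk_enrichment_test(tab, targets, name)
  }
  enrich <- list(
    prop_rare = run_enrich(rare_prep, prop_target_genes, "propsychotic"),
    prop_common = run_enrich(common_prep, prop_target_genes, "propsychotic"),
    anti_rare = run_enrich(rare_prep, anti_target_genes, "antipsychotic"),
    anti_common = run_enrich(common_prep, anti_target_genes, "antipsychotic")
  )
  # high-confidence calls on the unrestricted tables, before the
  # drugged-gene filter
  hc_rare <- high_confidence_rare(inputs$risk_rare)
  m <- config$bonferroni_m %||% nrow(inputs$risk_common)
  hc_common <- high_confidence_common(inputs$risk_common, alpha = 0.05,
                                      m = m)

  # stage 6: overlap statistics --------------------------------------------
  target_overlap <- if (length(prop_target_genes) &&
                          length(anti_target_genes)) {
    overlap_test(length(prop_target_genes), length(anti_target_genes),
                 length(intersect(prop_target_genes, anti_target_genes)),
                 length(drugged))
  } else {
    NULL
  }
  # validation overlap: detected propsychotics vs the planted truth set,
  # standing in for the independent-label validation of the published work
  validation_overlap <- if (length(propsychotics) &&
                              length(truth$propsychotic_meds)) {
    overlap_test(length(truth$propsychotic_meds), length(propsychotics),
                 length(intersect(truth$propsychotic_meds, propsychotics)),
                 length(vocab$medications))
  } else {
    NULL
  }

  # stage 7: convergence ----------------------------------------------------
  conv <- convergence_report(prop_target_genes, anti_target_genes,
                             hc_rare, hc_common)
  triple <- sort(conv$gene[conv$triple_evidence])

  summary <- list(
    seed = seed,
    n_iterations = config$n_iterations,
    n_reports_input = n_reports_in,
    n_reports_retained = n_reports_kept,
    n_signal_pairs = sum(sig$signals$is_signal),
    n_psychosis_signal_pairs = nrow(sig$psychosis_signals),
    n_propsychotics = length(propsychotics),
    n_prop_target_genes = length(prop_target_genes),
    n_anti_target_genes = length(anti_target_genes),
    n_shared_target_genes = if (is.null(target_overlap)) 0L else
      target_overlap$k,
    n_moa_calls_prop = if (is.null(moa_prop)) 0L else
      sum(moa_prop$significant),
    n_moa_calls_anti = if (is.null(moa_anti)) 0L else
      sum(moa_anti$significant),
    n_opposed = if (is.null(shared)) 0L else sum(shared$opposed),
    n_same = if (is.null(shared)) 0L else sum(shared$same),
    n_mixed = if (is.null(shared)) 0L else sum(shared$relation == "mixed"),
    enrichment_p = lapply(enrich, function(e) if (is.null(e)) NA_real_
                          else e$wilcoxon_p),
    n_hc_rare = length(hc_rare),
    n_hc_common = length(hc_common),
    triple_evidence_genes = triple
  )

  out <- list(
    summary = summary, propsychotics = propsychotics, signals = sig$signals,
    psychosis_signals = sig$psychosis_signals, targets_prop = tg_prop,
    targets_anti = tg_anti, moa_prop = moa_prop, moa_anti = moa_anti,
    shared_targets = shared, enrichment = enrich,
    hc_rare = hc_rare, hc_common = hc_common,
    target_overlap = target_overlap,
    validation_overlap = validation_overlap,
    convergence = conv, truth = truth
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) {
      if (!is.null(x) && is.data.frame(x)) {
        data.table::fwrite(x, file.path(config$out_dir, f), sep = "\t")
      }
    }
    wr(out$signals, "signals.tsv")
    wr(out$targets_prop, "targets_propsychotic.tsv")
    wr(out$targets_anti, "targets_antipsychotic.tsv")
    wr(out$moa_prop, "moa_propsychotic.tsv")
    wr(out$moa_anti, "moa_antipsychotic.tsv")
    wr(out$shared_targets, "shared_targets.tsv")
    wr(out$convergence, "convergence.tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
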