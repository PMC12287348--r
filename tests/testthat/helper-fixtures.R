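# Shared fixture builders; everything is generated in code at test time.

# A tiny report database from a compact spec: one row per report,
# medications and side-effect terms as comma-separated strings.
make_report_db <- function(meds, terms, roles = NULL) {
  stopifnot(length(meds) == length(terms))
  rows <- lapply(seq_along(meds), function(i) {
    m <- strsplit(meds[i], ",", fixed = TRUE)[[1]]
    t <- strsplit(terms[i], ",", fixed = TRUE)[[1]]
    expand.grid(report_id = i, medication_id = m, term_id = t,
                term_role = "side_effect", stringsAsFactors = FALSE)
  })
  data.table::rbindlist(rows)
}

# A random link table over given medication/gene universes.
make_link_table <- function(meds, genes, density = 0.4,
                            label_frac = 0.5, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    grid <- expand.grid(medication_id = meds, gene = genes,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < density, , drop = FALSE]
    labels <- c(action_label_map()$activating, action_label_map()$inhibiting,
                "binder")
    n <- nrow(grid)
    data.table::data.table(
      medication_id = grid$medication_id,
      gene = grid$gene,
      source = sample(c("curated", "predicted"), n, replace = TRUE),
      action_label = ifelse(runif(n) < label_frac,
                            sample(labels, n, replace = TRUE),
                            NA_character_)
    )
  })
}

tiny_sim_config <- function(...) {
  defaults <- list(
    n_reports = 2000L, n_medications = 25L, n_genes = 60L,
    n_psychosis_terms = 5L, n_other_terms = 20L,
    frac_multi_med_reports = 0.3, n_planted_propsychotics = 3L,
    planted_pair_rate_ratio = 6, baseline_term_rate = 0.02,
    n_planted_antipsychotics = 3L, n_mechanism_genes = 8L,
    target_link_density = 0.03, moa_label_coverage = 0.7,
    n_planted_risk_genes_rare = 8L, n_planted_risk_genes_common = 8L,
    risk_effect = 3, seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
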