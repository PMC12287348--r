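#' Prepare a gene-level risk table for enrichment testing
#'
#' Applies the three published preparation rules in order: rows with a
#' missing p-value are dropped; genes appearing in more than one row are
#' dropped entirely (every occurrence, not keep-first); the remaining rows
#' are restricted to genes targeted by at least one medication. The operation
#' is idempotent.
#'
#' @param raw a `data.frame`/`data.table` with columns `gene` and `p_value`.
#' @param drugged character vector of genes linked to at least one
#'   medication (see [drugged_genes()]).
#' @return a `data.table` with one row per retained gene; errors if nothing
#'   survives.
#' @export
prepare_risk_table <- function(raw, drugged) {
  x <- data.table::as.data.table(raw)[, c("gene", "p_value")]
  x <- x[!is.na(x$p_value)]
  dup <- unique(x$gene[duplicated(x$gene)])
  x <- x[!x$gene %in% dup]
  x <- x[x$gene %in% drugged]
  if (nrow(x) == 0L) stop("no testable genes remain after preparation")
  if (any(x$p_value <= 0 | x$p_value > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  data.table::setorder(x, gene)
  x[]
}

#' One-sided rank-sum enrichment of a target-gene set in genetic risk
#'
#' Tests whether the target genes' risk p-values are stochastically smaller
#' than the non-targets' via a one-sided two-sample Wilcoxon test on
#' -log10(p) (alternative: targets greater). Being rank-based, the result is
#' invariant to strictly monotone transforms of the p-value column. The
#' exact null distribution is used when both groups have at most 25
#' observations and no ties; otherwise the normal approximation with
#' continuity correction.
#'
#' @param table a prepared risk table (see [prepare_risk_table()]).
#' @param targets character vector of target genes.
#' @param target_set_name label stored in the result.
#' @return a list with `target_set_name`, `risk_class`, `n_target`,
#'   `n_nontarget`, `wilcoxon_p` and `statistic`.
#' @export
risk_enrichment_test <- function(table, targets,
                                 target_set_name = "targets") {
  is_target <- table$gene %in% targets
  nx <- sum(is_target); ny <- sum(!is_target)
  if (nx == 0L || ny == 0L) {
    stop("both target and non-target groups must be non-empty")
  }
  x <- -log10(table$p_value[is_target])
  y <- -log10(table$p_value[!is_target])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- nx <= 25 && ny <= 25 && !ties
  wt <- stats::wilcox.test(x, y, alternative = "greater",
                           exact = exact, correct = TRUE)
  list(
    target_set_name = target_set_name,
    risk_class = attr(table, "risk_class") %||% NA_character_,
    n_target = nx, n_nontarget = ny,
    wilcoxon_p = unname(wt$p.value),
    statistic = unname(wt$statistic)
  )
}

#' High-confidence risk genes by the rare-LoF exome-wide threshold
#'
#' Genes with p strictly below the exome-wide significance threshold
#' (default 2.14e-6, the published rare-LoF cutoff). Conventionally applied
#' to the unrestricted risk table, before the drugged-gene filter.
#'
#' @param table a risk table with columns `gene`, `p_value`.
#' @param threshold significance threshold; the boundary is excluded.
#' @return sorted character vector of gene symbols.
#' @export
high_confidence_rare <- function(table, threshold = RARE_LOF_SIGNIFICANCE) {
  sort(table$gene[table$p_value < threshold])
}

#' High-confidence risk genes by Bonferroni correction
#'
#' Genes whose Bonferroni-adjusted p-value (`min(p * m, 1)`) is strictly
#' below `alpha`. `m` defaults in the pipeline to the full row count of the
#' unrestricted gene-level table.
#'
#' @param table a risk table with columns `gene`, `p_value`.
#' @param alpha significance level after adjustment.
#' @param m number of tests used in the correction; must be at least the
#'   number of rows considered.
#' @return sorted character vector of gene symbols.
#' @export
high_confidence_common <- function(table, alpha = 0.05, m) {
  if (missing(m) || length(m) != 1L || m <= 0) {
    stop("m must be a single positive count")
  }
  if (m < nrow(table)) {
    warning("Bonferroni m (", m, ") is smaller than the table (",
            nrow(table), " rows)")
  }
  adj <- pmin(table$p_value * m, 1)
  sort(table$gene[adj < alpha])
}

#' Intersect the evidence streams into a convergence report
#'
#' Builds the per-gene boolean evidence matrix over the union of the inputs.
#' `triple_evidence` flags genes that are simultaneously a propsychotic
#' target gene, a high-confidence rare-LoF risk gene, and a high-confidence
#' common-SNP risk gene.
#'
#' @param prop_targets,anti_targets significant target-gene sets of the two
#'   medication classes.
#' @param hc_rare,hc_common high-confidence risk gene sets.
#' @return a `data.table` with one row per gene and logical columns
#'   `is_propsychotic_target`, `is_antipsychotic_target`,
#'   `is_rare_lof_high_conf`, `is_common_snp_high_conf`, `triple_evidence`.
#' @export
convergence_report <- function(prop_targets, anti_targets, hc_rare,
                               hc_common) {
  genes <- sort(unique(c(prop_targets, anti_targets, hc_rare, hc_common)))
  out <- data.table::data.table(
    gene = genes,
    is_propsychotic_target = genes %in% prop_targets,
    is_antipsychotic_target = genes %in% anti_targets,
    is_rare_lof_high_conf = genes %in% hc_rare,
    is_common_snp_high_conf = genes %in% hc_common
  )
  out$triple_evidence <- out$is_propsychotic_target &
    out$is_rare_lof_high_conf & out$is_common_snp_high_conf
  out[]
}
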