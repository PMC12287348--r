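#' Permutation configuration
#'
#' @param n_iterations number of null draws (the published analyses used
#'   100,000).
#' @param seed integer seed for the sampler.
#' @param alpha significance cutoff applied to the empirical p-value.
#' @param comparison `"greater"` counts null proportions strictly greater
#'   than the observed proportion (the published convention, which can yield
#'   p = 0); `"geq"` counts ties as exceedances.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_iterations = 100000L, seed = 1L,
                               alpha = 0.05,
                               comparison = c("greater", "geq")) {
  comparison <- match.arg(comparison)
  assert_count(n_iterations, "n_iterations", min = 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), alpha = alpha,
                 comparison = comparison),
            class = "permutation_config")
}

# Collapse a link table to unique medication-gene pairs, optionally
# restricting by source or to labeled links.
collapse_links <- function(links, source = NULL, labeled_only = FALSE) {
  x <- links
  if (!is.null(source)) x <- x[x$source %in% source]
  if (labeled_only) x <- x[!is.na(x$action_label) & x$action_label != ""]
  unique(x[, c("medication_id", "gene")])
}

#' Genes linked to at least one medication of a set
#'
#' @param links a link `data.table` (`medication_id`, `gene`, `source`,
#'   `action_label`).
#' @param medications character vector of medication ids.
#' @return sorted character vector of gene symbols, union over both link
#'   sources.
#' @export
drugged_genes <- function(links, medications) {
  sort(unique(links$gene[links$medication_id %in% medications]))
}

#' Build a background medication set for permutation sampling
#'
#' The background is the universe minus the exclusions, restricted to
#' medications carrying at least one link (at least one labeled link when
#' `require_moa` is `TRUE`, as in the mechanism-of-action analyses).
#'
#' @param universe character vector of candidate medication ids.
#' @param exclusions medication ids to remove (e.g. the opposing class).
#' @param links a link `data.table`.
#' @param require_moa require a non-missing action label on the qualifying
#'   link.
#' @return sorted character vector of background medication ids.
#' @export
build_background <- function(universe, exclusions, links,
                             require_moa = FALSE) {
  if (length(universe) == 0L) stop("medication universe is empty")
  linked <- if (require_moa) {
    unique(links$medication_id[!is.na(links$action_label) &
                                 links$action_label != ""])
  } else {
    unique(links$medication_id)
  }
  sort(intersect(setdiff(universe, exclusions), linked))
}

# Shared permutation core. `inc` is a 0/1 matrix (background medications x
# statistics columns); one medication set of size `sample_size` is drawn per
# iteration and scores every column jointly. Returns exceedance counts of
# null column sums versus `obs_counts`, without materialising the full
# B x ncol null matrix.
perm_exceedance <- function(inc, sample_size, obs_counts, n_iterations, seed,
                            chunk = 2000L) {
  n_bg <- nrow(inc)
  if (sample_size > n_bg) {
    stop("background (", n_bg, ") smaller than the class sample size (",
         sample_size, ")")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  g <- ncol(inc)
  n_gt <- n_ge <- numeric(g)
  with_seed(seed, {
    done <- 0L
    while (done < n_iterations) {
      m <- min(chunk, n_iterations - done)
      sel <- matrix(0, m, n_bg)
      for (i in seq_len(m)) {
        sel[i, sample.int(n_bg, sample_size)] <- 1
      }
      counts <- sel %*% inc # m x g null counts
      obs <- rep(obs_counts, each = m)
      n_gt <- n_gt + .colSums(counts > obs, m, g)
      n_ge <- n_ge + .colSums(counts >= obs, m, g)
      done <- done + m
    }
  })
  list(n_greater = n_gt, n_geq = n_ge, n_iterations = n_iterations)
}

perm_pvalue <- function(exc, comparison) {
  if (comparison == "greater") exc$n_greater / exc$n_iterations
  else exc$n_geq / exc$n_iterations
}

# Incidence matrix of meds x genes from a collapsed link table.
incidence_matrix <- function(pairs, meds, genes) {
  inc <- matrix(0, length(meds), length(genes),
                dimnames = list(meds, genes))
  keep <- pairs$medication_id %in% meds & pairs$gene %in% genes
  if (any(keep)) {
    inc[cbind(pairs$medication_id[keep], pairs$gene[keep])] <- 1
  }
  inc
}

#' Permutation test for class-enriched target genes
#'
#' For each prospective target gene (any gene linked to at least one class
#' medication), compares the proportion of linked class medications targeting
#' the gene with a null built by repeatedly sampling class-sized medication
#' sets from the background uniformly without replacement. One sampled set
#' scores all genes jointly per iteration. The empirical p-value is the
#' fraction of null proportions exceeding the observed proportion under the
#' configured comparison.
#'
#' The class sample size is the number of class medications with at least one
#' link (mirroring the published 240-of-276 / 46-of-64 class sizes). Curated
#' and predicted links collapse to a single medication-gene link before
#' counting.
#'
#' @param class_meds character vector of class medication ids.
#' @param background character vector of background medication ids (see
#'   [build_background()]); must be at least as large as the class sample
#'   size.
#' @param links a link `data.table`.
#' @param config a [permutation_config()].
#' @return a `data.table` with one row per prospective gene: `gene`,
#'   `n_class_targeting`, `observed_proportion`, `empirical_p`, `significant`.
#'   Attributes `sample_size`, `n_iterations` and `comparison` record the
#'   run; no multiple-testing correction is applied across genes.
#' @export
target_enrichment <- function(class_meds, background, links,
                              config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  pairs <- collapse_links(links)
  linked_class <- sort(intersect(class_meds, unique(pairs$medication_id)))
  if (length(linked_class) == 0L) {
    stop("no class medication is linked to any target gene")
  }
  genes <- sort(unique(pairs$gene[pairs$medication_id %in% linked_class]))
  obs <- colSums(incidence_matrix(pairs, linked_class, genes))
  bg <- sort(unique(background))
  inc <- incidence_matrix(pairs, bg, genes)
  exc <- perm_exceedance(inc, length(linked_class), obs,
                         config$n_iterations, config$seed)
  p <- perm_pvalue(exc, config$comparison)
  out <- data.table::data.table(
    gene = genes,
    n_class_targeting = as.integer(obs),
    observed_proportion = obs / length(linked_class),
    empirical_p = p,
    significant = p < config$alpha
  )
  data.table::setattr(out, "sample_size", length(linked_class))
  data.table::setattr(out, "n_iterations", config$n_iterations)
  data.table::setattr(out, "comparison", config$comparison)
  out[]
}

#' Exhaustive enumeration oracle for small permutation instances
#'
#' Computes the exact null by enumerating every class-sized subset of the
#' background, for validating [target_enrichment()] on small instances. Kept
#' exported as a testing utility; it is never used as a shortcut for the
#' sampled permutation.
#'
#' @inheritParams target_enrichment
#' @param sample_size number of medications drawn per subset.
#' @return a `data.table` with `gene`, `p_greater` and `p_geq`: the exact
#'   probabilities that a random subset's targeting proportion exceeds (or
#'   ties) the observed proportion.
#' @export
enumerate_target_null <- function(class_meds, background, links, sample_size) {
  pairs <- collapse_links(links)
  linked_class <- sort(intersect(class_meds, unique(pairs$medication_id)))
  genes <- sort(unique(pairs$gene[pairs$medication_id %in% linked_class]))
  obs <- colSums(incidence_matrix(pairs, linked_class, genes))
  bg <- sort(unique(background))
  inc <- incidence_matrix(pairs, bg, genes)
  subsets <- utils::combn(length(bg), sample_size)
  null_counts <- apply(subsets, 2, function(idx) {
    colSums(inc[idx, , drop = FALSE])
  })
  if (is.null(dim(null_counts))) {
    null_counts <- matrix(null_counts, nrow = length(genes))
  }
  data.table::data.table(
    gene = genes,
    p_greater = rowMeans(null_counts > obs),
    p_geq = rowMeans(null_counts >= obs)
  )
}
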