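#' Mechanism-of-action label vocabulary
#'
#' The published label collapse: activating labels (agonist, activator,
#' inducer, potentiator, positive allosteric modulator, positive modulator,
#' stimulator) and inhibiting labels (inhibitor, antagonist, blocker,
#' negative modulator, inactivator, suppressor, weak inhibitor, inhibitory
#' allosteric modulator). The two sets are disjoint.
#'
#' @return an `action_label_map` list with `activating` and `inhibiting`
#'   character vectors.
#' @export
action_label_map <- function() {
  structure(list(
    activating = c("agonist", "activator", "inducer", "potentiator",
                   "positive allosteric modulator", "positive modulator",
                   "stimulator"),
    inhibiting = c("inhibitor", "antagonist", "blocker", "negative modulator",
                   "inactivator", "suppressor", "weak inhibitor",
                   "inhibitory allosteric modulator")
  ), class = "action_label_map")
}

#' Collapse an action label into a direction
#'
#' Case-insensitive lookup after trimming; labels in neither list map to
#' `"unknown"`.
#'
#' @param label character vector of raw action labels.
#' @param map an [action_label_map()].
#' @return character vector over `"activating"`, `"inhibiting"`, `"unknown"`.
#' @export
classify_action <- function(label, map = action_label_map()) {
  x <- tolower(trimws(as.character(label)))
  out <- rep("unknown", length(x))
  out[x %in% map$activating] <- "activating"
  out[x %in% map$inhibiting] <- "inhibiting"
  out[is.na(label)] <- "unknown"
  out
}

# Labeled curated link table with a direction column. Mechanism labels are
# sourced exclusively from the curated database; predicted links never carry
# labels.
moa_links <- function(links, map) {
  x <- links[links$source == "curated" & !is.na(links$action_label) &
               links$action_label != ""]
  x <- x[, c("medication_id", "gene", "action_label")]
  x$direction <- classify_action(x$action_label, map)
  x
}

# Medications counting toward the class denominator: any labeled link
# ("any_label", the literal published phrasing) or at least one link with a
# known direction ("known_direction", the strict mode).
moa_denominator_meds <- function(labeled, meds,
                                 mode = c("any_label", "known_direction")) {
  mode <- match.arg(mode)
  ok <- if (mode == "any_label") {
    unique(labeled$medication_id)
  } else {
    unique(labeled$medication_id[labeled$direction != "unknown"])
  }
  sort(intersect(meds, ok))
}

#' Per-gene, per-direction class proportions of mechanism labels
#'
#' The denominator is the number of class medications with at least one
#' labeled link of any kind (`denominator = "any_label"`, the default) or
#' with at least one known-direction label (`"known_direction"`). A
#' medication contributes at most once per (gene, direction) regardless of
#' how many qualifying labels it carries; labels with unknown direction are
#' never counted in a direction.
#'
#' @param class_meds character vector of class medication ids.
#' @param links a link `data.table`.
#' @param map an [action_label_map()].
#' @param denominator denominator mode, see above.
#' @return a `data.table` with `gene`, `direction`, `n_class_with_direction`
#'   and `proportion`; attribute `n_denominator` records the denominator.
#' @export
moa_proportions <- function(class_meds, links, map = action_label_map(),
                            denominator = c("any_label", "known_direction")) {
  denominator <- match.arg(denominator)
  labeled <- moa_links(links, map)
  denom_meds <- moa_denominator_meds(labeled, class_meds, denominator)
  if (length(denom_meds) == 0L) {
    stop("no class medication carries a mechanism label")
  }
  medication_id <- NULL
  directed <- unique(labeled[labeled$medication_id %in% denom_meds &
                               labeled$direction != "unknown",
                             c("medication_id", "gene", "direction")])
  counts <- directed[, list(n_class_with_direction =
                              data.table::uniqueN(medication_id)),
                     by = c("gene", "direction")]
  counts$proportion <- counts$n_class_with_direction / length(denom_meds)
  data.table::setorder(counts, gene, direction)
  data.table::setattr(counts, "n_denominator", length(denom_meds))
  counts[]
}

#' Permutation test for directional mechanism-of-action enrichment
#'
#' For each gene targeted with a known direction by at least one class
#' medication, two empirical p-values are computed (activating and
#' inhibiting). Per iteration one class-sized medication set is sampled from
#' the background without replacement and the proportions carrying each
#' (gene, direction) label are recorded; both direction nulls therefore share
#' the sampled sets, as in the published procedure. The class sample size is
#' the number of class medications with at least one labeled link.
#'
#' @inheritParams moa_proportions
#' @param background background medication ids; every member should carry a
#'   labeled link (see [build_background()] with `require_moa = TRUE`).
#' @param config a [permutation_config()].
#' @return a `data.table` with `gene`, `direction`, `n_class_with_direction`,
#'   `proportion`, `empirical_p` and `significant`; attributes as in
#'   [target_enrichment()].
#' @export
moa_enrichment <- function(class_meds, background, links,
                           map = action_label_map(),
                           config = permutation_config(),
                           denominator = c("any_label", "known_direction")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(config, "permutation_config"))
  labeled <- moa_links(links, map)
  denom_meds <- moa_denominator_meds(labeled, class_meds, denominator)
  if (length(denom_meds) == 0L) {
    stop("no class medication carries a mechanism label")
  }
  n_class <- length(denom_meds)
  directed <- unique(labeled[labeled$direction != "unknown",
                             c("medication_id", "gene", "direction")])
  class_directed <- directed[directed$medication_id %in% denom_meds]
  genes <- sort(unique(class_directed$gene))
  if (length(genes) == 0L) {
    stop("no class medication carries a known-direction label")
  }

  dir_pairs <- function(dir) {
    x <- directed[directed$direction == dir, c("medication_id", "gene")]
    names(x) <- c("medication_id", "gene")
    x
  }
  bg <- sort(unique(background))
  inc <- cbind(
    incidence_matrix(dir_pairs("activating"), bg, genes),
    incidence_matrix(dir_pairs("inhibiting"), bg, genes)
  )
  obs <- c(
    colSums(incidence_matrix(
      class_directed[class_directed$direction == "activating",
                     c("medication_id", "gene")], denom_meds, genes)),
    colSums(incidence_matrix(
      class_directed[class_directed$direction == "inhibiting",
                     c("medication_id", "gene")], denom_meds, genes))
  )
  exc <- perm_exceedance(inc, n_class, obs, config$n_iterations, config$seed)
  p <- perm_pvalue(exc, config$comparison)
  out <- data.table::data.table(
    gene = rep(genes, 2L),
    direction = rep(c("activating", "inhibiting"), each = length(genes)),
    n_class_with_direction = as.integer(obs),
    proportion = obs / n_class,
    empirical_p = p,
    significant = p < config$alpha
  )
  data.table::setorder(out, gene, direction)
  data.table::setattr(out, "sample_size", n_class)
  data.table::setattr(out, "n_iterations", config$n_iterations)
  data.table::setattr(out, "comparison", config$comparison)
  out[]
}

#' Shared target genes with opposing or same mechanism directions
#'
#' For every gene with at least one significant direction in each class,
#' reports whether the two classes act in opposition (a significant direction
#' in one class whose opposite is significant in the other), in the same
#' direction, or both (`"mixed"`, possible when a class has both directions
#' significant for a gene).
#'
#' @param results_class1,results_class2 outputs of [moa_enrichment()]
#'   computed on the same gene vocabulary.
#' @return a `data.table` with `gene`, comma-collapsed significant direction
#'   sets per class, logical `opposed` and `same` flags, and `relation`
#'   (`opposed` / `same` / `mixed`).
#' @export
shared_target_calls <- function(results_class1, results_class2) {
  sig_dirs <- function(res) {
    x <- res[res$significant, c("gene", "direction")]
    split(x$direction, x$gene)
  }
  d1 <- sig_dirs(results_class1)
  d2 <- sig_dirs(results_class2)
  shared <- sort(intersect(names(d1), names(d2)))
  if (length(shared) == 0L) {
    return(data.table::data.table(
      gene = character(), class1_directions = character(),
      class2_directions = character(), opposed = logical(),
      same = logical(), relation = character()
    ))
  }
  opp <- c(activating = "inhibiting", inhibiting = "activating")
  rows <- lapply(shared, function(g) {
    s1 <- sort(unique(d1[[g]])); s2 <- sort(unique(d2[[g]]))
    opposed <- any(opp[s1] %in% s2)
    same <- length(intersect(s1, s2)) > 0
    data.table::data.table(
      gene = g,
      class1_directions = paste(s1, collapse = ","),
      class2_directions = paste(s2, collapse = ","),
      opposed = opposed, same = same,
      relation = if (opposed && same) "mixed" else if (opposed) "opposed"
                 else "same"
    )
  })
  data.table::rbindlist(rows)
}
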