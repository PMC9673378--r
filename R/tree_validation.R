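#' Test lineage monophyly on an unrooted gene tree
#'
#' On the unrooted tree, a lineage is monophyletic iff some edge
#' bipartition separates exactly its tips from all other tips. Lineages
#' with zero or one tip are trivially monophyletic; trees with fewer than
#' three tips mapped to the focal lineages are flagged `untestable` (and
#' returned as trivially true). Tips mapping to neither focal lineage are
#' ignored with a warning. With exactly two lineages present the two flags
#' coincide (a split that isolates one side isolates the other).
#'
#' @param gene_tree A gene-tree record (`list(tree, tip_species)`) as
#'   produced by [read_gene_trees()], or a `phylo` object when
#'   `tip_species` is supplied.
#' @param cfg A [lineage_config()].
#' @param tip_species Named character vector tip label -> species, used
#'   when `gene_tree` is a bare `phylo`.
#' @return A one-row tibble: per-lineage monophyly flags, tip counts,
#'   `both_monophyletic`, `untestable`.
#' @export
lineage_monophyly <- function(gene_tree, cfg, tip_species = NULL) {
  if (inherits(gene_tree, "phylo")) {
    tree <- gene_tree
  } else {
    tree <- gene_tree$tree
    tip_species <- gene_tree$tip_species
  }
  sp <- tip_species[tree$tip.label]
  lin <- cfg$species_to_lineage[sp]
  focal <- cfg$focal
  mapped <- lin %in% focal
  if (any(!mapped)) {
    warning(sum(!mapped), " tip(s) not in a focal lineage; ignored")
  }
  tipsA <- tree$tip.label[mapped & lin == focal[1]]
  tipsB <- tree$tip.label[mapped & lin == focal[2]]
  n_mapped <- length(tipsA) + length(tipsB)

  untestable <- n_mapped < 3
  if (untestable) {
    monoA <- monoB <- TRUE
  } else {
    keep <- tree$tip.label[mapped]
    sub <- if (length(keep) < length(tree$tip.label)) {
      ape::keep.tip(tree, keep)
    } else {
      tree
    }
    splits <- tree_tip_splits(sub)
    monoA <- is_split_group(tipsA, splits, sub$tip.label)
    monoB <- is_split_group(tipsB, splits, sub$tip.label)
  }
  out <- tibble::tibble(
    mono_a = monoA, mono_b = monoB,
    n_tips_a = length(tipsA), n_tips_b = length(tipsB),
    both_monophyletic = monoA && monoB,
    untestable = untestable
  )
  names(out)[1:2] <- paste0("mono_", focal)
  names(out)[3:4] <- paste0("n_tips_", focal)
  out
}

# All non-trivial tip bipartitions of a tree (one side of each internal
# edge, as sets of tip indices); rooting is irrelevant because each clade
# of the rooted representation is one side of an unrooted split.
tree_tip_splits <- function(tree) {
  parts <- ape::prop.part(tree)
  lapply(parts, as.integer)
}

is_split_group <- function(tips, splits, tip_labels) {
  if (length(tips) <= 1) return(TRUE)
  idx <- sort(match(tips, tip_labels))
  all_idx <- seq_along(tip_labels)
  if (length(idx) == length(all_idx)) return(TRUE)
  # the pendant edge of the one excluded tip is a valid bipartition
  if (length(idx) == length(all_idx) - 1) return(TRUE)
  for (s in splits) {
    s <- sort(s)
    if (identical(s, idx)) return(TRUE)
    comp <- setdiff(all_idx, s)
    if (identical(comp, idx)) return(TRUE)
  }
  FALSE
}

#' Validation rate over a set of monophyly results
#'
#' @param results Tibble of rows from [lineage_monophyly()] (bind them with
#'   `dplyr::bind_rows()`).
#' @return A list: `rate` (fraction of testable trees with both lineages
#'   monophyletic; `NA` when no tree is testable), `n_testable`,
#'   `n_validated`, `n_untestable`.
#' @export
validation_rate <- function(results) {
  if (nrow(results) == 0) stop("no monophyly results supplied")
  testable <- !results$untestable
  n_testable <- sum(testable)
  n_val <- sum(results$both_monophyletic[testable])
  list(
    rate = if (n_testable > 0) n_val / n_testable else NA_real_,
    n_testable = n_testable,
    n_validated = n_val,
    n_untestable = sum(!testable)
  )
}
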