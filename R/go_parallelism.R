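#' Propagate gene annotations up the ontology graph
#'
#' A gene annotated to a term is annotated to every ancestor of that term
#' (following `is_a` and `part_of` edges). The operation is idempotent and
#' never removes annotations.
#'
#' @param dag An [ontology_dag()].
#' @param gomap Tibble `gene_id`, `term_id`.
#' @return The closed map (distinct `gene_id`, `term_id` rows).
#' @export
propagate_annotations <- function(dag, gomap) {
  if (nrow(dag$edges) == 0) return(dplyr::distinct(gomap))
  g <- igraph::graph_from_data_frame(
    dag$edges[c("term_id", "parent_id")], directed = TRUE,
    vertices = unique(c(dag$terms$term_id, dag$edges$term_id,
                        dag$edges$parent_id)))
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  terms <- unique(gomap$term_id)
  anc <- lapply(terms, function(t) {
    if (!t %in% igraph::V(g)$name) return(t)
    names(igraph::subcomponent(g, t, mode = "out"))  # includes t itself
  })
  names(anc) <- terms
  n_per <- lengths(anc[gomap$term_id])
  closed <- tibble::tibble(
    gene_id = rep(gomap$gene_id, n_per),
    term_id = unlist(anc[gomap$term_id], use.names = FALSE)
  )
  dplyr::distinct(closed)
}

#' Transfer annotations between species through orthogroups
#'
#' Every target-species gene inherits the union of the terms annotated to
#' the source-species genes of its orthogroup, and the source genes
#' likewise inherit the orthogroup union (so that the source side is not
#' annotated more restrictively than the target side). Genes in
#' orthogroups lacking the partner species are excluded from both outputs.
#'
#' @param source_gomap Propagated annotation map for the source species
#'   (e.g. human).
#' @param table An [orthogroup_table()].
#' @param source_species,target_species Species ids.
#' @return A list with `target` and `source` annotation maps (tibbles
#'   `gene_id`, `term_id`).
#' @export
transfer_annotations <- function(source_gomap, table, source_species,
                                 target_species) {
  src <- table[table$species_id == source_species, ]
  tgt <- table[table$species_id == target_species, ]
  shared_ogs <- intersect(src$orthogroup_id, tgt$orthogroup_id)
  src <- src[src$orthogroup_id %in% shared_ogs, ]
  tgt <- tgt[tgt$orthogroup_id %in% shared_ogs, ]

  og_terms <- src |>
    dplyr::inner_join(source_gomap, by = "gene_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$orthogroup_id, .data$term_id)

  assign_terms <- function(genes) {
    genes |>
      dplyr::inner_join(og_terms, by = "orthogroup_id",
                        relationship = "many-to-many") |>
      dplyr::distinct(.data$gene_id, .data$term_id)
  }
  list(target = assign_terms(tgt), source = assign_terms(src))
}

#' Per-GO-term duplication percentages in both lineages
#'
#' For every term, the percentage of annotated genes (on each side) whose
#' orthogroup is duplicated, under three definitions of "duplicated" for
#' the WGD-bearing side: small-scale only, ohnolog only, or either. Terms
#' with fewer than `min_genes` annotated genes on either side are dropped
#' (the filter is applied after transfer and propagation).
#'
#' @param gomap_a,gomap_b Annotation maps for the two sides (A = the
#'   non-WGD side, e.g. amphioxus; B = the WGD side, e.g. human).
#' @param table An [orthogroup_table()].
#' @param profile Output of [lineage_status()].
#' @param dag Optional [ontology_dag()] used to attach term namespaces.
#' @param min_genes Minimum annotated genes per side (default 50).
#' @return A tibble: `term_id`, `namespace`, gene counts and `pct_dup_a`,
#'   `pct_dup_b_ssd`, `pct_dup_b_ohno`, `pct_dup_b_both`.
#' @export
per_term_duplication <- function(gomap_a, gomap_b, table, profile,
                                 dag = NULL, min_genes = 50) {
  gene_og <- stats::setNames(table$orthogroup_id, table$gene_id)
  stA <- profile_col(profile, "status", "a")
  stB <- profile_col(profile, "status", "b")
  dup_a_og <- profile$orthogroup_id[stA %in% c("small_scale_dup", "ohnolog")]
  ssd_b_og <- profile$orthogroup_id[stB == "small_scale_dup"]
  ohno_b_og <- profile$orthogroup_id[stB == "ohnolog"]

  side_stats <- function(gomap, dup_sets) {
    if (nrow(gomap) == 0) {
      out <- tibble::as_tibble(
        stats::setNames(as.list(rep(list(numeric(0)),
                                    length(dup_sets) + 1)),
                        c("n", names(dup_sets))))
      out$term_id <- character(0)
      return(out)
    }
    og <- gene_og[gomap$gene_id]
    by_term <- split(seq_len(nrow(gomap)), gomap$term_id)
    rows <- lapply(names(by_term), function(t) {
      i <- by_term[[t]]
      ogs <- og[i]
      c(n = length(i),
        vapply(dup_sets, function(s) sum(ogs %in% s), numeric(1)))
    })
    out <- tibble::as_tibble(do.call(rbind, rows))
    out$term_id <- names(by_term)
    out
  }

  a <- side_stats(gomap_a, list(dup = dup_a_og))
  b <- side_stats(gomap_b, list(ssd = ssd_b_og, ohno = ohno_b_og,
                                both = union(ssd_b_og, ohno_b_og)))
  merged <- dplyr::inner_join(a, b, by = "term_id",
                              suffix = c("_a", "_b"))
  merged <- merged[merged$n_a >= min_genes & merged$n_b >= min_genes, ]
  out <- tibble::tibble(
    term_id = merged$term_id,
    n_genes_a = as.integer(merged$n_a),
    n_genes_b = as.integer(merged$n_b),
    n_dup_a = as.integer(merged$dup),
    n_dup_b_ssd = as.integer(merged$ssd),
    n_dup_b_ohno = as.integer(merged$ohno),
    n_dup_b_both = as.integer(merged$both),
    pct_dup_a = 100 * merged$dup / merged$n_a,
    pct_dup_b_ssd = 100 * merged$ssd / merged$n_b,
    pct_dup_b_ohno = 100 * merged$ohno / merged$n_b,
    pct_dup_b_both = 100 * merged$both / merged$n_b
  )
  if (!is.null(dag)) {
    out <- dplyr::left_join(
      out, dag$terms[c("term_id", "namespace")], by = "term_id")
  } else {
    out$namespace <- NA_character_
  }
  out
}

#' Paired percentage series for the three duplication definitions
#'
#' Emits the three paired series (A-side percentage against each B-side
#' definition), one row per term per definition, split by namespace when
#' available. No correlation test is attached: GO terms are nested and not
#' independent, so a test statistic would overstate the evidence.
#'
#' @param stats Output of [per_term_duplication()].
#' @return A tibble `term_id`, `namespace`, `definition` (`ssd_plus_ohno`,
#'   `ssd_only`, `ohno_only`), `pct_a`, `pct_b`, `n_genes_b`.
#' @export
parallelism_summary <- function(stats) {
  if (nrow(stats) == 0) {
    return(tibble::tibble(term_id = character(), namespace = character(),
                          definition = character(), pct_a = numeric(),
                          pct_b = numeric(), n_genes_b = integer()))
  }
  defs <- c(ssd_plus_ohno = "pct_dup_b_both", ssd_only = "pct_dup_b_ssd",
            ohno_only = "pct_dup_b_ohno")
  dplyr::bind_rows(lapply(names(defs), function(d) {
    tibble::tibble(
      term_id = stats$term_id,
      namespace = stats$namespace,
      definition = d,
      pct_a = stats$pct_dup_a,
      pct_b = stats[[defs[[d]]]],
      n_genes_b = stats$n_genes_b
    )
  }))
}
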