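#' One-to-one ortholog pairs between two species
#'
#' Orthogroups with exactly one gene in each of the two species (other
#' species' copy numbers are ignored).
#'
#' @param table An [orthogroup_table()].
#' @param species_a,species_b Species ids.
#' @return Tibble `orthogroup_id`, `gene_a`, `gene_b`.
#' @export
one_to_one_pairs <- function(table, species_a, species_b) {
  a <- table[table$species_id == species_a, ]
  b <- table[table$species_id == species_b, ]
  na <- table(a$orthogroup_id)
  nb <- table(b$orthogroup_id)
  ok <- intersect(names(na)[na == 1], names(nb)[nb == 1])
  tibble::tibble(
    orthogroup_id = ok,
    gene_a = a$gene_id[match(ok, a$orthogroup_id)],
    gene_b = b$gene_id[match(ok, b$orthogroup_id)]
  )
}

#' Dotplot points for one-to-one orthologs
#'
#' Each gene is represented by its midpoint coordinate in its genome;
#' pairs lacking a coordinate on either side are skipped with a message.
#'
#' @param pairs Output of [one_to_one_pairs()].
#' @param ann_a,ann_b [gene_records()] for the two species.
#' @return Tibble `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `mid_a`,
#'   `mid_b`, `rank_a`, `rank_b`.
#' @export
dotplot_points <- function(pairs, ann_a, ann_b) {
  ia <- match(pairs$gene_a, ann_a$gene_id)
  ib <- match(pairs$gene_b, ann_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) without coordinates skipped")
  }
  ia <- ia[keep]; ib <- ib[keep]
  tibble::tibble(
    gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
    chrom_a = ann_a$chrom[ia], chrom_b = ann_b$chrom[ib],
    mid_a = gene_midpoint(ann_a$start[ia], ann_a$end[ia]),
    mid_b = gene_midpoint(ann_b$start[ib], ann_b$end[ib]),
    rank_a = ann_a$rank[ia], rank_b = ann_b$rank[ib]
  )
}

#' Plot a synteny dotplot
#' @param points Output of [dotplot_points()].
#' @return A ggplot object (points colored by A-side chromosome).
#' @export
plot_dotplot <- function(points) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(points, ggplot2::aes(
    x = .data$mid_a, y = .data$mid_b, colour = .data$chrom_a)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(.data$chrom_b ~ .data$chrom_a,
                        scales = "free", space = "free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = "genome A midpoint", y = "genome B midpoint")
}

#' Classify paralog pair locations within a species
#'
#' A pair of within-species paralogs is `tandem` when the two genes are
#' consecutive along the chromosome (same chromosome, adjacent gene ranks;
#' `max_intervening` relaxes adjacency for sensitivity analysis),
#' `intra_distant` when on the same chromosome but not adjacent, and
#' `inter_chromosomal` otherwise. The orthogroup aggregate is `tandem` if
#' any pair is tandem, else `intra_distant` if all located members share a
#' chromosome, else `inter_chromosomal`. Both pair-level and
#' orthogroup-level tallies are useful because "percentage of
#' duplications" can be counted per pair or per family.
#'
#' @param table An [orthogroup_table()].
#' @param ann [gene_records()] for the species.
#' @param species Species id.
#' @param max_intervening Maximum genes allowed between tandem partners
#'   (default 0 = strictly consecutive).
#' @return A list: `pairs` (tibble `orthogroup_id`, `gene_1`, `gene_2`,
#'   `class`) and `orthogroups` (tibble `orthogroup_id`, `class`,
#'   `n_genes`). Singleton orthogroups are skipped.
#' @export
classify_duplicate_locations <- function(table, ann, species,
                                         max_intervening = 0) {
  genes <- table[table$species_id == species, ]
  genes <- genes[genes$gene_id %in% ann$gene_id, ]
  idx <- match(genes$gene_id, ann$gene_id)
  genes$chrom <- ann$chrom[idx]
  genes$rank <- ann$rank[idx]
  multi <- genes |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  per_og <- split(multi, multi$orthogroup_id)
  pair_rows <- lapply(per_og, function(d) {
    cmb <- utils::combn(seq_len(nrow(d)), 2)
    same <- d$chrom[cmb[1, ]] == d$chrom[cmb[2, ]]
    gap <- abs(d$rank[cmb[1, ]] - d$rank[cmb[2, ]])
    cls <- ifelse(!same, "inter_chromosomal",
                  ifelse(gap <= 1 + max_intervening, "tandem",
                         "intra_distant"))
    tibble::tibble(
      orthogroup_id = d$orthogroup_id[1],
      gene_1 = d$gene_id[cmb[1, ]], gene_2 = d$gene_id[cmb[2, ]],
      class = cls
    )
  })
  pairs <- dplyr::bind_rows(pair_rows)
  og_rows <- lapply(per_og, function(d) {
    p <- pair_rows[[d$orthogroup_id[1]]]
    cls <- if (any(p$class == "tandem")) "tandem"
      else if (length(unique(d$chrom)) == 1) "intra_distant"
      else "inter_chromosomal"
    tibble::tibble(orthogroup_id = d$orthogroup_id[1], class = cls,
                   n_genes = nrow(d))
  })
  list(pairs = pairs, orthogroups = dplyr::bind_rows(og_rows))
}

#' Chromosome homology map from one-to-one orthologs
#'
#' For every A-side chromosome, the B-side chromosomes receiving at least
#' `min_fraction` of its one-to-one orthologs are its partners. A
#' chromosome with a single partner is called `one_to_one`; one with two
#' or more partners is called `fusion_or_fission` (one chromosome in A
#' corresponding to several in B, i.e. a fusion in A or a fission in B).
#' Chromosomes with fewer than `min_orthologs` mapped orthologs are left
#' uncalled.
#'
#' @param points Output of [dotplot_points()] (or any tibble with
#'   `chrom_a`, `chrom_b`).
#' @param min_fraction Partner threshold on the fraction of a chromosome's
#'   orthologs (default 0.2, separating a ~50/50 fusion signal from
#'   background scatter).
#' @param min_orthologs Minimum orthologs for a chromosome to be called
#'   (default 10).
#' @return A list: `fractions` (tibble `chrom_a`, `chrom_b`,
#'   `n_orthologs`, `fraction`) and `calls` (tibble `chrom_a`, `partners`,
#'   `n_partners`, `call`).
#' @export
chromosome_homology <- function(points, min_fraction = 0.2,
                                min_orthologs = 10) {
  tab <- points |>
    dplyr::count(.data$chrom_a, .data$chrom_b, name = "n_orthologs") |>
    dplyr::group_by(.data$chrom_a) |>
    dplyr::mutate(fraction = .data$n_orthologs / sum(.data$n_orthologs),
                  total = sum(.data$n_orthologs)) |>
    dplyr::ungroup()
  calls <- tab |>
    dplyr::group_by(.data$chrom_a) |>
    dplyr::summarise(
      partners = paste(sort(.data$chrom_b[.data$fraction >= min_fraction]),
                       collapse = ","),
      n_partners = sum(.data$fraction >= min_fraction),
      total = .data$total[1],
      .groups = "drop") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$total < min_orthologs ~ "uncalled",
      .data$n_partners >= 2 ~ "fusion_or_fission",
      .data$n_partners == 1 ~ "one_to_one",
      TRUE ~ "uncalled"
    )) |>
    dplyr::select(-"total")
  list(fractions = dplyr::select(tab, -"total"), calls = calls)
}
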