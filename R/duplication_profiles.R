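#' Per-species gene counts for every orthogroup
#'
#' @param table An [orthogroup_table()].
#' @param species Species universe (columns); default all species present.
#' @return Integer matrix, orthogroups in rows, species in columns; a
#'   species absent from an orthogroup counts 0.
#' @export
copy_number_matrix <- function(table, species = NULL) {
  if (is.null(species)) species <- sort(unique(table$species_id))
  ogs <- unique(table$orthogroup_id)
  cnm <- matrix(0L, nrow = length(ogs), ncol = length(species),
                dimnames = list(ogs, species))
  tab <- table(table$orthogroup_id, table$species_id)
  cnm[rownames(tab), colnames(tab)] <- tab
  cnm
}

#' Classify orthogroups by duplication status in two lineages
#'
#' For each orthogroup and each focal lineage, the status is one of
#' `absent` (no gene in any species of the lineage), `single_copy` (every
#' species that has the orthogroup has exactly one gene),
#' `small_scale_dup` (some species has two or more genes) or, for the
#' WGD-bearing lineage only, `ohnolog`. A duplicated orthogroup in the WGD
#' lineage is reassigned to `ohnolog` when any of its member genes in that
#' lineage carries a 2R label. Orthogroups whose vertebrate duplication is
#' confined to the 3R-bearing species and attributable to the 3R round
#' (at least one 3R-labelled member gene there) are demoted to
#' `single_copy`, so that the lineage comparison reflects 2R and
#' small-scale events only; the 2R check takes precedence over the
#' demotion.
#'
#' @param table An [orthogroup_table()].
#' @param cfg A [lineage_config()] covering every species in the table.
#' @param ohnologs Optional ohnolog list ([read_ohnologs()] layout).
#' @return A tibble with one row per orthogroup: per-lineage `status_*` and
#'   `mean_copies_*` columns (mean copy number over species of the lineage
#'   that have at least one gene) and the joint class (`both_single`,
#'   `A_specific_dup`, `B_specific_dup`, `parallel_dup`,
#'   `A_only_orthogroup`, `B_only_orthogroup`), where A and B are the two
#'   focal lineages in order.
#' @export
lineage_status <- function(table, cfg, ohnologs = NULL) {
  unknown <- setdiff(unique(table$species_id),
                     names(cfg$species_to_lineage))
  if (length(unknown) > 0) {
    stop("species missing from lineage config: ",
         paste(unknown, collapse = ", "))
  }
  cnm <- copy_number_matrix(table,
                            species = names(cfg$species_to_lineage))
  linA <- cfg$focal[1]; linB <- cfg$focal[2]
  spA <- lineage_species(cfg, linA)
  spB <- lineage_species(cfg, linB)

  base_status <- function(counts) {
    if (all(counts == 0)) return("absent")
    if (any(counts >= 2)) return("small_scale_dup")
    "single_copy"
  }
  mean_present <- function(counts) {
    present <- counts[counts >= 1]
    if (length(present) == 0) NA_real_ else mean(present)
  }

  ogs <- rownames(cnm)
  stA <- apply(cnm[, spA, drop = FALSE], 1, base_status)
  stB <- apply(cnm[, spB, drop = FALSE], 1, base_status)
  mcA <- apply(cnm[, spA, drop = FALSE], 1, mean_present)
  mcB <- apply(cnm[, spB, drop = FALSE], 1, mean_present)

  wgd_sp <- lineage_species(cfg, cfg$wgd_lineage)
  wgd_is_A <- cfg$wgd_lineage == linA
  if (!is.null(ohnologs) && nrow(ohnologs) > 0) {
    key2r <- with(ohnologs[ohnologs$wgd_round == "2R", ],
                  paste(species_id, gene_id))
    key3r <- with(ohnologs[ohnologs$wgd_round == "3R", ],
                  paste(species_id, gene_id))
    wgd_rows <- table[table$species_id %in% wgd_sp, ]
    gene_key <- paste(wgd_rows$species_id, wgd_rows$gene_id)
    has2r <- unique(wgd_rows$orthogroup_id[gene_key %in% key2r])

    # 3R demotion candidates: duplication confined to the 3R species, and
    # at least one member gene there labelled 3R (retention established)
    sp3 <- intersect(cfg$wgd_3r_species, wgd_sp)
    other <- setdiff(wgd_sp, sp3)
    if (length(sp3) > 0) {
      dup3_only <- rowSums(cnm[, sp3, drop = FALSE] >= 2) > 0 &
        rowSums(cnm[, other, drop = FALSE] >= 2) == 0
      rows3 <- table[table$species_id %in% sp3, ]
      key3 <- paste(rows3$species_id, rows3$gene_id)
      has3r <- unique(rows3$orthogroup_id[key3 %in% key3r])
      demote <- ogs[dup3_only] [ogs[dup3_only] %in% has3r]
      demote <- setdiff(demote, has2r)  # 2R evidence takes precedence
    } else {
      demote <- character()
    }
    st_wgd <- if (wgd_is_A) stA else stB
    st_wgd[ogs %in% has2r & st_wgd == "small_scale_dup"] <- "ohnolog"
    st_wgd[ogs %in% demote & st_wgd == "small_scale_dup"] <- "single_copy"
    if (wgd_is_A) stA <- st_wgd else stB <- st_wgd
  }

  dupA <- stA %in% c("small_scale_dup", "ohnolog")
  dupB <- stB %in% c("small_scale_dup", "ohnolog")
  joint <- dplyr::case_when(
    stA == "absent" & stB == "absent" ~ NA_character_,
    stB == "absent" ~ "A_only_orthogroup",
    stA == "absent" ~ "B_only_orthogroup",
    dupA & dupB ~ "parallel_dup",
    dupA ~ "A_specific_dup",
    dupB ~ "B_specific_dup",
    TRUE ~ "both_single"
  )

  out <- tibble::tibble(
    orthogroup_id = ogs,
    status_a = unname(stA), status_b = unname(stB),
    mean_copies_a = unname(mcA), mean_copies_b = unname(mcB),
    joint_class = unname(joint)
  )
  names(out)[2:5] <- c(paste0("status_", c(linA, linB)),
                       paste0("mean_copies_", c(linA, linB)))
  attr(out, "lineages") <- c(linA, linB)
  out
}

profile_col <- function(profile, what, side = c("a", "b")) {
  side <- match.arg(side)
  lin <- attr(profile, "lineages")[if (side == "a") 1 else 2]
  profile[[paste0(what, "_", lin)]]
}

#' Per-species duplication summary
#'
#' For every species: total genes, genes in orthogroups where that species
#' itself has two or more copies ("duplicated genes"), orthogroups
#' containing the species, orthogroups duplicated in the species, the mean
#' number of genes per duplicated orthogroup, and the same gene columns
#' restricted to orthogroups shared between the two focal lineages
#' (at least one gene in each).
#'
#' @param table An [orthogroup_table()].
#' @param cfg A [lineage_config()].
#' @param total_genes Optional named vector of per-species annotated gene
#'   totals. Orthology tools leave some genes unassigned to any orthogroup;
#'   when the annotated total exceeds the genes present in the table, pass
#'   it here so percentages use the full denominator. Defaults to the
#'   per-species counts in the table.
#' @return A tibble, one row per species.
#' @export
species_summary <- function(table, cfg, total_genes = NULL) {
  cnm <- copy_number_matrix(table, species = names(cfg$species_to_lineage))
  spA <- lineage_species(cfg, cfg$focal[1])
  spB <- lineage_species(cfg, cfg$focal[2])
  shared <- rowSums(cnm[, spA, drop = FALSE]) > 0 &
    rowSums(cnm[, spB, drop = FALSE]) > 0

  per_species <- lapply(colnames(cnm), function(sp) {
    counts <- cnm[, sp]
    in_table <- sum(counts)
    total <- if (!is.null(total_genes) && sp %in% names(total_genes)) {
      total_genes[[sp]]
    } else {
      in_table
    }
    dup_og <- counts >= 2
    dup_genes <- sum(counts[dup_og])
    og_total <- sum(counts >= 1)
    og_dup <- sum(dup_og)
    tibble::tibble(
      species_id = sp,
      lineage = unname(cfg$species_to_lineage[sp]),
      genes_total = total,
      genes_dup = dup_genes,
      pct_genes_dup = 100 * dup_genes / total,
      ortho_genes_total = sum(counts[shared]),
      ortho_genes_dup = sum(counts[shared & dup_og]),
      pct_ortho_genes_dup =
        if (sum(counts[shared]) > 0)
          100 * sum(counts[shared & dup_og]) / sum(counts[shared])
        else NA_real_,
      og_total = og_total,
      og_dup = og_dup,
      pct_og_dup = if (og_total > 0) 100 * og_dup / og_total else NA_real_,
      mean_genes_per_dup_og =
        if (og_dup > 0) dup_genes / og_dup else NA_real_
    )
  })
  dplyr::bind_rows(per_species)
}

#' Lineage-specific orthogroups partitioned by species combination
#'
#' Counts orthogroups present in only one focal lineage, partitioned by the
#' exact subset of that lineage's species containing them (the cells of a
#' Venn diagram over the lineage's species).
#'
#' @param table An [orthogroup_table()].
#' @param cfg A [lineage_config()].
#' @param lineage Which focal lineage to report; default the first.
#' @return A tibble `species_combination` (comma-joined sorted species
#'   ids), `n_orthogroups`.
#' @export
lineage_specific_overlap <- function(table, cfg, lineage = cfg$focal[1]) {
  cnm <- copy_number_matrix(table, species = names(cfg$species_to_lineage))
  sp_in <- lineage_species(cfg, lineage)
  sp_out <- setdiff(names(cfg$species_to_lineage), sp_in)
  specific <- rowSums(cnm[, sp_in, drop = FALSE]) > 0 &
    rowSums(cnm[, sp_out, drop = FALSE]) == 0
  combos <- apply(cnm[specific, sp_in, drop = FALSE] > 0, 1, function(p) {
    paste(sort(sp_in[p]), collapse = ",")
  })
  out <- tibble::as_tibble(table(species_combination = combos))
  names(out)[2] <- "n_orthogroups"
  out$n_orthogroups <- as.integer(out$n_orthogroups)
  out
}
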