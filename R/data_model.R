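#' Construct an orthogroup table
#'
#' The central container of the package: a long-format tibble with one row
#' per gene, columns `orthogroup_id`, `species_id`, `gene_id`. An orthogroup
#' is a set of genes descended from a single gene in the last common
#' ancestor of the species panel; every gene belongs to at most one
#' orthogroup.
#'
#' @param x A data frame with columns `orthogroup_id`, `species_id`,
#'   `gene_id` (one row per gene).
#' @return A tibble of class `orthogroup_tbl`.
#' @export
orthogroup_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("orthogroup_id", "species_id", "gene_id")
  if (!all(need %in% names(x))) {
    stop("orthogroup table needs columns: ", paste(need, collapse = ", "))
  }
  x <- x[need]
  x[] <- lapply(x, as.character)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    bad <- unique(x$gene_id[x$gene_id %in% dup])
    # a gene in two orthogroups breaks every downstream count
    stop("gene id(s) present in more than one orthogroup: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  class(x) <- c("orthogroup_tbl", class(x))
  x
}

#' @export
print.orthogroup_tbl <- function(x, ...) {
  cat("<orthogroup table> ", dplyr::n_distinct(x$orthogroup_id),
      " orthogroups, ", nrow(x), " genes, ",
      dplyr::n_distinct(x$species_id), " species\n", sep = "")
  NextMethod()
}

#' Construct a gene coordinate table
#'
#' Coordinates are 1-based inclusive (GFF3 convention). `rank` is the 0-based
#' position of the gene among the genes of its chromosome ordered by
#' ascending start (ties broken by end, then gene id); it is recomputed
#' unless supplied.
#'
#' @param x Data frame with columns `gene_id`, `species_id`, `chrom`,
#'   `start`, `end` and optionally `strand`, `rank`.
#' @return A tibble with a unique rank per (species, chrom).
#' @export
gene_records <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("gene_id", "species_id", "chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("gene records need columns: ", paste(need, collapse = ", "))
  }
  if (!"strand" %in% names(x)) x$strand <- "."
  if (any(x$start > x$end)) stop("gene record with start > end")
  if (any(x$start < 1)) stop("coordinates must be 1-based (start >= 1)")
  x <- dplyr::arrange(x, .data$species_id, .data$chrom, .data$start,
                      .data$end, .data$gene_id)
  x <- dplyr::mutate(
    dplyr::group_by(x, .data$species_id, .data$chrom),
    rank = dplyr::row_number() - 1L
  )
  dplyr::ungroup(x)
}

#' Midpoint coordinate of a gene
#' @param start,end 1-based inclusive coordinates.
#' @return `(start + end) / 2`, always inside `[start, end]`.
#' @export
gene_midpoint <- function(start, end) (start + end) / 2

#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric matrix of TPM, genes in rows, samples in columns
#'   (non-negative; row and column names required).
#' @param samples Data frame with columns `sample_id`, `condition_id` and
#'   optionally `condition_class` (`adult_tissue` or `dev_stage`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene row names and sample column names")
  }
  if (any(values < 0)) stop("negative TPM value in expression matrix")
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "condition_id") %in% names(samples))) {
    stop("sample metadata needs columns sample_id, condition_id")
  }
  if (!"condition_class" %in% names(samples)) {
    samples$condition_class <- "adult_tissue"
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("a sample maps to more than one condition")
  }
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta) > 0) {
    warning("dropping ", length(missing_meta),
            " sample(s) without metadata: ",
            paste(utils::head(missing_meta, 5), collapse = ", "))
    values <- values[, setdiff(colnames(values), missing_meta), drop = FALSE]
  }
  samples <- samples[samples$sample_id %in% colnames(values), ]
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression matrix> ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (",
      dplyr::n_distinct(x$samples$condition_id), " conditions)\n", sep = "")
  invisible(x)
}

#' Describe a two-lineage species panel
#'
#' @param species_to_lineage Named character vector mapping species ids to
#'   lineage ids.
#' @param focal Character vector of length 2: the two lineages being
#'   compared (order matters: deltas and joint classes use A minus B).
#' @param wgd_lineage The lineage that experienced whole-genome duplication
#'   (ohnolog status is only permitted there); default the second focal
#'   lineage.
#' @param wgd_3r_species Species carrying an additional lineage-restricted
#'   WGD round (e.g. the teleost 3R); duplications confined to these species
#'   and attributable to that round are not counted as lineage duplications.
#' @return A list of class `lineage_config`.
#' @export
lineage_config <- function(species_to_lineage, focal,
                           wgd_lineage = focal[2],
                           wgd_3r_species = character()) {
  stopifnot(length(focal) == 2, !is.null(names(species_to_lineage)))
  spA <- names(species_to_lineage)[species_to_lineage == focal[1]]
  spB <- names(species_to_lineage)[species_to_lineage == focal[2]]
  if (length(spA) == 0 || length(spB) == 0) {
    stop("both focal lineages need at least one species")
  }
  if (length(intersect(spA, spB)) > 0) stop("focal lineages must be disjoint")
  if (!wgd_lineage %in% focal) stop("wgd_lineage must be a focal lineage")
  structure(list(species_to_lineage = species_to_lineage, focal = focal,
                 wgd_lineage = wgd_lineage,
                 wgd_3r_species = wgd_3r_species),
            class = "lineage_config")
}

#' Species of one lineage
#' @param cfg A [lineage_config()].
#' @param lineage Lineage id.
#' @export
lineage_species <- function(cfg, lineage) {
  names(cfg$species_to_lineage)[cfg$species_to_lineage == lineage]
}

#' Default chordate panel: three amphioxus and four vertebrates
#'
#' Blan, Bflo, Bbel are assigned to the `amphioxus` lineage; Drer, Ggal,
#' Mmus, Hsap to `vertebrate`, with the 2R whole-genome duplications on the
#' vertebrate branch and zebrafish (Drer) flagged as the 3R-bearing teleost.
#' @return A [lineage_config()].
#' @export
default_panel_config <- function() {
  lineage_config(
    species_to_lineage = c(
      Blan = "amphioxus", Bflo = "amphioxus", Bbel = "amphioxus",
      Drer = "vertebrate", Ggal = "vertebrate", Mmus = "vertebrate",
      Hsap = "vertebrate"
    ),
    focal = c("amphioxus", "vertebrate"),
    wgd_lineage = "vertebrate",
    wgd_3r_species = "Drer"
  )
}

#' Default amphioxus-zebrafish condition map
#'
#' Seven homologous expression conditions used to compare presence/absence
#' of expression across the two species: embryo, male gonads/testis,
#' muscle, neural tube/brain, gut/intestine, gills/pharyngeal gill and
#' hepatic diverticulum/liver. Shipped as data (a TSV under `extdata`), not
#' code, so other pairings can be substituted.
#' @return A tibble with columns `condition_a`, `condition_b`.
#' @export
default_condition_map <- function() {
  path <- system.file("extdata", "condition_map_blan_drer.tsv",
                      package = "orthodup")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
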