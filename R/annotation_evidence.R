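#' Classify sequence-similarity evidence per gene and database
#'
#' A gene has *strong* similarity evidence in a database when any of its
#' hits covers more than 75% of both the query and the subject sequence
#' (`aln_length / qlen > 0.75` and `aln_length / slen > 0.75`) with
#' e-value below 1e-8; *weak* evidence when any hit has e-value below
#' 1e-4; *none* otherwise. The thresholds are read as alignment coverage
#' of query and subject — a literal length ratio would be at least 1 for
#' ungapped alignments and the rule vacuous.
#'
#' @param hits A BLAST hit tibble ([read_blast_hits()] layout); may mix
#'   database tags.
#' @param genes Optional gene universe; genes without hits are reported as
#'   `none` for every database tag present in `hits`.
#' @return Tibble `gene_id`, `database_tag`, `evidence`.
#' @export
classify_seqsim <- function(hits, genes = NULL) {
  if (any(hits$qlen <= 0 | hits$slen <= 0)) {
    stop("zero-length query or subject in BLAST table")
  }
  hits <- dplyr::mutate(
    hits,
    qcov = .data$aln_length / .data$qlen,
    scov = .data$aln_length / .data$slen,
    strong = .data$qcov > 0.75 & .data$scov > 0.75 & .data$evalue < 1e-8,
    weak = .data$evalue < 1e-4
  )
  per <- hits |>
    dplyr::group_by(gene_id = .data$query_id, .data$database_tag) |>
    dplyr::summarise(
      evidence = if (any(.data$strong)) "strong"
        else if (any(.data$weak)) "weak" else "none",
      .groups = "drop")
  if (!is.null(genes)) {
    grid <- tidyr::expand_grid(gene_id = genes,
                               database_tag = unique(hits$database_tag))
    per <- dplyr::left_join(grid, per,
                            by = c("gene_id", "database_tag")) |>
      dplyr::mutate(evidence = tidyr::replace_na(.data$evidence, "none"))
  }
  per
}

#' Classify expression evidence per gene
#'
#' Strong evidence when the gene is expressed (TPM at or above
#' `threshold`) in more than 3 libraries; none when expressed in no
#' library; weak otherwise. Expression in exactly 3 libraries counts as
#' weak — the strong rule is strictly "more than 3" and the conservative
#' reading is adopted for the boundary.
#'
#' @param m An [expression_matrix()]; libraries are the individual
#'   samples.
#' @param threshold TPM presence threshold per library (default 1, the
#'   same convention as [presence_profile()]).
#' @return Tibble `gene_id`, `n_expressed_libraries`, `evidence`.
#' @export
classify_expression <- function(m, threshold = 1) {
  n_lib <- rowSums(m$values >= threshold)
  tibble::tibble(
    gene_id = rownames(m$values),
    n_expressed_libraries = as.integer(n_lib),
    evidence = dplyr::case_when(
      n_lib > 3 ~ "strong",
      n_lib == 0 ~ "none",
      TRUE ~ "weak"
    )
  )
}

#' Retention under the at-least-one-strong rule
#'
#' A gene is retained when at least one validation strategy (any
#' similarity database, or expression) reports strong evidence.
#'
#' @param seqsim Tibble from [classify_seqsim()].
#' @param expr Tibble from [classify_expression()] (optional).
#' @param genes Gene universe; defaults to the union of genes seen in the
#'   evidence tables.
#' @return A list: `records` (tibble `gene_id`, `n_strong`, `retained`),
#'   `n_total`, `n_retained`, `pct_retained` (percent, full precision —
#'   round for display).
#' @export
retention <- function(seqsim, expr = NULL, genes = NULL) {
  strong_tbl <- dplyr::bind_rows(
    seqsim[c("gene_id", "evidence")],
    if (!is.null(expr)) expr[c("gene_id", "evidence")]
  )
  if (is.null(genes)) genes <- unique(strong_tbl$gene_id)
  n_strong <- strong_tbl |>
    dplyr::filter(.data$evidence == "strong") |>
    dplyr::count(.data$gene_id, name = "n_strong")
  records <- tibble::tibble(gene_id = genes) |>
    dplyr::left_join(n_strong, by = "gene_id") |>
    dplyr::mutate(n_strong = tidyr::replace_na(.data$n_strong, 0L),
                  retained = .data$n_strong >= 1)
  list(
    records = records,
    n_total = nrow(records),
    n_retained = sum(records$retained),
    pct_retained = 100 * sum(records$retained) / nrow(records)
  )
}

#' Translate a CDS and measure correspondence to a protein sequence
#'
#' The CDS (length a multiple of 3 after removing a trailing stop codon)
#' is translated with the standard genetic code and compared position by
#' position to the protein over the shorter of the two lengths; the length
#' difference is added to the mismatch count, and the fraction is taken
#' over the longer length. Untranslatable (ambiguous) codons translate to
#' `X` and count as mismatches unless the protein also has `X` there. A
#' gene passes at a mismatch fraction of at most `max_mismatch`.
#'
#' @param cds Character string of nucleotides (a single CDS).
#' @param protein Character string of amino acids (no trailing stop).
#' @param max_mismatch Pass threshold, inclusive (default 0.10).
#' @return A list: `mismatch_fraction`, `pass`, `n_compared`.
#' @export
protein_correspondence <- function(cds, protein, max_mismatch = 0.10) {
  cds <- toupper(gsub("\\s", "", cds))
  protein <- toupper(gsub("\\s|\\*$", "", protein))
  if (nchar(cds) %% 3 == 0 &&
      substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    cds <- substr(cds, 1, nchar(cds) - 3)
  }
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length not a multiple of 3 after trailing-stop trimming")
  }
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
  la <- nchar(aa); lp <- nchar(protein)
  n_cmp <- min(la, lp)
  a1 <- strsplit(substr(aa, 1, n_cmp), "")[[1]]
  a2 <- strsplit(substr(protein, 1, n_cmp), "")[[1]]
  mism <- sum(a1 != a2) + abs(la - lp)
  frac <- if (max(la, lp) > 0) mism / max(la, lp) else 0
  list(mismatch_fraction = frac, pass = frac <= max_mismatch,
       n_compared = n_cmp)
}
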