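#' Read an orthogroup membership table
#'
#' Both supported dialects are tab-separated with a header row naming the
#' species columns and the first column holding the orthogroup id. Cell
#' members may be separated by commas, semicolons or whitespace (field
#' conventions vary between tools); empty cells mean the species has no
#' gene in the orthogroup.
#'
#' @param path Path to the TSV file.
#' @param dialect `"broccoli"` or `"orthofinder"`. The two layouts parse
#'   identically here; the argument records provenance and rejects unknown
#'   dialects.
#' @return An [orthogroup_table()].
#' @export
read_orthogroups <- function(path, dialect = c("broccoli", "orthofinder")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("orthogroup table needs an id column plus species columns")
  species <- names(raw)[-1]
  og_ids <- raw[[1]]
  long <- lapply(seq_along(species), function(j) {
    cells <- raw[[j + 1]]
    genes <- strsplit(ifelse(is.na(cells), "", cells), "[,;]\\s*|\\s+")
    n <- lengths(genes)
    tibble::tibble(
      orthogroup_id = rep(og_ids, n),
      species_id = species[j],
      gene_id = unlist(genes, use.names = FALSE)
    )
  })
  long <- dplyr::bind_rows(long)
  long <- long[long$gene_id != "", ]
  orthogroup_table(long)
}

#' Write an orthogroup table in the wide TSV layout
#' @param table An [orthogroup_table()].
#' @param path Output path.
#' @param species Column order; default all species in the table, sorted.
#' @export
write_orthogroups <- function(table, path, species = NULL) {
  if (is.null(species)) species <- sort(unique(table$species_id))
  wide <- table |>
    dplyr::group_by(.data$orthogroup_id, .data$species_id) |>
    dplyr::summarise(members = paste(.data$gene_id, collapse = ","),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species_id", values_from = "members",
                       values_fill = "")
  for (sp in setdiff(species, names(wide))) wide[[sp]] <- ""
  wide <- wide[c("orthogroup_id", species)]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read gene coordinates from GFF3 or BED
#'
#' Internal coordinates are normalized to 1-based inclusive (the GFF3
#' convention); BED's 0-based half-open intervals are converted at the
#' boundary. From GFF3 only records of type `gene` are taken, keeping the
#' longest span per gene id. Ranks are assigned per chromosome by ascending
#' start (ties by end, then gene id).
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param species_id Species label stored on every record.
#' @return A [gene_records()] tibble.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed"),
                                 species_id = "unknown") {
  format <- match.arg(format)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop("failed to parse ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (format == "gff3") {
    md <- S4Vectors::mcols(gr)
    gr <- gr[!is.na(md$type) & as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else as.character(md$Name)
    ids <- sub("^gene:", "", ids)
  } else {
    ids <- as.character(S4Vectors::mcols(gr)$name)
  }
  if (length(gr) == 0) stop("no gene records found in ", basename(path))
  df <- tibble::tibble(
    gene_id = ids,
    species_id = species_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  df$strand[df$strand == "*"] <- "."
  # one row per gene id: keep the longest span (isoform rows, if any)
  df <- df |>
    dplyr::mutate(len = .data$end - .data$start + 1L) |>
    dplyr::arrange(dplyr::desc(.data$len)) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-"len")
  gene_records(df)
}

#' Write gene records as BED6
#' @param records A [gene_records()] tibble.
#' @param path Output path.
#' @export
write_gene_annotation_bed <- function(records, path) {
  bed <- tibble::tibble(
    chrom = records$chrom,
    start = records$start - 1L,       # BED is 0-based half-open
    end = records$end,
    name = records$gene_id,
    score = 0L,
    strand = ifelse(records$strand %in% c("+", "-"), records$strand, ".")
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an ohnolog gene list
#'
#' Three-column table (species, gene, WGD round), with or without a header.
#' Round labels are normalized to upper case and restricted to `2R`
#' (the two rounds at the origin of vertebrates) and `3R` (the
#' teleost-specific round); duplicate records are collapsed.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `species_id`, `gene_id`, `wgd_round`.
#' @export
read_ohnologs <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("\t[0-9]+[Rr]\\s*$", first)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("ohnolog list needs 3 columns: species, gene, round")
  names(df)[1:3] <- c("species_id", "gene_id", "wgd_round")
  df$wgd_round <- toupper(trimws(df$wgd_round))
  bad <- setdiff(unique(df$wgd_round), c("2R", "3R"))
  if (length(bad) > 0) {
    stop("unknown WGD round label(s): ", paste(bad, collapse = ", "))
  }
  dplyr::distinct(tibble::as_tibble(df[1:3]))
}

#' Query ohnolog membership
#' @param ohnologs Tibble from [read_ohnologs()] (or the same layout).
#' @param species_id,gene_id,wgd_round Query values; `wgd_round = NULL`
#'   matches either round.
#' @return Logical; unknown genes return `FALSE` without error.
#' @export
is_ohnolog <- function(ohnologs, species_id, gene_id, wgd_round = NULL) {
  hit <- ohnologs$species_id == species_id & ohnologs$gene_id == gene_id
  if (!is.null(wgd_round)) hit <- hit & ohnologs$wgd_round == wgd_round
  any(hit)
}

#' Read a TPM expression matrix plus sample metadata
#'
#' @param path TSV matrix, first column gene ids, remaining columns samples.
#' @param meta_path TSV with columns `sample_id`, `condition_id` and
#'   optionally `condition_class`. Samples absent from the metadata are
#'   dropped with a warning; negative values are an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, meta_path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  values <- as.matrix(df[-1])
  if (!is.numeric(values)) stop("non-numeric value in expression matrix")
  rownames(values) <- df[[1]]
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and its sample metadata as TSV
#' @param m An [expression_matrix()].
#' @param path,meta_path Output paths for the matrix and metadata.
#' @export
write_expression <- function(m, path, meta_path) {
  df <- tibble::as_tibble(m$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(m$samples, meta_path, progress = FALSE)
  invisible(path)
}

#' Read gene trees with a tip-to-species mapping
#'
#' @param path Newick file, one or more trees.
#' @param species_map Optional named character vector tip label -> species.
#'   When `NULL`, species are extracted with `species_regex`.
#' @param species_regex Regex whose first capture group is the species id
#'   (default: everything before the first underscore).
#' @return A list of gene-tree records: `list(tree = <phylo>,
#'   tip_species = <named chr>)`.
#' @export
read_gene_trees <- function(path, species_map = NULL,
                            species_regex = "^([^_]+)_") {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) {
    tips <- tr$tip.label
    if (!is.null(species_map)) {
      sp <- unname(species_map[tips])
    } else {
      m <- regmatches(tips, regexec(species_regex, tips))
      sp <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                   character(1))
    }
    if (anyNA(sp)) {
      stop("tip label(s) not mappable to a species: ",
           paste(tips[is.na(sp)], collapse = ", "))
    }
    list(tree = tr, tip_species = stats::setNames(sp, tips))
  })
}

#' Write a list of gene-tree records to a newick file
#' @param trees List as returned by [read_gene_trees()].
#' @param path Output path.
#' @export
write_gene_trees <- function(trees, path) {
  cls <- lapply(trees, `[[`, "tree")
  class(cls) <- "multiPhylo"
  ape::write.tree(cls, file = path)
  invisible(path)
}

#' Read a Gene Ontology graph from OBO
#'
#' A minimal OBO stanza parser (no R OBO reader is among the package's
#' dependencies) keeping `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines of non-obsolete `[Term]` stanzas. Only
#' `is_a` and `part_of` edges are retained, the standard choice for
#' annotation propagation.
#'
#' @param path Path to the OBO file.
#' @return A list of class `ontology_dag` with elements `terms` (tibble:
#'   `term_id`, `name`, `namespace`) and `edges` (tibble: `term_id`,
#'   `parent_id`, `relation`). The graph is checked to be acyclic.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  in_term <- FALSE
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  store <- function(cur) {
    if (is.null(cur)) return()
    terms[[length(terms) + 1]] <<- tibble::tibble(
      term_id = cur$id,
      name = cur$name %||% NA_character_,
      namespace = cur$namespace %||% NA_character_
    )
    for (p in cur$is_a) {
      edges[[length(edges) + 1]] <<- tibble::tibble(
        term_id = cur$id, parent_id = p, relation = "is_a")
    }
    for (p in cur$part_of) {
      edges[[length(edges) + 1]] <<- tibble::tibble(
        term_id = cur$id, parent_id = p, relation = "part_of")
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      store(flush(cur)); cur <- list(is_a = character(), part_of = character())
      in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) { store(flush(cur)); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete: *true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    } else if (grepl("^relationship: *part_of", ln)) {
      cur$part_of <- c(cur$part_of,
                       trimws(sub("!.*$", "", sub("^relationship: *part_of", "", ln))))
    }
  }
  store(flush(cur))
  dag <- ontology_dag(dplyr::bind_rows(terms), dplyr::bind_rows(edges))
  dag
}

#' Construct an ontology DAG from term and edge tables
#' @param terms Tibble with at least `term_id` (optionally `name`,
#'   `namespace`).
#' @param edges Tibble with `term_id`, `parent_id` (optionally `relation`).
#' @return An `ontology_dag`; errors on cycles.
#' @export
ontology_dag <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  if (!"name" %in% names(terms)) terms$name <- NA_character_
  if (!"namespace" %in% names(terms)) terms$namespace <- NA_character_
  if (nrow(edges) > 0) {
    if (!"relation" %in% names(edges)) edges$relation <- "is_a"
    g <- igraph::graph_from_data_frame(
      edges[c("term_id", "parent_id")], directed = TRUE)
    if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  }
  structure(list(terms = terms, edges = edges), class = "ontology_dag")
}

#' Read gene-to-GO-term associations
#'
#' @param path Two-column TSV (gene, term) or a GAF file (columns 2 and 5
#'   are used; `!` comment lines skipped).
#' @param format `"tsv"` or `"gaf"`.
#' @param dag Optional [ontology_dag()]; terms absent from the DAG are
#'   flagged with a warning (kept in the map).
#' @return A tibble `gene_id`, `term_id` (distinct rows).
#' @export
read_gene_go_map <- function(path, format = c("tsv", "gaf"), dag = NULL) {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- readLines(path)
    lines <- lines[!grepl("^!", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- tibble::tibble(
      gene_id = vapply(parts, `[`, character(1), 2),
      term_id = vapply(parts, `[`, character(1), 5)
    )
  } else {
    df <- readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                          col_types = "cc", progress = FALSE)
    if (identical(unlist(df[1, ], use.names = FALSE),
                  c("gene_id", "term_id"))) df <- df[-1, ]
  }
  df <- dplyr::distinct(df)
  if (!is.null(dag)) {
    unknown <- setdiff(df$term_id, dag$terms$term_id)
    if (length(unknown) > 0) {
      warning(length(unknown), " annotation term(s) absent from the DAG")
    }
  }
  df
}

#' Read BLAST tabular hits
#'
#' Expects `-outfmt "6 qseqid sseqid pident length qlen slen evalue"`.
#'
#' @param path Path to the tabular file.
#' @param database_tag Label for the database searched (one file per
#'   database; evidence classification is per database).
#' @return A tibble `query_id`, `subject_id`, `pct_identity`, `aln_length`,
#'   `qlen`, `slen`, `evalue`, `database_tag`.
#' @export
read_blast_hits <- function(path, database_tag) {
  df <- readr::read_tsv(
    path,
    col_names = c("query_id", "subject_id", "pct_identity", "aln_length",
                  "qlen", "slen", "evalue"),
    col_types = "ccddddd", progress = FALSE)
  if (any(df$aln_length < 1)) stop("alignment length < 1 in BLAST table")
  if (any(df$evalue < 0)) stop("negative e-value in BLAST table")
  df$database_tag <- database_tag
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
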