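#' Parameters of the synthetic data generator
#'
#' Defaults encode the study conditions the pipeline is built for: a
#' three-amphioxus plus four-vertebrate panel, roughly one fifth of
#' orthogroups duplicated per lineage, 2R ohnolog labelling of half of the
#' duplicated vertebrate orthogroups, a small teleost-only 3R fraction, a
#' quarter of duplicate placements in tandem, seven matched expression
#' conditions and a subfunctionalization probability above one half (the
#' regime in which duplicates partition an ancestral expression domain).
#'
#' @param seed Master seed; one independent stream per component is derived
#'   from it, so disabling a component does not shift the others.
#' @param n_orthogroups Number of orthogroups.
#' @param cfg A [lineage_config()]; default [default_panel_config()].
#' @param p_dup_a,p_dup_b Marginal per-lineage duplication probabilities
#'   for shared orthogroups.
#' @param enrichment_f Joint-duplication multiplier:
#'   `P(dup A and dup B) = f * p_dup_a * p_dup_b`, capped at the smaller
#'   marginal. `f = 1` means independence.
#' @param p_lineage_specific Fraction of orthogroups present in only one
#'   lineage (split evenly).
#' @param p_species_dup Probability that each species of a duplicated
#'   lineage carries the duplication (at least one is forced).
#' @param p_species_missing Per-species probability of absence from an
#'   orthogroup (at least one species per present lineage is forced).
#' @param copies_geom_p Geometric parameter for extra copies beyond the
#'   second in a duplicated species.
#' @param p_ohnolog Fraction of vertebrate-duplicated shared orthogroups
#'   labelled as 2R ohnolog.
#' @param p_3r_only Fraction of the remaining vertebrate-duplicated shared
#'   orthogroups whose duplication is confined to the 3R-bearing species
#'   and 3R-labelled (these should be demoted by the classifier).
#' @param tandem_fraction Probability that an extra copy is placed
#'   immediately adjacent to the previous copy.
#' @param n_chrom_a,n_chrom_b Chromosome counts for A- and B-lineage
#'   species.
#' @param expr_species Length-2 named character vector: the species (one
#'   per lineage) for which expression matrices are generated.
#' @param n_conditions Number of matched expression conditions.
#' @param p_cond_present Per-condition probability in the ancestral
#'   presence profile.
#' @param subfun_prob Probability that duplicates partition the ancestral
#'   condition set (vs all inheriting it fully).
#' @param expr_mu,expr_sigma Lognormal (meanlog, sdlog) for TPM in present
#'   conditions.
#' @param n_reps Samples per condition.
#' @param dropout Per-sample probability of zeroing a present condition.
#' @param scramble_prob Probability of breaking lineage monophyly of a
#'   gene tree (by exchanging one tip across lineages).
#' @param go_n_terms Number of GO terms in the synthetic DAG.
#' @param go_coupling Strength in `[0, 1]` of the association between a
#'   term's latent duplicability and the duplication status of the
#'   orthogroups annotated to it (0 = annotation independent of
#'   duplication).
#' @param go_terms_per_og Mean number of terms annotated per orthogroup.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(seed = 1,
                         n_orthogroups = 1000,
                         cfg = default_panel_config(),
                         p_dup_a = 0.20, p_dup_b = 0.25,
                         enrichment_f = 1,
                         p_lineage_specific = 0.2,
                         p_species_dup = 0.6,
                         p_species_missing = 0.1,
                         copies_geom_p = 0.6,
                         p_ohnolog = 0.5,
                         p_3r_only = 0.05,
                         tandem_fraction = 0.25,
                         n_chrom_a = 19, n_chrom_b = 25,
                         expr_species = c(a = "Blan", b = "Drer"),
                         n_conditions = 7,
                         p_cond_present = 0.8,
                         subfun_prob = 0.7,
                         expr_mu = 3, expr_sigma = 1,
                         n_reps = 2,
                         dropout = 0.02,
                         scramble_prob = 0.1,
                         go_n_terms = 40,
                         go_coupling = 0.8,
                         go_terms_per_og = 2) {
  p <- as.list(environment())
  probs <- c(p$p_dup_a, p$p_dup_b, p$p_lineage_specific, p$p_species_dup,
             p$p_species_missing, p$copies_geom_p, p$p_ohnolog, p$p_3r_only,
             p$tandem_fraction, p$p_cond_present, p$subfun_prob, p$dropout,
             p$scramble_prob, p$go_coupling)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p$enrichment_f < 1) stop("enrichment_f must be >= 1")
  fmax <- min(p$p_dup_a, p$p_dup_b) / (p$p_dup_a * p$p_dup_b)
  if (p$enrichment_f > fmax) {
    stop("enrichment_f infeasible for these marginals; maximum is ",
         signif(fmax, 4))
  }
  class(p) <- "synth_params"
  p
}

# One pseudo-random stream per component, derived from the master seed.
stream_seed <- function(seed, component) {
  (as.integer(seed) %% 100000L) * 17L + component * 104729L
}

#' Simulate a complete synthetic input bundle
#'
#' Draws orthogroups with per-lineage duplication and a tunable
#' co-duplication enrichment, places gene copies on chromosomes with a
#' tandem fraction, labels vertebrate duplicates as 2R ohnologs (plus a
#' teleost-only 3R subset), simulates condition-level expression in which
#' duplicates partition an ancestral presence profile with the
#' subfunctionalization probability, builds lineage-monophyletic gene
#' trees scrambled with a known probability, and attaches a synthetic GO
#' DAG whose term annotations can be coupled to duplication status. A
#' truth table records every latent label so that each pipeline stage's
#' estimate can be checked against the generating parameter.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `synth_bundle`: `table` (orthogroup table),
#'   `records` (gene coordinates for all species), `ohnologs`, `expr_a`,
#'   `expr_b` (expression matrices for the two `expr_species`),
#'   `condition_map`, `dag`, `gomap` (source-species annotations),
#'   `trees`, `truth`, `cfg`, `params`.
#' @export
simulate_bundle <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  cfg <- params$cfg
  spA <- lineage_species(cfg, cfg$focal[1])
  spB <- lineage_species(cfg, cfg$focal[2])
  n <- params$n_orthogroups
  og_ids <- sprintf("og%05d", seq_len(n))

  ## --- component 1: orthogroup structure -------------------------------
  set.seed(stream_seed(params$seed, 1L))
  u_class <- stats::runif(n)
  og_class <- ifelse(u_class < params$p_lineage_specific / 2, "a_only",
              ifelse(u_class < params$p_lineage_specific, "b_only",
                     "shared"))
  pA <- params$p_dup_a; pB <- params$p_dup_b
  p11 <- min(params$enrichment_f * pA * pB, min(pA, pB))
  p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - p11 - p10 - p01
  joint <- sample(c("11", "10", "01", "00"), n, replace = TRUE,
                  prob = c(p11, p10, p01, p00))
  dup_a <- og_class != "b_only" &
    ifelse(og_class == "shared", joint %in% c("11", "10"),
           stats::runif(n) < pA)
  dup_b <- og_class != "a_only" &
    ifelse(og_class == "shared", joint %in% c("11", "01"),
           stats::runif(n) < pB)

  sp3 <- intersect(cfg$wgd_3r_species, spB)
  vert_dup <- which(dup_b & og_class != "a_only")
  is_2r <- rep(FALSE, n)
  is_2r[vert_dup] <- stats::runif(length(vert_dup)) < params$p_ohnolog
  is_3r_only <- rep(FALSE, n)
  cand3 <- which(dup_b & !is_2r & og_class == "shared")
  if (length(sp3) > 0 && length(cand3) > 0) {
    is_3r_only[cand3] <- stats::runif(length(cand3)) < params$p_3r_only
  }

  # per-species copy numbers
  counts <- matrix(0L, nrow = n, ncol = length(c(spA, spB)),
                   dimnames = list(og_ids, c(spA, spB)))
  fill_lineage <- function(i, sps, dup) {
    present <- stats::runif(length(sps)) >= params$p_species_missing
    if (!any(present)) present[sample(length(sps), 1)] <- TRUE
    cnt <- as.integer(present)
    if (dup) {
      cand <- which(present)
      dup_sp <- cand[stats::runif(length(cand)) < params$p_species_dup]
      if (length(dup_sp) == 0) dup_sp <- sample(cand, 1)
      cnt[dup_sp] <- 2L + stats::rgeom(length(dup_sp),
                                       params$copies_geom_p)
    }
    cnt
  }
  for (i in seq_len(n)) {
    if (og_class[i] != "b_only") {
      counts[i, spA] <- fill_lineage(i, spA, dup_a[i])
    }
    if (og_class[i] != "a_only") {
      if (is_3r_only[i]) {
        present <- rep(1L, length(spB))
        names(present) <- spB
        present[sp3] <- 2L + stats::rgeom(length(sp3), params$copies_geom_p)
        counts[i, spB] <- present
      } else {
        counts[i, spB] <- fill_lineage(i, spB, dup_b[i])
      }
    }
  }

  long <- lapply(colnames(counts), function(sp) {
    k <- counts[, sp]
    keep <- k > 0
    tibble::tibble(
      orthogroup_id = rep(og_ids[keep], k[keep]),
      species_id = sp,
      gene_id = paste0(sp, "_", rep(og_ids[keep], k[keep]), "_",
                       unlist(lapply(k[keep], seq_len)))
    )
  })
  table <- orthogroup_table(dplyr::bind_rows(long))

  # ohnolog list: 2R labels on up to two genes per duplicated vertebrate
  # species of a 2R orthogroup; 3R labels on the 3R species' genes of
  # 3R-only orthogroups
  ohno_sp <- character(); ohno_gene <- character(); ohno_round <- character()
  for (i in which(is_2r)) {
    for (sp in spB) {
      if (counts[i, sp] >= 2) {
        ohno_sp <- c(ohno_sp, sp, sp)
        ohno_gene <- c(ohno_gene, paste0(sp, "_", og_ids[i], "_", 1:2))
        ohno_round <- c(ohno_round, "2R", "2R")
      }
    }
  }
  for (i in which(is_3r_only)) {
    for (sp in sp3) {
      ids <- paste0(sp, "_", og_ids[i], "_", seq_len(counts[i, sp]))
      ohno_sp <- c(ohno_sp, rep(sp, length(ids)))
      ohno_gene <- c(ohno_gene, ids)
      ohno_round <- c(ohno_round, rep("3R", length(ids)))
    }
  }
  ohnologs <- tibble::tibble(species_id = ohno_sp, gene_id = ohno_gene,
                             wgd_round = ohno_round)

  ## --- component 2: chromosomal placement ------------------------------
  set.seed(stream_seed(params$seed, 2L))
  gene_len <- 1000L; gap <- 500L
  tandem_truth <- list()
  rec_rows <- list()
  for (sp in colnames(counts)) {
    n_chrom <- if (sp %in% spA) params$n_chrom_a else params$n_chrom_b
    chroms <- paste0("chr", seq_len(n_chrom))
    k_all <- counts[, sp]
    present <- which(k_all > 0)
    # gene ids in orthogroup order; extra copies join the previous copy's
    # block with probability tandem_fraction, else start a new block
    gene_ids <- unlist(lapply(present, function(i) {
      paste0(sp, "_", og_ids[i], "_", seq_len(k_all[i]))
    }), use.names = FALSE)
    copy_no <- unlist(lapply(present, function(i) seq_len(k_all[i])),
                      use.names = FALSE)
    og_of <- rep(og_ids[present], k_all[present])
    is_extra <- copy_no > 1
    tand <- rep(FALSE, length(gene_ids))
    tand[is_extra] <- stats::runif(sum(is_extra)) < params$tandem_fraction
    new_block <- !tand
    block_id <- cumsum(new_block)
    if (any(is_extra)) {
      tandem_truth[[sp]] <- tibble::tibble(
        species_id = sp, orthogroup_id = og_of[is_extra],
        gene_id = gene_ids[is_extra], tandem = tand[is_extra])
    }
    n_blocks <- max(block_id)
    block_chrom <- sample(chroms, n_blocks, replace = TRUE)
    blocks <- split(seq_along(gene_ids), block_id)
    ord <- sample(n_blocks)
    gidx <- unlist(blocks[ord], use.names = FALSE)
    chrom_vec <- rep(block_chrom[ord], lengths(blocks[ord]))
    pos_in_chrom <- stats::ave(rep(1L, length(gidx)), chrom_vec,
                               FUN = cumsum)
    start <- 1L + (pos_in_chrom - 1L) * (gene_len + gap)
    rec_rows[[sp]] <- tibble::tibble(
      gene_id = gene_ids[gidx], species_id = sp, chrom = chrom_vec,
      start = start, end = start + gene_len - 1L,
      strand = sample(c("+", "-"), length(gidx), replace = TRUE))
  }
  records <- gene_records(dplyr::bind_rows(rec_rows))

  ## --- component 3: expression -----------------------------------------
  set.seed(stream_seed(params$seed, 3L))
  C <- params$n_conditions
  if (C == 7) {
    cmap <- default_condition_map()
  } else {
    cmap <- tibble::tibble(condition_a = paste0("cond", seq_len(C)),
                           condition_b = paste0("cond", seq_len(C)))
  }
  anc <- matrix(stats::runif(n * C) < params$p_cond_present, nrow = n)
  none <- rowSums(anc) == 0
  anc[cbind(which(none), sample(C, sum(none), replace = TRUE))] <- TRUE
  subfun <- matrix(stats::runif(n * 2) < params$subfun_prob, nrow = n,
                   dimnames = list(og_ids, c("a", "b")))

  make_expr <- function(sp, side, conds) {
    genes <- table[table$species_id == sp, ]
    gene_ids <- genes$gene_id
    og_idx <- match(genes$orthogroup_id, og_ids)
    present <- matrix(FALSE, nrow = length(gene_ids), ncol = C,
                      dimnames = list(gene_ids, conds))
    for (i in unique(og_idx)) {
      rows <- which(og_idx == i)
      conds_on <- which(anc[i, ])
      if (length(rows) == 1 || !subfun[i, side]) {
        present[rows, conds_on] <- TRUE
      } else {
        owner <- sample(rows, length(conds_on), replace = TRUE)
        for (j in seq_along(conds_on)) {
          present[owner[j], conds_on[j]] <- TRUE
        }
      }
    }
    sample_ids <- paste0(rep(conds, each = params$n_reps), "_r",
                         seq_len(params$n_reps))
    vals <- matrix(0, nrow = length(gene_ids), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(conds)) {
      cols <- (j - 1) * params$n_reps + seq_len(params$n_reps)
      on <- present[, j]
      n_on <- sum(on)
      if (n_on > 0) {
        draws <- matrix(stats::rlnorm(n_on * params$n_reps,
                                      params$expr_mu, params$expr_sigma),
                        nrow = n_on)
        draws[matrix(stats::runif(length(draws)) < params$dropout,
                     nrow = n_on)] <- 0
        vals[on, cols] <- draws
      }
    }
    meta <- tibble::tibble(
      sample_id = sample_ids,
      condition_id = rep(conds, each = params$n_reps),
      condition_class = "adult_tissue")
    expression_matrix(vals, meta)
  }
  expr_a <- make_expr(params$expr_species[["a"]], "a", cmap$condition_a)
  expr_b <- make_expr(params$expr_species[["b"]], "b", cmap$condition_b)

  ## --- component 4: gene trees -----------------------------------------
  set.seed(stream_seed(params$seed, 4L))
  rand_clade <- function(tips) {
    if (length(tips) == 1) return(tips)
    k <- sample(length(tips) - 1, 1)
    left <- sample(tips, k)
    paste0("(", rand_clade(left), ",",
           rand_clade(setdiff(tips, left)), ")")
  }
  trees <- list()
  scrambled_truth <- stats::setNames(rep(NA, n), og_ids)
  genes_by_og_a <- split(table$gene_id[table$species_id %in% spA],
                         table$orthogroup_id[table$species_id %in% spA])
  genes_by_og_b <- split(table$gene_id[table$species_id %in% spB],
                         table$orthogroup_id[table$species_id %in% spB])
  for (i in seq_len(n)) {
    tipsA <- genes_by_og_a[[og_ids[i]]]
    tipsB <- genes_by_og_b[[og_ids[i]]]
    if (is.null(tipsA) || is.null(tipsB)) next
    if (length(tipsA) < 2 || length(tipsB) < 2) next
    scr <- stats::runif(1) < params$scramble_prob
    scrambled_truth[i] <- scr
    if (scr) {   # exchange one tip across lineages: breaks both clades
      ia <- sample(length(tipsA), 1); ib <- sample(length(tipsB), 1)
      tmp <- tipsA[ia]; tipsA[ia] <- tipsB[ib]; tipsB[ib] <- tmp
    }
    nwk <- paste0("(", rand_clade(tipsA), ",", rand_clade(tipsB), ");")
    tr <- ape::read.tree(text = nwk)
    sp <- sub("_.*$", "", tr$tip.label)
    trees[[og_ids[i]]] <- list(tree = tr,
                               tip_species = stats::setNames(sp, tr$tip.label))
  }

  ## --- component 5: GO -------------------------------------------------
  set.seed(stream_seed(params$seed, 5L))
  nt <- params$go_n_terms
  term_ids <- sprintf("GO:%07d", seq_len(nt))
  ns <- rep(c("molecular_function", "biological_process"), length.out = nt)
  edges <- list()
  for (i in 3:nt) {
    cand <- which(seq_len(i - 1) >= 1 & ns[seq_len(i - 1)] == ns[i])
    parent <- if (length(cand) > 0) sample(cand, 1) else (i %% 2) + 1
    edges[[length(edges) + 1]] <- tibble::tibble(
      term_id = term_ids[i], parent_id = term_ids[parent],
      relation = "is_a")
  }
  dag <- ontology_dag(
    tibble::tibble(term_id = term_ids, name = paste("term", seq_len(nt)),
                   namespace = ns),
    dplyr::bind_rows(edges))
  w <- stats::runif(nt)
  src_sp <- "Hsap"
  gomap_rows <- list()
  shared_idx <- which(og_class == "shared")
  genes_by_og_src <- split(table$gene_id[table$species_id == src_sp],
                           table$orthogroup_id[table$species_id == src_sp])
  for (i in shared_idx) {
    d <- dup_a[i] || dup_b[i]
    pref <- 1 + params$go_coupling * (2 * w - 1) * (if (d) 1 else -1)
    pref[pref < 0] <- 0
    k <- min(nt, max(1, stats::rpois(1, params$go_terms_per_og)))
    terms <- sample(term_ids, k, prob = pref)
    src_genes <- genes_by_og_src[[og_ids[i]]]
    if (is.null(src_genes)) src_genes <- character(0)
    if (length(src_genes) > 0) {
      gomap_rows[[length(gomap_rows) + 1]] <- list(
        gene_id = rep(src_genes, each = length(terms)),
        term_id = rep(terms, times = length(src_genes)))
    }
  }
  gomap <- dplyr::distinct(tibble::tibble(
    gene_id = as.character(unlist(lapply(gomap_rows, `[[`, "gene_id"),
                                  use.names = FALSE)),
    term_id = as.character(unlist(lapply(gomap_rows, `[[`, "term_id"),
                                  use.names = FALSE))))

  truth <- tibble::tibble(
    orthogroup_id = og_ids,
    og_class = og_class,
    dup_a = dup_a, dup_b = dup_b,
    is_2r = is_2r, is_3r_only = is_3r_only,
    n_anc_conditions = rowSums(anc),
    subfun_a = subfun[, "a"], subfun_b = subfun[, "b"],
    tree_scrambled = unname(scrambled_truth)
  )
  tandem <- if (length(tandem_truth) > 0) dplyr::bind_rows(tandem_truth) else
    tibble::tibble(species_id = character(), orthogroup_id = character(),
                   gene_id = character(), tandem = logical())

  structure(list(table = table, records = records, ohnologs = ohnologs,
                 expr_a = expr_a, expr_b = expr_b, condition_map = cmap,
                 dag = dag, gomap = gomap, go_source_species = src_sp,
                 trees = trees, truth = truth, tandem_truth = tandem,
                 cfg = cfg, params = params),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("<synthetic bundle> ", dplyr::n_distinct(x$table$orthogroup_id),
      " orthogroups, ", nrow(x$table), " genes, seed ",
      x$params$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle in the external file formats
#'
#' Emits every format the readers consume: the wide orthogroup TSV, one
#' BED6 annotation per species, the ohnolog TSV, expression matrices plus
#' sample metadata, a newick tree file, an OBO ontology with a two-column
#' annotation TSV, the truth table TSV and the parameters as YAML.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_orthogroups(bundle$table, fp("orthogroups.tsv"))
  for (sp in unique(bundle$records$species_id)) {
    write_gene_annotation_bed(
      bundle$records[bundle$records$species_id == sp, ],
      fp(paste0("genes_", sp, ".bed")))
  }
  readr::write_tsv(bundle$ohnologs, fp("ohnologs.tsv"), progress = FALSE)
  write_expression(bundle$expr_a, fp("expr_a.tsv"), fp("expr_a_meta.tsv"))
  write_expression(bundle$expr_b, fp("expr_b.tsv"), fp("expr_b_meta.tsv"))
  readr::write_tsv(bundle$condition_map, fp("condition_map.tsv"),
                   progress = FALSE)
  if (length(bundle$trees) > 0) {
    write_gene_trees(bundle$trees, fp("gene_trees.nwk"))
  }
  write_obo(bundle$dag, fp("ontology.obo"))
  readr::write_tsv(bundle$gomap, fp("gene_go_map.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth, fp("truth.tsv"), progress = FALSE)
  prm <- bundle$params
  prm$cfg <- list(species_to_lineage = as.list(prm$cfg$species_to_lineage),
                  focal = prm$cfg$focal, wgd_lineage = prm$cfg$wgd_lineage,
                  wgd_3r_species = prm$cfg$wgd_3r_species)
  prm$expr_species <- as.list(prm$expr_species)
  yaml::write_yaml(unclass(prm), fp("params.yaml"))
  invisible(dir)
}

#' Write an ontology DAG as a minimal OBO file
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    writeLines(c("", "[Term]",
                 paste0("id: ", dag$terms$term_id[i]),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    e <- dag$edges[dag$edges$term_id == dag$terms$term_id[i], ]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", e$parent_id[j]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent_id[j]), con)
      }
    }
  }
  invisible(path)
}

#' Construct a minimal orthogroup table with exact summary counts
#'
#' Builds, for one species, a table achieving the requested totals
#' exactly: total annotated genes, genes in duplicated orthogroups,
#' orthogroup count, duplicated orthogroup count and (optionally) the
#' cross-lineage orthologous-gene totals, by marking the right amount of
#' orthogroups as shared with a single reference partner species of the
#' opposite lineage. Genes beyond those in orthogroups are reported in the
#' returned `total_genes` (orthology tools leave some genes unassigned,
#' so the annotated total may exceed the genes in the table).
#'
#' @param species_id Focal species id.
#' @param lineage,partner_lineage Lineage names for the species and the
#'   reference partner.
#' @param genes_total,genes_dup,og_total,og_dup Target counts.
#' @param ortho_genes_total,ortho_genes_dup Optional targets for the
#'   columns restricted to orthogroups shared with the partner lineage.
#' @param partner_species Partner species id (default `"REF"`).
#' @return A list: `table`, `cfg`, `total_genes` (named vector for
#'   [species_summary()]).
#' @export
build_counts_fixture <- function(species_id, lineage, partner_lineage,
                                 genes_total, genes_dup, og_total, og_dup,
                                 ortho_genes_total = NULL,
                                 ortho_genes_dup = NULL,
                                 partner_species = "REF") {
  if (genes_dup < 2 * og_dup) {
    stop("infeasible targets: duplicated genes must be >= 2 x duplicated ",
         "orthogroups")
  }
  singles <- og_total - og_dup
  if (singles < 0) stop("infeasible targets: og_dup exceeds og_total")
  unassigned <- genes_total - genes_dup - singles
  if (unassigned < 0) {
    stop("infeasible targets: genes_total smaller than genes implied by ",
         "the orthogroup counts")
  }
  if (is.null(ortho_genes_total)) ortho_genes_total <- 0
  if (is.null(ortho_genes_dup)) ortho_genes_dup <- 0
  g_od <- ortho_genes_dup
  g_os <- ortho_genes_total - g_od
  if (g_od > genes_dup || g_os > singles || g_os < 0) {
    stop("infeasible cross-lineage targets")
  }
  g_dn <- genes_dup - g_od
  lo <- max(if (g_od > 0) 1 else 0, og_dup - floor(g_dn / 2))
  hi <- min(if (g_dn > 0) og_dup - 1 else og_dup, floor(g_od / 2))
  if (lo > hi) stop("infeasible cross-lineage duplicated-gene target")
  s_d <- hi

  sizes_shared <- if (s_d > 0) {
    v <- rep(2, s_d); v[1] <- v[1] + (g_od - 2 * s_d); v
  } else {
    numeric(0)
  }
  n_rest <- og_dup - s_d
  sizes_rest <- if (n_rest > 0) {
    v <- rep(2, n_rest); v[1] <- v[1] + (g_dn - 2 * n_rest); v
  } else {
    numeric(0)
  }

  og_id <- sprintf("og%06d", seq_len(og_total))
  sizes <- c(sizes_shared, sizes_rest, rep(1, singles))
  shared <- c(rep(TRUE, s_d), rep(FALSE, n_rest),
              rep(TRUE, g_os), rep(FALSE, singles - g_os))
  gene_no <- 0L
  rows <- vector("list", og_total)
  for (i in seq_len(og_total)) {
    ids <- paste0(species_id, "_g", gene_no + seq_len(sizes[i]))
    gene_no <- gene_no + sizes[i]
    rows[[i]] <- tibble::tibble(orthogroup_id = og_id[i],
                                species_id = species_id, gene_id = ids)
  }
  tab <- dplyr::bind_rows(rows)
  partner <- tibble::tibble(
    orthogroup_id = og_id[shared],
    species_id = partner_species,
    gene_id = paste0(partner_species, "_g", seq_len(sum(shared))))
  table <- orthogroup_table(dplyr::bind_rows(tab, partner))
  cfg <- lineage_config(
    stats::setNames(c(lineage, partner_lineage),
                    c(species_id, partner_species)),
    focal = c(lineage, partner_lineage))
  total_genes <- stats::setNames(c(genes_total, sum(shared)),
                                 c(species_id, partner_species))
  list(table = table, cfg = cfg, total_genes = total_genes)
}

#' Simulate coding sequences with matching proteins
#'
#' Random sense codons (no internal stop), translated with the standard
#' genetic code; used to exercise the CDS/protein correspondence filter.
#'
#' @param n_genes Number of genes.
#' @param n_codons Codons per CDS.
#' @param seed Seed.
#' @return Tibble `gene_id`, `cds`, `protein`.
#' @export
synth_cds_protein <- function(n_genes, n_codons, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  rows <- lapply(seq_len(n_genes), function(i) {
    cds <- paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    tibble::tibble(gene_id = sprintf("cds%03d", i), cds = cds,
                   protein = prot)
  })
  dplyr::bind_rows(rows)
}

#' Point-mutate a nucleotide sequence at a fixed per-site rate
#' @param seq Nucleotide string.
#' @param rate Per-site substitution probability.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(toupper(seq), "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste0(chars, collapse = "")
}
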