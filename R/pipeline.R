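#' Run pipeline stages over a directory of input files
#'
#' Orchestrates the analysis stages as composable steps reading and
#' writing plain TSV under `out_dir`. The `simulate` stage writes a
#' synthetic bundle ([write_bundle()] layout); every other stage reads the
#' files a previous stage (or the user) placed in the directory. Outputs
#' are deterministic for fixed inputs and seed, and a machine-readable
#' manifest (input file hashes, parameters, package version) is written
#' alongside the results. No stage mutates its inputs.
#'
#' @param stage One of `simulate`, `profile`, `enrich`, `trees`,
#'   `goterms`, `expression`, `synteny`, `evidence`, `all`.
#' @param out_dir Directory for inputs and outputs.
#' @param seed Seed for the `simulate` stage.
#' @param params Optional [synth_params()] overriding the default
#'   generator settings (its seed is replaced by `seed`).
#' @param cfg A [lineage_config()]; default [default_panel_config()].
#' @param thresholds Named list of analysis thresholds:
#'   `presence_tpm` (default 1), `min_genes` (50), `mean_copy` (2.5),
#'   `min_fraction` (0.2), `tandem_gap` (0).
#' @return Invisibly, the paths of the files written by the stage.
#' @export
run_pipeline <- function(stage = c("simulate", "profile", "enrich",
                                   "trees", "goterms", "expression",
                                   "synteny", "evidence", "all"),
                         out_dir, seed = 1, params = NULL,
                         cfg = default_panel_config(),
                         thresholds = list()) {
  stage <- match.arg(stage)
  th <- utils::modifyList(
    list(presence_tpm = 1, min_genes = 50, mean_copy = 2.5,
         min_fraction = 0.2, tandem_gap = 0),
    thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  need <- function(...) {
    path <- fp(...)
    if (!file.exists(path)) {
      stop("missing input '", basename(path),
           "' in ", out_dir, "; run the producing stage first",
           call. = FALSE)
    }
    path
  }
  written <- character()

  if (stage %in% c("simulate", "all")) {
    if (is.null(params)) params <- synth_params(seed = seed, cfg = cfg)
    params$seed <- seed
    bundle <- simulate_bundle(params)
    write_bundle(bundle, out_dir)
    written <- c(written, fp("orthogroups.tsv"))
  }

  read_inputs <- function() {
    table <- read_orthogroups(need("orthogroups.tsv"))
    ohno <- read_ohnologs(need("ohnologs.tsv"))
    list(table = table, ohnologs = ohno)
  }

  if (stage %in% c("profile", "all")) {
    inp <- read_inputs()
    profile <- lineage_status(inp$table, cfg, inp$ohnologs)
    readr::write_tsv(profile, fp("profile.tsv"), progress = FALSE)
    readr::write_tsv(species_summary(inp$table, cfg),
                     fp("species_summary.tsv"), progress = FALSE)
    written <- c(written, fp("profile.tsv"), fp("species_summary.tsv"))
  }

  read_profile <- function() {
    path <- need("profile.tsv")
    prof <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    attr(prof, "lineages") <- cfg$focal
    prof
  }

  if (stage %in% c("enrich", "all")) {
    inp <- read_inputs()
    profile <- read_profile()
    enr <- intersection_table(profile, inp$table, cfg)
    readr::write_tsv(enr, fp("enrichment.tsv"), progress = FALSE)
    assoc <- tryCatch(
      copy_number_association(profile, threshold = th$mean_copy),
      error = function(e) NULL)
    if (!is.null(assoc)) {
      readr::write_tsv(
        tibble::tibble(spearman_rho = assoc$spearman_rho,
                       chi2 = assoc$chi2, chi2_p = assoc$chi2_p,
                       n = assoc$n),
        fp("copy_association.tsv"), progress = FALSE)
    }
    written <- c(written, fp("enrichment.tsv"))
  }

  if (stage %in% c("trees", "all")) {
    path <- fp("gene_trees.nwk")
    if (file.exists(path)) {
      trees <- read_gene_trees(path)
      res <- dplyr::bind_rows(lapply(trees, lineage_monophyly, cfg = cfg))
      vr <- validation_rate(res)
      readr::write_tsv(res, fp("monophyly.tsv"), progress = FALSE)
      readr::write_tsv(
        tibble::tibble(rate = vr$rate, n_testable = vr$n_testable,
                       n_validated = vr$n_validated,
                       n_untestable = vr$n_untestable),
        fp("monophyly_rate.tsv"), progress = FALSE)
      written <- c(written, fp("monophyly.tsv"))
    } else if (stage == "trees") {
      need("gene_trees.nwk")
    }
  }

  if (stage %in% c("goterms", "all")) {
    inp <- read_inputs()
    profile <- read_profile()
    dag <- read_obo(need("ontology.obo"))
    gomap <- read_gene_go_map(need("gene_go_map.tsv"))
    closed <- propagate_annotations(dag, gomap)
    tr <- transfer_annotations(closed, inp$table, "Hsap",
                               names(cfg$species_to_lineage)[1])
    stats <- per_term_duplication(tr$target, tr$source, inp$table,
                                  profile, dag,
                                  min_genes = th$min_genes)
    readr::write_tsv(stats, fp("go_term_duplication.tsv"),
                     progress = FALSE)
    readr::write_tsv(parallelism_summary(stats),
                     fp("go_parallelism.tsv"), progress = FALSE)
    written <- c(written, fp("go_term_duplication.tsv"))
  }

  if (stage %in% c("expression", "all")) {
    inp <- read_inputs()
    expr_a <- read_expression(need("expr_a.tsv"), need("expr_a_meta.tsv"))
    expr_b <- read_expression(need("expr_b.tsv"), need("expr_b_meta.tsv"))
    cmap <- readr::read_tsv(need("condition_map.tsv"),
                            show_col_types = FALSE, progress = FALSE)
    means_a <- condition_means(expr_a)
    means_b <- condition_means(expr_b)
    readr::write_tsv(tau_index(means_a), fp("tau_a.tsv"), progress = FALSE)
    pa <- presence_profile(means_a, cmap$condition_a, th$presence_tpm)
    pb <- presence_profile(means_b, cmap$condition_b, th$presence_tpm)
    spa <- names(cfg$species_to_lineage)[1]
    spb <- cfg$wgd_3r_species[1]
    deltas <- dplyr::bind_rows(
      suppressMessages(expression_delta(inp$table, pa, pb, spa, spb,
                                        config = "1:1")),
      suppressMessages(expression_delta(inp$table, pa, pb, spa, spb,
                                        config = "1:many",
                                        mode = "union_vs_single")),
      suppressMessages(expression_delta(inp$table, pa, pb, spa, spb,
                                        config = "many:1",
                                        mode = "union_vs_single")))
    readr::write_tsv(deltas, fp("expression_deltas.tsv"), progress = FALSE)
    written <- c(written, fp("tau_a.tsv"), fp("expression_deltas.tsv"))
  }

  if (stage %in% c("synteny", "all")) {
    inp <- read_inputs()
    sps <- names(cfg$species_to_lineage)
    spa <- sps[1]; spb <- sps[2]
    ann_a <- read_gene_annotation(need(paste0("genes_", spa, ".bed")),
                                  "bed", spa)
    ann_b <- read_gene_annotation(need(paste0("genes_", spb, ".bed")),
                                  "bed", spb)
    pts <- dotplot_points(one_to_one_pairs(inp$table, spa, spb),
                          ann_a, ann_b)
    readr::write_tsv(pts, fp("dotplot_points.tsv"), progress = FALSE)
    loc <- classify_duplicate_locations(inp$table, ann_a, spa,
                                        max_intervening = th$tandem_gap)
    readr::write_tsv(loc$pairs, fp("duplicate_locations.tsv"),
                     progress = FALSE)
    hom <- chromosome_homology(pts, min_fraction = th$min_fraction)
    readr::write_tsv(hom$calls, fp("chromosome_homology.tsv"),
                     progress = FALSE)
    written <- c(written, fp("dotplot_points.tsv"))
  }

  if (stage %in% c("evidence", "all")) {
    expr_a <- read_expression(need("expr_a.tsv"), need("expr_a_meta.tsv"))
    ev <- classify_expression(expr_a, threshold = th$presence_tpm)
    ret <- retention(
      seqsim = tibble::tibble(gene_id = character(),
                              database_tag = character(),
                              evidence = character()),
      expr = ev)
    readr::write_tsv(ev, fp("expression_evidence.tsv"), progress = FALSE)
    readr::write_tsv(
      tibble::tibble(n_total = ret$n_total, n_retained = ret$n_retained,
                     pct_retained = ret$pct_retained),
      fp("retention_summary.tsv"), progress = FALSE)
    written <- c(written, fp("retention_summary.tsv"))
  }

  manifest <- list(
    package = "orthodup",
    version = as.character(utils::packageVersion("orthodup")),
    stage = stage, seed = seed, thresholds = th,
    inputs = as.list(tools::md5sum(
      sort(list.files(out_dir, pattern = "\\.(tsv|bed|nwk|obo|yaml)$",
                      full.names = TRUE))))
  )
  names(manifest$inputs) <- basename(names(manifest$inputs))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(written)
}
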