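chain_dag <- function() {
  ontology_dag(
    tibble::tibble(term_id = c("A", "B", "C"),
                   namespace = "biological_process"),
    tibble::tibble(term_id = c("C", "B"), parent_id = c("B", "A")))
}

test_that("propagation closes annotations upward and is idempotent", {
  gomap <- tibble::tibble(gene_id = "g1", term_id = "C")
  closed <- propagate_annotations(chain_dag(), gomap)
  expect_setequal(closed$term_id, c("A", "B", "C"))
  expect_equal(propagate_annotations(chain_dag(), closed), closed)
  # never removes annotations
  expect_gte(nrow(closed), nrow(gomap))
})

test_that("propagation equals a reflexive-transitive closure oracle", {
  set.seed(55)
  nt <- 30
  terms <- paste0("T", seq_len(nt))
  edges <- dplyr::bind_rows(lapply(2:nt, function(i) {
    n_par <- sample(1:2, 1)
    tibble::tibble(term_id = terms[i],
                   parent_id = terms[sample(i - 1, min(n_par, i - 1))])
  }))
  dag <- ontology_dag(tibble::tibble(term_id = terms), dplyr::distinct(edges))
  genes <- paste0("g", 1:40)
  gomap <- tibble::tibble(
    gene_id = sample(genes, 120, replace = TRUE),
    term_id = sample(terms, 120, replace = TRUE)) |> dplyr::distinct()
  closed <- propagate_annotations(dag, gomap)

  # oracle: boolean matrix closure (repeated multiplication to fixpoint)
  M <- matrix(FALSE, nt, nt, dimnames = list(terms, terms))
  M[cbind(dag$edges$term_id, dag$edges$parent_id)] <- TRUE
  diag(M) <- TRUE
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  for (g in unique(gomap$gene_id)) {
    direct <- gomap$term_id[gomap$gene_id == g]
    reach <- terms[colSums(M[direct, , drop = FALSE]) > 0]
    expect_setequal(closed$term_id[closed$gene_id == g], reach)
  }
})

test_that("orthology transfer unions terms over the orthogroup, both ways", {
  tab <- make_table(list(og1 = list(Hsap = 1, Blan = 2),
                         og2 = list(Hsap = 2, Blan = 1),
                         og3 = list(Hsap = 1),       # no partner: excluded
                         og4 = list(Blan = 1)))
  gomap <- tibble::tibble(
    gene_id = c("Hsap_og1_1", "Hsap_og2_1", "Hsap_og2_2", "Hsap_og3_1"),
    term_id = c("T1", "T1", "T2", "T9"))
  tr <- transfer_annotations(gomap, tab, "Hsap", "Blan")
  # both amphioxus genes of og1 get the human gene's term
  expect_setequal(tr$target$gene_id[tr$target$term_id == "T1"],
                  c("Blan_og1_1", "Blan_og1_2", "Blan_og2_1"))
  # two human genes with different terms: all members get the union,
  # human genes included
  expect_setequal(tr$target$term_id[tr$target$gene_id == "Blan_og2_1"],
                  c("T1", "T2"))
  expect_setequal(tr$source$term_id[tr$source$gene_id == "Hsap_og2_1"],
                  c("T1", "T2"))
  # genes in orthogroups without the partner species are dropped
  expect_false("Hsap_og3_1" %in% tr$source$gene_id)
  expect_false("Blan_og4_1" %in% tr$target$gene_id)

  # symmetry: per-orthogroup term unions identical with roles swapped
  og_union <- function(map, tab) {
    dplyr::inner_join(map, tab, by = "gene_id") |>
      dplyr::distinct(orthogroup_id, term_id) |>
      dplyr::arrange(orthogroup_id, term_id)
  }
  u_tgt <- og_union(tr$target, tab)
  u_src <- og_union(tr$source, tab)
  expect_equal(u_tgt, u_src)
})

test_that("per-term percentages respect counts and the min-genes filter", {
  # two terms: one passes the filter on both sides, one fails on side B
  n_side <- 60
  tab <- make_table(stats::setNames(
    lapply(seq_len(n_side), function(i) list(Hsap = 1, Blan = 1)),
    sprintf("og%03d", seq_len(n_side))))
  # first 30 orthogroups duplicated in both lineages
  dup <- sprintf("og%03d", 1:30)
  prof <- tibble::tibble(
    orthogroup_id = sprintf("og%03d", seq_len(n_side)),
    status_amphioxus = ifelse(sprintf("og%03d", seq_len(n_side)) %in% dup,
                              "small_scale_dup", "single_copy"),
    status_vertebrate = ifelse(sprintf("og%03d", seq_len(n_side)) %in% dup,
                               "small_scale_dup", "single_copy"),
    mean_copies_amphioxus = 1, mean_copies_vertebrate = 1,
    joint_class = "both_single")
  attr(prof, "lineages") <- c("amphioxus", "vertebrate")
  ga <- tibble::tibble(gene_id = paste0("Blan_", sprintf("og%03d", 1:60), "_1"),
                       term_id = "T1")
  gb <- tibble::tibble(gene_id = paste0("Hsap_", sprintf("og%03d", 1:60), "_1"),
                       term_id = "T1")
  small <- tibble::tibble(
    gene_id = paste0("Hsap_", sprintf("og%03d", 1:49), "_1"),
    term_id = "T2")
  st <- per_term_duplication(
    dplyr::bind_rows(ga, tibble::tibble(
      gene_id = paste0("Blan_", sprintf("og%03d", 1:60), "_1"),
      term_id = "T2")),
    dplyr::bind_rows(gb, small), tab, prof, min_genes = 50)
  expect_equal(st$term_id, "T1")
  expect_equal(st$pct_dup_a, 50)
  expect_equal(st$pct_dup_b_ssd, 50)

  # combined definition counts the union of SSD and ohnolog orthogroups
  bundle <- simulate_bundle(synth_params(seed = 61, n_orthogroups = 300))
  prof2 <- lineage_status(bundle$table, bundle$cfg, bundle$ohnologs)
  closed <- propagate_annotations(bundle$dag, bundle$gomap)
  tr <- transfer_annotations(closed, bundle$table, "Hsap", "Blan")
  st2 <- per_term_duplication(tr$target, tr$source, bundle$table, prof2,
                              bundle$dag, min_genes = 5)
  gene_og <- stats::setNames(bundle$table$orthogroup_id,
                             bundle$table$gene_id)
  ssd <- prof2$orthogroup_id[prof2$status_vertebrate == "small_scale_dup"]
  ohno <- prof2$orthogroup_id[prof2$status_vertebrate == "ohnolog"]
  for (t in utils::head(st2$term_id, 10)) {
    genes <- tr$source$gene_id[tr$source$term_id == t]
    ogs <- gene_og[genes]
    expect_equal(st2$n_dup_b_both[st2$term_id == t],
                 sum(ogs %in% union(ssd, ohno)))
    expect_lte(st2$n_dup_b_both[st2$term_id == t],
               st2$n_dup_b_ssd[st2$term_id == t] +
                 st2$n_dup_b_ohno[st2$term_id == t])
  }
})

test_that("coupled duplicability produces a cross-lineage trend, uncoupled does not", {
  run <- function(coupling, f) {
    bundle <- simulate_bundle(synth_params(
      seed = 71, n_orthogroups = 1500, go_coupling = coupling,
      enrichment_f = f, go_n_terms = 30))
    prof <- lineage_status(bundle$table, bundle$cfg, bundle$ohnologs)
    closed <- propagate_annotations(bundle$dag, bundle$gomap)
    tr <- transfer_annotations(closed, bundle$table, "Hsap", "Blan")
    st <- per_term_duplication(tr$target, tr$source, bundle$table, prof,
                               bundle$dag, min_genes = 30)
    stats::cor(st$pct_dup_a, st$pct_dup_b_both, method = "spearman")
  }
  coupled <- run(coupling = 0.9, f = 2)
  uncoupled <- run(coupling = 0, f = 1)
  expect_gt(coupled, 0.7)
  # with 30 terms the null correlation is noisy; assert the contrast
  expect_gt(coupled - uncoupled, 0.4)
})

test_that("empty statistics give an empty summary with the right shape", {
  empty <- per_term_duplication(
    tibble::tibble(gene_id = character(), term_id = character()),
    tibble::tibble(gene_id = character(), term_id = character()),
    make_table(list(og1 = list(Hsap = 1, Blan = 1))),
    {
      p <- tibble::tibble(orthogroup_id = "og1",
                          status_amphioxus = "single_copy",
                          status_vertebrate = "single_copy",
                          mean_copies_amphioxus = 1,
                          mean_copies_vertebrate = 1,
                          joint_class = "both_single")
      attr(p, "lineages") <- c("amphioxus", "vertebrate")
      p
    })
  s <- parallelism_summary(empty)
  expect_equal(nrow(s), 0)
  expect_true(all(c("definition", "pct_a", "pct_b") %in% names(s)))
})
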