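test_that("copy numbers count members and conserve totals", {
  tab <- make_table(list(og1 = list(Blan = 2, Hsap = 1),
                         og2 = list(Bflo = 1)))
  cnm <- copy_number_matrix(tab, names(panel_cfg()$species_to_lineage))
  expect_equal(cnm["og1", "Blan"], 2L)
  expect_equal(cnm["og1", "Drer"], 0L)
  # column totals equal per-species gene counts in the table
  tab2 <- random_table(200, seed = 3)
  cnm2 <- copy_number_matrix(tab2)
  expect_equal(colSums(cnm2)[sort(unique(tab2$species_id))],
               table(tab2$species_id)[sort(unique(tab2$species_id))] |>
                 as.numeric() |> stats::setNames(sort(unique(tab2$species_id))))
})

test_that("lineage statuses follow the duplication, 2R and 3R rules", {
  cfg <- panel_cfg()
  # all single copy
  tab <- make_table(list(og1 = single_copy_counts()))
  p <- lineage_status(tab, cfg)
  expect_equal(p$status_amphioxus, "single_copy")
  expect_equal(p$status_vertebrate, "single_copy")
  expect_equal(p$joint_class, "both_single")

  # one amphioxus species duplicated -> lineage-level duplication
  cts <- single_copy_counts(); cts$Blan <- 2
  p <- lineage_status(make_table(list(og1 = cts)), cfg)
  expect_equal(p$status_amphioxus, "small_scale_dup")
  expect_equal(p$joint_class, "A_specific_dup")
  expect_equal(p$mean_copies_amphioxus, mean(c(2, 1, 1)))

  # zebrafish-only duplication with 3R members is demoted to single copy
  cts <- single_copy_counts(); cts$Drer <- 2
  tab <- make_table(list(og1 = cts))
  oh3 <- tibble::tibble(species_id = "Drer",
                        gene_id = c("Drer_og1_1", "Drer_og1_2"),
                        wgd_round = "3R")
  p <- lineage_status(tab, cfg, oh3)
  expect_equal(p$status_vertebrate, "single_copy")
  expect_equal(p$joint_class, "both_single")
  # without the 3R label it stays a small-scale duplication
  p <- lineage_status(tab, cfg)
  expect_equal(p$status_vertebrate, "small_scale_dup")

  # a 2R member reassigns to ohnolog and blocks the 3R demotion
  oh23 <- dplyr::bind_rows(oh3, tibble::tibble(
    species_id = "Drer", gene_id = "Drer_og1_1", wgd_round = "2R"))
  p <- lineage_status(tab, cfg, oh23)
  expect_equal(p$status_vertebrate, "ohnolog")
  expect_equal(p$joint_class, "B_specific_dup")

  # ohnolog status is structurally forbidden on the non-WGD lineage
  cts <- single_copy_counts(); cts$Blan <- 2
  ohA <- tibble::tibble(species_id = "Blan", gene_id = "Blan_og1_1",
                        wgd_round = "2R")
  p <- lineage_status(make_table(list(og1 = cts)), cfg, ohA)
  expect_equal(p$status_amphioxus, "small_scale_dup")

  expect_error(
    lineage_status(make_table(list(og1 = list(Xenu = 1))), cfg),
    "missing from lineage config")
})

test_that("statuses match an independent rule-by-rule oracle on random tables", {
  cfg <- panel_cfg()
  tab <- random_table(1000, seed = 17)
  # random ohnolog labels on some vertebrate genes
  set.seed(18)
  vg <- tab[tab$species_id %in% c("Drer", "Ggal", "Mmus", "Hsap"), ]
  lab <- vg[sample(nrow(vg), 200), c("species_id", "gene_id")]
  lab$wgd_round <- sample(c("2R", "3R"), nrow(lab), replace = TRUE)
  prof <- lineage_status(tab, cfg, lab)

  # oracle: re-derive each orthogroup independently from first principles
  spA <- c("Blan", "Bflo", "Bbel"); spB <- c("Drer", "Ggal", "Mmus", "Hsap")
  for (og in sample(unique(tab$orthogroup_id), 250)) {
    rows <- tab[tab$orthogroup_id == og, ]
    nA <- sapply(spA, function(s) sum(rows$species_id == s))
    nB <- sapply(spB, function(s) sum(rows$species_id == s))
    stA <- if (all(nA == 0)) "absent" else
      if (any(nA >= 2)) "small_scale_dup" else "single_copy"
    stB <- if (all(nB == 0)) "absent" else
      if (any(nB >= 2)) "small_scale_dup" else "single_copy"
    key <- paste(lab$species_id, lab$gene_id)
    has2 <- any(paste(rows$species_id, rows$gene_id) %in%
                  key[lab$wgd_round == "2R"] & rows$species_id %in% spB)
    drer3 <- any(paste(rows$species_id, rows$gene_id) %in%
                   key[lab$wgd_round == "3R"] & rows$species_id == "Drer")
    only_drer_dup <- nB["Drer"] >= 2 && all(nB[c("Ggal", "Mmus", "Hsap")] <= 1)
    if (stB == "small_scale_dup" && has2) stB <- "ohnolog"
    else if (stB == "small_scale_dup" && only_drer_dup && drer3)
      stB <- "single_copy"
    i <- which(prof$orthogroup_id == og)
    expect_equal(prof$status_amphioxus[i], stA)
    expect_equal(prof$status_vertebrate[i], stB)
  }

  # joint classes partition the orthogroup set
  expect_false(anyNA(prof$joint_class))
  expect_true(all(prof$joint_class %in%
                    c("both_single", "A_specific_dup", "B_specific_dup",
                      "parallel_dup", "A_only_orthogroup",
                      "B_only_orthogroup")))
  dupA <- prof$status_amphioxus %in% c("small_scale_dup", "ohnolog")
  dupB <- prof$status_vertebrate %in% c("small_scale_dup", "ohnolog")
  expect_equal(prof$joint_class == "parallel_dup", dupA & dupB &
                 prof$status_amphioxus != "absent" &
                 prof$status_vertebrate != "absent")
})

test_that("species summary reproduces hand-computed counts", {
  tab <- make_table(list(og1 = list(Blan = 2, Hsap = 1),
                         og2 = list(Blan = 1, Hsap = 1)))
  s <- species_summary(tab, panel_cfg())
  b <- s[s$species_id == "Blan", ]
  expect_equal(b$genes_total, 3)
  expect_equal(b$genes_dup, 2)
  expect_equal(round(b$pct_genes_dup, 1), 66.7)
  expect_equal(b$og_dup, 1)
  expect_equal(b$mean_genes_per_dup_og, 2.0)

  # mean column always equals dup genes / dup orthogroups, recomputed
  tab2 <- random_table(300, seed = 9)
  s2 <- species_summary(tab2, panel_cfg())
  cnm <- copy_number_matrix(tab2, names(panel_cfg()$species_to_lineage))
  for (sp in s2$species_id) {
    dup <- cnm[, sp] >= 2
    if (sum(dup) > 0) {
      expect_equal(s2$mean_genes_per_dup_og[s2$species_id == sp],
                   sum(cnm[dup, sp]) / sum(dup))
    }
  }
})

test_that("lineage-specific overlaps partition the lineage-specific set", {
  tab <- make_table(list(
    og1 = list(Blan = 1, Bflo = 1),           # amphioxus-specific, {Bflo,Blan}
    og2 = list(Blan = 1, Hsap = 1),           # shared -> excluded
    og3 = list(Bbel = 2),                     # amphioxus-specific, {Bbel}
    og4 = list(Blan = 1, Bflo = 1, Bbel = 1)  # all three
  ))
  ov <- lineage_specific_overlap(tab, panel_cfg(), "amphioxus")
  expect_equal(ov$n_orthogroups[ov$species_combination == "Bflo,Blan"], 1L)
  expect_equal(ov$n_orthogroups[ov$species_combination == "Bbel"], 1L)
  expect_false("og2" %in% ov$species_combination)
  expect_equal(sum(ov$n_orthogroups), 3L)

  tab2 <- random_table(400, seed = 23)
  ov2 <- lineage_specific_overlap(tab2, panel_cfg(), "amphioxus")
  cnm <- copy_number_matrix(tab2, names(panel_cfg()$species_to_lineage))
  spA <- c("Blan", "Bflo", "Bbel")
  n_specific <- sum(rowSums(cnm[, spA]) > 0 &
                      rowSums(cnm[, setdiff(colnames(cnm), spA)]) == 0)
  expect_equal(sum(ov2$n_orthogroups), n_specific)
})
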