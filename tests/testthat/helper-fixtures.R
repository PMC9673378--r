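# Small in-code fixtures shared across test files.

panel_cfg <- function() default_panel_config()

# one gene per species, counts given as a named list per orthogroup
make_table <- function(og_counts) {
  rows <- lapply(names(og_counts), function(og) {
    counts <- og_counts[[og]]
    sp <- rep(names(counts), unlist(counts))
    tibble::tibble(
      orthogroup_id = og,
      species_id = sp,
      gene_id = paste0(sp, "_", og, "_",
                       unlist(lapply(unlist(counts), seq_len)))
    )
  })
  orthogroup_table(dplyr::bind_rows(rows))
}

# the seven-species panel with every species single-copy
single_copy_counts <- function() {
  list(Blan = 1, Bflo = 1, Bbel = 1, Drer = 1, Ggal = 1, Mmus = 1, Hsap = 1)
}

# random orthogroup table over the default panel
random_table <- function(n_og, seed, max_copies = 4) {
  set.seed(seed)
  sps <- names(panel_cfg()$species_to_lineage)
  ogs <- lapply(seq_len(n_og), function(i) {
    counts <- as.list(sample(0:max_copies, length(sps), replace = TRUE,
                             prob = c(0.3, 0.4, 0.15, 0.1, 0.05)))
    names(counts) <- sps
    if (all(unlist(counts) == 0)) counts[[sample(length(sps), 1)]] <- 1
    counts
  })
  names(ogs) <- sprintf("og%04d", seq_len(n_og))
  make_table(ogs)
}

# presence profile straight from a logical matrix
presence_from_matrix <- function(m, threshold = 1) {
  structure(list(calls = m, threshold = threshold),
            class = "presence_profile")
}
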