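#' Hypergeometric enrichment test for one category intersection
#'
#' Tests whether `k` orthogroups falling in both of two categories deviates
#' from the expectation under marginal independence in a universe of size
#' `N` with `K` orthogroups in category A and `n` in category B. The upper
#' tail (P[X >= k]) is used when the observed count is at or above
#' expectation, the lower tail otherwise, and the reported direction flag
#' records which.
#'
#' @param N,K,n,k Universe size, category-A count, category-B count and
#'   observed intersection.
#' @param n_tests Number of cells tested in the run, used for the
#'   Bonferroni correction (`min(1, p * n_tests)`).
#' @return A one-row tibble with observed/expected counts and percentages,
#'   fold change (`observed / expected`), its binary logarithm, the raw and
#'   Bonferroni-corrected p-value and the test direction.
#' @export
enrichment_test <- function(N, K, n, k, n_tests = 1) {
  if (k > min(K, n)) stop("observed intersection exceeds min(K, n)")
  if (N <= 0) stop("empty universe")
  expected <- N * (K / N) * (n / N)
  fold <- if (expected > 0) k / expected else NA_real_
  enriched <- !is.na(fold) && fold >= 1
  p <- if (enriched) {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  tibble::tibble(
    n_universe = N, n_cat_a = K, n_cat_b = n,
    observed = k, expected = expected,
    observed_pct = 100 * k / N, expected_pct = 100 * expected / N,
    fold = fold,
    log2_fold = log2(fold),
    direction = if (enriched) "enrichment" else "depletion",
    p_raw = p,
    p_bonferroni = min(1, p * n_tests)
  )
}

#' Observed vs expected duplication-category intersections
#'
#' Cross-classifies a universe of orthogroups by duplication category in
#' each lineage and compares the observed cell counts against the
#' expectation under independence of the two margins. The universe defaults
#' to orthogroups with at least one gene in each focal lineage (shared
#' orthogroups). The A side is classified as `single` vs `ssd` — by a
#' single reference species' own copy number when `a_species` is given
#' (the headline view), otherwise by the lineage-level status — and the B
#' side as `single` / `ohnolog` / `ssd` from the lineage-level status.
#'
#' @param profile Output of [lineage_status()].
#' @param table The [orthogroup_table()] the profile was computed from
#'   (needed for the per-species view and the universe rule).
#' @param cfg The [lineage_config()].
#' @param a_species Reference species for the A margin (e.g. `"Blan"`), or
#'   `NULL` for the lineage rule.
#' @param universe Optional character vector of orthogroup ids overriding
#'   the default shared-orthogroup universe.
#' @return A tibble with one row per category pair (cells of the design),
#'   all [enrichment_test()] columns included; Bonferroni is over the
#'   number of cells.
#' @export
intersection_table <- function(profile, table, cfg, a_species = NULL,
                               universe = NULL) {
  cnm <- copy_number_matrix(table, species = names(cfg$species_to_lineage))
  spA <- lineage_species(cfg, cfg$focal[1])
  spB <- lineage_species(cfg, cfg$focal[2])
  if (is.null(universe)) {
    shared <- rowSums(cnm[, spA, drop = FALSE]) > 0 &
      rowSums(cnm[, spB, drop = FALSE]) > 0
    if (!is.null(a_species)) {
      shared <- shared & cnm[, a_species] > 0
    }
    universe <- rownames(cnm)[shared]
  }
  if (length(universe) == 0) stop("empty universe")
  prof <- profile[match(universe, profile$orthogroup_id), ]

  if (!is.null(a_species)) {
    cat_a <- ifelse(cnm[universe, a_species] >= 2, "ssd", "single")
  } else {
    stA <- profile_col(prof, "status", "a")
    cat_a <- dplyr::case_when(
      stA %in% c("small_scale_dup", "ohnolog") ~ "ssd",
      TRUE ~ "single"
    )
  }
  stB <- profile_col(prof, "status", "b")
  cat_b <- dplyr::case_when(
    stB == "ohnolog" ~ "ohnolog",
    stB == "small_scale_dup" ~ "ssd",
    TRUE ~ "single"
  )

  cells <- expand.grid(category_a = unique(sort(cat_a)),
                       category_b = unique(sort(cat_b)),
                       stringsAsFactors = FALSE)
  n_tests <- nrow(cells)
  N <- length(universe)
  res <- lapply(seq_len(n_tests), function(i) {
    a <- cells$category_a[i]; b <- cells$category_b[i]
    K <- sum(cat_a == a); n <- sum(cat_b == b)
    k <- sum(cat_a == a & cat_b == b)
    cbind(tibble::tibble(category_a = a, category_b = b),
          enrichment_test(N, K, n, k, n_tests = n_tests))
  })
  dplyr::bind_rows(res)
}

#' Copy-number association between jointly duplicated orthogroups
#'
#' Restricted to orthogroups duplicated in both lineages: Spearman rank
#' correlation between the two lineages' mean copy numbers, and a 2x2
#' chi-squared test after dichotomizing each lineage at a mean-copy
#' threshold (low `<= threshold` vs high).
#'
#' @param profile Output of [lineage_status()].
#' @param threshold Mean-copy dichotomization point (default 2.5).
#' @return A list: `spearman_rho`, `chi2`, `chi2_p`, `contingency` (2x2
#'   counts, rows = lineage A low/high), `n`.
#' @export
copy_number_association <- function(profile, threshold = 2.5) {
  joint <- profile$joint_class == "parallel_dup" &
    !is.na(profile$joint_class)
  ma <- profile_col(profile, "mean_copies", "a")[joint]
  mb <- profile_col(profile, "mean_copies", "b")[joint]
  if (sum(joint) < 3) stop("fewer than 3 jointly duplicated orthogroups")
  rho <- stats::cor(ma, mb, method = "spearman")
  low_a <- factor(ma <= threshold, levels = c(TRUE, FALSE),
                  labels = c("low", "high"))
  low_b <- factor(mb <= threshold, levels = c(TRUE, FALSE),
                  labels = c("low", "high"))
  cont <- table(lineage_a = low_a, lineage_b = low_b)
  chi <- suppressWarnings(stats::chisq.test(cont))
  list(spearman_rho = rho, chi2 = unname(chi$statistic),
       chi2_p = chi$p.value, contingency = cont, n = sum(joint))
}
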