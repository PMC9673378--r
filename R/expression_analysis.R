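#' Per-condition mean expression
#'
#' Arithmetic mean of TPM over the samples of each condition.
#'
#' @param m An [expression_matrix()].
#' @param condition_class Optional filter: keep only samples of this class
#'   (`adult_tissue` or `dev_stage`).
#' @return Numeric matrix, genes x conditions.
#' @export
condition_means <- function(m, condition_class = NULL) {
  samples <- m$samples
  if (!is.null(condition_class)) {
    samples <- samples[samples$condition_class %in% condition_class, ]
  }
  conds <- unique(samples$condition_id)
  out <- vapply(conds, function(cd) {
    cols <- samples$sample_id[samples$condition_id == cd]
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(m$values), conds))
  out
}

#' Tissue-specificity index Tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)` over per-condition mean
#' expression: 0 for a uniform profile, 1 for expression confined to a
#' single condition. Invariant under positive rescaling of the vector.
#' Undefined (NA, with a warning) when the gene is expressed nowhere.
#'
#' @param x Non-negative per-condition mean vector (length >= 2).
#' @param transform `"none"` (default: untransformed TPM) or `"log2"`
#'   (`log2(x + 1)` before the index).
#' @return Tau in `[0, 1]`, or `NA` for an all-zero vector.
#' @export
tau <- function(x, transform = c("none", "log2")) {
  transform <- match.arg(transform)
  if (length(x) < 2) stop("tau needs at least 2 conditions")
  if (any(x < 0)) stop("negative expression value")
  if (transform == "log2") x <- log2(x + 1)
  mx <- max(x)
  if (mx == 0) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}

#' Tau for every gene of a condition-mean matrix
#' @param means Matrix from [condition_means()].
#' @inheritParams tau
#' @return Tibble `gene_id`, `tau`, `n_conditions`.
#' @export
tau_index <- function(means, transform = c("none", "log2")) {
  transform <- match.arg(transform)
  vals <- suppressWarnings(
    apply(means, 1, tau, transform = transform))
  tibble::tibble(gene_id = rownames(means), tau = unname(vals),
                 n_conditions = ncol(means))
}

#' Presence/absence expression profile over matched conditions
#'
#' A gene is called expressed in a condition when its mean TPM is at or
#' above `threshold`. Only the conditions named in `conditions` appear, in
#' that order (so excluded conditions never enter downstream counts).
#'
#' @param means Matrix from [condition_means()].
#' @param conditions Character vector of condition ids to keep, in order
#'   (e.g. one side of [default_condition_map()]).
#' @param threshold TPM presence threshold (default 1).
#' @return A list of class `presence_profile`: logical matrix `calls`
#'   (genes x conditions) and `threshold`.
#' @export
presence_profile <- function(means, conditions, threshold = 1) {
  missing <- setdiff(conditions, colnames(means))
  if (length(missing) > 0) {
    stop("condition(s) absent from the mean matrix: ",
         paste(missing, collapse = ", "))
  }
  calls <- means[, conditions, drop = FALSE] >= threshold
  structure(list(calls = calls, threshold = threshold),
            class = "presence_profile")
}

#' Cross-species difference in number of expressed conditions
#'
#' For orthogroups in a requested copy-number configuration between two
#' species, computes the difference in expressed-condition counts with the
#' species-A-minus-species-B sign convention. In `one_to_one` mode every
#' (A gene, B gene) pair contributes one record (for 1:many and many:1
#' configurations this compares the single gene against each duplicate
#' separately). In `union_vs_single` mode the duplicated side is collapsed
#' to the union of its duplicates' expressed conditions — the number of
#' conditions in which at least one duplicate is expressed — before the
#' difference is taken.
#'
#' @param table An [orthogroup_table()].
#' @param presence_a,presence_b [presence_profile()] objects for the two
#'   species, over the same number of matched conditions.
#' @param species_a,species_b Species ids in the table.
#' @param config Copy-number configuration to keep: `"1:1"`, `"1:many"`
#'   (A single, B duplicated) or `"many:1"` (A duplicated, B single).
#'   Non-matching orthogroups are skipped (with a message).
#' @param mode `"one_to_one"` or `"union_vs_single"`.
#' @return Tibble `orthogroup_id`, `gene_a`, `gene_b`, `mode`, `delta`
#'   (integer in `[-C, C]`, C = number of matched conditions). In union
#'   mode the gene column on the duplicated side holds the joined ids.
#' @export
expression_delta <- function(table, presence_a, presence_b,
                             species_a, species_b,
                             config = c("1:1", "1:many", "many:1"),
                             mode = c("one_to_one", "union_vs_single")) {
  config <- match.arg(config)
  mode <- match.arg(mode)
  if (ncol(presence_a$calls) != ncol(presence_b$calls)) {
    stop("the two presence profiles cover different numbers of conditions")
  }
  ga <- split(table$gene_id[table$species_id == species_a],
              table$orthogroup_id[table$species_id == species_a])
  gb <- split(table$gene_id[table$species_id == species_b],
              table$orthogroup_id[table$species_id == species_b])
  ogs <- intersect(names(ga), names(gb))
  want <- switch(config,
    "1:1" = function(na, nb) na == 1 && nb == 1,
    "1:many" = function(na, nb) na == 1 && nb >= 2,
    "many:1" = function(na, nb) na >= 2 && nb == 1)
  keep <- vapply(ogs, function(og) {
    a <- ga[[og]]; b <- gb[[og]]
    all(a %in% rownames(presence_a$calls)) &&
      all(b %in% rownames(presence_b$calls)) &&
      want(length(a), length(b))
  }, logical(1))
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(skipped, " orthogroup(s) not matching configuration ", config,
            " (or lacking expression data); skipped")
  }
  ogs <- ogs[keep]
  counts <- function(p, genes) {
    m <- p$calls[genes, , drop = FALSE]
    rowSums(m)
  }
  rows <- lapply(ogs, function(og) {
    a <- ga[[og]]; b <- gb[[og]]
    if (mode == "one_to_one") {
      grid <- expand.grid(gene_a = a, gene_b = b,
                          stringsAsFactors = FALSE)
      tibble::tibble(
        orthogroup_id = og,
        gene_a = grid$gene_a, gene_b = grid$gene_b, mode = mode,
        delta = as.integer(counts(presence_a, grid$gene_a) -
                             counts(presence_b, grid$gene_b))
      )
    } else {
      union_count <- function(p, genes) {
        sum(colSums(p$calls[genes, , drop = FALSE]) > 0)
      }
      tibble::tibble(
        orthogroup_id = og,
        gene_a = paste(a, collapse = "|"),
        gene_b = paste(b, collapse = "|"),
        mode = mode,
        delta = as.integer(union_count(presence_a, a) -
                             union_count(presence_b, b))
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(orthogroup_id = character(), gene_a = character(),
                          gene_b = character(), mode = character(),
                          delta = integer())
  }
  out
}

#' Summary statistics of a delta distribution
#'
#' @param deltas Integer vector of condition-count differences (or the
#'   tibble from [expression_delta()]).
#' @param support Half-width of the histogram support (number of matched
#'   conditions); default the observed absolute maximum.
#' @return A list: `n`, `median`, `mean`, `skewness` (Fisher-Pearson
#'   adjusted sample skewness, `NA` for n < 3 or zero variance) and
#'   `histogram` (named counts over the integer support).
#' @export
delta_distribution_stats <- function(deltas, support = NULL) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  n <- length(deltas)
  if (is.null(support)) support <- max(abs(deltas), 0)
  breaks <- seq(-support, support)
  hist <- table(factor(deltas, levels = breaks))
  skew <- if (n >= 3) {
    m2 <- mean((deltas - mean(deltas))^2)
    m3 <- mean((deltas - mean(deltas))^3)
    if (m2 == 0) NA_real_ else
      sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
  } else {
    NA_real_
  }
  list(n = n, median = stats::median(deltas), mean = mean(deltas),
       skewness = skew, histogram = hist)
}

#' Boxplot statistics per gene group
#'
#' Median, quartiles (linear-interpolation rule, `quantile` type 7) and
#' whisker ends at the last observations within 1.5 IQR outside the box;
#' points beyond the whiskers are outliers and excluded from the summary.
#'
#' @param values Numeric vector (e.g. mean TPM or tau per gene).
#' @param groups Factor or character vector of the same length (e.g.
#'   single-copy vs duplicated, or the vertebrate-ortholog status).
#' @return A tibble, one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
group_expression_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (length(values) == 0) stop("no values to summarise")
  parts <- split(values, groups)
  rows <- lapply(names(parts), function(g) {
    v <- parts[[g]][!is.na(parts[[g]])]
    if (length(v) == 0) stop("empty group: ", g)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
    tibble::tibble(
      group = g, n = length(v),
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside),
      n_outliers = length(v) - length(inside)
    )
  })
  dplyr::bind_rows(rows)
}
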