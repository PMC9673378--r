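small_expr <- function() {
  vals <- rbind(g1 = c(2, 4, 10, 0), g2 = c(0, 0, 3, 3))
  colnames(vals) <- paste0("s", 1:4)
  expression_matrix(vals, tibble::tibble(
    sample_id = paste0("s", 1:4),
    condition_id = c("liver", "liver", "brain", "brain")))
}

test_that("condition means average replicates", {
  m <- condition_means(small_expr())
  expect_equal(m["g1", "liver"], 3)
  expect_equal(m["g1", "brain"], 5)
  # single-replicate conditions pass through unchanged
  one <- expression_matrix(
    matrix(7, 1, 1, dimnames = list("g1", "s1")),
    tibble::tibble(sample_id = "s1", condition_id = "x"))
  expect_equal(condition_means(one)["g1", "x"], 7)
  # per-cell recomputation on random matrices
  set.seed(3)
  vals <- matrix(stats::rexp(60), nrow = 6,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         condition_id = rep(c("a", "b", "c", "d", "e"), 2))
  mm <- condition_means(expression_matrix(vals, meta))
  for (cd in c("a", "e")) {
    cols <- meta$sample_id[meta$condition_id == cd]
    expect_equal(mm[, cd], rowMeans(vals[, cols]))
  }
})

test_that("tau matches the closed form and its invariances", {
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_equal(tau(c(0, 0, 9)), 1)
  expect_equal(tau(c(1, 2, 4)), 0.625)
  # scale invariance
  set.seed(8)
  for (i in 1:20) {
    x <- stats::rexp(7)
    expect_equal(tau(x), tau(x * stats::runif(1, 0.1, 50)))
  }
  expect_warning(expect_true(is.na(tau(c(0, 0, 0)))), "undefined")
  expect_error(tau(5), "at least 2")
  expect_error(tau(c(-1, 2)), "negative")
  # matrix wrapper
  ti <- tau_index(condition_means(small_expr()))
  expect_equal(ti$tau[ti$gene_id == "g2"], 1)
})

test_that("presence calls respect threshold, ordering and exclusions", {
  means <- rbind(g1 = c(0, 1.2, 0.4))
  colnames(means) <- c("c1", "c2", "c3")
  p <- presence_profile(means, c("c1", "c2", "c3"), threshold = 1)
  expect_equal(unname(p$calls["g1", ]), c(FALSE, TRUE, FALSE))
  # threshold 0 marks everything present
  p0 <- presence_profile(means, c("c1", "c2", "c3"), threshold = 0)
  expect_true(all(p0$calls))
  # excluded conditions never appear
  p2 <- presence_profile(means, c("c2", "c3"))
  expect_equal(colnames(p2$calls), c("c2", "c3"))
  expect_error(presence_profile(means, c("c2", "nope")), "nope")
  # monotonicity: presence counts never increase with the threshold
  set.seed(12)
  mm <- matrix(stats::rexp(70, 0.5), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:7)))
  counts <- sapply(c(0, 0.5, 1, 2, 4), function(th) {
    sum(presence_profile(mm, paste0("c", 1:7), th)$calls)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("expression deltas follow the worked configuration examples", {
  tab <- make_table(list(og1 = list(Blan = 1, Drer = 2),
                         og2 = list(Blan = 1, Drer = 1)))
  C <- 7
  calls_a <- rbind(
    Blan_og1_1 = c(rep(TRUE, 5), rep(FALSE, 2)),   # expressed in 5
    Blan_og2_1 = c(rep(TRUE, 3), rep(FALSE, 4)))
  calls_b <- rbind(
    Drer_og1_1 = c(rep(TRUE, 3), rep(FALSE, 4)),   # 3 conditions
    Drer_og1_2 = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),  # 4, union 5
    Drer_og2_1 = c(rep(TRUE, 3), rep(FALSE, 4)))
  pa <- presence_from_matrix(calls_a)
  pb <- presence_from_matrix(calls_b)

  # identical profiles: delta 0
  d <- suppressMessages(
    expression_delta(tab, pa, pb, "Blan", "Drer", config = "1:1"))
  expect_equal(d$delta, 0L)

  # single gene in 5 vs duplicates in 3 and 4: per-gene deltas +2 and +1
  d1 <- suppressMessages(
    expression_delta(tab, pa, pb, "Blan", "Drer", config = "1:many",
                     mode = "one_to_one"))
  expect_setequal(d1$delta, c(2L, 1L))
  # union of the duplicates covers 5 conditions: union delta 0
  du <- suppressMessages(
    expression_delta(tab, pa, pb, "Blan", "Drer", config = "1:many",
                     mode = "union_vs_single"))
  expect_equal(du$delta, 0L)

  # non-matching orthogroups are skipped with a message
  expect_message(
    expression_delta(tab, pa, pb, "Blan", "Drer", config = "many:1"),
    "skipped")
})

test_that("union counts bound individual counts on random profiles", {
  set.seed(19)
  C <- 7
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    calls <- matrix(stats::runif(k * C) < 0.5, nrow = k)
    union_ct <- sum(colSums(calls) > 0)
    expect_gte(union_ct, max(rowSums(calls)))
    expect_lte(union_ct, C)
  }
  # delta of a species against itself is identically zero
  tab <- make_table(list(og1 = list(Blan = 1, Drer = 1)))
  calls <- rbind(Blan_og1_1 = c(TRUE, FALSE, TRUE),
                 Drer_og1_1 = c(TRUE, FALSE, TRUE))
  p <- presence_from_matrix(calls)
  d <- suppressMessages(
    expression_delta(tab, p, p, "Blan", "Drer", config = "1:1"))
  expect_equal(d$delta, 0L)
})

test_that("delta summaries match a direct moment computation", {
  s <- delta_distribution_stats(c(-1L, 0L, 1L))
  expect_equal(s$skewness, 0)
  expect_equal(s$median, 0)
  expect_gt(delta_distribution_stats(c(0L, 0L, 0L, 3L))$skewness, 0)
  expect_true(is.na(delta_distribution_stats(c(0L, 1L))$skewness))

  set.seed(30)
  for (i in 1:100) {
    x <- sample(-5:5, sample(5:30, 1), replace = TRUE)
    s <- delta_distribution_stats(x, support = 5)
    n <- length(x)
    m <- mean(x)
    m2 <- sum((x - m)^2) / n
    m3 <- sum((x - m)^3) / n
    g1 <- m3 / m2^1.5
    G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    if (m2 > 0) expect_equal(s$skewness, G1)
    expect_equal(sum(s$histogram), n)
    expect_equal(names(s$histogram), as.character(-5:5))
  }
})

test_that("subfunctionalized duplicates show the skew-and-reversion signature", {
  bundle <- simulate_bundle(synth_params(
    seed = 51, n_orthogroups = 1500, subfun_prob = 0.8,
    p_dup_a = 0.3, p_dup_b = 0.3))
  ma <- condition_means(bundle$expr_a)
  mb <- condition_means(bundle$expr_b)
  pa <- presence_profile(ma, bundle$condition_map$condition_a)
  pb <- presence_profile(mb, bundle$condition_map$condition_b)

  d11 <- suppressMessages(expression_delta(
    bundle$table, pa, pb, "Blan", "Drer", config = "1:1"))
  d1m <- suppressMessages(expression_delta(
    bundle$table, pa, pb, "Blan", "Drer", config = "1:many",
    mode = "one_to_one"))
  dun <- suppressMessages(expression_delta(
    bundle$table, pa, pb, "Blan", "Drer", config = "1:many",
    mode = "union_vs_single"))
  expect_gt(nrow(d1m), 100)
  # 1:1 comparisons are centred at zero
  expect_gt(stats::binom.test(sum(d11$delta > 0),
                              sum(d11$delta != 0))$p.value, 0.01)
  # per-gene comparisons against duplicates skew toward the single-copy side
  expect_lt(stats::binom.test(sum(d1m$delta > 0),
                              sum(d1m$delta != 0),
                              alternative = "greater")$p.value, 1e-6)
  # the union of duplicates reverts the skew (centred at zero again)
  nz_un <- sum(dun$delta != 0)
  if (nz_un > 0) {
    expect_gt(stats::binom.test(sum(dun$delta > 0), nz_un)$p.value, 0.01)
  } else {
    expect_equal(nz_un, 0)  # perfect reversion: every union delta is zero
  }
  expect_lt(abs(mean(dun$delta)), abs(mean(d1m$delta)))
})

test_that("group boxplot statistics follow the IQR whisker convention", {
  s <- group_expression_summary(1:9, rep("g", 9))
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 9)

  # an extreme point beyond 1.5 IQR is excluded from the whisker
  v <- c(1:9, 7 + 2 * 6)   # q3 + 2 x IQR
  s2 <- group_expression_summary(v, rep("g", length(v)))
  expect_lt(s2$whisker_high, max(v))
  expect_equal(s2$n_outliers, 1)

  # sorting-based quantile recomputation on random groups
  set.seed(44)
  vals <- stats::rlnorm(200)
  grp <- sample(c("x", "y"), 200, replace = TRUE)
  s3 <- group_expression_summary(vals, grp)
  for (g in c("x", "y")) {
    v <- sort(vals[grp == g])
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    row <- s3[s3$group == g, ]
    expect_equal(row$median, q[2])
    iqr <- q[3] - q[1]
    expect_equal(row$whisker_high, max(v[v <= q[3] + 1.5 * iqr]))
    expect_equal(row$whisker_low, min(v[v >= q[1] - 1.5 * iqr]))
  }
  expect_error(group_expression_summary(numeric(0), character(0)))
})
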