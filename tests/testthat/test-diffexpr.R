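make_expr <- function(m) mirpanel:::expression_tibble(m)

two_class_samples <- function(n1, n0, prefix = "S") {
  tibble::tibble(
    sample_id = sprintf("%s%03d", prefix, seq_len(n1 + n0)),
    class = rep(c("cancer", "non_cancer"), c(n1, n0))
  )
}

test_that("marker statistics match their definitions on a separable marker", {
  set.seed(1)
  n <- 10
  m <- cbind(up = 2^c(rnorm(n, 12), rnorm(n, 8)),
             null = 2^rnorm(2 * n, 10))
  rownames(m) <- sprintf("S%03d", 1:(2 * n))
  s <- two_class_samples(n, n)
  ms <- marker_stats(make_expr(m), s)
  up <- ms[ms$mirna_id == "up", ]
  expect_equal(up$auc, 1)
  expect_lt(up$p_value, 1e-6)
  l <- log2(m[, "up"])
  expect_equal(up$log2fc, mean(l[1:n]) - mean(l[(n + 1):(2 * n)]),
               tolerance = 1e-12)
  # pooled-variance t cross-check against stats::t.test
  tt <- t.test(l[1:n], l[(n + 1):(2 * n)], var.equal = TRUE)
  expect_equal(up$t_stat, unname(tt$statistic), tolerance = 1e-12)
})

test_that("p-values are uniform under label permutation", {
  set.seed(2)
  x <- rnorm(30)
  m <- matrix(2^x, dimnames = list(sprintf("S%03d", 1:30), "m1"))
  ps <- vapply(1:400, function(i) {
    s <- tibble::tibble(sample_id = rownames(m),
                        class = sample(rep(c("cancer", "non_cancer"), 15)))
    marker_stats(make_expr(m), s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("BH q-values reproduce the step-up hand computation and oracle", {
  set.seed(3)
  m <- matrix(2^rnorm(40), 10, 4,
              dimnames = list(sprintf("S%03d", 1:10), paste0("m", 1:4)))
  s <- two_class_samples(5, 5)
  ms <- marker_stats(make_expr(m), s)
  expect_equal(ms$q_value, bh_stepup_oracle(ms$p_value), tolerance = 1e-12)
  # frozen hand computation: p = (.01,.02,.03,.04), m = 4 -> q all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(bh_stepup_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("per-marker AUC equals brute-force pair counting", {
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(3:40, 1); n0 <- sample(3:40, 1)
    vals <- sample(c(rnorm(n1 + n0), rep(0.3, 5))[1:(n1 + n0)])
    m <- matrix(2^vals, dimnames = list(sprintf("S%03d", 1:(n1 + n0)), "m1"))
    s <- two_class_samples(n1, n0)
    y <- rep(1:0, c(n1, n0))
    expect_equal(marker_stats(make_expr(m), s)$auc,
                 pairs_auc_oracle(log2(m[, 1]), y), tolerance = 1e-12)
  }
})

test_that("candidate selection applies strict thresholds and directional AUC", {
  stats <- tibble::tibble(
    mirna_id = c("exact", "up", "down", "discordant", "weak_p"),
    log2fc = c(0.5, 1.2, -1.1, 0.9, 2.0),
    t_stat = 0, q_value = 0.5,
    p_value = c(0.001, 0.001, 0.002, 0.001, 0.5),
    auc = c(0.9, 0.8, 0.2, 0.4, 0.9),
    n_cancer = 10, n_control = 10
  )
  sel <- select_candidates(stats)
  # |log2FC| = 0.5 exactly fails the strict inequality; AUC 0.4 on an
  # up-regulated marker contradicts its fold change
  expect_setequal(sel$mirna_id, c("up", "down"))
})

test_that("selection is monotone in its thresholds", {
  set.seed(5)
  stats <- tibble::tibble(
    mirna_id = sprintf("m%03d", 1:200),
    log2fc = rnorm(200), t_stat = 0,
    p_value = runif(200), q_value = runif(200),
    auc = runif(200), n_cancer = 20, n_control = 20
  )
  base <- select_candidates(stats, 0.05, 0.5, 0.55)$mirna_id
  expect_true(all(base %in% select_candidates(stats, 0.10, 0.5, 0.55)$mirna_id))
  expect_true(all(base %in% select_candidates(stats, 0.05, 0.3, 0.55)$mirna_id))
  expect_true(all(base %in% select_candidates(stats, 0.05, 0.5, 0.50)$mirna_id))
})

test_that("null data yield few discovery candidates", {
  set.seed(6)
  counts <- vapply(1:5, function(i) {
    m <- matrix(2^rnorm(60 * 200, 10), 60, 200,
                dimnames = list(sprintf("S%03d", 1:60), sprintf("m%03d", 1:200)))
    s <- two_class_samples(30, 30)
    nrow(select_candidates(marker_stats(make_expr(m), s)))
  }, numeric(1))
  # pass counts are bounded by the p < 0.01 null rate: the pooled total over
  # the 5 runs stays under the Binomial(1000, 0.01) 99.9th percentile
  expect_lte(sum(counts), qbinom(0.999, 5 * 200, 0.01))
})

test_that("planted strong markers survive the discovery filter", {
  cfg <- tiny_config(
    seed = 7, n_mirnas = 60, n_differential = 30,
    log2fc_effects = default_log2fc_effects(30, n_strong = 30, strong = 0.9,
                                            moderate = 0.9),
    cohorts = small_cohort_design(100, 100)
  )
  st <- generate_cohort(cfg)
  ms <- marker_stats(make_expr(st$truth$abundance), st$samples)
  sel <- select_candidates(ms)
  planted <- st$truth$mirna_info$mirna_id[st$truth$mirna_info$is_differential]
  expect_gte(length(intersect(sel$mirna_id, planted)), 27)
})

test_that("validation confirms consistent markers and explains exclusions", {
  disc <- tibble::tibble(
    mirna_id = c("a", "b", "c", "d"),
    log2fc = c(1, -1, 0.8, 0.9),
    p_value = rep(0.001, 4), q_value = rep(0.01, 4),
    t_stat = 0, auc = 0.8, n_cancer = 10, n_control = 10
  )
  val <- disc
  expect_true(all(validate_candidates(val, disc)$status == "validated"))

  val2 <- disc
  val2$log2fc[2] <- 1        # sign flip
  val2$p_value[3] <- 0.2     # not significant
  val2$log2fc[4] <- 0.3      # too small
  out <- validate_candidates(val2, disc)
  expect_equal(out$status, c("validated", "excluded", "excluded", "excluded"))
  expect_equal(out$reason[2:4],
               c("sign_flip", "not_significant", "small_fold_change"))
})

test_that("discovery-only false positives are mostly excluded in validation", {
  set.seed(8)
  excluded <- 0L; total <- 0L
  for (i in 1:20) {
    n <- 40
    m_val <- matrix(2^rnorm(n * 3, 10), n, 3,
                    dimnames = list(sprintf("S%03d", 1:n), c("f1", "f2", "f3")))
    s <- two_class_samples(20, 20)
    stats_val <- marker_stats(make_expr(m_val), s)
    fake_disc <- stats_val |>
      dplyr::mutate(log2fc = c(1, -1, 1), p_value = 0.001)
    out <- validate_candidates(stats_val, fake_disc)
    excluded <- excluded + sum(out$status == "excluded")
    total <- total + 3L
  }
  expect_gte(excluded / total, 0.9)
})

test_that("fold-change correlation matches the closed form", {
  mk <- function(fc) tibble::tibble(mirna_id = c("a", "b", "c"), log2fc = fc)
  expect_equal(fold_change_correlation(mk(c(0.6, -0.8, 1.1)),
                                       mk(c(0.6, -0.8, 1.1)))$r, 1)
  expect_equal(fold_change_correlation(mk(c(0.6, -0.8, 1.1)),
                                       mk(-c(0.6, -0.8, 1.1)))$r, -1)
  a <- c(0.6, -0.8, 1.1); b <- c(0.5, -0.7, 1.3)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(fold_change_correlation(mk(a), mk(b))$r, r_hand,
               tolerance = 1e-12)
  expect_error(fold_change_correlation(mk(c(1, 1, 1)), mk(b)), "variance")
})

test_that("hierarchical clustering merges nearest structures first", {
  m <- matrix(2^c(0, 1, 10, 11, 0, 1, 10, 11), 4, 2,
              dimnames = list(c("P0", "P1", "P10", "P11"), c("d1", "d2")))
  cl <- hierarchical_cluster(mirpanel:::expression_tibble(m))
  h <- cl$sample_tree
  first_merge <- sort(abs(h$merge[1, ]))
  second_merge <- sort(abs(h$merge[2, ]))
  labs <- h$labels
  expect_setequal(labs[first_merge], c("P0", "P1"))
  expect_setequal(labs[second_merge], c("P10", "P11"))

  m2 <- rbind(m, P0b = m["P0", ])
  cl2 <- hierarchical_cluster(mirpanel:::expression_tibble(m2))
  expect_equal(cl2$sample_tree$height[1], 0)
  expect_setequal(cl2$sample_tree$labels[abs(cl2$sample_tree$merge[1, ])],
                  c("P0", "P0b"))
})

test_that("cluster merge heights are invariant to row permutation", {
  set.seed(9)
  m <- matrix(2^rnorm(40, 10), 8, 5,
              dimnames = list(sprintf("S%d", 1:8), sprintf("m%d", 1:5)))
  cl1 <- hierarchical_cluster(mirpanel:::expression_tibble(m))
  perm <- sample(8)
  cl2 <- hierarchical_cluster(mirpanel:::expression_tibble(m[perm, ]))
  expect_equal(cl1$sample_tree$height, cl2$sample_tree$height,
               tolerance = 1e-12)
})
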