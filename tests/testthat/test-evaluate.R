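test_that("ROC endpoints, ties, and the 4-pair toy behave as defined", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3)), 1)
  expect_equal(roc_auc(rep(0.4, 8), rep(0:1, 4)), 0.5)
  pts <- roc_points(rep(0.4, 8), rep(0:1, 4))
  expect_equal(pts$fpr, c(0, 1))
  sc <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(sc, y), 0.75)
  expect_equal(roc_auc(sc, y), pairs_auc_oracle(sc, y))
  p2 <- roc_points(sc, y)
  expect_equal(p2$fpr[1], 0); expect_equal(p2$tpr[1], 0)
  expect_equal(p2$fpr[nrow(p2)], 1); expect_equal(p2$tpr[nrow(p2)], 1)
})

test_that("trapezoid AUC equals Mann-Whitney pair counting on random instances", {
  set.seed(1)
  for (i in 1:25) {
    n1 <- sample(2:60, 1); n0 <- sample(2:60, 1)
    sc <- round(rnorm(n1 + n0), sample(0:2, 1))  # force ties
    y <- rep(1:0, c(n1, n0))
    expect_equal(roc_auc(sc, y), pairs_auc_oracle(sc, y), tolerance = 1e-12)
    expect_equal(mirpanel:::mw_auc(sc, y), pairs_auc_oracle(sc, y),
                 tolerance = 1e-12)
    expect_equal(mirpanel:::.mw_auc_cpp(sc, y), pairs_auc_oracle(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("pROC agrees with the trapezoid implementation (independent cross-check)", {
  set.seed(2)
  sc <- rnorm(80); y <- rbinom(80, 1, 0.5)
  expect_equal(roc_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC confidence intervals clip, agree across methods, and shrink with n", {
  sc <- c(rnorm(60) + 10, rnorm(60) - 10); y <- rep(1:0, each = 60)
  ci <- auc_ci(sc, y)
  expect_equal(ci$auc, 1)
  expect_equal(ci$conf_high, 1)

  set.seed(3)
  sc2 <- c(rnorm(50, 0.8), rnorm(50)); y2 <- rep(1:0, each = 50)
  d <- auc_ci(sc2, y2, method = "delong")
  b <- auc_ci(sc2, y2, method = "bootstrap", seed = 7)
  expect_lt(max(abs(c(d$conf_low - b$conf_low, d$conf_high - b$conf_high))),
            0.03)

  d2 <- auc_ci(rep(sc2, 4), rep(y2, 4), method = "delong")
  expect_lt(d2$conf_high - d2$conf_low, d$conf_high - d$conf_low)
})

test_that("max-accuracy cutoff matches exhaustive enumeration", {
  out <- max_accuracy_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(out$accuracy, 1)
  expect_equal(out$cutoff, 0.5)

  sc <- c(0.1, 0.6, 0.4, 0.9); y <- c(0, 0, 1, 1)
  out2 <- max_accuracy_cutoff(sc, y)
  expect_equal(out2$accuracy, 0.75)
  # exhaustive scan oracle
  accs <- vapply(sort(unique(sc)), function(cut) mean((sc >= cut) == y),
                 numeric(1))
  expect_equal(out2$accuracy, max(accs))

  # inverted labels: the trivial-classifier bound still holds
  out3 <- max_accuracy_cutoff(sc, 1 - y)
  expect_gte(out3$accuracy, 0.5)
})

test_that("max accuracy is invariant under strictly monotone score transforms", {
  set.seed(4)
  sc <- rnorm(60); y <- rbinom(60, 1, 0.5)
  a1 <- max_accuracy_cutoff(sc, y)
  a2 <- max_accuracy_cutoff(plogis(3 * sc + 1), y)
  expect_equal(a1$accuracy, a2$accuracy)
  expect_equal(a1$sensitivity, a2$sensitivity)
  expect_gte(a1$accuracy, max(mean(y), 1 - mean(y)))
})

test_that("Wilson interval matches the closed-form quadratic and stays in range", {
  w <- proportion_ci(8, 10)
  expect_equal(c(w$conf_low, w$conf_high), wilson_oracle(8, 10),
               tolerance = 1e-12)
  expect_equal(proportion_ci(10, 10)$conf_high, 1)
  expect_equal(proportion_ci(0, 10)$conf_low, 0)
  # cross-check against prop.test without continuity correction
  pt <- prop.test(8, 10, correct = FALSE)
  expect_equal(c(w$conf_low, w$conf_high), as.numeric(pt$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:50, 1); s <- sample(0:n, 1)
    ci <- proportion_ci(s, n)
    expect_true(ci$conf_low <= ci$estimate && ci$estimate <= ci$conf_high)
    expect_true(ci$conf_low >= 0 && ci$conf_high <= 1)
  }
})

make_eval_setup <- function(coefs, seed = 6, n = 60) {
  set.seed(seed)
  l <- matrix(rnorm(n * 2, 10), n, 2, dimnames = list(sprintf("S%03d", 1:n),
                                                      c("m1", "m2")))
  samples <- tibble::tibble(
    sample_id = rownames(l),
    cohort = "validation2",
    source_id = rep(c("s1", "s2"), length.out = n),
    class = rep(c("cancer", "non_cancer"), each = n / 2),
    stage = ifelse(rep(c(TRUE, FALSE), each = n / 2),
                   sample(c("0", "I", "II", "III", "IV"), n, TRUE),
                   "not_applicable")
  )
  model <- structure(list(mirna_ids = c("m1", "m2"), coefficients = coefs,
                          intercept = 0, cutoff = NA_real_),
                     class = "panel_model")
  list(expr = mirpanel:::expression_tibble(2^l), samples = samples,
       model = model)
}

test_that("a zero-coefficient model scores every stratum at AUC 0.5", {
  s <- make_eval_setup(c(m1 = 0, m2 = 0))
  ev <- evaluate_panel(s$model, s$expr, s$samples)
  expect_equal(ev$auc$auc, 0.5)
  expect_true(all(abs(na.omit(ev$by_source$auc) - 0.5) < 1e-12))
  expect_true(all(abs(na.omit(ev$by_stage$auc) - 0.5) < 1e-12))
})

test_that("single-source evaluation equals the global section", {
  s <- make_eval_setup(c(m1 = 1.2, m2 = -0.4), seed = 7)
  s$samples$source_id <- "only"
  ev <- evaluate_panel(s$model, s$expr, s$samples)
  expect_equal(nrow(ev$by_source), 1)
  expect_equal(ev$by_source$auc, ev$auc$auc, tolerance = 1e-12)
})

test_that("per-stage AUC uses all controls and reports composite strata", {
  s <- make_eval_setup(c(m1 = 1, m2 = 0.5), seed = 8, n = 80)
  ev <- evaluate_panel(s$model, s$expr, s$samples)
  y <- as.integer(s$samples$class == "cancer")
  sc <- ev$scores$score
  for (st in c("I", "II")) {
    idx <- which(y == 1 & s$samples$stage == st)
    if (length(idx) >= 2) {
      ctrl <- which(y == 0)
      manual <- mirpanel:::mw_auc(sc[c(idx, ctrl)],
                                  rep(1:0, c(length(idx), length(ctrl))))
      expect_equal(ev$by_stage$auc[ev$by_stage$stage == st], manual,
                   tolerance = 1e-12)
    }
  }
  expect_true(all(c("early", "late", "non_cancer") %in% ev$by_stage$stage))
})

test_that("stage-scaled effects give higher AUC in later stages", {
  aucs <- purrr::map(1:5, function(s) {
    cfg <- tiny_config(
      seed = 400 + s, n_mirnas = 20, n_differential = 6,
      cohorts = small_cohort_design(60, 60, "validation2"),
      stage_probs = c("0" = 0.2, "I" = 0.2, "II" = 0.2, "III" = 0.2,
                      "IV" = 0.2, "unknown" = 0),
      stage_effect = c("0" = 0.4, "I" = 0.7, "II" = 1, "III" = 1.3,
                       "IV" = 1.6, "unknown" = 1)
    )
    st <- generate_cohort(cfg)
    info <- st$truth$mirna_info
    planted <- info$mirna_id[info$is_differential]
    coefs <- setNames(sign(info$true_log2fc[info$is_differential]), planted)
    model <- structure(list(mirna_ids = planted, coefficients = coefs,
                            intercept = 0, cutoff = NA_real_),
                       class = "panel_model")
    ev <- evaluate_panel(model, mirpanel:::expression_tibble(st$truth$abundance),
                         st$samples)
    ev$by_stage |>
      dplyr::filter(stage %in% c("0", "I", "II", "III", "IV")) |>
      dplyr::pull(auc)
  })
  rho <- vapply(aucs, function(a) {
    ok <- is.finite(a)
    cor(seq_along(a)[ok], a[ok], method = "spearman")
  }, numeric(1))
  expect_true(all(rho >= 0))
})
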