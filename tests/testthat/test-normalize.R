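test_that("geNORM M is zero for pairwise-proportional candidates", {
  base <- rnorm(8)
  l <- cbind(a = base, b = base + 2, c = base - 1.3)
  expect_equal(genorm_m(l)$genorm_m, rep(0, 3), tolerance = 1e-12)
})

test_that("with two candidates both M values equal the SD of their log ratio", {
  set.seed(1)
  l <- cbind(a = rnorm(12), b = rnorm(12))
  m <- genorm_m(l)
  expect_equal(m$genorm_m, rep(sd(l[, 1] - l[, 2]), 2), tolerance = 1e-12)
})

test_that("geNORM M matches the brute-force pairwise-SD oracle", {
  set.seed(7)
  for (i in 1:20) {
    l <- matrix(rnorm(40), 4, 10,
                dimnames = list(NULL, sprintf("c%02d", 1:10)))
    expect_equal(genorm_m(l)$genorm_m, genorm_oracle(l), tolerance = 1e-12)
  }
})

test_that("iterative ranking excludes the noisiest candidate first", {
  set.seed(3)
  base <- rnorm(20)
  l <- cbind(A = base + rnorm(20, 0, 0.05),
             B = base + rnorm(20, 0, 0.05),
             C = base + rnorm(20, 0, 3))
  # brute-force M comparison says C is worst
  expect_equal(which.max(genorm_oracle(l)), 3L)
  gr <- genorm_rank(l)
  expect_equal(gr$ranking$genorm_rank[gr$ranking$mirna_id == "C"], 2L)
  expect_equal(gr$ranking$genorm_rank[gr$ranking$mirna_id %in% c("A", "B")],
               c(1L, 1L))
})

test_that("exclusion order is invariant to candidate column permutation", {
  set.seed(11)
  l <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, sprintf("c%02d", 1:10)))
  r1 <- genorm_rank(l)$ranking |> dplyr::arrange(mirna_id)
  perm <- sample(10)
  r2 <- genorm_rank(l[, perm])$ranking |> dplyr::arrange(mirna_id)
  expect_equal(r1$genorm_rank, r2$genorm_rank)
})

test_that("NormFinder rho is zero for a candidate constant after centring", {
  # all candidates identical per sample: centring removes everything
  s <- rnorm(10)
  l <- cbind(a = s, b = s, c = s)
  rho <- normfinder_stability(l, rep(c("x", "y"), each = 5))
  expect_equal(rho$normfinder_rho, rep(0, 3), tolerance = 1e-12)
})

test_that("single-group NormFinder reduces to sqrt(w/n)", {
  set.seed(5)
  l <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, letters[1:5]))
  rho <- normfinder_stability(l, rep("only", 6))
  centred <- l - rowMeans(l)
  expect_equal(rho$normfinder_rho,
               unname(sqrt(apply(centred, 2, var) / 6)), tolerance = 1e-12)
})

test_that("NormFinder matches the step-by-step oracle on a toy", {
  set.seed(9)
  l <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, letters[1:4]))
  groups <- rep(c("cancer", "non_cancer"), each = 3)
  expect_equal(normfinder_stability(l, groups)$normfinder_rho,
               normfinder_oracle(l, groups), tolerance = 1e-12)
})

test_that("stability measures are invariant to a constant shift of one candidate", {
  set.seed(13)
  l <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, letters[1:5]))
  groups <- rep(c("cancer", "non_cancer"), each = 4)
  l2 <- l
  l2[, 2] <- l2[, 2] + 7
  expect_equal(genorm_m(l)$genorm_m, genorm_m(l2)$genorm_m,
               tolerance = 1e-12)
  expect_equal(normfinder_stability(l, groups)$normfinder_rho,
               normfinder_stability(l2, groups)$normfinder_rho,
               tolerance = 1e-12)
})

test_that("planted references are selected from simulated cohorts", {
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(seed = 100 + s, n_mirnas = 40,
                       cohorts = small_cohort_design(20, 20))
    st <- generate_cohort(cfg)
    stab <- reference_stability(st$truth$abundance |>
                                  mirpanel:::expression_tibble(),
                                st$samples)
    sel <- select_references(stab, 3)
    planted <- st$truth$mirna_info$mirna_id[st$truth$mirna_info$is_reference]
    setequal(sel$mirna_ids, planted)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("consensus selection respects k and tie rules", {
  stab <- tibble::tibble(
    mirna_id = c("b", "a", "c", "d"),
    genorm_m = c(0.2, 0.2, 0.5, 0.9),
    genorm_rank = c(1L, 1L, 2L, 3L),
    normfinder_rho = c(0.1, 0.1, 0.3, 0.6),
    normfinder_rank = c(2L, 1L, 3L, 4L)
  )
  expect_equal(select_references(stab, 3)$mirna_ids, c("a", "b", "c"))
  expect_equal(sort(select_references(stab, 4)$mirna_ids),
               c("a", "b", "c", "d"))
  expect_error(select_references(stab, 5), "exceeds")
})

test_that("normalization is scale-invariant and identity for unit references", {
  set.seed(21)
  m <- matrix(2^rnorm(30, 10), 5, 6,
              dimnames = list(sprintf("S%d", 1:5), sprintf("m%d", 1:6)))
  expr <- mirpanel:::expression_tibble(m)
  norm1 <- normalize_expression(expr, c("m1", "m2"))
  m2 <- m
  m2[3, ] <- m2[3, ] * 10
  norm2 <- normalize_expression(mirpanel:::expression_tibble(m2),
                                c("m1", "m2"))
  expect_equal(as.data.frame(norm1), as.data.frame(norm2), tolerance = 1e-12)

  m3 <- m
  m3[, "m1"] <- 1
  norm3 <- normalize_expression(mirpanel:::expression_tibble(m3), "m1")
  expect_equal(as.matrix(norm3[-1]), unname(m3) , ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("normalization divides by each sample's reference value (hand toy)", {
  m <- matrix(c(8, 2, 4, 16, 2, 32), 2, 3,
              dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  norm <- normalize_expression(mirpanel:::expression_tibble(m), "A")
  expect_equal(unname(as.matrix(norm[-1])),
               unname(m / m[, "A"]), tolerance = 1e-12)
})

test_that("samples with non-positive reference values are excluded", {
  m <- matrix(c(8, 0, 4, 16), 2, 2,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  norm <- suppressMessages(
    normalize_expression(mirpanel:::expression_tibble(m), "A"))
  expect_equal(norm$sample_id, "S1")
  expect_equal(attr(norm, "excluded_samples"), "S2")
})

test_that("reference normalization shrinks null-marker variance under input noise", {
  cfg <- tiny_config(seed = 31, n_mirnas = 40, sample_scale_sd = 0.5,
                     cohorts = small_cohort_design(40, 40))
  st <- simulate_study(cfg)
  q <- absolute_quantify(st$ct_data, st$samples)
  stab <- reference_stability(q, st$samples)
  refs <- select_references(stab, 3)
  norm <- normalize_expression(q$expression, refs)
  info <- st$truth$mirna_info
  nulls <- info$mirna_id[!info$is_differential & !info$is_reference]
  raw_sd <- apply(log2(as.matrix(q$expression[nulls])), 2, sd)
  norm_sd <- apply(log2(as.matrix(norm[nulls])), 2, sd)
  expect_lt(median(norm_sd), median(raw_sd))
})
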