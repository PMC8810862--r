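# Internal helpers shared across modules.

# Derive a reproducible 31-bit substream seed from a master seed and a stage
# index. Uses a Lehmer step in double arithmetic (exact below 2^53), so stages
# draw from independent streams: changing how many numbers one stage consumes
# never perturbs another stage's draws.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- as.double(seed) %% 2147483647
  as.integer(((s * 48271) + as.double(index) * 69621) %% 2147483629) + 1L
}

with_substream <- function(seed, index, code) {
  withr::with_seed(derive_seed(seed, index), code)
}

geometric_mean <- function(x) {
  exp(mean(log(x)))
}

# Coerce a wide expression tibble (sample_id column + one column per miRNA)
# or a numeric matrix with rownames to a samples x miRNA matrix.
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) {
      abort("expression matrix must have sample_id rownames")
    }
    return(expr)
  }
  df <- as.data.frame(expr)
  if (!"sample_id" %in% names(df)) {
    abort("expression table must contain a 'sample_id' column")
  }
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- df$sample_id
  m
}

# Inverse of as_expression_matrix().
expression_tibble <- function(m) {
  dplyr::bind_cols(
    tibble(sample_id = rownames(m)),
    as_tibble(m)
  )
}

# Binary class labels aligned to a sample id vector. `samples` must carry
# sample_id and class in {cancer, non_cancer}.
class_vector <- function(samples, sample_ids) {
  cls <- samples$class[match(sample_ids, samples$sample_id)]
  if (anyNA(cls)) abort("some sample ids are missing from the sample table")
  bad <- setdiff(unique(cls), c("cancer", "non_cancer"))
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(cls == "cancer")
}

# Mann-Whitney AUC: P(score_case > score_control), ties counting 1/2.
mw_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stage_levels <- function() c("0", "I", "II", "III", "IV", "unknown")
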