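# Ridge-stabilized logistic panel models.

#' Fit a logistic panel model
#'
#' Maximum-likelihood logistic regression of class on log2 expression of the
#' panel miRNAs, with a small ridge penalty (`lambda`, default 1e-6) on
#' standardized features so coefficients remain finite on separable folds
#' (near-separable training folds are expected for strong panels).
#' Coefficients are mapped back to the log2 scale.
#'
#' @param x Samples x features matrix of log2 expression (or a wide
#'   expression tibble of positive values, which is log2-transformed).
#' @param y Class labels: 0/1 or cancer/non_cancer.
#' @param lambda Ridge penalty on standardized features.
#' @param max_iter,tol Newton iteration cap and relative objective tolerance.
#' @return A `panel_model`: `mirna_ids` (ordered), `coefficients` (log-odds
#'   per log2 unit), `intercept`, `cutoff` (NA until set), convergence info.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("miR-a", "miR-b")))
#' y <- rbinom(100, 1, plogis(x[, 1]))
#' fit <- fit_logistic(x, y)
#' tidy(fit)
fit_logistic <- function(x, y, lambda = 1e-6, max_iter = 200, tol = 1e-10) {
  if (!is.matrix(x)) {
    x <- log2(as_expression_matrix(x))
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  y <- to_binary(y)
  if (length(y) != nrow(x)) abort("x and y lengths differ")
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    abort("need at least one sample per class", class = "mirpanel_fit_error")
  }
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  if (any(sigma == 0)) {
    abort(paste0("zero-variance feature(s): ",
                 paste(colnames(x)[sigma == 0], collapse = ", ")),
          class = "mirpanel_fit_error")
  }
  xs <- sweep(sweep(x, 2, mu), 2, sigma, `/`)
  fit <- .ridge_logit_cpp(xs, y, lambda, as.integer(max_iter), tol)
  if (!fit$converged) {
    abort(paste0("logistic fit did not converge after ", fit$iterations,
                 " iterations (n=", nrow(x), ", p=", ncol(x), ")"),
          class = "mirpanel_convergence_error")
  }
  beta_std <- fit$coef[-1]
  beta <- beta_std / sigma
  intercept <- fit$coef[1] - sum(beta_std * mu / sigma)
  structure(list(
    mirna_ids = colnames(x),
    coefficients = setNames(beta, colnames(x)),
    intercept = intercept,
    cutoff = NA_real_,
    lambda = lambda,
    converged = fit$converged,
    iterations = fit$iterations,
    n = nrow(x),
    n_cancer = sum(y == 1),
    n_control = sum(y == 0)
  ), class = "panel_model")
}

to_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    return(class_vector(tibble(sample_id = seq_along(y), class = y),
                        seq_along(y)))
  }
  yi <- as.integer(y)
  if (!all(yi %in% c(0L, 1L))) abort("labels must be 0/1 or cancer/non_cancer")
  yi
}

#' Risk scores from a panel model
#'
#' Logistic risk score in \[0, 1\]:
#' \eqn{\sigma(\beta_0 + \sum_m \beta_m \log_2 x_m)}. Higher scores indicate
#' higher predicted cancer risk.
#'
#' @param object A `panel_model`.
#' @param newdata Wide expression tibble (positive normalized values) or a
#'   log2 matrix; must contain every panel miRNA.
#' @param ... Unused.
#' @return Numeric vector of scores named by sample id (when available).
#' @export
predict.panel_model <- function(object, newdata, ...) {
  l <- if (is.matrix(newdata)) newdata else log2(as_expression_matrix(newdata))
  missing_f <- setdiff(object$mirna_ids, colnames(l))
  if (length(missing_f) > 0) {
    abort(paste0("panel feature(s) missing from data: ",
                 paste(missing_f, collapse = ", ")),
          class = "mirpanel_config_error")
  }
  eta <- object$intercept +
    drop(l[, object$mirna_ids, drop = FALSE] %*% object$coefficients)
  stats::plogis(eta)
}

#' Score a cohort with a panel model
#'
#' @param expr Wide normalized expression tibble.
#' @param model A `panel_model`.
#' @param samples Optional sample table to carry class/stage/source along.
#' @return Tibble (`sample_id`, `score`, plus metadata columns if given).
#' @export
score_samples <- function(expr, model, samples = NULL) {
  s <- predict(model, expr)
  out <- tibble(sample_id = names(s) %||% as.character(seq_along(s)),
                score = unname(s))
  if (!is.null(samples)) {
    out <- out |> left_join(
      samples |> select(any_of(c("sample_id", "cohort", "source_id",
                                 "class", "stage"))),
      by = "sample_id")
  }
  out
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic miRNA panel model (", length(x$mirna_ids), " miRNAs, n = ",
      x$n, ")\n", sep = "")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  if (!is.na(x$cutoff)) cat("score cutoff:", round(x$cutoff, 4), "\n")
  invisible(x)
}

#' Coefficients of a panel model in broom's `tidy()` layout
#' @param x A `panel_model`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`).
#' @method tidy panel_model
#' @export
tidy.panel_model <- function(x, ...) {
  tibble(term = c("(Intercept)", x$mirna_ids),
         estimate = unname(c(x$intercept, x$coefficients)))
}

#' One-row summary of a panel model (`glance()`)
#' @param x A `panel_model`.
#' @param ... Unused.
#' @return One-row tibble of fit metadata.
#' @method glance panel_model
#' @export
glance.panel_model <- function(x, ...) {
  tibble(n = x$n, n_cancer = x$n_cancer, n_control = x$n_control,
         n_features = length(x$mirna_ids), lambda = x$lambda,
         iterations = x$iterations, converged = x$converged,
         cutoff = x$cutoff)
}
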