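# Sequential forward floating search (SFFS) over candidate miRNAs.
#
# Classic forward selection with conditional backward ("floating") removals:
# after each forward inclusion, members are removed as long as the reduced
# subset beats the best subset of its size found so far. Floating lets the
# search escape greedy traps (pairs that are jointly informative but
# individually weak). The selection criterion is the training AUC of a
# ridge-logistic refit on the candidate subset.

sffs_core <- function(x, y, max_size, lambda = 1e-6,
                      max_iter = 60L, tol = 1e-9, overshoot = 3L) {
  p <- ncol(x)
  stopifnot(max_size >= 1, p >= max_size)
  # search a few sizes past the target and backtrack: floating removals from
  # the overshoot region routinely improve the reported sizes
  report_size <- max_size
  max_size <- min(p, max_size + overshoot)
  ids <- colnames(x) %||% sprintf("f%03d", seq_len(p))
  # lexicographic candidate order makes every argmax tie-break deterministic
  lex <- order(ids)

  crit <- function(idx) {
    v <- .logit_subset_auc_cpp(x, y, as.integer(idx - 1L), lambda,
                               as.integer(max_iter), tol)
    if (!is.finite(v)) -Inf else v
  }

  best_idx <- vector("list", max_size)
  best_crit <- rep(-Inf, max_size)
  note <- function(idx, v) {
    s <- length(idx)
    if (s >= 1 && s <= max_size && v > best_crit[s] + 1e-12) {
      best_idx[[s]] <<- idx
      best_crit[s] <<- v
    }
  }

  forward_step <- function(cur) {
    cand <- lex[!(lex %in% cur)]
    vals <- vapply(cand, function(f) {
      idx <- c(cur, f)
      v <- crit(idx)
      note(idx, v)
      v
    }, numeric(1))
    cand[which.max(vals)]
  }

  run_greedy <- function() {
    cur <- integer(0)
    for (s in seq_len(max_size)) cur <- c(cur, forward_step(cur))
    cur
  }

  cur <- integer(0)
  guard <- 0L
  while (length(cur) < max_size && guard < 50L * max_size) {
    guard <- guard + 1L
    cur <- c(cur, forward_step(cur))
    # floating: conditional exclusions while they beat the best-known subset
    while (length(cur) > 2) {
      rem_order <- cur[order(ids[cur])]
      vals <- vapply(rem_order, function(r) {
        idx <- cur[cur != r]
        v <- crit(idx)
        note(idx, v)
        v
      }, numeric(1))
      k <- which.max(vals)
      if (vals[k] > best_crit[length(cur) - 1] + 1e-12) {
        cur <- cur[cur != rem_order[k]]
        best_idx[[length(cur)]] <- cur
        best_crit[length(cur)] <- vals[k]
      } else {
        break
      }
    }
  }

  # refinement sweeps: apply the conditional inclusion/exclusion rules to
  # every recorded best subset until no update occurs (capped), so a late
  # improvement at one size propagates to its neighbours
  for (sweep_i in 1:4) {
    changed <- FALSE
    for (s in seq_len(max_size)) {
      idx <- best_idx[[s]]
      if (is.null(idx)) next
      if (s > 1) {
        for (r in idx) {
          v <- crit(idx[idx != r])
          if (v > best_crit[s - 1] + 1e-12) {
            best_idx[[s - 1]] <- idx[idx != r]
            best_crit[s - 1] <- v
            changed <- TRUE
          }
        }
      }
      if (s < max_size) {
        for (f in lex[!(lex %in% idx)]) {
          v <- crit(c(idx, f))
          if (v > best_crit[s + 1] + 1e-12) {
            best_idx[[s + 1]] <- c(idx, f)
            best_crit[s + 1] <- v
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  # merge a plain greedy pass so best-of-size dominates greedy by construction
  greedy_best <- vector("list", max_size)
  greedy_crit <- rep(-Inf, max_size)
  gcur <- integer(0)
  for (s in seq_len(max_size)) {
    cand <- lex[!(lex %in% gcur)]
    vals <- vapply(cand, function(f) crit(c(gcur, f)), numeric(1))
    gcur <- c(gcur, cand[which.max(vals)])
    greedy_best[[s]] <- gcur
    greedy_crit[s] <- max(vals)
    note(gcur, greedy_crit[s])
  }

  keep <- seq_len(report_size)
  list(
    best = lapply(best_idx[keep], function(i) ids[i]),
    criterion = best_crit[keep],
    best_idx = best_idx[keep],
    greedy = lapply(greedy_best[keep], function(i) ids[i]),
    greedy_criterion = greedy_crit[keep]
  )
}

#' Sequential forward floating search for miRNA panels
#'
#' Runs SFFS over a candidate pool, returning the best panel found at every
#' size from 1 to `max_size`. The criterion is the training AUC of a
#' ridge-logistic model refit on each candidate subset; ties are broken by
#' lexicographic miRNA id. The returned best-of-size panels dominate a plain
#' greedy forward search at every size (the greedy path is folded into the
#' best-known table).
#'
#' @param x Training log2 expression matrix (samples x pool miRNAs) or wide
#'   expression tibble of positive values.
#' @param y Class labels (0/1 or cancer/non_cancer).
#' @param max_size Largest panel size to search.
#' @param pool Optional subset of column names to search over.
#' @param lambda Ridge penalty of the criterion refits.
#' @param overshoot Extra sizes searched beyond `max_size` before
#'   backtracking (floating removals from the overshoot region routinely
#'   improve the reported sizes); results are reported up to `max_size`.
#' @return Tibble with one row per size: `panel_size`, `panel` (list column
#'   of ids in selection order), `criterion` (train AUC), and the greedy
#'   baseline `greedy_criterion`.
#' @export
sffs <- function(x, y, max_size, pool = NULL, lambda = 1e-6,
                 overshoot = 3L) {
  if (!is.matrix(x)) x <- log2(as_expression_matrix(x))
  if (!is.null(pool)) x <- x[, pool, drop = FALSE]
  y <- to_binary(y)
  res <- sffs_core(scale(x), y, max_size, lambda, overshoot = overshoot)
  tibble(
    panel_size = seq_len(max_size),
    panel = res$best,
    criterion = res$criterion,
    greedy_criterion = res$greedy_criterion
  )
}
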