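#' Harmonic-mean F1 from sensitivity and precision
#'
#' `F1 = 2 * sen * pre / (sen + pre)`, defined as 0 whenever sensitivity or
#' precision is 0. On heavily imbalanced residue data this is the headline
#' ranking metric: accuracy saturates near the negative-class fraction and
#' says nothing about hot-spot retrieval.
#'
#' @param sen Sensitivity (recall), in \[0, 1\].
#' @param pre Precision, in \[0, 1\].
#' @return F1 in \[0, 1\]; vectorized.
#' @export
f1_measure <- function(sen, pre) {
  ifelse(sen == 0 | pre == 0, 0, 2 * sen * pre / (sen + pre))
}

#' Classification metrics for hot-spot prediction
#'
#' Confusion counts and the five derived indices: sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), accuracy
#' (TP+TN)/total, and the F1 measure. Ratios with a zero denominator are
#' reported as 0 and flagged in the `undefined` column so ranking code
#' never sees NaN.
#'
#' @param y_true Binary reference labels.
#' @param y_pred Binary predictions of equal length.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`, `sen`, `spe`,
#'   `pre`, `acc`, `f1` and `undefined` (comma-separated names of indices
#'   whose denominator was zero, or "").
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " true labels vs ",
         length(y_pred), " predictions", call. = FALSE)
  }
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  safe <- function(num, den) if (den == 0) 0 else num / den
  undef <- c(sen = tp + fn, spe = tn + fp, pre = tp + fp,
             acc = tp + tn + fp + fn)
  sen <- safe(tp, tp + fn)
  pre <- safe(tp, tp + fp)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sen = sen,
    spe = safe(tn, tn + fp),
    pre = pre,
    acc = safe(tp + tn, tp + tn + fp + fn),
    f1 = f1_measure(sen, pre),
    undefined = paste(names(undef)[undef == 0], collapse = ",")
  )
}

#' Chain-level cross-validation plan
#'
#' Chains (not residues) are the cross-validation unit, so no residue of a
#' chain ever appears in both a training and a test fold. Chains are
#' shuffled with the given seed and dealt round-robin into `n_folds` folds,
#' whose sizes therefore differ by at most one.
#'
#' @param chain_ids Character vector of chain identifiers.
#' @param n_folds Number of folds (default 10); must not exceed the number
#'   of chains.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `cv_plan` tibble with `chain_id` and `fold`, carrying `seed`
#'   and `n_folds` attributes.
#' @export
make_cv_plan <- function(chain_ids, n_folds = 10, seed) {
  stopifnot(!missing(seed), length(chain_ids) >= 1)
  if (n_folds > length(chain_ids)) {
    stop("n_folds (", n_folds, ") exceeds the number of chains (",
         length(chain_ids), ")", call. = FALSE)
  }
  shuffled <- with_local_seed(seed, sample(chain_ids))
  plan <- tibble::tibble(
    chain_id = shuffled,
    fold = rep_len(seq_len(n_folds), length(chain_ids))
  ) |> dplyr::arrange(.data$chain_id)
  attr(plan, "seed") <- seed
  attr(plan, "n_folds") <- n_folds
  class(plan) <- c("cv_plan", class(plan))
  plan
}

# run a seeded expression without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# per-chain encodings for one (cutoff, scheme) cell
encode_dataset <- function(data, scheme, params) {
  purrr::map(data$chain, function(ch) {
    spec <- gnm_modes(build_kirchhoff(ch, params), params)
    encode_features(spec, scheme)
  })
}

# CV over pre-encoded chains; x_list/y_list aligned with plan$chain_id order
cv_from_encodings <- function(x_list, y_list, chain_ids, plan) {
  counts <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  fold_of <- plan$fold[match(chain_ids, plan$chain_id)]
  for (f in sort(unique(plan$fold))) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    if (length(te) == 0) next
    x_tr <- do.call(rbind, x_list[tr])
    y_tr <- unlist(y_list[tr])
    model <- tryCatch(
      gnb_fit(x_tr, y_tr),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    y_te <- unlist(y_list[te])
    y_hat <- predict(model, do.call(rbind, x_list[te]))
    counts <- counts + c(
      tp = sum(y_te == 1L & y_hat == 1L), tn = sum(y_te == 0L & y_hat == 0L),
      fp = sum(y_te == 0L & y_hat == 1L), fn = sum(y_te == 1L & y_hat == 0L)
    )
  }
  counts
}

metrics_from_counts <- function(counts) {
  compute_metrics(
    rep(c(1L, 0L, 0L, 1L), counts[c("tp", "tn", "fp", "fn")]),
    rep(c(1L, 0L, 1L, 0L), counts[c("tp", "tn", "fp", "fn")])
  )
}

#' Cross-validated hot-spot classification for one experiment cell
#'
#' Fits the Gaussian Naive Bayes model on the pooled residues of the
#' training chains of each fold, predicts the held-out chains, and pools
#' the confusion counts over all folds into a single metrics row
#' (micro-averaging) — one report per (cutoff, scheme) cell, matching how
#' single sen/spe/pre/acc/F1 values are reported per cell.
#'
#' @param data A [hotspot_data()] tibble.
#' @param scheme A [feature_scheme()].
#' @param params A [gnm_params()] object.
#' @param plan A [make_cv_plan()] covering exactly the dataset's chains.
#' @return A one-row tibble: cell descriptors (`cutoff`, `scheme`, `mode`,
#'   `window`) followed by the [compute_metrics()] columns.
#' @export
run_cv <- function(data, scheme, params, plan) {
  stopifnot(setequal(plan$chain_id, data$chain_id))
  x_list <- encode_dataset(data, scheme, params)
  y_list <- purrr::map2(data$label, x_list, ~ .x[attr(.y, "nodes")])
  counts <- cv_from_encodings(x_list, y_list, data$chain_id, plan)
  cell <- tibble::tibble(cutoff = params$cutoff, scheme_kind = scheme$scheme,
                         mode = scheme$mode, window = scheme$window)
  names(cell)[2] <- "scheme"
  dplyr::bind_cols(cell, metrics_from_counts(counts))
}

#' Permutation null distribution for cross-validated F1
#'
#' Re-runs the cross-validation with residue labels randomly permuted
#' across the pooled dataset (class counts preserved, chain lengths
#' respected), giving the F1 distribution expected when features carry no
#' label information. Encodings are computed once and reused.
#'
#' @inheritParams run_cv
#' @param n_perm Number of label shuffles (default 200).
#' @param seed Seed for the shuffles.
#' @return Numeric vector of `n_perm` null F1 values.
#' @export
permutation_null <- function(data, scheme, params, plan, n_perm = 200, seed) {
  stopifnot(!missing(seed))
  x_list <- encode_dataset(data, scheme, params)
  y_list <- purrr::map2(data$label, x_list, ~ .x[attr(.y, "nodes")])
  pooled <- unlist(y_list)
  sizes <- lengths(y_list)
  with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(pooled)
      y_perm <- split(perm, rep(seq_along(sizes), sizes))
      counts <- cv_from_encodings(x_list, y_perm, data$chain_id, plan)
      metrics_from_counts(counts)$f1
    }, numeric(1))
  })
}

#' Grid search over cutoff and feature-scheme settings
#'
#' Evaluates every (cutoff, scheme) cell by chain-level cross-validation
#' under one fixed fold plan and returns the top cells ranked by F1
#' (ties: sensitivity descending, then cell order). This reproduces the
#' "top 20 F1" experiment tables; failing cells are skipped with a warning.
#'
#' @param data A [hotspot_data()] tibble.
#' @param cutoffs Numeric vector of contact cutoffs in Angstrom.
#' @param schemes List of [feature_scheme()] objects.
#' @param plan A [make_cv_plan()] for the dataset's chains.
#' @param top_k Number of rows to report (default 20).
#' @return A `hotspot_grid` tibble of at most `top_k` ranked metrics rows.
#' @export
grid_search <- function(data, cutoffs, schemes, plan, top_k = 20) {
  stopifnot(length(cutoffs) > 0, length(schemes) > 0)
  cells <- tidyr::expand_grid(cutoff = cutoffs, scheme_id = seq_along(schemes))
  rows <- purrr::pmap(cells, function(cutoff, scheme_id) {
    tryCatch(
      run_cv(data, schemes[[scheme_id]], gnm_params(cutoff = cutoff), plan),
      error = function(e) {
        rlang::warn(sprintf("grid cell (cutoff %.1f, scheme %d) failed: %s",
                            cutoff, scheme_id, conditionMessage(e)))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("every grid cell failed", call. = FALSE)
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$f1), dplyr::desc(.data$sen),
                   .data$cutoff, .data$scheme, .data$mode, .data$window) |>
    utils::head(top_k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("hotspot_grid", class(out))
  out
}

#' Write a ranked grid-search table as CSV
#'
#' Fixed 4-decimal formatting of the quality indices, one row per ranked
#' cell.
#'
#' @param grid A [grid_search()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  out <- grid |>
    dplyr::transmute(
      rank = .data$rank, cutoff = .data$cutoff, scheme = .data$scheme,
      i_or_m = .data$mode, sw = .data$window,
      sen = sprintf("%.4f", .data$sen), spe = sprintf("%.4f", .data$spe),
      pre = sprintf("%.4f", .data$pre), acc = sprintf("%.4f", .data$acc),
      f1 = sprintf("%.4f", .data$f1)
    )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
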