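test_that("metrics reproduce their defining ratios and edge cases", {
  # perfect prediction
  y <- c(1, 0, 0, 1, 0)
  m <- compute_metrics(y, y)
  expect_equal(c(m$sen, m$spe, m$pre, m$acc, m$f1), rep(1, 5))

  # all-negative calls on 95%-negative data: high accuracy, zero F1
  y_true <- rep(c(1, 0), c(5, 95))
  m2 <- compute_metrics(y_true, rep(0, 100))
  expect_equal(m2$acc, 0.95)
  expect_equal(m2$spe, 1)
  expect_equal(m2$sen, 0)
  expect_equal(m2$f1, 0)
  expect_match(m2$undefined, "pre")

  # counts partition the evaluated residues and rebuild every index
  set.seed(3)
  yt <- rbinom(400, 1, 0.1)
  yp <- rbinom(400, 1, 0.15)
  m3 <- compute_metrics(yt, yp)
  expect_equal(m3$tp + m3$tn + m3$fp + m3$fn, 400)
  expect_equal(m3$sen, m3$tp / (m3$tp + m3$fn))
  expect_equal(m3$spe, m3$tn / (m3$tn + m3$fp))
  expect_equal(m3$pre, m3$tp / (m3$tp + m3$fp))
  expect_equal(m3$acc, (m3$tp + m3$tn) / 400)
  expect_equal(m3$f1, 2 * m3$sen * m3$pre / (m3$sen + m3$pre))
  # harmonic-mean form when both are positive
  expect_equal(m3$f1, 2 / (1 / m3$sen + 1 / m3$pre))

  expect_error(compute_metrics(c(0, 1), c(0, 1, 1)), "length mismatch")
})

test_that("cross-validation plans partition chains with near-equal fold sizes, deterministically", {
  ids <- sprintf("c%02d", 1:32)
  plan <- make_cv_plan(ids, n_folds = 10, seed = 7)
  sizes <- table(plan$fold)
  expect_equal(length(sizes), 10L)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(as.integer(sizes)), rep(c(3L, 4L), c(8, 2)))
  expect_setequal(plan$chain_id, ids)
  expect_equal(anyDuplicated(plan$chain_id), 0L)

  plan2 <- make_cv_plan(ids, n_folds = 10, seed = 7)
  expect_identical(plan$fold, plan2$fold)
  plan3 <- make_cv_plan(ids, n_folds = 10, seed = 8)
  expect_false(identical(plan$fold, plan3$fold))

  expect_error(make_cv_plan(ids[1:5], n_folds = 6, seed = 1), "exceeds")
})

test_that("seeded plans do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(make_cv_plan(letters[1:6], n_folds = 3, seed = 5))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("leave-one-chain-out CV equals an independent per-chain loop", {
  data <- small_data()
  params <- gnm_params(cutoff = 7.0)
  scheme <- feature_scheme("top_m", mode = 2, window = 1)
  plan <- make_cv_plan(data$chain_id, n_folds = nrow(data), seed = 4)
  got <- run_cv(data, scheme, params, plan)

  # oracle: explicit loop over held-out chains
  enc <- lapply(data$chain, function(ch) encode_features(spectrum_at(ch), scheme))
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_len(nrow(data))) {
    x_tr <- do.call(rbind, enc[-i])
    y_tr <- unlist(data$label[-i])
    fit <- gnb_fit(x_tr, y_tr)
    y_hat <- predict(fit, enc[[i]])
    y_te <- data$label[[i]]
    counts <- counts + c(sum(y_te == 1 & y_hat == 1), sum(y_te == 0 & y_hat == 0),
                         sum(y_te == 0 & y_hat == 1), sum(y_te == 1 & y_hat == 0))
  }
  expect_equal(c(got$tp, got$tn, got$fp, got$fn), unname(counts))
  expect_equal(got$tp + got$tn + got$fp + got$fn, sum(data$n))
})

test_that("pooled metrics are invariant to chain order and linear under duplication", {
  data <- small_data()
  params <- gnm_params(cutoff = 7.0)
  scheme <- feature_scheme("single_mode", mode = 1, window = 3)
  plan <- make_cv_plan(data$chain_id, n_folds = 4, seed = 6)
  base <- run_cv(data, scheme, params, plan)

  perm <- data[rev(seq_len(nrow(data))), ]
  expect_equal(run_cv(perm, scheme, params, plan)[, -(1:4)], base[, -(1:4)])

  # duplicate every chain (fresh ids), duplicating fold assignments:
  # counts double, ratio metrics unchanged
  dup_chains <- c(data$chain, lapply(data$chain, function(ch) {
    ch$chain_id <- paste0(ch$chain_id, "x")
    ch
  }))
  dup <- hotspot_data(dup_chains)
  dup$label <- c(data$label, data$label)
  dup_plan <- dplyr::bind_rows(
    plan,
    dplyr::mutate(plan, chain_id = paste0(.data$chain_id, "x"))
  )
  got <- run_cv(dup, scheme, params, dup_plan)
  expect_equal(c(got$tp, got$tn, got$fp, got$fn),
               2 * c(base$tp, base$tn, base$fp, base$fn))
  expect_equal(got[, c("sen", "spe", "pre", "acc", "f1")],
               base[, c("sen", "spe", "pre", "acc", "f1")])
})

test_that("a single-cell grid equals a direct CV run and ranking is F1-descending", {
  data <- small_data()
  plan <- make_cv_plan(data$chain_id, n_folds = 4, seed = 2)
  scheme <- feature_scheme("top_m", mode = 2, window = 1)
  single <- grid_search(data, 7.0, list(scheme), plan)
  direct <- run_cv(data, scheme, gnm_params(cutoff = 7.0), plan)
  expect_equal(nrow(single), 1)
  expect_equal(as.data.frame(single[, -1]), as.data.frame(direct))

  grid <- grid_search(data, c(6.8, 7.0, 7.2),
                      list(feature_scheme("top_m", 2, 1),
                           feature_scheme("single_mode", 1, 1)),
                      plan, top_k = 4)
  expect_equal(nrow(grid), 4)  # min(top_k, cells)
  expect_true(all(diff(grid$f1) <= 0))
  expect_equal(grid$rank, 1:4)
})

test_that("failing grid cells are skipped with a warning, and the CSV export is fixed-point", {
  data <- small_data()
  plan <- make_cv_plan(data$chain_id, n_folds = 4, seed = 2)
  schemes <- list(feature_scheme("top_m", 2, 1),
                  feature_scheme("top_m", 10000, 1))  # impossible cell
  expect_warning(grid <- grid_search(data, 7.0, schemes, plan),
                 "insufficient modes")
  expect_equal(nrow(grid), 1)

  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(grid, f)
  got <- utils::read.csv(f, colClasses = "character")
  expect_equal(names(got),
               c("rank", "cutoff", "scheme", "i_or_m", "sw",
                 "sen", "spe", "pre", "acc", "f1"))
  expect_match(got$f1[1], "^0\\.\\d{4}$")
})
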