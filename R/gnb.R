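#' Fit a Gaussian Naive Bayes classifier
#'
#' From-scratch Gaussian Naive Bayes for binary residue classification.
#' Class priors are the training-label frequencies; each feature gets a
#' per-class Gaussian with the class mean and the *population* variance
#' (divide by the class count). A variance floor
#' `epsilon = var_smoothing * max_j Var(x_j)` over the pooled data is added
#' to every variance so that constant features (e.g. all-zero padded window
#' columns within one class) cannot produce infinite densities.
#'
#' The posterior for a residue with features x is proportional to
#' `P(y) * prod_j N(x_j; mu_jy, sigma2_jy)`; classification takes the larger
#' numerator, with ties resolved to the negative class (see
#' [predict.gnb()]).
#'
#' @param x Numeric feature matrix, one row per training residue.
#' @param y Binary labels (0/1), one per row; both classes must be present.
#' @param var_smoothing Relative variance floor (default 1e-9).
#' @return A `gnb` model object.
#' @export
gnb_fit <- function(x, y, var_smoothing = 1e-9) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (anyNA(x)) stop("missing feature values are not supported", call. = FALSE)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n0 == 0 || n1 == 0) {
    stop("degenerate training labels: both classes must be present (got ",
         n1, " positives and ", n0, " negatives)", call. = FALSE)
  }
  pop_var <- function(m) {
    mu <- colMeans(m)
    colMeans(m^2) - mu^2
  }
  pooled_mu <- colMeans(x)
  epsilon <- var_smoothing * max(colMeans(x^2) - pooled_mu^2)
  x0 <- x[y == 0L, , drop = FALSE]
  x1 <- x[y == 1L, , drop = FALSE]
  structure(
    list(
      prior = c(`0` = n0, `1` = n1) / (n0 + n1),
      mean = rbind(`0` = colMeans(x0), `1` = colMeans(x1)),
      var = rbind(`0` = pop_var(x0) + epsilon, `1` = pop_var(x1) + epsilon),
      epsilon = epsilon,
      d = ncol(x),
      n_train = c(`0` = n0, `1` = n1),
      features = colnames(x)
    ),
    class = "gnb"
  )
}

# joint log score log P(y) + sum_j log N(x_j; mu, sigma2) for one class
gnb_log_score <- function(model, x, class) {
  cls <- as.character(class)
  mu <- model$mean[cls, ]
  s2 <- model$var[cls, ]
  const <- -0.5 * sum(log(2 * pi * s2))
  centred <- sweep(x, 2, mu)
  log(model$prior[[cls]]) + const +
    rowSums(sweep(centred^2, 2, -1 / (2 * s2), `*`))
}

#' Predict hot-spot labels or posteriors from a GNB model
#'
#' Scores both classes in the log domain (products of hundreds of densities
#' underflow in the linear domain) and either thresholds them or returns the
#' normalized posterior via log-sum-exp. A residue is called a hot spot only
#' when its class-1 score strictly exceeds the class-0 score; exact ties go
#' to the negative class.
#'
#' @param object A [gnb_fit()] model.
#' @param newdata Feature matrix with the model's feature dimension.
#' @param type `"class"` for 0/1 labels, `"prob"` for P(y = 1 | x).
#' @param ... Unused.
#' @return Integer labels or numeric posteriors, one per row of `newdata`.
#' @export
predict.gnb <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$d) {
    stop("feature dimension mismatch: model expects ", object$d,
         " features, data has ", ncol(x), call. = FALSE)
  }
  s0 <- gnb_log_score(object, x, 0L)
  s1 <- gnb_log_score(object, x, 1L)
  if (type == "class") {
    as.integer(s1 > s0)
  } else {
    m <- pmax(s0, s1)
    exp(s1 - m) / (exp(s0 - m) + exp(s1 - m))
  }
}

#' @rdname gnb_tidiers
#' @method tidy gnb
#' @export
tidy.gnb <- function(x, ...) {
  feats <- if (is.null(x$features)) paste0("x", seq_len(x$d)) else x$features
  tidyr::expand_grid(class = c(0L, 1L), term = feats) |>
    dplyr::mutate(
      mean = purrr::map2_dbl(.data$class, .data$term,
                             ~ x$mean[as.character(.x), match(.y, feats)]),
      variance = purrr::map2_dbl(.data$class, .data$term,
                                 ~ x$var[as.character(.x), match(.y, feats)])
    )
}

#' Tidiers for Gaussian Naive Bayes models
#'
#' `tidy()` returns one row per (class, feature) with the fitted Gaussian
#' mean and variance; `glance()` returns a one-row model summary.
#'
#' @param x A `gnb` model.
#' @param ... Unused.
#' @name gnb_tidiers
#' @method glance gnb
#' @export
glance.gnb <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_train), n_hotspot = x$n_train[["1"]], d = x$d,
    prior_hotspot = x$prior[["1"]], epsilon = x$epsilon
  )
}

#' @export
print.gnb <- function(x, ...) {
  cat("<gnb> Gaussian Naive Bayes:", x$d, "features,",
      sum(x$n_train), "training residues",
      sprintf("(prior P(hot spot) = %.4f)\n", x$prior[["1"]]))
  invisible(x)
}

#' Save / load a GNB model as JSON
#'
#' Flat key-value document holding priors, per-class means and variances,
#' the variance floor and the feature dimension.
#'
#' @param model A `gnb` model.
#' @param path File path.
#' @return `write_gnb` returns `path` invisibly; `read_gnb` returns the model.
#' @export
write_gnb <- function(model, path) {
  doc <- list(
    prior = as.list(model$prior),
    mean0 = unname(model$mean["0", ]), mean1 = unname(model$mean["1", ]),
    var0 = unname(model$var["0", ]), var1 = unname(model$var["1", ]),
    epsilon = model$epsilon, d = model$d,
    n_train = as.list(model$n_train),
    features = model$features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gnb
#' @export
read_gnb <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      prior = c(`0` = doc$prior$`0`, `1` = doc$prior$`1`),
      mean = rbind(`0` = doc$mean0, `1` = doc$mean1),
      var = rbind(`0` = doc$var0, `1` = doc$var1),
      epsilon = doc$epsilon, d = doc$d,
      n_train = c(`0` = doc$n_train$`0`, `1` = doc$n_train$`1`),
      features = doc$features
    ),
    class = "gnb"
  )
}
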