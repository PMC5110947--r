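#' Gaussian network model parameters
#'
#' Collects the parameters of the elastic-network calculation. `cutoff` is
#' the contact distance R_C in Angstrom: two C-alpha atoms interact iff their
#' distance is at most R_C (the boundary counts as a contact). `scale` is the
#' fluctuation prefactor c = 3 kB T / gamma; it cancels in all normalized
#' quantities and defaults to 1 so mode amplitudes are reported in units of
#' the inverse force constant. `zero_tol` is the relative eigenvalue
#' tolerance used to identify the null space of the Kirchhoff matrix.
#'
#' @param cutoff Contact cutoff R_C in Angstrom (> 0). Typical grids run
#'   6.0-8.0 in 0.1 steps.
#' @param scale Prefactor c = 3 kB T / gamma (> 0, default 1).
#' @param zero_tol Relative tolerance for zero eigenvalues (default 1e-10
#'   times the largest eigenvalue).
#' @return A `gnm_params` list.
#' @export
gnm_params <- function(cutoff = 7.0, scale = 1.0, zero_tol = 1e-10) {
  stopifnot(cutoff > 0, scale > 0, zero_tol >= 0)
  structure(list(cutoff = cutoff, scale = scale, zero_tol = zero_tol),
            class = "gnm_params")
}

#' Build the Kirchhoff (connectivity) matrix of a C-alpha chain
#'
#' The Kirchhoff matrix is the graph Laplacian of the residue contact
#' network: Gamma_ij = -1 if residues i != j are within the cutoff, 0
#' otherwise, and Gamma_ii equals the contact degree of residue i. Every row
#' sums to zero and the matrix is positive semidefinite; its spectrum fully
#' determines the isotropic network dynamics.
#'
#' @param chain A `ca_chain`.
#' @param params A [gnm_params()] object (or a bare numeric cutoff).
#' @return A `kirchhoff` object wrapping the N x N matrix and the cutoff used.
#' @export
build_kirchhoff <- function(chain, params = gnm_params()) {
  if (is.numeric(params)) params <- gnm_params(cutoff = params)
  stopifnot(inherits(chain, "ca_chain"), chain$n >= 2)
  d <- as.matrix(stats::dist(chain$coords))
  contact <- (d <= params$cutoff)
  diag(contact) <- FALSE
  g <- -1 * contact
  diag(g) <- rowSums(contact)
  dimnames(g) <- NULL
  structure(list(matrix = g, cutoff = params$cutoff, n = chain$n),
            class = "kirchhoff")
}

#' @export
print.kirchhoff <- function(x, ...) {
  cat("<kirchhoff>", x$n, "x", x$n, "at cutoff", x$cutoff, "A;",
      "mean contact degree", round(mean(diag(x$matrix)), 2), "\n")
  invisible(x)
}

#' Decompose a Kirchhoff matrix into normal modes
#'
#' Full symmetric eigendecomposition Gamma = U Lambda U'. Eigenvalues are
#' returned in ascending order; the k-th *high-frequency* mode (hm_k) is the
#' eigenvector of the k-th largest eigenvalue. The eigenvector sign is fixed
#' by requiring the component of largest absolute value to be positive (ties
#' broken by lowest index), so that signed mode features are reproducible
#' across platforms. The number of (numerically) zero eigenvalues equals the
#' number of connected components of the contact graph and is always at
#' least one.
#'
#' Degenerate eigenvalue pairs (gap below `1e-8 * lambda_max`) are flagged in
#' the returned object: mode identity is not well defined inside a
#' degenerate block, and ties keep the sorted decomposition order.
#'
#' @param kirchhoff A [build_kirchhoff()] result.
#' @param params A [gnm_params()] object; supplies `zero_tol` and `scale`.
#' @return A `mode_spectrum`: eigenvalues `values` (ascending), orthonormal
#'   eigenvector matrix `vectors` (columns aligned with `values`), `n_zero`,
#'   `degenerate` flag, and the parameters used.
#' @export
gnm_modes <- function(kirchhoff, params = gnm_params(cutoff = kirchhoff$cutoff)) {
  stopifnot(inherits(kirchhoff, "kirchhoff"))
  eig <- tryCatch(
    eigen(kirchhoff$matrix, symmetric = TRUE),
    error = function(e) stop("eigendecomposition failed for ", kirchhoff$n,
                             " x ", kirchhoff$n, " Kirchhoff matrix: ",
                             conditionMessage(e), call. = FALSE)
  )
  ord <- rev(seq_along(eig$values))  # ascending
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-|component| entry positive
  for (j in seq_len(ncol(vectors))) {
    piv <- which.max(abs(vectors[, j]))
    if (vectors[piv, j] < 0) vectors[, j] <- -vectors[, j]
  }
  lmax <- max(abs(values))
  n_zero <- sum(values < params$zero_tol * lmax)
  degenerate <- any(diff(values) < 1e-8 * lmax)
  structure(
    list(values = values, vectors = vectors, n_zero = max(1L, n_zero),
         n = kirchhoff$n, cutoff = kirchhoff$cutoff, params = params,
         degenerate = degenerate),
    class = "mode_spectrum"
  )
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("<mode_spectrum>", x$n, "modes at cutoff", x$cutoff, "A;",
      x$n_zero, "zero mode(s); lambda range [",
      signif(x$values[1], 3), ",", signif(x$values[x$n], 3), "]\n")
  if (x$degenerate) cat("  note: degenerate eigenvalues present\n")
  invisible(x)
}

# column indices of the k-th, ... largest eigenvalues (high-frequency ranks)
hf_columns <- function(spectrum, mode_ranks) {
  n_avail <- spectrum$n - spectrum$n_zero
  if (any(mode_ranks < 1) || any(mode_ranks > n_avail)) {
    stop("insufficient modes: requested high-frequency rank(s) ",
         paste(mode_ranks, collapse = ","), " but only ", n_avail,
         " non-null modes exist", call. = FALSE)
  }
  spectrum$n - mode_ranks + 1L
}

check_nonnull <- function(spectrum, cols) {
  tol <- spectrum$params$zero_tol * max(abs(spectrum$values))
  if (any(spectrum$values[cols] <= tol)) {
    stop("zero eigenvalue in mode subset", call. = FALSE)
  }
}

#' Mean square fluctuations from a subset of modes
#'
#' The per-residue mean square fluctuation (MSF) weighted by a mode subset
#' is the inverse-eigenvalue-weighted average of squared eigenvector
#' components,
#' \deqn{MSF_i = c \sum_k \lambda_k^{-1} u_{ki}^2 / \sum_k \lambda_k^{-1},}
#' with c = 3 kB T / gamma. The normalized MSF divides out c; for a single
#' mode it reduces to the squared eigenvector components and sums to one
#' over residues. High-frequency subsets localize on tightly packed regions
#' and are the fluctuation signal behind the MSF-threshold hot-spot rules.
#'
#' @param spectrum A [gnm_modes()] result.
#' @param mode_ranks Integer vector of high-frequency ranks (1 = fastest
#'   mode, i.e. largest eigenvalue).
#' @param normalized If `TRUE` (default), divide by the scale c.
#' @return Numeric vector of length N.
#' @export
msf_weighted <- function(spectrum, mode_ranks = 1, normalized = TRUE) {
  cols <- hf_columns(spectrum, mode_ranks)
  check_nonnull(spectrum, cols)
  w <- 1 / spectrum$values[cols]
  u2 <- spectrum$vectors[, cols, drop = FALSE]^2
  msf <- drop(u2 %*% w) / sum(w)
  if (normalized) msf else spectrum$params$scale * msf
}

#' Residue fluctuation cross-correlations from a subset of modes
#'
#' C_ij = c * sum_k lambda_k^-1 u_ki u_kj over the selected modes; with the
#' full non-null mode set this is c times the Moore-Penrose pseudo-inverse
#' of the Kirchhoff matrix, the standard GNM correlation matrix.
#'
#' @inheritParams msf_weighted
#' @return An N x N symmetric matrix.
#' @export
correlation_matrix <- function(spectrum, mode_ranks = 1) {
  cols <- hf_columns(spectrum, mode_ranks)
  check_nonnull(spectrum, cols)
  u <- spectrum$vectors[, cols, drop = FALSE]
  w <- 1 / spectrum$values[cols]
  spectrum$params$scale * (u %*% (w * t(u)))
}

#' Mean square distance fluctuations from a subset of modes
#'
#' The fluctuation of the inter-residue distance for every pair,
#' D_ij = C_ii + C_jj - 2 C_ij, computed from [correlation_matrix()] on the
#' same mode subset. D is symmetric and non-negative with a zero diagonal.
#' High-frequency MSDF is the pairwise signal used by the distance-
#' fluctuation hot-spot scorer.
#'
#' @inheritParams msf_weighted
#' @return An N x N symmetric matrix with zero diagonal.
#' @export
msdf_matrix <- function(spectrum, mode_ranks = 1) {
  cc <- correlation_matrix(spectrum, mode_ranks)
  d <- diag(cc)
  out <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * cc
  diag(out) <- 0
  out
}

#' Tidy per-residue MSF profile
#'
#' Convenience wrapper returning the normalized MSF of one or more mode
#' subsets as a long tibble, ready for plotting.
#'
#' @param spectrum A [gnm_modes()] result.
#' @param mode_sets Named list of integer rank vectors, e.g.
#'   `list(hm1 = 1, `hm1-3` = 1:3)`.
#' @return A tibble with `node`, `mode_set`, `msf`.
#' @export
msf_profile <- function(spectrum, mode_sets = list(hm1 = 1)) {
  if (is.null(names(mode_sets))) {
    names(mode_sets) <- vapply(mode_sets, function(r) {
      paste0("hm", if (length(r) == 1) r else paste0(min(r), "-", max(r)))
    }, character(1))
  }
  purrr::imap(mode_sets, function(ranks, nm) {
    tibble::tibble(node = seq_len(spectrum$n), mode_set = nm,
                   msf = msf_weighted(spectrum, ranks))
  }) |> dplyr::bind_rows()
}
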