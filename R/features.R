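#' Feature-coding scheme for mode-based residue features
#'
#' Two codings of the high-frequency modes are supported. `single_mode` uses
#' the i-th fastest mode only; `top_m` stacks the m fastest modes. Either
#' way a sliding window of `window` consecutive residues centred on the
#' target residue supplies the components, so the feature dimension is
#' `window` (single_mode) or `m * window` (top_m). Ordering is mode-major:
#' all window positions of the fastest mode first, then the next mode, and
#' so on — for m = 3, window = 3 the row for residue i reads
#' (u1[i-1], u1[i], u1[i+1], u2[i-1], u2[i], u2[i+1], u3[i-1], u3[i], u3[i+1]).
#'
#' Window positions falling outside the chain are zero-filled by default
#' (`boundary = "pad"`), which keeps the dimension constant as the Gaussian
#' Naive Bayes model requires; `boundary = "drop"` instead removes residues
#' whose window is incomplete.
#'
#' @param scheme `"single_mode"` or `"top_m"`.
#' @param mode High-frequency rank i (single_mode) or mode count m (top_m),
#'   usually 1-20.
#' @param window Odd window size, usually 1-21.
#' @param boundary `"pad"` (zero-fill outside the chain) or `"drop"`.
#' @return A `feature_scheme` list.
#' @export
feature_scheme <- function(scheme = c("single_mode", "top_m"), mode = 1,
                           window = 1, boundary = c("pad", "drop")) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  stopifnot(mode >= 1, mode == as.integer(mode),
            window >= 1, window %% 2 == 1)
  structure(list(scheme = scheme, mode = as.integer(mode),
                 window = as.integer(window), boundary = boundary),
            class = "feature_scheme")
}

#' @export
print.feature_scheme <- function(x, ...) {
  lab <- if (x$scheme == "single_mode") paste0("hm", x$mode)
         else paste0("hm1-", x$mode)
  cat("<feature_scheme>", x$scheme, lab, "window", x$window,
      paste0("(", x$boundary, ")"), "\n")
  invisible(x)
}

# shift a vector by `off` along the sequence, zero-filling the gap
shift_pad <- function(v, off) {
  n <- length(v)
  if (off == 0) return(v)
  if (off > 0) c(v[-seq_len(off)], rep(0, off))
  else c(rep(0, -off), v[seq_len(n + off)])
}

#' Encode per-residue feature vectors from high-frequency modes
#'
#' Builds the N x d feature matrix for one chain's mode spectrum under a
#' coding scheme: each residue's features are the components of the selected
#' high-frequency eigenvectors at the window offsets around it.
#'
#' @param spectrum A [gnm_modes()] result.
#' @param scheme A [feature_scheme()].
#' @return A numeric matrix with one row per residue (attribute `nodes`
#'   gives the residue positions retained, which differ from `1:N` only for
#'   `boundary = "drop"`). Columns are named `hm<k>.off<o>`.
#' @export
encode_features <- function(spectrum, scheme) {
  stopifnot(inherits(spectrum, "mode_spectrum"),
            inherits(scheme, "feature_scheme"))
  ranks <- if (scheme$scheme == "single_mode") scheme$mode else seq_len(scheme$mode)
  cols <- hf_columns(spectrum, ranks)
  half <- (scheme$window - 1L) %/% 2L
  offsets <- seq.int(-half, half)
  blocks <- lapply(seq_along(ranks), function(j) {
    u <- spectrum$vectors[, cols[j]]
    m <- vapply(offsets, function(off) shift_pad(u, off), numeric(spectrum$n))
    colnames(m) <- sprintf("hm%d.off%+d", ranks[j], offsets)
    m
  })
  x <- do.call(cbind, blocks)
  nodes <- seq_len(spectrum$n)
  if (scheme$boundary == "drop" && half > 0) {
    keep <- nodes > half & nodes <= spectrum$n - half
    if (!any(keep)) stop("window of size ", scheme$window,
                         " leaves no complete rows for a chain of length ",
                         spectrum$n, call. = FALSE)
    x <- x[keep, , drop = FALSE]
    nodes <- nodes[keep]
  }
  attr(x, "nodes") <- nodes
  attr(x, "scheme") <- scheme
  x
}
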