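#' MSF threshold rule for baseline hot-spot prediction
#'
#' Two classical rules threshold the normalized fast-mode MSF profile:
#' a constant threshold (default 0.005) and a length-scaled threshold
#' theta = a / N with a = 6, where N is the chain length. For chains shorter
#' than 1200 residues the length-scaled rule is the stricter of the two, so
#' its prediction set is a subset of the constant rule's on the same MSF
#' profile.
#'
#' @param kind `"constant"` or `"length_scaled"`.
#' @param threshold Constant threshold theta (used when `kind = "constant"`).
#' @param scale Numerator a of theta = a / N (used when `kind = "length_scaled"`).
#' @return A `threshold_rule` list.
#' @export
threshold_rule <- function(kind = c("constant", "length_scaled"),
                           threshold = 0.005, scale = 6) {
  kind <- match.arg(kind)
  stopifnot(threshold > 0, scale > 0)
  structure(list(kind = kind, threshold = threshold, scale = scale),
            class = "threshold_rule")
}

rule_theta <- function(rule, n) {
  if (rule$kind == "constant") rule$threshold else rule$scale / n
}

#' Baseline hot-spot prediction by thresholding fast-mode MSF
#'
#' Computes the normalized MSF over the `mode_count` fastest modes and
#' labels residue i a hot spot iff MSF_i strictly exceeds the rule's
#' threshold. With the constant rule this emulates the classical fixed
#' 0.005 criterion; with the length-scaled rule, the 6/N criterion.
#'
#' @param spectrum A [gnm_modes()] result.
#' @param mode_count Number of fastest modes to combine (typically 1-5).
#' @param rule A [threshold_rule()].
#' @return Integer vector of 0/1 predictions, one per residue.
#' @export
msf_threshold_predict <- function(spectrum, mode_count = 1,
                                  rule = threshold_rule()) {
  stopifnot(mode_count >= 1)
  msf <- msf_weighted(spectrum, seq_len(mode_count), normalized = TRUE)
  as.integer(msf > rule_theta(rule, spectrum$n))
}

#' Per-residue score from fast-mode distance fluctuations
#'
#' Aggregates each row of the high-frequency mean square distance
#' fluctuation matrix into a single per-residue score: residues whose
#' distances to the rest of the chain fluctuate most in the fast modes
#' score highest and are considered functionally probable. The aggregate is
#' the row maximum by default, or the mean over the other residues. A
#' ranking score is returned, not labels; callers pick their own quantile
#' to binarize.
#'
#' @param spectrum A [gnm_modes()] result.
#' @param mode_count Number of fastest modes (at most 5 in common use).
#' @param aggregate `"max"` or `"mean"`.
#' @return Numeric score vector of length N.
#' @export
msdf_score <- function(spectrum, mode_count = 1,
                       aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  d <- msdf_matrix(spectrum, seq_len(mode_count))
  if (aggregate == "max") {
    apply(d, 1, max)
  } else {
    rowSums(d) / (spectrum$n - 1)  # exclude the zero self-distance
  }
}

#' Baseline comparison table on a hot-spot dataset
#'
#' Runs the constant-threshold and length-scaled MSF baselines for one up
#' to `max_modes` fastest modes over every chain of a dataset, pools the
#' confusion counts, and reports one metrics row per (rule, mode count)
#' cell — the shape of the classical method-comparison tables.
#'
#' @param data A [hotspot_data()] tibble.
#' @param params GNM parameters for the baseline runs (cutoff 7.0 A by
#'   convention).
#' @param max_modes Largest fast-mode count (default 5).
#' @return A tibble of metrics rows with `method` and `modes` columns.
#' @export
baseline_table <- function(data, params = gnm_params(cutoff = 7.0),
                           max_modes = 5) {
  spectra <- purrr::map(data$chain, ~ gnm_modes(build_kirchhoff(.x, params), params))
  rules <- list(constant = threshold_rule("constant"),
                length_scaled = threshold_rule("length_scaled"))
  tidyr::expand_grid(method = names(rules), modes = seq_len(max_modes)) |>
    dplyr::mutate(purrr::map2(.data$method, .data$modes, function(meth, k) {
      pred <- purrr::map(spectra, msf_threshold_predict, mode_count = k,
                         rule = rules[[meth]])
      compute_metrics(unlist(data$label), unlist(pred))
    }) |> dplyr::bind_rows()) |>
    dplyr::mutate(cutoff = params$cutoff, .after = "modes")
}
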