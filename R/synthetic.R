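#' Specification for synthetic C-alpha chains with planted hot spots
#'
#' Defines the study conditions for a fully in-silico dataset: compact
#' self-avoiding C-alpha walks with protein-like geometry (3.8 A virtual
#' bonds, a 4 A excluded-volume radius, and confinement to a sphere whose
#' radius scales as N^(1/3) so the 7 A contact density falls in the range
#' seen for globular proteins), plus binary residue labels planted from the
#' normalized fast-mode MSF at a chosen "true" cutoff. The default label
#' quantile 0.96 mimics the ~4% hot-spot prevalence of curated
#' protein-interface datasets, and `label_noise` flips each label
#' independently to emulate annotation error.
#'
#' @param n_chains Number of chains (default 30).
#' @param length_range Integer range for chain lengths, drawn uniformly
#'   (default 80-200; minimum allowed length is 20).
#' @param bond_length Consecutive C-alpha spacing in Angstrom (default 3.8).
#' @param exclusion Excluded-volume radius in Angstrom: no non-consecutive
#'   pair may come closer (default 4.0).
#' @param compactness Confinement sphere radius is
#'   `compactness * N^(1/3)` Angstrom (default 3.2, giving a protein-like
#'   packing density).
#' @param planted_cutoff GNM cutoff R* at which labels are planted
#'   (default 7.0 A).
#' @param planted_modes Number of fastest modes m* whose normalized MSF
#'   defines the planted signal (default 3).
#' @param hotspot_quantile Quantile q of the per-chain MSF above which a
#'   residue is labelled a hot spot before noise (default 0.96).
#' @param label_noise Independent label-flip probability eta in \[0, 0.5)
#'   (default 0.1).
#' @param seed Integer master seed; every chain and label draw derives
#'   deterministically from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chains = 30, length_range = c(80, 200),
                           bond_length = 3.8, exclusion = 4.0,
                           compactness = 3.2, planted_cutoff = 7.0,
                           planted_modes = 3, hotspot_quantile = 0.96,
                           label_noise = 0.1, seed = 1) {
  stopifnot(n_chains >= 1, length(length_range) == 2,
            length_range[1] >= 20, length_range[2] >= length_range[1],
            bond_length > 0, exclusion > 0, compactness > 0,
            planted_cutoff > 0, planted_modes >= 1,
            hotspot_quantile > 0, hotspot_quantile < 1,
            label_noise >= 0, label_noise < 0.5)
  structure(
    list(n_chains = as.integer(n_chains),
         length_range = as.integer(length_range),
         bond_length = bond_length, exclusion = exclusion,
         compactness = compactness, planted_cutoff = planted_cutoff,
         planted_modes = as.integer(planted_modes),
         hotspot_quantile = hotspot_quantile, label_noise = label_noise,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# single-character chain ids, unique up to 62 chains
synthetic_chain_id <- function(index) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (index > length(pool)) stop("at most ", length(pool),
                                 " synthetic chains per dataset", call. = FALSE)
  pool[index]
}

# deterministic per-(seed, index, purpose) sub-seed below 2^31
sub_seed <- function(seed, index, purpose) {
  (as.double(seed) * 7919 + index * 104729 + purpose * 15485863) %% 2147483647
}

#' Generate one synthetic C-alpha chain
#'
#' Grows a self-avoiding random walk with fixed bond length inside a
#' confinement sphere centred at the origin: each step proposes a direction
#' biased toward the centre when the walk drifts outward, and is rejected
#' if it lands within the excluded-volume radius of any earlier residue or
#' outside the sphere. Blocked walks back up a few residues and retry;
#' persistent failure raises an error echoing the spec. Deterministic given
#' `(spec$seed, index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param index Chain index (1-based); also selects the chain id.
#' @return A `ca_chain` with residues numbered 1..N.
#' @export
generate_chain <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 1)
  with_local_seed(sub_seed(spec$seed, index, 1), {
    n <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    radius <- spec$compactness * n^(1 / 3)
    coords <- NULL
    for (attempt in seq_len(100)) {
      coords <- matrix(NA_real_, n, 3)
      coords[1, ] <- c(0, 0, 0)
      dir0 <- stats::rnorm(3)
      coords[2, ] <- spec$bond_length * dir0 / sqrt(sum(dir0^2))
      i <- 3L
      backtracks <- 0L
      while (i <= n && backtracks <= 200L) {
        placed <- FALSE
        for (try in seq_len(60)) {
          cur <- coords[i - 1, ]
          pull <- (sqrt(sum(cur^2)) / radius)^2  # stronger pull near the wall
          dir <- stats::rnorm(3) - 1.2 * pull * cur / max(sqrt(sum(cur^2)), 1e-9)
          dir <- dir / sqrt(sum(dir^2))
          cand <- cur + spec$bond_length * dir
          if (sqrt(sum(cand^2)) > radius) next
          prior <- coords[seq_len(i - 2), , drop = FALSE]
          d2 <- (prior[, 1] - cand[1])^2 + (prior[, 2] - cand[2])^2 +
            (prior[, 3] - cand[3])^2
          if (min(d2) < spec$exclusion^2) next
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
        if (placed) {
          i <- i + 1L
        } else {
          # back up a few residues and regrow; a persistently blocked walk
          # is abandoned and restarted from scratch (fresh draws from the
          # same seeded stream, so the result is still deterministic)
          backtracks <- backtracks + 1L
          i <- max(3L, i - 3L)
          coords[seq(i, n), ] <- NA_real_
        }
      }
      if (i > n) break
      coords <- NULL
    }
    if (is.null(coords)) {
      stop("generation failed for chain index ", index, " (n = ", n,
           ", bond ", spec$bond_length, " A, exclusion ", spec$exclusion,
           " A, radius ", round(radius, 1), " A): walk blocked",
           call. = FALSE)
    }
    new_ca_chain(
      chain_id = synthetic_chain_id(index),
      residues = tibble::tibble(resno = seq_len(n), insert = "",
                                resid = "ALA"),
      coords = coords, index = as.integer(index)
    )
  })
}

#' Plant hot-spot labels from the fast-mode MSF of a chain
#'
#' Residues whose normalized MSF over the `planted_modes` fastest modes at
#' the planted cutoff lies above the `hotspot_quantile` of the chain's MSF
#' distribution are labelled 1; each label is then flipped independently
#' with probability `label_noise`. This plants exactly the statistical
#' structure the classifier is asked to recover: a fluctuation-defined
#' positive class observed through noisy annotation. Deterministic given
#' `(spec$seed, chain index)`.
#'
#' @param chain A [generate_chain()] result (carries its index).
#' @param spec The [synthetic_spec()] used to generate it.
#' @return A label tibble (`chain_id`, `resno`, `insert`, `label`) covering
#'   every residue of the chain.
#' @export
plant_labels <- function(chain, spec) {
  stopifnot(inherits(chain, "ca_chain"), inherits(spec, "synthetic_spec"))
  if (is.na(chain$index)) {
    stop("chain has no generation index; plant_labels needs a chain from ",
         "generate_chain()", call. = FALSE)
  }
  params <- gnm_params(cutoff = spec$planted_cutoff)
  msf <- msf_weighted(gnm_modes(build_kirchhoff(chain, params), params),
                      seq_len(spec$planted_modes))
  y <- as.integer(msf > stats::quantile(msf, spec$hotspot_quantile))
  y <- with_local_seed(sub_seed(spec$seed, chain$index, 2), {
    flip <- stats::runif(length(y)) < spec$label_noise
    as.integer(xor(y == 1L, flip))
  })
  out <- tibble::tibble(chain_id = chain$chain_id,
                        resno = chain$residues$resno,
                        insert = chain$residues$insert, label = y)
  class(out) <- c("label_set", class(out))
  out
}

#' Simulate a full hot-spot dataset
#'
#' Generates `spec$n_chains` chains and their planted labels and assembles
#' them into a [hotspot_data()] tibble.
#'
#' @param spec A [synthetic_spec()].
#' @return A [hotspot_data()] tibble.
#' @export
simulate_dataset <- function(spec) {
  chains <- purrr::map(seq_len(spec$n_chains), ~ generate_chain(spec, .x))
  labels <- dplyr::bind_rows(purrr::map(chains, plant_labels, spec = spec))
  hotspot_data(chains, labels)
}

#' Write a C-alpha chain as a PDB file
#'
#' Emits fixed-width wwPDB v3.3 ATOM records, one CA atom per residue with
#' occupancy 1.00 and B-factor 0.00, terminated by TER/END. Coordinates are
#' rounded to the PDB's three decimals, so [read_ca_chain()] round-trips
#' them to 1e-3 A. Output is byte-deterministic for a given chain.
#'
#' @param chain A `ca_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(chain, path) {
  ins <- ifelse(chain$residues$insert == "", " ",
                substr(chain$residues$insert, 1, 1))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(chain$n), chain$residues$resid, chain$chain_id,
    chain$residues$resno, ins,
    chain$coords[, 1], chain$coords[, 2], chain$coords[, 3], 1, 0
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
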