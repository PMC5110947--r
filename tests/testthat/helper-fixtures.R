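# Shared fixtures and independent oracles. Fixtures are generated in code
# (no stored data) and cached for the test run.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- force(expr)
  fixture_cache[[name]]
}

make_chain <- function(coords, chain_id = "A", index = NA_integer_) {
  coords <- as.matrix(coords)
  gnmhotspots:::new_ca_chain(
    chain_id = chain_id,
    residues = tibble::tibble(resno = seq_len(nrow(coords)), insert = "",
                              resid = "ALA"),
    coords = coords, index = index
  )
}

small_spec <- function() {
  synthetic_spec(n_chains = 8, length_range = c(60, 90), seed = 5)
}

small_data <- function() fixture("small_data", simulate_dataset(small_spec()))

small_chain <- function() small_data()$chain[[1]]

spectrum_at <- function(chain, cutoff = 7.0) {
  p <- gnm_params(cutoff = cutoff)
  gnm_modes(build_kirchhoff(chain, p), p)
}

# --- independent oracles ----------------------------------------------------

# O(N^2) double-loop Kirchhoff construction
kirchhoff_brute <- function(coords, cutoff) {
  n <- nrow(coords)
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
      g[i, j] <- -1
    }
  }
  diag(g) <- -rowSums(g)
  g
}

# connected components of the contact graph by breadth-first search
bfs_components <- function(gamma) {
  n <- nrow(gamma)
  adj <- gamma < 0
  seen <- logical(n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# term-by-term mode-weighted MSF (direct sum)
msf_brute <- function(spectrum, mode_ranks) {
  n <- spectrum$n
  cols <- n - mode_ranks + 1
  out <- numeric(n)
  denom <- sum(1 / spectrum$values[cols])
  for (i in seq_len(n)) {
    s <- 0
    for (k in cols) s <- s + spectrum$vectors[i, k]^2 / spectrum$values[k]
    out[i] <- s / denom
  }
  out
}

# per-class mean/population-variance by explicit loops
gnb_fit_brute <- function(x, y) {
  out <- list()
  for (cls in c(0, 1)) {
    rows <- which(y == cls)
    mu <- numeric(ncol(x))
    v <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
      mu[j] <- sum(x[rows, j]) / length(rows)
      v[j] <- sum((x[rows, j] - mu[j])^2) / length(rows)
    }
    out[[as.character(cls)]] <- list(mean = mu, var = v)
  }
  out
}

# linear-domain evaluation of the posterior numerators P(y) prod N(x_j)
gnb_predict_linear <- function(model, x) {
  apply(x, 1, function(row) {
    num <- vapply(c("0", "1"), function(cls) {
      model$prior[[cls]] *
        prod(stats::dnorm(row, model$mean[cls, ], sqrt(model$var[cls, ])))
    }, numeric(1))
    as.integer(num[["1"]] > num[["0"]])
  })
}
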