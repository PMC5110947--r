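test_that("Kirchhoff matrix matches closed forms and the double-loop oracle", {
  # two residues in contact
  two <- make_chain(rbind(c(0, 0, 0), c(5, 0, 0)))
  g2 <- build_kirchhoff(two, gnm_params(6.5))$matrix
  expect_equal(g2, rbind(c(1, -1), c(-1, 1)))

  # three collinear residues: 7.6 A pair beyond a 7.1 A cutoff
  three <- make_chain(cbind(c(0, 3.8, 7.6), 0, 0))
  g3 <- build_kirchhoff(three, gnm_params(7.1))$matrix
  expect_equal(diag(g3), c(1, 2, 1))
  expect_equal(g3[1, 3], 0)

  # boundary counts as contact
  gb <- build_kirchhoff(two, gnm_params(5.0))$matrix
  expect_equal(gb[1, 2], -1)

  # synthetic chain vs brute force at several cutoffs
  ch <- small_chain()
  for (rc in c(6.0, 7.0, 8.0)) {
    expect_equal(build_kirchhoff(ch, gnm_params(rc))$matrix,
                 kirchhoff_brute(ch$coords, rc))
  }
})

test_that("Kirchhoff invariants: zero row sums, PSD, contact monotonicity, rigid-motion invariance", {
  ch <- small_chain()
  g <- build_kirchhoff(ch, gnm_params(7.0))$matrix
  expect_equal(max(abs(rowSums(g))), 0)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))

  d_small <- diag(build_kirchhoff(ch, gnm_params(6.5))$matrix)
  d_large <- diag(build_kirchhoff(ch, gnm_params(7.5))$matrix)
  expect_true(all(d_large >= d_small))

  # rotate + translate: spectrum depends only on distances
  theta <- 0.83
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  moved <- make_chain(sweep(ch$coords %*% rot, 2, c(11, -4, 7), `+`))
  expect_equal(build_kirchhoff(moved, gnm_params(7.0))$matrix, g)
})

test_that("mode decomposition reproduces closed-form spectra and orthonormality", {
  two <- make_chain(rbind(c(0, 0, 0), c(5, 0, 0)))
  s2 <- spectrum_at(two, 6.5)
  expect_equal(s2$values, c(0, 2))
  expect_equal(abs(s2$vectors[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  # 3-node path graph: eigenvalues 0, 1, 3 from the characteristic polynomial
  three <- make_chain(cbind(c(0, 3.8, 7.6), 0, 0))
  s3 <- spectrum_at(three, 7.1)
  expect_equal(s3$values, c(0, 1, 3), tolerance = 1e-12)

  s <- spectrum_at(small_chain())
  u <- s$vectors
  expect_lt(max(abs(crossprod(u) - diag(s$n))), 1e-8)
  recon <- u %*% (s$values * t(u))
  g <- build_kirchhoff(small_chain(), gnm_params(7.0))$matrix
  expect_lt(max(abs(recon - g)) / max(abs(g)), 1e-8)
})

test_that("zero-mode count equals connected components found by BFS", {
  # compact chain: one component
  s <- spectrum_at(small_chain())
  g <- build_kirchhoff(small_chain(), gnm_params(7.0))$matrix
  expect_equal(s$n_zero, bfs_components(g))

  # two far-apart fragments: two components
  frag <- rbind(cbind(seq(0, by = 3.8, length.out = 6), 0, 0),
                cbind(seq(200, by = 3.8, length.out = 6), 0, 0))
  ch2 <- make_chain(frag)
  s2 <- spectrum_at(ch2, 7.0)
  g2 <- build_kirchhoff(ch2, gnm_params(7.0))$matrix
  expect_equal(bfs_components(g2), 2L)
  expect_equal(s2$n_zero, 2L)
})

test_that("eigenvector signs follow the largest-component-positive convention", {
  s <- spectrum_at(small_chain())
  for (j in seq_len(s$n)) {
    expect_gt(s$vectors[which.max(abs(s$vectors[, j])), j], 0)
  }
})

test_that("mode-weighted MSF matches the direct-sum oracle and its closed forms", {
  s <- spectrum_at(small_chain())
  # single fast mode: squared eigenvector components, summing to 1
  m1 <- msf_weighted(s, 1)
  expect_equal(m1, s$vectors[, s$n]^2)
  expect_equal(sum(m1), 1)
  for (k in c(2, 5, 10)) expect_equal(sum(msf_weighted(s, k)), 1)

  # multi-mode subsets match brute force term-by-term
  expect_equal(msf_weighted(s, 1:3), msf_brute(s, 1:3))
  expect_equal(msf_weighted(s, c(2, 7)), msf_brute(s, c(2, 7)))

  # equal eigenvalues weight both modes equally
  s_eq <- s
  cols <- c(s$n, s$n - 1)
  s_eq$values[cols] <- 4
  expect_equal(msf_weighted(s_eq, 1:2),
               rowMeans(s_eq$vectors[, cols]^2))

  # unnormalized form carries the scale c
  p2 <- gnm_params(cutoff = 7, scale = 2.5)
  s_sc <- gnm_modes(build_kirchhoff(small_chain(), p2), p2)
  expect_equal(msf_weighted(s_sc, 1:3, normalized = FALSE),
               2.5 * msf_weighted(s_sc, 1:3))

  expect_error(msf_weighted(s, s$n), "insufficient modes")
})

test_that("mode-subset correlation matrix reproduces the pseudo-inverse and rank-k sums", {
  ch <- small_chain()
  g <- build_kirchhoff(ch, gnm_params(7.0))$matrix
  s <- spectrum_at(ch)
  full <- correlation_matrix(s, seq_len(s$n - s$n_zero))
  # pseudo-inverse identity Gamma C Gamma = Gamma
  expect_lt(max(abs(g %*% full %*% g - g)), 1e-8)
  # diagonal equals the unnormalized MSF numerator
  sub <- correlation_matrix(s, 1:3)
  cols <- s$n - (1:3) + 1
  expect_equal(diag(sub),
               drop(s$vectors[, cols]^2 %*% (1 / s$values[cols])))
  # rank-2 subset equals the explicit outer-product sum
  ch8 <- generate_chain(synthetic_spec(n_chains = 1, length_range = c(20, 20),
                                       seed = 9), 1)
  s8 <- spectrum_at(ch8)
  c2 <- correlation_matrix(s8, 1:2)
  manual <- matrix(0, s8$n, s8$n)
  for (k in s8$n - (1:2) + 1) {
    manual <- manual + tcrossprod(s8$vectors[, k]) / s8$values[k]
  }
  expect_equal(c2, manual)
})

test_that("distance-fluctuation matrix is symmetric, zero-diagonal, non-negative and matches the single-mode closed form", {
  s <- spectrum_at(small_chain())
  d <- msdf_matrix(s, 1:4)
  expect_equal(diag(d), rep(0, s$n))
  expect_lt(max(abs(d - t(d))), 1e-12)
  expect_gte(min(d), -1e-12)

  d1 <- msdf_matrix(s, 1)
  u <- s$vectors[, s$n]
  lam <- s$values[s$n]
  expect_equal(d1, outer(u, u, function(a, b) (a - b)^2) / lam)
})
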