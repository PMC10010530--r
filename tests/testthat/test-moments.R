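test_that("empirical frequencies are indicator averages with exact margins", {
  set.seed(61)
  m <- matrix(sample.int(61, 40 * 4, replace = TRUE), 40, 4)
  f <- empirical_frequencies(round_sample(m, 2))
  expect_equal(rowSums(f$first), rep(1, 4), tolerance = 1e-12)
  expect_equal(colSums(f$second), rep(1, ncol(f$second)), tolerance = 1e-12)
  # single sequence: pure indicators
  f1 <- empirical_frequencies(round_sample(m[1, , drop = FALSE], 0))
  expect_true(all(f1$first %in% c(0, 1)))
  expect_equal(rowSums(f1$first), rep(1, 4))
  # marginal consistency: pair blocks marginalize to first-order rows
  expect_lt(check_local_consistency(f, tol = 1e-12), 1e-12)
  # hand count one entry
  expect_equal(f$first[2, 17], mean(m[, 2] == 17))
  blk <- matrix(f$second[, 1], 61, 61)
  expect_equal(blk[m[1, 1], m[1, 2]],
               mean(m[, 1] == m[1, 1] & m[, 2] == m[1, 2]))
})

test_that("round-0 moments are exact wild-type indicators", {
  wt <- c(3L, 45L, 61L)
  mv <- init_moments(wt)
  expect_true(all(mv$first %in% c(0, 1)))
  expect_equal(rowSums(mv$first), rep(1, 3))
  expect_identical(which(mv$first[2, ] == 1), 45L)
  expect_true(all(colSums(mv$second) == 1))
  blk <- matrix(mv$second[, 2], 61, 61)   # pair (1, 3)
  expect_identical(unname(which(blk == 1, arr.ind = TRUE)[1, ]),
                   c(3L, 61L))
})

test_that("identity kernel leaves moments unchanged; normalization is exact", {
  L <- 4
  mm <- build_mutation_model(read_bias_tsv(), 0, L)  # identity kernels
  set.seed(62)
  land_first <- matrix(rexp(L * 61), L, 61); land_first <- land_first / rowSums(land_first)
  pairs <- all_pairs(L)
  land_sec <- matrix(rexp(3721 * nrow(pairs)), 3721, nrow(pairs))
  land_sec <- land_sec / rep(colSums(land_sec), each = 3721)
  mu_land <- moment_vector(land_first, land_sec, pairs)
  p <- matrix(rexp(L * 61), L, 61); p <- p / rowSums(p)
  psec <- matrix(rexp(3721 * nrow(pairs)), 3721, nrow(pairs))
  psec <- psec / rep(colSums(psec), each = 3721)
  mu_r <- moment_vector(p, psec, pairs)
  out <- propagate_moments(mu_land, mu_r, mm)
  expect_equal(out$first, p, tolerance = 1e-12)
  expect_equal(out$second, psec, tolerance = 1e-12)
})

test_that("propagation preserves normalization to near machine precision", {
  L <- 5
  mm <- build_mutation_model(read_bias_tsv(), 3, L)
  set.seed(63)
  land <- matrix(rexp(L * 61), L, 61); land <- land / rowSums(land)
  pairs <- all_pairs(L)
  lsec <- matrix(rexp(3721 * nrow(pairs)), 3721, nrow(pairs))
  lsec <- lsec / rep(colSums(lsec), each = 3721)
  mu_land <- moment_vector(land, lsec, pairs)
  cur <- init_moments(c(1L, 12L, 25L, 40L, 58L))
  for (r in 1:4) {
    cur <- propagate_moments(mu_land, cur, mm)
    expect_lt(max(abs(rowSums(cur$first) - 1)), 1e-12)
    expect_lt(max(abs(colSums(cur$second) - 1)), 1e-12)
  }
})

test_that("first-order recursion is exact for independent-site landscapes", {
  # enumerable L = 2 space: recursive marginals vs exact chain propagation
  mm <- build_mutation_model(read_bias_tsv(), 0.8, 2)
  set.seed(64)
  h <- matrix(rnorm(40), 2, 20)
  land <- potts_model(h)
  states <- enumerate_states(2)
  K <- exact_kernel(mm, land, states)
  wt <- c(10L, 50L)
  p0 <- rep(0, nrow(states))
  p0[which(states[, 1] == wt[1] & states[, 2] == wt[2])] <- 1
  exact <- state_marginals(states, propagate_exact(K, p0, 4))
  ab <- codon_alphabet()
  mu <- matrix(0, 2, 61)
  for (i in 1:2) {
    w <- exp(h[i, ab$ac_map]); mu[i, ] <- w / sum(w)
  }
  cur <- init_moments(wt, second = FALSE)
  for (r in 1:4) {
    cur <- propagate_moments(moment_vector(mu), cur, mm)
    expect_lt(max(abs(cur$first - exact[[r + 1]])), 1e-10)
  }
})

test_that("with couplings the recursion converges toward a fixed point", {
  L <- 3
  mm <- build_mutation_model(read_bias_tsv(), 2, L)
  set.seed(65)
  land <- matrix(rexp(L * 61), L, 61); land <- land / rowSums(land)
  pairs <- all_pairs(L)
  lsec <- matrix(rexp(3721 * nrow(pairs)), 3721, nrow(pairs))
  lsec <- lsec / rep(colSums(lsec), each = 3721)
  mu_land <- moment_vector(land, lsec, pairs)
  cur <- init_moments(c(2L, 30L, 59L))
  deltas <- numeric(0)
  for (r in 1:25) {
    nxt <- propagate_moments(mu_land, cur, mm)
    deltas <- c(deltas, max(abs(nxt$first - cur$first)))
    cur <- nxt
  }
  expect_lt(deltas[25], deltas[1] / 10)
  expect_lt(deltas[25], 0.01)
})

test_that("zero landscape mass on a populated codon raises a named error", {
  L <- 2
  mm <- build_mutation_model(read_bias_tsv(), 0, L)  # identity kernel
  land <- matrix(0, L, 61); land[, 1] <- 1           # all mass on codon 1
  cur <- init_moments(c(5L, 5L), second = FALSE)     # population elsewhere
  expect_error(propagate_moments(moment_vector(land), cur, mm),
               "zero denominator")
})
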