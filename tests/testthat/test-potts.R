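test_that("scores match explicit summation and are linear in parameters", {
  L <- 6
  model <- random_dense_potts(L, seed = 2)
  zero <- potts_model(matrix(0, L, 20))
  set.seed(8)
  for (rep in 1:10) {
    aa <- sample.int(20, L, replace = TRUE)
    expect_equal(score_sequences(model, aa), oracle_score(model, aa))
    expect_equal(score_sequences(zero, aa), 0)
  }
  # L = 1: score is the field
  m1 <- potts_model(matrix(1:20, 1, 20) * 1.0)
  expect_equal(score_sequences(m1, 7L), 7)
  # linearity: score under summed parameters = sum of scores
  m2 <- random_dense_potts(L, seed = 3)
  msum <- potts_model(model$h + m2$h, model$pairs, model$blocks + m2$blocks)
  aa <- sample.int(20, L, replace = TRUE)
  expect_equal(score_sequences(msum, aa),
               score_sequences(model, aa) + score_sequences(m2, aa),
               tolerance = 1e-12)
})

test_that("score differences are invariant under gauge transformations", {
  L <- 5
  model <- random_dense_potts(L, seed = 4)
  set.seed(10)
  # per-site constants on h, plus a shift of u_i(a) between h_i and e_ij
  h2 <- model$h + rep(rnorm(L, 0, 3), 20)
  blocks2 <- model$blocks
  u <- rnorm(20, 0, 2)
  p <- 1L  # pair (1, 2)
  blocks2[, , p] <- blocks2[, , p] + outer(u, rep(1, 20))
  h2[model$pairs[p, 1], ] <- h2[model$pairs[p, 1], ] - u
  gauged <- potts_model(h2, model$pairs, blocks2)
  aa1 <- sample.int(20, L, replace = TRUE)
  aa2 <- sample.int(20, L, replace = TRUE)
  d1 <- score_sequences(model, aa1) - score_sequences(model, aa2)
  d2 <- score_sequences(gauged, aa1) - score_sequences(gauged, aa2)
  expect_equal(d1, d2, tolerance = 1e-9 * max(1, abs(d1)))
})

test_that("mutation effect map equals direct rescoring of single mutants", {
  L <- 5
  model <- random_dense_potts(L, seed = 6)
  set.seed(12)
  wt <- sample.int(20, L, replace = TRUE)
  mem <- mutation_effect_map(model, wt)
  expect_equal(unname(mem[cbind(seq_len(L), wt)]), rep(0, L))
  s0 <- score_sequences(model, wt)
  for (i in seq_len(L)) for (a in 1:20) {
    mut <- wt; mut[i] <- a
    expect_equal(unname(mem[i, a]), score_sequences(model, mut) - s0,
                 tolerance = 1e-10)
  }
  # coupling-free model: effects reduce to field differences
  add <- potts_model(model$h)
  mem2 <- mutation_effect_map(add, wt)
  expect_equal(unname(mem2),
               unname(model$h - model$h[cbind(seq_len(L), wt)]),
               tolerance = 1e-12)
})

test_that("zero-sum gauge zeroes block margins, is idempotent, preserves scores", {
  L <- 5
  model <- random_dense_potts(L, seed = 7)
  g <- zero_sum_gauge(model)
  for (p in seq_len(nrow(g$pairs))) {
    blk <- g$blocks[, , p]
    expect_lt(max(abs(rowSums(blk))), 1e-10)
    expect_lt(max(abs(colSums(blk))), 1e-10)
  }
  g2 <- zero_sum_gauge(g)
  expect_equal(g2$blocks, g$blocks, tolerance = 1e-12)
  # absorbing the removed means preserves every score exactly
  set.seed(13)
  for (rep in 1:10) {
    aa <- sample.int(20, L, replace = TRUE)
    expect_equal(score_sequences(g, aa), score_sequences(model, aa),
                 tolerance = 1e-10)
  }
})

test_that("Frobenius interaction scores match brute-force norms and rankings", {
  L <- 12
  zero <- potts_model(matrix(0, L, 20))
  sc0 <- interaction_scores(zero)
  expect_true(all(sc0$F == 0))
  # planted single long-range block tops the ranking
  blk <- array(rnorm(400, 0, 2), c(20, 20, 1))
  planted <- potts_model(matrix(0, L, 20), cbind(2L, 11L), blk)
  sc <- interaction_scores(planted)
  top <- top_interactions(sc)
  expect_identical(c(top$i[1], top$j[1]), c(2L, 11L))
  expect_true(all(top$F[-1] == 0))
  # brute-force norm of a hand-gauged 2-residue block
  m2 <- potts_model(matrix(0, 8, 20), cbind(1L, 8L),
                    array(rnorm(400), c(20, 20, 1)))
  gb <- zero_sum_gauge(m2, absorb = FALSE)$blocks[, , 1]
  fr <- 0
  for (a in 1:20) for (b in 1:20) fr <- fr + gb[a, b]^2
  expect_equal(interaction_scores(m2)$F[1, 8], sqrt(fr), tolerance = 1e-12)
  # short-range pairs are excluded from rankings
  short <- potts_model(matrix(0, L, 20), cbind(3L, 6L),
                       array(1, c(20, 20, 1)))
  expect_identical(nrow(top_interactions(interaction_scores(short))[
    top_interactions(interaction_scores(short))$F > 0, ]), 0L)
})

test_that("interaction scores are invariant under gauge perturbations", {
  L <- 6
  model <- random_dense_potts(L, seed = 21)
  F1 <- interaction_scores(model)$F
  set.seed(22)
  h2 <- model$h + rep(rnorm(L, 0, 5), 20)
  blocks2 <- model$blocks
  for (p in seq_len(nrow(model$pairs))) {
    u <- rnorm(20); v <- rnorm(20)
    blocks2[, , p] <- blocks2[, , p] + outer(u, rep(1, 20)) +
      outer(rep(1, 20), v)
    h2[model$pairs[p, 1], ] <- h2[model$pairs[p, 1], ] - u
    h2[model$pairs[p, 2], ] <- h2[model$pairs[p, 2], ] - v
  }
  F2 <- interaction_scores(potts_model(h2, model$pairs, blocks2))$F
  expect_equal(F1, F2, tolerance = 1e-9)
})

test_that("Potts JSON serialization round-trips", {
  model <- random_dense_potts(4, seed = 30)
  path <- tempfile(fileext = ".json")
  write_potts(model, path)
  back <- read_potts(path)
  expect_equal(back$h, model$h)
  expect_identical(back$pairs, model$pairs)
  expect_equal(back$blocks, model$blocks)
  add <- potts_model(matrix(rnorm(40), 2, 20))
  write_potts(add, path)
  expect_equal(read_potts(path)$h, add$h)
})
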