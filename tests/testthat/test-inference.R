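test_that("gamma-to-marginal map is normalized, uniform at zero, synonymous-uniform", {
  L <- 4
  g <- gamma_params(matrix(0, L, 20), matrix(0, 400, choose(L, 2)))
  marg <- gamma_to_marginals(g)
  expect_equal(marg$nu_first, matrix(1 / 20, L, 20))
  expect_equal(marg$mu_first, matrix(1 / 61, L, 61), tolerance = 1e-14)
  expect_equal(marg$nu_second, matrix(1 / 400, 400, choose(L, 2)))
  expect_equal(marg$mu_second, matrix(1 / 3721, 3721, choose(L, 2)),
               tolerance = 1e-14)
  # random gamma: blocks stay normalized and synonymous codons get equal mass
  set.seed(71)
  g2 <- gamma_params(matrix(rnorm(L * 20), L, 20),
                     matrix(rnorm(400 * choose(L, 2)), 400, choose(L, 2)))
  m2 <- gamma_to_marginals(g2)
  expect_equal(rowSums(m2$nu_first), rep(1, L), tolerance = 1e-12)
  expect_equal(rowSums(m2$mu_first), rep(1, L), tolerance = 1e-12)
  expect_equal(colSums(m2$mu_second), rep(1, choose(L, 2)), tolerance = 1e-12)
  ab <- codon_alphabet()
  syn <- which(ab$ac_map == ab$ac_map[1])  # codons synonymous with codon 1
  expect_true(all(abs(m2$mu_first[, syn] - m2$mu_first[, syn[1]]) < 1e-14))
})

test_that("penalty and regularizers vanish where they should", {
  L <- 3
  fx <- tiny_trajectory(L)
  cfg <- inference_config()
  # consistent pair marginals: products of the site marginals
  set.seed(72)
  nu1 <- matrix(rexp(L * 20), L, 20); nu1 <- nu1 / rowSums(nu1)
  pairs <- all_pairs(L)
  nu2 <- vapply(seq_len(nrow(pairs)), function(p)
    as.vector(outer(nu1[pairs[p, 1], ], nu1[pairs[p, 2], ])),
    numeric(400))
  res <- evoscape:::.penalty_residual(nu1, nu2, pairs)
  expect_lt(max(abs(res)), 1e-12)
  # R_main = R_int = 0 at gamma = 0
  g0 <- gamma_params(matrix(0, L, 20), matrix(0, 400, nrow(pairs)))
  out <- trajectory_loss(g0, fx$freqs, fx$mm, fx$wt, cfg, gradient = FALSE)
  expect_equal(unname(out$pieces["r_main"]), 0)
  expect_equal(unname(out$pieces["r_int"]), 0)
})

test_that("analytic gradient matches central finite differences (L = 3)", {
  fx <- tiny_trajectory(3)
  cfg <- inference_config()
  set.seed(73)
  g <- gamma_params(matrix(rnorm(3 * 20, 0, 0.5), 3, 20),
                    matrix(rnorm(400 * 3, 0, 0.5), 400, 3))
  res <- trajectory_loss(g, fx$freqs, fx$mm, fx$wt, cfg)
  eps <- 1e-5
  for (block in c("first", "second")) {
    idx <- sample(length(g[[block]]), 12)
    for (k in idx) {
      gp <- g; gp[[block]][k] <- gp[[block]][k] + eps
      gm <- g; gm[[block]][k] <- gm[[block]][k] - eps
      fd <- (trajectory_loss(gp, fx$freqs, fx$mm, fx$wt, cfg,
                             gradient = FALSE)$loss -
             trajectory_loss(gm, fx$freqs, fx$mm, fx$wt, cfg,
                             gradient = FALSE)$loss) / (2 * eps)
      an <- res$grad[[block]][k]
      expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("fitting is deterministic and decreases the loss", {
  fx <- tiny_trajectory(3)
  cfg <- inference_config(max_steps = 40)
  f1 <- fit_mean_parameters(fx$freqs, fx$mm, fx$wt, cfg)
  f2 <- fit_mean_parameters(fx$freqs, fx$mm, fx$wt, cfg)
  expect_identical(f1$gamma, f2$gamma)
  expect_lt(f1$loss_trace[length(f1$loss_trace)], f1$initial_loss)
  expect_true(all(is.finite(f1$loss_trace)))
})

test_that("independent-site landscapes are recovered from simulated data", {
  # planted fields only; first-order fit; compare fitted codon marginals
  # to the planted landscape marginals
  L <- 10
  set.seed(74)
  h <- matrix(rnorm(L * 20, 0, 1), L, 20)
  land <- potts_model(h)
  mm <- build_mutation_model(read_bias_tsv(), 4, L)
  wt <- vapply(max.col(h), function(a) which(ALPHABET$ac_map == a)[1],
               integer(1))
  ds <- simulate_trajectory(wt, mm, land, rounds = 5, pop_size = 2000,
                            brood = 50, sample_sizes = 2000, seed = 74)
  fit <- fit_mean_parameters(ds, mm, config = inference_config(),
                             pairwise = FALSE)
  ab <- codon_alphabet()
  mu_true <- t(vapply(seq_len(L), function(i) {
    w <- exp(h[i, ab$ac_map]); w / sum(w)
  }, numeric(61)))
  r <- cor(as.vector(fit$marginals$mu_first), as.vector(mu_true))
  expect_gte(r, 0.9)
})

test_that("mean-field inversion: independent marginals give zero couplings", {
  L <- 5
  set.seed(75)
  nu1 <- matrix(rexp(L * 20), L, 20); nu1 <- nu1 / rowSums(nu1)
  pairs <- all_pairs(L)
  nu2 <- vapply(seq_len(nrow(pairs)), function(p)
    as.vector(outer(nu1[pairs[p, 1], ], nu1[pairs[p, 2], ])),
    numeric(400))
  model <- invert_to_canonical(list(nu_first = nu1, nu_second = nu2,
                                    pairs = pairs), lambda_reg = 1)
  expect_equal(dim(model$h), c(L, 20))
  expect_identical(nrow(model$pairs), nrow(pairs))
  expect_lt(max(abs(model$blocks)), 1e-8)
})

test_that("inversion recovers the coupled pair of an enumerable Potts model", {
  # L = 3 over the full amino-acid alphabet, one coupled pair (1, 3);
  # marginals computed exactly by enumerating all 20^3 sequences
  L <- 3
  set.seed(76)
  h <- matrix(rnorm(L * 20, 0, 0.3), L, 20)
  blk <- array(rnorm(400, 0, 1.2), c(20, 20, 1))
  model <- potts_model(h, cbind(1L, 3L), blk)
  grid <- as.matrix(expand.grid(a1 = 1:20, a2 = 1:20, a3 = 1:20))
  en <- exp(h[1, grid[, 1]] + h[2, grid[, 2]] + h[3, grid[, 3]] +
              blk[cbind(grid[, 1], grid[, 3], 1)])
  pr <- en / sum(en)
  nu1 <- t(vapply(1:L, function(i)
    vapply(1:20, function(a) sum(pr[grid[, i] == a]), numeric(1)),
    numeric(20)))
  pairs <- all_pairs(L)
  nu2 <- vapply(seq_len(nrow(pairs)), function(p) {
    out <- matrix(0, 20, 20)
    for (a in 1:20) for (b in 1:20)
      out[a, b] <- sum(pr[grid[, pairs[p, 1]] == a & grid[, pairs[p, 2]] == b])
    as.vector(out)
  }, numeric(400))
  inv <- invert_to_canonical(list(nu_first = nu1, nu_second = nu2,
                                  pairs = pairs), lambda_reg = 0.5)
  fn <- apply(zero_sum_gauge(inv, absorb = FALSE)$blocks^2, 3, sum)
  expect_identical(unname(which.max(fn)), 2L)  # pair (1, 3) in combn order
})

test_that("degenerate inputs raise informative errors", {
  fx <- tiny_trajectory(3)
  expect_error(fit_mean_parameters(list(), fx$mm, fx$wt), "no sequenced")
  cfg <- inference_config(learning_rate = 1e6, max_steps = 10)
  expect_error(fit_mean_parameters(fx$freqs, fx$mm, fx$wt, cfg),
               "divergent|zero denominator")
})
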