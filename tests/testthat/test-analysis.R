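test_that("walks from a local peak are empty; scores strictly increase", {
  L <- 6
  set.seed(81)
  h <- matrix(rnorm(L * 20), L, 20)
  add <- potts_model(h)
  peak <- max.col(h, ties.method = "first")
  w <- adaptive_walk(add, peak)
  expect_identical(length(w$scores), 0L)
  expect_identical(w$endpoint, peak)
  start <- sample.int(20, L, replace = TRUE)
  w2 <- adaptive_walk(add, start)
  expect_true(all(diff(c(w2$start_score, w2$scores)) > 0))
  expect_true(is_local_peak(add, w2$endpoint))
})

test_that("additive landscapes converge to the per-site argmax within L steps", {
  L <- 12
  set.seed(82)
  h <- matrix(rnorm(L * 20), L, 20)
  add <- potts_model(h)
  peak <- max.col(h, ties.method = "first")
  for (k in 1:100) {
    start <- sample.int(20, L, replace = TRUE)
    w <- adaptive_walk(add, start)
    expect_identical(w$endpoint, peak)
    expect_lte(length(w$scores), L)
  }
})

test_that("endpoints are locally optimal by exhaustive neighborhood re-check", {
  model <- random_dense_potts(8, seed = 83, coupling_sd = 0.4)
  set.seed(84)
  for (k in 1:5) {
    start <- sample.int(20, 8, replace = TRUE)
    w <- adaptive_walk(model, start)
    # oracle re-check: rescore every single mutant of the endpoint
    s_end <- oracle_score(model, w$endpoint)
    for (i in 1:8) for (a in setdiff(1:20, w$endpoint[i])) {
      mut <- w$endpoint; mut[i] <- a
      expect_lte(oracle_score(model, mut), s_end + 1e-10)
    }
  }
})

test_that("single+double move selection matches brute-force enumeration", {
  model <- random_dense_potts(6, seed = 85, coupling_sd = 0.8)
  set.seed(86)
  for (k in 1:4) {
    cur <- sample.int(20, 6, replace = TRUE)
    w <- adaptive_walk(model, cur, moves = "single+double", max_steps = 1)
    # oracle: enumerate all single and double mutants
    s0 <- oracle_score(model, cur)
    best <- 0
    for (i in 1:6) for (a in setdiff(1:20, cur[i])) {
      mut <- cur; mut[i] <- a
      best <- max(best, oracle_score(model, mut) - s0)
      for (j in seq_len(6)[-seq_len(i)]) for (b in setdiff(1:20, cur[j])) {
        mut2 <- mut; mut2[j] <- b
        best <- max(best, oracle_score(model, mut2) - s0)
      }
    }
    gain <- if (length(w$scores)) w$scores[1] - w$start_score else 0
    expect_equal(gain, best, tolerance = 1e-10)
  }
})

test_that("double-mutant walks also terminate at double-mutant-optimal points", {
  model <- random_dense_potts(5, seed = 87, coupling_sd = 0.6)
  w <- adaptive_walk(model, rep(1L, 5), moves = "single+double")
  s_end <- oracle_score(model, w$endpoint)
  for (i in 1:5) for (a in setdiff(1:20, w$endpoint[i]))
    for (j in seq_len(5)[-seq_len(i)]) for (b in setdiff(1:20, w$endpoint[j])) {
      mut <- w$endpoint; mut[i] <- a; mut[j] <- b
      expect_lte(oracle_score(model, mut), s_end + 1e-10)
    }
})

test_that("convergence survey matches exhaustive basin enumeration", {
  # two-peak landscape: amino acids 1 and 2 are good, all others terrible;
  # the coupling makes (1,1) and (2,2) the only local optima
  h <- matrix(-10, 2, 20); h[, 1] <- 1; h[, 2] <- 1.5
  blk <- array(0, c(20, 20, 1))
  blk[1, 1, 1] <- 3; blk[2, 2, 1] <- 2.4
  model <- potts_model(h, cbind(1L, 2L), blk)
  sv <- convergence_survey(model, n_starts = 200, seed = 88,
                           reference = c(1L, 1L))
  expect_identical(nrow(sv), 2L)
  expect_identical(sum(sv$basin), 200L)
  # oracle: greedy walks re-implemented as a plain loop over all 400 starts
  basins <- c()
  for (a in 1:20) for (b in 1:20) {
    cur <- c(a, b)
    repeat {
      s0 <- oracle_score(model, cur)
      cand <- list()
      for (i in 1:2) for (x in setdiff(1:20, cur[i])) {
        mut <- cur; mut[i] <- x
        cand[[length(cand) + 1]] <- list(mut = mut,
                                         gain = oracle_score(model, mut) - s0)
      }
      gains <- vapply(cand, `[[`, numeric(1), "gain")
      if (max(gains) <= 0) break
      cur <- cand[[which.max(gains)]]$mut
    }
    basins <- c(basins, paste(cur, collapse = "-"))
  }
  oracle_endpoints <- sort(unique(basins))
  got <- sort(vapply(sv$endpoint, function(e) paste(aa_index(e), collapse = "-"), ""))
  expect_identical(unname(got), oracle_endpoints)
  # deterministic given the seed
  sv2 <- convergence_survey(model, n_starts = 200, seed = 88,
                            reference = c(1L, 1L))
  expect_identical(sv, sv2)
})

test_that("contact PPV is exact for oracle scores and monotone in threshold", {
  L <- 40
  set.seed(89)
  pairs_all <- all_pairs(L)
  long <- pairs_all[pairs_all[, 2] - pairs_all[, 1] > 5, ]
  ctrue <- long[sample.int(nrow(long), 30), ]
  cmap <- contact_map(ctrue[, 1], ctrue[, 2], rep(4, 30))
  # oracle scores: F = 1 exactly on the true contacts
  F <- matrix(0, L, L)
  F[ctrue] <- 1; F[ctrue[, 2:1]] <- 1
  sc <- structure(list(F = F, long_range = abs(row(F) - col(F)) > 5,
                       min_separation = 5), class = "interaction_scores")
  ppv <- contact_ppv(sc, cmap, top_k = 20)
  expect_equal(ppv$ppv, c(1, 1))
  # default top_k is floor(L/2)
  ppv2 <- contact_ppv(sc, cmap)
  expect_equal(unique(ppv2$top_k), 20)
  # monotone: stricter thresholds cannot raise PPV
  set.seed(90)
  Fr <- matrix(0, L, L); Fr[upper.tri(Fr)] <- runif(sum(upper.tri(Fr)))
  Fr <- Fr + t(Fr)
  scr <- structure(list(F = Fr, long_range = abs(row(F) - col(F)) > 5,
                        min_separation = 5), class = "interaction_scores")
  dists <- runif(nrow(long), 2, 12)
  cmap2 <- contact_map(long[, 1], long[, 2], dists)
  ppv3 <- contact_ppv(scr, cmap2, thresholds = c(3, 5, 8, 11))
  expect_true(all(diff(ppv3$ppv) >= 0))
  expect_true(all(diff(ppv3$baseline) >= 0))
})

test_that("random scores achieve baseline PPV on average (permutation oracle)", {
  L <- 30
  set.seed(91)
  pairs_all <- all_pairs(L)
  long <- pairs_all[pairs_all[, 2] - pairs_all[, 1] > 5, ]
  n_contact <- 40
  ctrue <- long[sample.int(nrow(long), n_contact), ]
  cmap <- contact_map(ctrue[, 1], ctrue[, 2], rep(4, n_contact))
  top_k <- 15
  hits <- numeric(1000)
  for (s in 1:1000) {
    F <- matrix(0, L, L)
    v <- sample(nrow(long))              # random ranking = score shuffle
    F[long] <- v; F[long[, 2:1]] <- v
    sc <- structure(list(F = F, long_range = abs(row(F) - col(F)) > 5,
                         min_separation = 5), class = "interaction_scores")
    hits[s] <- contact_ppv(sc, cmap, thresholds = 5, top_k = top_k)$ppv
  }
  base <- n_contact / nrow(long)
  # hypergeometric standard error of the mean of 1000 shuffles
  se <- sqrt(base * (1 - base) / top_k *
               (nrow(long) - top_k) / (nrow(long) - 1) / 1000)
  expect_lt(abs(mean(hits) - base), 3 * se)
})

test_that("walk export round-trips through FASTA and the score trace", {
  model <- random_dense_potts(5, seed = 92)
  w <- adaptive_walk(model, rep(3L, 5))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_walk(w, fa, tsv)
  aa <- as.character(Biostrings::readAAStringSet(fa))
  expect_identical(length(aa), length(w$scores) + 1L)
  expect_identical(unname(aa[length(aa)]),
                   paste0(ALPHABET$amino_acids[w$endpoint], collapse = ""))
  tr <- utils::read.delim(tsv)
  expect_equal(tr$score, w$scores)
})
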