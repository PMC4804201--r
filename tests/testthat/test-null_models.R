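test_that("null envelopes use type-7 quantiles and consistent verdicts", {
  e <- null_envelope(5, 1:100)
  expect_equal(e$q_low, unname(quantile(1:100, 0.025, type = 7)))
  expect_equal(e$q_high, unname(quantile(1:100, 0.975, type = 7)))
  expect_equal(e$verdict, "within")
  expect_equal(null_envelope(0, 1:100)$verdict, "below")
  expect_equal(null_envelope(200, 1:100)$verdict, "above")
})

test_that("a single individual gives a degenerate richness null", {
  ds <- census_of(c(1L, 0L, 0L))
  env <- suppressWarnings(
    randomize_individuals_null(ds, "P", n_reps = 50, seed = 1))
  expect_true(all(env$richness$null_draws == 1))
  expect_equal(env$richness$verdict, "within")
})

test_that("clustering on one species is detected against uniform placement", {
  ds <- census_of(c(200L, rep(0L, 19)), n_species = 20)
  env <- randomize_individuals_null(ds, "P", n_reps = 500, seed = 2)
  expect_equal(env$richness$observed, 1)
  expect_equal(env$richness$verdict, "below")
  expect_gt(env$richness$q_low, 1)
  # PD and FD of a single species are below the null band too
  expect_equal(env$pd$verdict, "below")
  expect_equal(env$fd$verdict, "below")
})

test_that("individual randomization is seed-reproducible", {
  ds <- census_of(c(5L, 3L, 0L, 2L, 0L))
  a <- randomize_individuals_null(ds, "P", n_reps = 200, seed = 9)
  b <- randomize_individuals_null(ds, "P", n_reps = 200, seed = 9)
  c_ <- randomize_individuals_null(ds, "P", n_reps = 200, seed = 10)
  expect_identical(a$pd$null_draws, b$pd$null_draws)
  expect_false(identical(a$pd$null_draws, c_$pd$null_draws))
  expect_warning(randomize_individuals_null(ds, "P", n_reps = 50, seed = 1),
                 "n_reps")
})

test_that("tip shuffling draws lie in the enumerated permutation set", {
  phy <- ape::read.tree(text = "((a:1,b:2):1,c:3);")
  comm <- matrix(c(4, 1, 0, 2, 1, 3), 2, 3,
                 dimnames = list(c("k1", "k2"), c("a", "b", "c")))
  env <- tip_shuffle_test(comm, phy, n_runs = 300, seed = 3)
  # oracle: enumerate all 6 tip-label permutations directly
  S <- schoener_matrix(comm); s <- S[upper.tri(S)]
  D <- cophenetic(phy)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  support <- sapply(perms, function(p) {
    Dp <- D[p, p]
    cor(s, Dp[upper.tri(Dp)])
  })
  expect_true(all(vapply(env$null_draws, function(v)
    any(abs(v - support) < 1e-12), TRUE)))
  expect_lte(length(unique(round(env$null_draws, 12))), 6)
  # label-only: the observed correlation is the identity permutation's value
  expect_equal(env$observed, support[1])
})

test_that("frequency-preserving shuffle conserves totals and occurrences", {
  comm <- matrix(c(3, 0, 0,
                   1, 2, 0,
                   5, 4, 1), 3, 3,
                 dimnames = list(paste0("k", 1:3), paste0("s", 1:3)))
  sh <- frequency_preserving_shuffle(comm, seed = 4)
  expect_equal(colSums(sh), colSums(comm))
  expect_equal(colSums(sh > 0), colSums(comm > 0))
  expect_true(all(sort(sh[, 1]) == sort(comm[, 1])))

  # uniformity over the 3 placements of a (3,0,0) column
  pos <- vapply(1:3000, function(i)
    which(frequency_preserving_shuffle(comm, seed = 10000 + i)[, 1] > 0), 0L)
  expect_gt(stats::chisq.test(table(pos))$p.value, 0.001)
})

test_that("pooled-row psd null degenerates when shuffles cannot move species", {
  phy <- simulate_phylogeny(3, "yule", seed = 5, labels = paste0("s", 1:3))
  comm <- matrix(c(3, 0, 1, 2, 0, 4), 2, 3,
                 dimnames = list(c("k1", "k2"), paste0("s", 1:3)))
  res <- psd_null_test(comm, phy, n_reps = 100, seed = 6)
  for (m in c("psv", "psr", "pse", "psc")) {
    e <- res$all[[m]]
    expect_equal(e$q_low, e$observed)
    expect_equal(e$q_high, e$observed)
    expect_equal(e$verdict, "within")
    expect_equal(attr(e, "structure"), "Random")
  }
})

test_that("grouped psd null matches the enumerated two-point support", {
  phy <- simulate_phylogeny(3, "yule", seed = 8, labels = c("A", "B", "C"))
  # columns B and C constant across samples; only A (one nonzero) can move
  comm <- matrix(c(5, 0, 0, 0,
                   1, 1, 1, 1,
                   2, 2, 2, 2), 4, 3,
                 dimnames = list(paste0("k", 1:4), c("A", "B", "C")))
  pool <- c("g1", "g1", "g2", "g2")
  res <- psd_null_test(comm, phy, pool = pool, n_reps = 400, seed = 9)
  ps <- phylo_structure(phy)
  v_with <- epihost:::psd_metrics_from_structure(
    c(A = 5, B = 2, C = 4), ps$C)[["psv"]]
  v_without <- epihost:::psd_metrics_from_structure(
    c(B = 2, C = 4), ps$C)[["psv"]]
  draws <- res$g1$psv$null_draws
  expect_true(all(abs(draws - v_with) < 1e-12 | abs(draws - v_without) < 1e-12))
  # A sits in g1 with probability 1/2 under the shuffle
  frac <- mean(abs(draws - v_with) < 1e-12)
  expect_gt(frac, 0.38); expect_lt(frac, 0.62)
  expect_equal(res$g1$psv$observed, v_with)
})

test_that("overdispersion labelling follows the envelope position", {
  e <- null_envelope(3.585, c(2.1, 2.3, 2.6, 2.9, 3.0))
  expect_equal(e$verdict, "above")
  expect_equal(epihost:::psd_structure_label(e$verdict), "Overdispersed")
  expect_equal(epihost:::psd_structure_label("below"), "Clustered")
  expect_equal(epihost:::psd_structure_label("within"), "Random")
})
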