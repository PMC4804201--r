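# minimal multi-patch census with prescribed per-tree counts
patch_census <- function(counts_by_patch, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in names(counts_by_patch)) {
    k <- counts_by_patch[[p]]
    for (i in seq_along(k)) {
      trunk <- rbinom(1, k[i], 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = sprintf("%s_t%d", p, i), patch = p,
        plot = paste0(p, "_p", 1 + (i - 1) %/% 5),
        species = c("A", "B")[1 + i %% 2], dbh = 20, height = 6, lai = 1,
        e1_trunk = trunk, e1_branch = k[i] - trunk)
    }
  }
  epihost:::build_dataset(do.call(rbind, rows), toy_traits(), toy_phylo())
}

test_that("identical patches give a zero chi-square and one letter group", {
  ds <- patch_census(list(P1 = rep(4L, 10), P2 = rep(4L, 10)))
  res <- patch_comparison(ds, "abund")
  expect_equal(res$chi2, 0, tolerance = 1e-10)
  expect_equal(unname(res$letters["P1"]), unname(res$letters["P2"]))
})

test_that("separated patches get distinct letters", {
  ds <- patch_census(list(P1 = rep(0L, 10), P2 = rep(10L, 10)))
  res <- patch_comparison(ds, "abund")
  expect_lt(res$p, 0.001)
  expect_false(res$letters["P1"] == res$letters["P2"])
})

test_that("a hyperabundant patch stands alone in the letter display", {
  means <- c(EP = 1, TP = 400, PP = 30, RP = 2, SF = 2)
  counts <- lapply(means, function(m) rpois(15, m))
  ds <- patch_census(counts, seed = 5)
  res <- patch_comparison(ds, "abund")
  expect_equal(res$df, 4)
  tp_letter <- res$letters["TP"]
  expect_false(any(vapply(res$letters[names(res$letters) != "TP"],
                          function(l) grepl(tp_letter, l), TRUE)))
  # Holm adjustment is monotone in the raw p-values
  pw <- res$pairwise[order(res$pairwise$p), ]
  expect_true(all(diff(pw$p_adj) >= -1e-15))
})

test_that("diversity regressions recover exact linear signal", {
  d <- data.frame(ab_abund = 2 * (1:10), richness = 1:10,
                  pd = rnorm(10), fd = rnorm(10))
  # anova.lm warns on an exact fit; the warning is the expected behaviour
  res <- suppressWarnings(diversity_regressions(d, "ab_abund"))
  expect_equal(res$slope[res$predictor == "richness"], 2, tolerance = 1e-10)
  expect_lt(res$p[res$predictor == "richness"], 1e-10)
  dc <- d; dc$pd <- 1
  expect_error(suppressWarnings(diversity_regressions(dc, "ab_abund")),
               "constant")
})

test_that("regression F-tests are calibrated under independence", {
  set.seed(8)
  p <- replicate(400, {
    d <- data.frame(ab_abund = rnorm(12), richness = rnorm(12),
                    pd = rnorm(12), fd = rnorm(12))
    diversity_regressions(d, "ab_abund", "richness")$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("pattern PCA reduces a single axis of variation exactly", {
  asg <- data.frame(tree_id = paste0("t", 1:20),
                    best = rep(c(TRUE, FALSE), 10),
                    worst = rep(c(FALSE, TRUE), 10),
                    trunk = FALSE, branches = FALSE)
  pc <- pattern_pca(asg)
  expect_equal(pc$pct_variance, 100)
  expect_lt(pc$loadings["best"], 0)

  # eigen-decomposition oracle for the variance share
  set.seed(9)
  asg2 <- data.frame(tree_id = paste0("t", 1:50),
                     best = sample(c(TRUE, FALSE), 50, TRUE),
                     worst = sample(c(TRUE, FALSE), 50, TRUE),
                     trunk = sample(c(TRUE, FALSE), 50, TRUE),
                     branches = sample(c(TRUE, FALSE), 50, TRUE))
  pc2 <- pattern_pca(asg2)
  m <- as.matrix(asg2[, -1]) * 1
  ev <- eigen(stats::cov(m))$values
  expect_equal(pc2$pct_variance, 100 * ev[1] / sum(ev), tolerance = 1e-10)
  # reconstruction from all components reproduces the centered matrix
  pr <- prcomp(m)
  expect_equal(pr$x %*% t(pr$rotation), scale(m, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)
  const <- asg; const$best <- TRUE; const$worst <- FALSE
  expect_error(pattern_pca(const), "variation")
})

test_that("score GLMs recover generating slopes", {
  set.seed(10)
  n <- 500
  scores <- rnorm(n)
  y <- rpois(n, exp(1 + 0.8 * scores))
  res <- score_glm(y, scores, "poisson")
  expect_equal(res$slope, 0.8, tolerance = 0.1)
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-6)
  # binomial: trunk share increasing in score gives a positive slope
  tr <- rbinom(n, 20, plogis(0.9 * scores))
  res_b <- score_glm(cbind(tr, 20 - tr), scores, "binomial")
  expect_gt(res_b$slope, 0)
  expect_equal(score_glm(y, rep(1, n), "poisson")$chi2, 0, tolerance = 1e-8)
})

test_that("crosstab tests equal the hand-computed 2x2 LR chi-square", {
  # table (a, b, c, d) = (30, 5, 10, 55) for trunk x best
  asg <- data.frame(
    tree_id = paste0("t", 1:100),
    best = rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 5, 10, 55)),
    trunk = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 5, 10, 55)),
    worst = rep(c(TRUE, FALSE), 50), branches = rep(c(FALSE, TRUE), 50))
  res <- assignment_crosstab_tests(asg)
  row <- res[res$response == "trunk" & res$predictor == "best", ]
  O <- matrix(c(30, 10, 5, 55), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2_hand <- 2 * sum(O * log(O / E))
  expect_equal(row$chi2, chi2_hand, tolerance = 1e-8)
  expect_equal(row$df, 1L)
  expect_equal(row$direction, "likely")   # positive association

  # degenerate margin is untestable, not an error
  asg$worst <- FALSE
  res2 <- assignment_crosstab_tests(asg)
  expect_false(any(res2$testable[res2$predictor == "worst"]))
})

test_that("crosstab p-values are calibrated under independent assignments", {
  set.seed(11)
  p <- replicate(300, {
    asg <- data.frame(tree_id = paste0("t", 1:200),
                      best = sample(c(TRUE, FALSE), 200, TRUE),
                      worst = FALSE,
                      trunk = sample(c(TRUE, FALSE), 200, TRUE),
                      branches = FALSE)
    r <- assignment_crosstab_tests(asg)
    r$p[r$response == "trunk" & r$predictor == "best"]
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})
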