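test_that("trunk-share statistic covers its closed-form cases", {
  expect_equal(ab_dst(5, 10), 0.5)
  expect_equal(ab_dst(0, 7), 0)
  expect_equal(ab_dst(12, 12), 1)          # all individuals on the trunk
  expect_error(ab_dst(0, 0), "undefined")
  # trunk share and branch share always sum to one
  tr <- runif(20, 0, 1)
  tot <- ceiling(runif(20, 1, 50))
  trk <- floor(tr * tot)
  expect_equal(ab_dst(trk, tot) + (tot - trk) / tot, rep(1, 20))
})

test_that("Faith's PD matches brute-force root-path marking", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(faith_pd(c("a", "b"), star), 2)

  set.seed(11)
  phy <- ape::rtree(8)
  expect_equal(faith_pd(phy$tip.label, phy), sum(phy$edge.length))

  # independent oracle: union of each leaf's root path via ape::nodepath
  brute_pd <- function(set, phy) {
    root <- length(phy$tip.label) + 1L
    edges <- unique(do.call(rbind, lapply(match(set, phy$tip.label), function(tip) {
      np <- ape::nodepath(phy, root, tip)
      cbind(np[-length(np)], np[-1])
    })))
    sum(apply(edges, 1, function(e)
      phy$edge.length[which(phy$edge[, 1] == e[1] & phy$edge[, 2] == e[2])]))
  }
  for (i in 1:10) {
    set <- sample(phy$tip.label, 4)
    expect_equal(faith_pd(set, phy), brute_pd(set, phy), tolerance = 1e-12)
  }
  # monotone under set inclusion
  s3 <- sample(phy$tip.label, 3)
  expect_gte(faith_pd(c(s3, sample(setdiff(phy$tip.label, s3), 2)), phy),
             faith_pd(s3, phy))
  expect_error(faith_pd("nope", phy), "unknown taxon")
})

test_that("Gower dissimilarity handles mixed traits with equal weights", {
  tt <- as_trait_table(
    data.frame(a = c("x", "y"), b = c("u", "v"), c = c(TRUE, FALSE),
               d = c(0, 10), e = c("p", "q"), row.names = c("s1", "s2")),
    c(a = "categorical", b = "categorical", c = "binary",
      d = "quantitative", e = "categorical"))
  expect_equal(as.matrix(gower_dissimilarity(tt))["s1", "s2"], 1)

  t2 <- as_trait_table(
    data.frame(a = c("x", "y"), b = c("u", "v"), c = c(TRUE, TRUE),
               d = c(5, 5), row.names = c("s1", "s2")),
    c(a = "categorical", b = "categorical", c = "binary", d = "quantitative"))
  expect_equal(as.matrix(gower_dissimilarity(t2))["s1", "s2"], 0.5)
})

test_that("UPGMA agglomeration matches average-linkage hclust", {
  set.seed(21)
  n <- 6
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[lower.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)  # tie-free
  d <- as.dist(d + t(d))
  dend <- ape::read.tree(text = epihost:::upgma_newick(d))
  ref <- stats::hclust(d, method = "average")
  # patristic distances on the dendrogram equal twice the merge heights,
  # i.e. the cophenetic matrix of average-linkage clustering
  got <- cophenetic(dend)[letters[1:n], letters[1:n]]
  want <- as.matrix(stats::cophenetic(ref))[letters[1:n], letters[1:n]]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("functional dendrogram rejects degenerate trait tables", {
  tt <- as_trait_table(
    data.frame(a = c("x", "x"), b = c(1, 1), row.names = c("s1", "s2")),
    c(a = "categorical", b = "quantitative"))
  expect_error(functional_dendrogram(tt), "identical")
})

test_that("functional diversity behaves like PD on the dendrogram", {
  set.seed(4)
  tt <- as_trait_table(
    data.frame(a = sample(c("x", "y", "z"), 6, TRUE),
               b = runif(6), c = sample(c(TRUE, FALSE), 6, TRUE),
               row.names = paste0("s", 1:6)),
    c(a = "categorical", b = "quantitative", c = "binary"))
  dend <- functional_dendrogram(tt)
  full <- functional_fd(paste0("s", 1:6), dend)
  expect_equal(full, sum(dend$edge.length))
  expect_lte(functional_fd(c("s1", "s2"), dend), full)
})

test_that("phylogenetic species metrics match their defining formulas", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  m <- psd_metrics(c(a = 1, b = 2, c = 1, d = 3), star)
  expect_equal(unname(m["psv"]), 1)
  expect_equal(unname(m["psc"]), 1)
  expect_equal(unname(m["psr"]), 4)

  # n = 2 with off-diagonal correlation c: PSV = 1 - c
  phy2 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")  # cor(a,b) = 0.5
  m2 <- psd_metrics(c(a = 1, b = 1), phy2)
  expect_equal(unname(m2["psv"]), 0.5)

  expect_error(psd_metrics(c(a = 3), star), "2 species")
})

test_that("PSE equals the PSV formula on the expanded individual matrix", {
  set.seed(3)
  phy <- ape::rcoal(5)
  abund <- setNames(c(1, 1, 2, 3, 5), phy$tip.label)
  got <- psd_metrics(abund, phy)
  # brute-force expansion: 12 x 12 individual-level correlation matrix
  C <- ape::vcv(phy); C <- C / max(diag(C)); diag(C) <- 1
  idx <- rep(seq_along(abund), abund)
  Ci <- C[idx, idx]
  Ci[outer(idx, idx, "==")] <- 1      # conspecific (and self) correlation 1
  M <- sum(abund)
  # numerator: total lack of correlation over all individual pairs;
  # denominator: its maximum given the conspecific blocks are fixed at 1
  pse_brute <- (M * M - sum(Ci)) / (M * M - M * mean(abund))
  expect_equal(unname(got["pse"]), pse_brute, tolerance = 1e-12)
  # equal abundances collapse PSE to PSV
  eq <- psd_metrics(setNames(rep(3, 5), phy$tip.label), phy)
  expect_equal(unname(eq["pse"]), unname(eq["psv"]), tolerance = 1e-12)
})

test_that("PSV/PSR/PSC agree with picante on an ultrametric tree", {
  skip_if_not_installed("picante")
  set.seed(8)
  phy <- ape::rcoal(7)
  comm <- matrix(rpois(14, 3) + 1, 2, 7,
                 dimnames = list(c("r1", "r2"), phy$tip.label))
  got <- psd_metrics(comm[1, ], phy)
  expect_equal(unname(got["psv"]), unname(picante::psv(comm, phy)[1, 1]),
               tolerance = 1e-10)
  expect_equal(unname(got["psr"]), unname(picante::psr(comm, phy)[1, 1]),
               tolerance = 1e-10)
  expect_equal(unname(got["psc"]), unname(picante::psc(comm, phy)[1, 1]),
               tolerance = 1e-10)
  expect_equal(unname(got["pse"]), unname(picante::pse(comm, phy)[1, 1]),
               tolerance = 1e-10)
})

test_that("Schoener index covers its closed-form cases and invariances", {
  comm <- matrix(c(5, 5, 10, 10,   # identical relative use
                   4, 0, 0, 6),    # disjoint from nobody; see below
                 nrow = 2, byrow = FALSE)
  comm <- matrix(c(5, 10, 5, 10), 2, 2,
                 dimnames = list(c("k1", "k2"), c("i", "j")))
  S <- schoener_matrix(comm)
  expect_equal(S["i", "j"], 1)

  disj <- matrix(c(3, 0, 0, 8), 2, 2,
                 dimnames = list(c("k1", "k2"), c("i", "j")))
  expect_equal(schoener_matrix(disj)["i", "j"], 0)

  half <- matrix(c(1, 1, 2, 0), 2, 2,
                 dimnames = list(c("k1", "k2"), c("i", "j")))
  expect_equal(schoener_matrix(half)["i", "j"], 0.5)

  set.seed(5)
  comm3 <- matrix(rpois(20, 4) + 1, 4, 5,
                  dimnames = list(paste0("k", 1:4), paste0("s", 1:5)))
  scaled <- comm3; scaled[, 2] <- scaled[, 2] * 7
  expect_equal(schoener_matrix(comm3), schoener_matrix(scaled),
               tolerance = 1e-12)
  zero <- comm3; zero[, 3] <- 0
  expect_error(schoener_matrix(zero), "s3")
})

test_that("co-occurrence/distance correlation matches direct Pearson", {
  phy <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  # close relatives share samples exactly; distant pairs do not
  comm <- matrix(c(5, 0, 5, 0, 0, 5, 0, 5), 2, 4,
                 dimnames = list(c("k1", "k2"), c("a", "b", "c", "d")))
  r <- phylo_cooccurrence_correlation(comm, phy)
  S <- schoener_matrix(comm)
  D <- cophenetic(phy)[colnames(comm), colnames(comm)]
  expect_equal(r, cor(S[upper.tri(S)], D[upper.tri(D)]))
  expect_lt(r, 0)

  # relabeling invariance: joint permutation changes nothing
  perm <- c("d", "b", "a", "c")
  expect_equal(phylo_cooccurrence_correlation(comm[, perm], phy), r)

  const <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1), 2, 4,
                  dimnames = dimnames(comm))
  expect_error(phylo_cooccurrence_correlation(const, phy), "zero variance")
})
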