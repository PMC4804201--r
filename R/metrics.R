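#' Trunk share of a host tree's bromeliad load
#'
#' The within-crown distribution statistic: the fraction of a tree's
#' atmospheric bromeliads attached to its trunk, `a_trunk / a_total`.
#' 1 means every individual sits on the trunk, 0 means all are on the
#' branches, 0.5 a balanced crown.
#'
#' @param a_trunk trunk-attached count(s).
#' @param a_total total count(s); must be > 0 (non-hosts have no defined
#'   distribution and are excluded upstream).
#' @return numeric in \[0, 1\], vectorized.
#' @export
ab_dst <- function(a_trunk, a_total) {
  if (any(a_total <= 0))
    stop_undefined("ab_dst is undefined for trees hosting no bromeliads (a_total = 0)")
  if (any(a_trunk < 0) || any(a_trunk > a_total))
    stop("a_trunk must lie in [0, a_total]")
  a_trunk / a_total
}

# edge incidence of root->tip paths: tips x edges logical matrix
path_edge_matrix <- function(phylo) {
  ntip <- length(phylo$tip.label)
  parent_edge <- integer(max(phylo$edge))          # edge index leading into node
  parent_edge[phylo$edge[, 2]] <- seq_len(nrow(phylo$edge))
  root <- ntip + 1L
  M <- matrix(FALSE, ntip, nrow(phylo$edge),
              dimnames = list(phylo$tip.label, NULL))
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      M[tip, e] <- TRUE
      node <- phylo$edge[e, 1]
    }
  }
  M
}

#' Faith's phylogenetic diversity of a species set
#'
#' Total branch length of the minimal rooted subtree connecting the set,
#' root included, so a single species contributes its root-to-tip path
#' length. Monotone non-decreasing under set inclusion and equal to the
#' total tree length on the full leaf set.
#'
#' @param species_set character vector of tip labels (length >= 1).
#' @param phylo an `ape` phylogeny with branch lengths.
#' @return branch-length sum.
#' @export
faith_pd <- function(species_set, phylo) {
  unknown <- setdiff(species_set, phylo$tip.label)
  if (length(unknown))
    stop("unknown taxon label(s): ", paste(unknown, collapse = ", "))
  if (!length(species_set)) stop("species_set must be nonempty")
  M <- path_edge_matrix(phylo)
  sum(phylo$edge.length[colSums(M[species_set, , drop = FALSE]) > 0])
}

#' Gower dissimilarity over a mixed trait table
#'
#' Equal trait weights; quantitative traits are range-normalized over the
#' species pool (a constant quantitative trait contributes zero);
#' categorical and binary traits use simple matching.
#'
#' @param traits trait table from [read_traits()] (carries a `kinds`
#'   attribute).
#' @return a `dist` object over the species.
#' @export
gower_dissimilarity <- function(traits) {
  kinds <- attr(traits, "kinds")
  if (is.null(kinds)) stop("traits must carry declared kinds; see read_traits()")
  n <- nrow(traits)
  acc <- matrix(0, n, n)
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (kinds[[tr]] == "quantitative") {
      rng <- diff(range(v))
      d <- if (rng > 0) abs(outer(v, v, "-")) / rng else matrix(0, n, n)
    } else {
      d <- 1 * outer(as.character(v), as.character(v), "!=")
    }
    acc <- acc + d
  }
  out <- as.dist(acc / length(traits))
  attr(out, "Labels") <- rownames(traits)
  out
}

# UPGMA (average linkage) agglomeration with a pinned tie rule: among
# minimal-distance pairs, merge the one whose representative leaf labels
# (lexicographically smallest member of each cluster) sort first.
upgma_newick <- function(d) {
  labels <- attr(d, "Labels")
  dm <- as.matrix(d)
  n <- length(labels)
  members <- as.list(labels)
  reps <- labels                      # lexicographically smallest leaf per cluster
  newick <- labels
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- dm[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    cand <- which(sub - mn <= 1e-12 * (1 + mn), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(rc) {
      r <- sort(c(reps[idx[rc[1]]], reps[idx[rc[2]]]))
      paste(r, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- idx[pick[1L]]; j <- idx[pick[2L]]
    h <- dm[i, j] / 2
    bi <- h - heights[i]; bj <- h - heights[j]
    newick[i] <- sprintf("(%s:%.17g,%s:%.17g)", newick[i], bi, newick[j], bj)
    # average-linkage update
    upd <- setdiff(which(active), c(i, j))
    dm[i, upd] <- dm[upd, i] <-
      (sizes[i] * dm[i, upd] + sizes[j] * dm[j, upd]) / (sizes[i] + sizes[j])
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    reps[i] <- min(reps[i], reps[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
  }
  paste0(newick[active], ";")
}

#' Functional dendrogram of the tree-species pool
#'
#' Gower dissimilarity over the declared mixed traits followed by UPGMA
#' agglomeration, returned as an ultrametric `ape` phylogeny so that
#' dendrogram-based functional diversity can reuse the same spanning
#' branch-length machinery as Faith's PD.
#'
#' @param traits trait table from [read_traits()].
#' @return an ultrametric `phylo` object.
#' @export
functional_dendrogram <- function(traits) {
  if (nrow(traits) < 2) stop("need at least 2 species")
  d <- gower_dissimilarity(traits)
  if (all(d <= 0))
    stop("all species functionally identical: dissimilarity is zero everywhere")
  ape::read.tree(text = upgma_newick(d))
}

#' Dendrogram-based functional diversity of a species set
#'
#' Total branch length of the functional dendrogram spanning the set
#' (root included), the dendrogram analogue of Faith's PD.
#'
#' @param species_set character vector of species.
#' @param dendrogram output of [functional_dendrogram()].
#' @return branch-length sum.
#' @export
functional_fd <- function(species_set, dendrogram) {
  faith_pd(species_set, dendrogram)
}

#' Phylogenetic correlation and distance structure of a tree
#'
#' The species-by-species correlation matrix `C` is the shared root-to-tip
#' branch length divided by the maximum root-to-tip depth -- i.e. the tree
#' is made ultrametric by extending terminal branches to the deepest tip --
#' with unit diagonal. `D` is the patristic (cophenetic) distance matrix.
#'
#' @param phylo an `ape` phylogeny with branch lengths.
#' @return list with `C`, `D` and `n`.
#' @export
phylo_structure <- function(phylo) {
  V <- ape::vcv(phylo)
  C <- V / max(diag(V))
  diag(C) <- 1
  list(C = C, D = cophenetic(phylo), n = length(phylo$tip.label))
}

#' Phylogenetic species variability, richness, evenness and clustering
#'
#' Correlation-matrix summaries of a community's phylogenetic structure:
#' `psv = (n^2 - sum(C)) / (n (n - 1))` on the present-species correlation
#' submatrix, `psr = n * psv`, `pse` the abundance-weighted version on the
#' individual-level correlation matrix (each individual a unit, conspecific
#' correlation 1, heterospecific pairs in both numerator and denominator, so
#' equal abundances collapse PSE to PSV), and
#' `psc = 1 - mean_i max_{j != i} C_ij`.
#'
#' @param abund named abundance vector (one community row); species with
#'   abundance 0 are absent.
#' @param phylo phylogeny covering the named species.
#' @return named numeric vector `c(psv, psr, pse, psc)`.
#' @export
psd_metrics <- function(abund, phylo) {
  ps <- phylo_structure(phylo)
  psd_metrics_from_structure(abund, ps$C)
}

psd_metrics_from_structure <- function(abund, C) {
  abund <- abund[abund > 0]
  sp <- names(abund)
  if (length(sp) < 2)
    stop_undefined("phylogenetic species metrics need >= 2 species present")
  unknown <- setdiff(sp, rownames(C))
  if (length(unknown))
    stop("unknown taxon label(s): ", paste(unknown, collapse = ", "))
  Cs <- C[sp, sp]
  n <- length(sp)
  psv <- (n * n - sum(Cs)) / (n * (n - 1))
  a <- as.numeric(abund)
  M <- sum(a)
  pse <- (M * M - drop(a %*% Cs %*% a)) / (M * M - M * mean(a))
  offmax <- vapply(seq_len(n), function(i) max(Cs[i, -i]), 0)
  c(psv = psv, psr = n * psv, pse = pse, psc = 1 - mean(offmax))
}

#' Schoener co-occurrence index matrix
#'
#' `S_ij = 1 - 0.5 * sum_k |p_ik - p_jk|` where `p_ik` is species i's
#' relative abundance in sample k. 1 means identical relative use of the
#' samples, 0 disjoint use; invariant to rescaling any species' abundances.
#'
#' @param comm samples x species abundance matrix.
#' @return symmetric species x species matrix with unit diagonal.
#' @export
schoener_matrix <- function(comm) {
  tot <- colSums(comm)
  if (any(tot <= 0))
    stop("species with zero total abundance: ",
         paste(colnames(comm)[tot <= 0], collapse = ", "))
  P <- sweep(comm, 2, tot, "/")
  S <- 1 - 0.5 * as.matrix(dist(t(P), method = "manhattan"))
  diag(S) <- 1
  S
}

#' Correlation of co-occurrence with phylogenetic distance
#'
#' Pearson correlation between the upper-triangle Schoener indices and the
#' corresponding patristic distances; a negative value means closer
#' relatives share samples more.
#'
#' @param comm samples x species abundance matrix (>= 3 species).
#' @param phylo phylogeny covering the columns.
#' @return correlation coefficient.
#' @export
phylo_cooccurrence_correlation <- function(comm, phylo) {
  sp <- colnames(comm)
  if (length(sp) < 3) stop("need at least 3 species")
  S <- schoener_matrix(comm)
  D <- cophenetic(phylo)[sp, sp]
  ut <- upper.tri(S)
  s <- S[ut]; d <- D[ut]
  if (sd(s) == 0 || sd(d) == 0)
    stop_undefined("zero variance in co-occurrence or distance; correlation undefined")
  cor(s, d)
}

#' Per-tree and per-sample diversity report
#'
#' @param dataset an `epihost_dataset`.
#' @param sample_by `"plot"` or `"patch"`.
#' @return list of two data.frames: `trees` (tree_id, ab_abund, ab_dst) and
#'   `samples` (richness of host tree species, Faith's PD, functional
#'   diversity and the four phylogenetic species metrics; metrics needing
#'   >= 2 host species are NA where undefined).
#' @export
metrics_report <- function(dataset, sample_by = c("plot", "patch")) {
  sample_by <- match.arg(sample_by)
  comm <- community_from_records(dataset, sample_by, "host_tree_species")
  dend <- functional_dendrogram(dataset$traits)
  ps <- phylo_structure(dataset$phylo)
  rows <- lapply(rownames(comm), function(s) {
    a <- comm[s, ]
    present <- colnames(comm)[a > 0]
    psd <- if (sum(a > 0) >= 2) psd_metrics_from_structure(a[a > 0], ps$C)
           else c(psv = NA_real_, psr = NA_real_, pse = NA_real_, psc = NA_real_)
    data.frame(sample = s, richness = length(present),
               pd = if (length(present)) faith_pd(present, dataset$phylo) else 0,
               fd = if (length(present)) functional_fd(present, dend) else 0,
               t(psd))
  })
  tr <- dataset$trees
  list(trees = data.frame(tree_id = tr$tree_id, ab_abund = tr$ab_abund,
                          ab_dst = tr$ab_dst),
       samples = do.call(rbind, rows))
}
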