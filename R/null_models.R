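#' Construct a null envelope
#'
#' Wraps an observed statistic with its randomization distribution and the
#' 2.5\\%/97.5\\% empirical quantiles (type-7, linear interpolation, so test
#' fixtures are exactly reproducible).
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of null replicates.
#' @return object of class `null_envelope` with fields `observed`,
#'   `null_draws`, `q_low`, `q_high` and `verdict` (`below`, `within`,
#'   `above`).
#' @export
null_envelope <- function(observed, null_draws) {
  q <- unname(quantile(null_draws, c(0.025, 0.975), type = 7, names = FALSE))
  verdict <- if (observed < q[1]) "below" else if (observed > q[2]) "above" else "within"
  structure(list(observed = observed, null_draws = null_draws,
                 q_low = q[1], q_high = q[2], verdict = verdict),
            class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf("null envelope (%d draws): observed %.4g vs [%.4g, %.4g] -> %s\n",
              length(x$null_draws), x$observed, x$q_low, x$q_high, x$verdict))
  invisible(x)
}

# fast spanning branch-length sum given a precomputed path-edge matrix
spanning_length <- function(species, M, lens) {
  sum(lens[colSums(M[species, , drop = FALSE]) > 0])
}

#' Individual-randomization null model for host diversity
#'
#' Tests whether the host trees of a vegetation patch are a random draw
#' from the patch's tree pool. Each replicate reassigns every bromeliad
#' individual of the patch independently and uniformly to one of the
#' patch's trees (total count conserved), then records the species
#' richness, Faith's PD and functional diversity of the tree species that
#' received at least one individual. Observed values outside the 95\\%
#' envelope indicate non-random host use (e.g. clustering on fewer species
#' than chance predicts).
#'
#' @param dataset an `epihost_dataset`.
#' @param patch patch label to analyse.
#' @param n_reps number of randomizations (default 10000).
#' @param seed optional integer seed.
#' @param weights optional per-tree placement weights (e.g. tree size);
#'   default uniform across the patch's individual trees.
#' @return named list of `null_envelope` objects for `richness`, `pd`, `fd`.
#' @export
randomize_individuals_null <- function(dataset, patch, n_reps = 10000,
                                       seed = NULL, weights = NULL) {
  stopifnot(inherits(dataset, "epihost_dataset"))
  tr <- dataset$trees[dataset$trees$patch == patch, ]
  if (!nrow(tr)) stop("no trees in patch '", patch, "'")
  n_ind <- sum(tr$a_total)
  if (n_ind == 0) stop("patch '", patch, "' has no bromeliad individuals")
  if (nrow(tr) < 2) stop("patch '", patch, "' has fewer than 2 trees")
  if (n_reps < 100)
    warning("n_reps < 100 gives unstable envelope quantiles", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  species <- tr$species
  pool <- unique(species)
  Mp <- path_edge_matrix(dataset$phylo)[pool, , drop = FALSE]
  lp <- dataset$phylo$edge.length
  dend <- functional_dendrogram(dataset$traits)
  Md <- path_edge_matrix(dend)[pool, , drop = FALSE]
  ld <- dend$edge.length
  sp_idx <- match(species, pool)

  obs_sp <- unique(species[tr$a_total > 0])
  observed <- c(richness = length(obs_sp),
                pd = spanning_length(obs_sp, Mp, lp),
                fd = spanning_length(obs_sp, Md, ld))

  prob <- if (is.null(weights)) NULL else weights / sum(weights)
  draws <- matrix(NA_real_, n_reps, 3)
  for (r in seq_len(n_reps)) {
    placed <- tabulate(sample.int(nrow(tr), n_ind, replace = TRUE, prob = prob),
                       nbins = nrow(tr))
    occ <- pool[unique(sp_idx[placed > 0])]
    draws[r, ] <- c(length(occ), spanning_length(occ, Mp, lp),
                    spanning_length(occ, Md, ld))
  }
  list(richness = null_envelope(observed[["richness"]], draws[, 1]),
       pd = null_envelope(observed[["pd"]], draws[, 2]),
       fd = null_envelope(observed[["fd"]], draws[, 3]))
}

#' Tip-shuffle test of phylogenetic co-occurrence structure
#'
#' Compares the observed correlation between Schoener co-occurrence and
#' patristic distance with its distribution under random permutation of
#' the phylogeny's tip labels (the community matrix, and hence the
#' Schoener matrix, never changes).
#'
#' @param comm samples x species abundance matrix.
#' @param phylo phylogeny covering the columns.
#' @param n_runs number of label shuffles (default 1000).
#' @param seed optional integer seed.
#' @return a `null_envelope` of the correlation.
#' @export
tip_shuffle_test <- function(comm, phylo, n_runs = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- colnames(comm)
  S <- schoener_matrix(comm)
  ut <- upper.tri(S)
  s <- S[ut]
  if (sd(s) == 0)
    stop_undefined("zero variance in co-occurrence; correlation undefined")
  D <- cophenetic(phylo)
  labels <- phylo$tip.label
  pos <- match(sp, labels)
  d_obs <- D[pos, pos][ut]
  if (sd(d_obs) == 0)
    stop_undefined("zero variance in phylogenetic distance; correlation undefined")
  observed <- cor(s, d_obs)
  draws <- vapply(seq_len(n_runs), function(r) {
    perm <- sample.int(length(labels))
    # tree with shuffled labels: species sp now sit at positions perm^-1[pos]
    newpos <- match(pos, perm)
    cor(s, D[newpos, newpos][ut])
  }, 0)
  null_envelope(observed, draws)
}

#' Occurrence-frequency-preserving abundance shuffle
#'
#' Permutes each species' abundances across samples independently, exactly
#' preserving every species' total abundance and its occurrence frequency
#' (number of samples where it is present).
#'
#' @param comm samples x species abundance matrix.
#' @param seed optional integer seed.
#' @return shuffled matrix of the same shape and dimnames.
#' @export
frequency_preserving_shuffle <- function(comm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(comm)) stop("empty community matrix")
  out <- apply(comm, 2, function(col) col[sample.int(length(col))])
  dimnames(out) <- dimnames(comm)
  out
}

psd_structure_label <- function(verdict) {
  switch(verdict, below = "Clustered", within = "Random", above = "Overdispersed")
}

#' Null test of phylogenetic species structure
#'
#' For each group of samples (e.g. each vegetation patch), compares the
#' observed phylogenetic species variability/richness/evenness/clustering
#' of the pooled abundance row against their distribution when the whole
#' community matrix is repeatedly shuffled with
#' [frequency_preserving_shuffle()]. Shuffling moves abundance between
#' groups while conserving every species' total and occurrence frequency;
#' with a single group covering all samples the pooled row is invariant
#' and the envelopes are degenerate at the observed values.
#'
#' @param comm samples x species abundance matrix.
#' @param phylo phylogeny covering the columns.
#' @param pool grouping of rows (factor/character, default one group).
#' @param n_reps number of shuffles (default 1000).
#' @param seed optional integer seed.
#' @return named list per group; each element a list of `null_envelope`s
#'   for `psv`, `psr`, `pse`, `psc`, each with a `structure` attribute
#'   (`Clustered` / `Random` / `Overdispersed`).
#' @export
psd_null_test <- function(comm, phylo, pool = NULL, n_reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- rep("all", nrow(comm))
  pool <- as.factor(pool)
  ps <- phylo_structure(phylo)
  pooled <- function(m) rowsum(m, pool)
  metric_rows <- function(m) {
    pm <- pooled(m)
    t(vapply(rownames(pm), function(g) {
      a <- pm[g, ]
      psd_metrics_from_structure(a[a > 0], ps$C)
    }, c(psv = 0, psr = 0, pse = 0, psc = 0)))
  }
  obs <- metric_rows(comm)
  draws <- array(NA_real_, c(n_reps, nrow(obs), 4),
                 dimnames = list(NULL, rownames(obs), colnames(obs)))
  for (r in seq_len(n_reps))
    draws[r, , ] <- metric_rows(frequency_preserving_shuffle(comm))
  out <- lapply(rownames(obs), function(g) {
    envs <- lapply(colnames(obs), function(metric) {
      e <- null_envelope(obs[g, metric], draws[, g, metric])
      attr(e, "structure") <- psd_structure_label(e$verdict)
      e
    })
    names(envs) <- colnames(obs)
    envs
  })
  names(out) <- rownames(obs)
  out
}

#' Tabulate null-envelope results
#'
#' @param envelopes a named list of `null_envelope` objects (possibly
#'   nested one level, e.g. the per-group output of [psd_null_test()]).
#' @return data.frame with columns metric, observed, q2.5, q97.5, verdict
#'   (and group for nested input).
#' @export
envelope_table <- function(envelopes) {
  flat_one <- function(envs, group = NA_character_) {
    do.call(rbind, lapply(names(envs), function(nm) {
      e <- envs[[nm]]
      data.frame(group = group, metric = nm, observed = e$observed,
                 q2.5 = e$q_low, q97.5 = e$q_high, verdict = e$verdict,
                 structure = attr(e, "structure") %||% NA_character_)
    }))
  }
  if (inherits(envelopes[[1]], "null_envelope")) flat_one(envelopes)
  else do.call(rbind, Map(flat_one, envelopes, names(envelopes)))
}
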