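# a census with one tree per species, counts set by the caller
census_of <- function(counts_trunk, counts_branch = 0 * counts_trunk,
                      n_species = length(counts_trunk)) {
  stopifnot(length(counts_trunk) <= n_species)
  sp <- paste0("s", seq_len(n_species))
  n <- n_species
  trees <- data.frame(tree_id = paste0("t", seq_len(n)), patch = "P",
                      plot = "p1", species = sp,
                      dbh = 10 + seq_len(n), height = 5, lai = 1,
                      e1_trunk = c(counts_trunk,
                                   rep(0L, n - length(counts_trunk))),
                      e1_branch = c(counts_branch,
                                    rep(0L, n - length(counts_branch))))
  traits <- as_trait_table(
    data.frame(bark = rep(c("smooth", "grooved"), length.out = n),
               size = seq_len(n), row.names = sp),
    c(bark = "categorical", size = "quantitative"))
  phylo <- simulate_phylogeny(n, "yule", seed = 7, labels = sp)
  epihost:::build_dataset(trees, traits, phylo)
}


# hand-built trees with known leaf means, for the classification logic
mock_tree <- function(response, leaves) {
  children <- lapply(leaves, function(l)
    list(members = l$ids, n = length(l$ids), mean = l$mean, is_leaf = TRUE))
  names(children) <- paste0("g", seq_along(children))
  all_ids <- unlist(lapply(leaves, `[[`, "ids"))
  root <- if (length(leaves) == 1) children[[1]] else
    list(members = all_ids, n = length(all_ids),
         mean = mean(unlist(lapply(leaves, function(l)
           rep(l$mean, length(l$ids))))),
         is_leaf = FALSE, split_var = "trait",
         rule = list(kind = "categorical", levels = names(children)),
         pct = 50, z = 3, children = children)
  structure(list(root = root, response = response,
                 family = if (response == "abund") "poisson" else "binomial",
                 predictors = "trait",
                 config = list(min_node = 10, n_rand = 199, seed = 0)),
            class = "trait_tree")
}


# brute-force oracle: average the fit increment of each predictor over all
# k! orderings, with R(S) computed by stats::glm / stats::lm directly
all_orderings <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (first in seq_len(k))
    for (rest in all_orderings(k - 1))
      out[[length(out) + 1L]] <- c(first, setdiff(seq_len(k), first)[rest])
  out
}

glm_gof <- function(y, X, family, sub) {
  if (!length(sub)) return(0)
  fit <- glm(y ~ ., data = X[, sub, drop = FALSE], family = family)
  1 - fit$deviance / fit$null.deviance
}

brute_partition <- function(y, X, family) {
  k <- ncol(X)
  I <- numeric(k)
  ords <- all_orderings(k)
  for (ord in ords) {
    sofar <- integer()
    for (x in ord) {
      I[x] <- I[x] + glm_gof(y, X, family, c(sofar, x)) -
        glm_gof(y, X, family, sofar)
      sofar <- c(sofar, x)
    }
  }
  I / length(ords)
}

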