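#' Host-pattern classification thresholds
#'
#' Defaults follow the field convention for atmospheric-bromeliad surveys:
#' a trait-combination group is a best-host pattern when its mean abundance
#' exceeds 400 individuals, a worst-host pattern below 10; trunk-host and
#' branches-host patterns hold more than 90\\% of individuals on the trunk
#' (mean trunk share > 0.9) or on the branches (< 0.1) respectively.
#'
#' @param best_min minimum mean abundance of a best-host leaf.
#' @param worst_max maximum mean abundance of a worst-host leaf.
#' @param trunk_min_share minimum mean trunk share of a trunk-host leaf.
#' @param branches_max_share maximum mean trunk share of a branches-host leaf.
#' @return a `pattern_thresholds` list.
#' @export
pattern_thresholds <- function(best_min = 400, worst_max = 10,
                               trunk_min_share = 0.9, branches_max_share = 0.1) {
  stopifnot(worst_max < best_min, branches_max_share < trunk_min_share)
  structure(list(best_min = best_min, worst_max = worst_max,
                 trunk_min_share = trunk_min_share,
                 branches_max_share = branches_max_share),
            class = "pattern_thresholds")
}

quantitative_tree_vars <- function() c("dbh", "height", "lai")

default_tree_predictors <- function(recs) {
  intersect(c("deciduousness", "bark", "peeling", "light_guild", "thorns",
              "needles", "dbh", "height", "lai"), names(recs))
}

#' Grow a successive-hierarchic-partition trait tree
#'
#' Recursively partitions the trees by the functional trait that best
#' explains the response. At each node a hierarchical-partitioning
#' randomization test ([hier_part()]) is run on the remaining candidate
#' predictors; if none is significant (z >= 1.65) the node becomes a leaf,
#' otherwise the node splits on the most significant predictor --
#' categorical traits give one child per observed level, quantitative
#' traits a two-way split at the node median (ties to the lower side) --
#' and the chosen predictor is removed from all descendants' candidates.
#' Nodes smaller than `min_node` or with a constant response become leaves.
#'
#' The `"abund"` response (total bromeliad count, Poisson) uses all trees,
#' hosts and non-hosts; the `"dist"` response (trunk share, binomial on
#' trunk/branch counts) uses hosts only.
#'
#' @param dataset an `epihost_dataset`.
#' @param response `"abund"` or `"dist"`.
#' @param predictors character vector of candidate predictors (default:
#'   the six categorical/binary traits plus dbh, height, lai).
#' @param min_node minimum node size to attempt a split (default 10).
#' @param n_rand permutations per node test (default 1000).
#' @param seed integer seed; node-level streams are derived from it so the
#'   grown tree is reproducible.
#' @return object of class `trait_tree`.
#' @export
trait_tree <- function(dataset, response = c("abund", "dist"),
                       predictors = NULL, min_node = 10, n_rand = 1000,
                       seed = NULL) {
  stopifnot(inherits(dataset, "epihost_dataset"))
  response <- match.arg(response)
  recs <- records(dataset, hosts_only = response == "dist")
  if (is.null(predictors)) predictors <- default_tree_predictors(recs)
  missing <- setdiff(predictors, names(recs))
  if (length(missing))
    stop("unknown predictor(s): ", paste(missing, collapse = ", "))
  family <- if (response == "abund") "poisson" else "binomial"
  leaf_value <- if (response == "abund") recs$a_total else recs$ab_dst
  names(leaf_value) <- recs$tree_id
  yfun <- if (response == "abund") function(r) r$a_total
          else function(r) cbind(r$a_trunk, r$a_branch)
  if (is.null(seed)) seed <- 0L
  counter <- new.env()
  counter$i <- 0L

  grow <- function(ids, candidates) {
    counter$i <- counter$i + 1L
    r <- recs[ids, , drop = FALSE]
    node <- list(members = ids, n = length(ids),
                 mean = mean(leaf_value[ids]), candidates = candidates)
    vary <- candidates[vapply(candidates, function(v)
      length(unique(r[[v]])) > 1, TRUE)]
    y <- yfun(r)
    y_const <- if (is.matrix(y)) sd(leaf_value[ids]) == 0 else sd(y) == 0
    if (length(ids) < min_node || !length(vary) || y_const)
      return(c(node, list(is_leaf = TRUE)))
    X <- r[vary]
    X[] <- lapply(X, function(v) if (is.factor(v)) droplevels(v) else v)
    ncoef <- sum(vapply(X, function(v)
      if (is.factor(v)) nlevels(v) - 1L else 1L, 0L))
    if (length(ids) <= ncoef + 2L) return(c(node, list(is_leaf = TRUE)))
    hp <- hier_part(y, X, family = family, n_rand = n_rand,
                    seed = derive_seed(seed, counter$i))
    tab <- hp$table
    sig <- tab[tab$sig, , drop = FALSE]
    if (!nrow(sig)) return(c(node, list(is_leaf = TRUE)))
    best <- sig$predictor[which.max(sig$z)]
    v <- r[[best]]
    if (best %in% quantitative_tree_vars() && is.numeric(v)) {
      m <- median(v)
      groups <- list(ids[v <= m], ids[v > m])
      names(groups) <- paste0(c("<= ", "> "), format(m, digits = 6))
      rule <- list(kind = "quantitative", threshold = m)
    } else {
      lv <- if (is.factor(v)) levels(droplevels(v)) else
        as.character(sort(unique(v)))
      groups <- lapply(lv, function(l) ids[as.character(v) == l])
      names(groups) <- lv
      rule <- list(kind = "categorical", levels = lv)
    }
    groups <- groups[vapply(groups, length, 0L) > 0]
    if (length(groups) < 2) return(c(node, list(is_leaf = TRUE)))
    children <- lapply(groups, grow, candidates = setdiff(candidates, best))
    c(node, list(is_leaf = FALSE, split_var = best, rule = rule,
                 pct = tab$pct[tab$predictor == best],
                 z = tab$z[tab$predictor == best], children = children))
  }

  root <- grow(recs$tree_id, predictors)
  structure(list(root = root, response = response, family = family,
                 predictors = predictors,
                 config = list(min_node = min_node, n_rand = n_rand,
                               seed = seed)),
            class = "trait_tree")
}

#' Collect the leaves of a trait tree
#'
#' @param tree a `trait_tree`.
#' @return data.frame with one row per tree individual: `tree_id`,
#'   `leaf` (node path label), `leaf_mean`, `leaf_n`.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (node$is_leaf) {
      out[[length(out) + 1L]] <<- data.frame(
        tree_id = node$members, leaf = path,
        leaf_mean = node$mean, leaf_n = node$n)
    } else {
      for (nm in names(node$children))
        walk(node$children[[nm]],
             paste0(path, "/", node$split_var, "=", nm))
    }
  }
  walk(tree$root, "root")
  do.call(rbind, out)
}

#' @export
print.trait_tree <- function(x, ...) {
  cat(sprintf("Trait tree for %s (%s GLMs, %d permutations/node)\n",
              x$response, x$family, x$config$n_rand))
  walk <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s%s -> mean %s = %.3g (n = %d)\n", pad, label,
                  x$response, node$mean, node$n))
    } else {
      cat(sprintf("%s%s: split on %s (%.1f%%, z = %.2f)\n", pad, label,
                  node$split_var, node$pct, node$z))
      for (nm in names(node$children))
        walk(node$children[[nm]], indent + 1L, nm)
    }
  }
  walk(x$root, 0L, "root")
  invisible(x)
}

#' @export
summary.trait_tree <- function(object, ...) {
  lv <- tree_leaves(object)
  unique(lv[c("leaf", "leaf_mean", "leaf_n")])
}

#' Predict leaf means for tree records
#'
#' Drops each record down the fitted trait tree and returns its leaf mean
#' response (`NA` for records whose categorical level was not observed at
#' the corresponding split during fitting).
#'
#' @param object a `trait_tree`.
#' @param newdata data.frame with the predictor columns, e.g. from
#'   [records()]; defaults to the fitted members.
#' @param ... unused.
#' @return named numeric vector of leaf means.
#' @export
predict.trait_tree <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    lv <- tree_leaves(object)
    return(setNames(lv$leaf_mean, lv$tree_id))
  }
  one <- function(row) {
    node <- object$root
    while (!node$is_leaf) {
      v <- row[[node$split_var]]
      nm <- if (node$rule$kind == "quantitative") {
        if (v <= node$rule$threshold) 1L else 2L
      } else match(as.character(v), names(node$children))
      if (is.na(nm) || nm > length(node$children)) return(NA_real_)
      node <- node$children[[nm]]
    }
    node$mean
  }
  out <- vapply(seq_len(nrow(newdata)), function(i) one(newdata[i, ]), 0)
  names(out) <- rownames(newdata)
  out
}

#' Serialize a trait tree to JSON
#'
#' @param tree a `trait_tree`.
#' @return JSON string (nodes with split variable, rule, pct, z, leaf
#'   means and member ids).
#' @export
trait_tree_json <- function(tree) {
  strip <- function(node) {
    base <- list(n = node$n, mean = node$mean, members = node$members)
    if (node$is_leaf) c(base, list(leaf = TRUE))
    else c(base, list(leaf = FALSE, split_var = node$split_var,
                      rule = node$rule, pct = node$pct, z = node$z,
                      children = lapply(node$children, strip)))
  }
  jsonlite::toJSON(list(response = tree$response, family = tree$family,
                        config = tree$config, root = strip(tree$root)),
                   auto_unbox = TRUE, digits = NA)
}

#' Assign host patterns from the fitted abundance and distribution trees
#'
#' A tree individual is a best (worst) host when its abundance-tree leaf
#' mean exceeds `best_min` (falls below `worst_max`), and a trunk
#' (branches) host when its distribution-tree leaf mean exceeds
#' `trunk_min_share` (falls below `branches_max_share`). Trees in
#' intermediate leaves get no label; non-hosts (absent from the
#' distribution tree) get `trunk = branches = FALSE` so downstream
#' all-trees analyses have a complete matrix.
#'
#' @param abund_tree `trait_tree` fitted with `response = "abund"`.
#' @param dist_tree `trait_tree` fitted with `response = "dist"`.
#' @param thresholds a [pattern_thresholds()] object.
#' @return data.frame with columns tree_id, best, worst, trunk, branches.
#' @export
assign_patterns <- function(abund_tree, dist_tree,
                            thresholds = pattern_thresholds()) {
  stopifnot(abund_tree$response == "abund", dist_tree$response == "dist")
  la <- tree_leaves(abund_tree)
  ld <- tree_leaves(dist_tree)
  if (!all(ld$tree_id %in% la$tree_id))
    stop("distribution-tree members missing from the abundance tree: ",
         paste(setdiff(ld$tree_id, la$tree_id), collapse = ", "))
  out <- data.frame(tree_id = la$tree_id,
                    best = la$leaf_mean > thresholds$best_min,
                    worst = la$leaf_mean < thresholds$worst_max,
                    trunk = FALSE, branches = FALSE)
  i <- match(ld$tree_id, out$tree_id)
  out$trunk[i] <- ld$leaf_mean > thresholds$trunk_min_share
  out$branches[i] <- ld$leaf_mean < thresholds$branches_max_share
  out
}

#' Count species per exact host-pattern combination
#'
#' For each tree species, takes the union of host patterns over its
#' individuals and tabulates species by that exact combination -- the
#' counts behind an Euler diagram of pattern overlap. Species whose
#' individuals carry no pattern are not counted.
#'
#' @param assignment output of [assign_patterns()].
#' @param species_of named character vector mapping tree_id to species.
#' @return data.frame with columns `combination` (e.g. `"best+branches"`)
#'   and `n_species`.
#' @export
pattern_overlap_counts <- function(assignment, species_of) {
  if (!nrow(assignment)) return(data.frame(combination = character(),
                                           n_species = integer()))
  pats <- c("best", "worst", "trunk", "branches")
  sp <- species_of[assignment$tree_id]
  combos <- vapply(split(seq_len(nrow(assignment)), sp), function(idx) {
    has <- vapply(pats, function(p) any(assignment[[p]][idx]), TRUE)
    paste(pats[has], collapse = "+")
  }, "")
  combos <- combos[combos != ""]
  if (!length(combos)) return(data.frame(combination = character(),
                                         n_species = integer()))
  tab <- table(combos)
  data.frame(combination = names(tab), n_species = as.integer(tab),
             row.names = NULL)
}
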