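# likelihood-ratio chi-square of a single-term GLM against the intercept model
lr_test <- function(y, x, family) {
  fit <- glm(y ~ x, family = family)
  chi2 <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       slope = if (is.numeric(x)) unname(coef(fit)[2]) else NA_real_,
       r2 = if (fit$null.deviance > 0) chi2 / fit$null.deviance else 0)
}

# clique-based compact letter display: groups not significantly different
# share a letter; cliques are maximal non-significant subsets
compact_letters <- function(groups, pair_p, alpha = 0.05) {
  k <- length(groups)
  if (k == 1) return(setNames("a", groups))
  nonsig <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pair_p)))
    nonsig[pair_p$g1[i], pair_p$g2[i]] <- nonsig[pair_p$g2[i], pair_p$g1[i]] <-
      pair_p$p_adj[i] >= alpha
  cliques <- list()
  for (size in k:1) {
    for (s in asplit(combn(k, size), 2)) {
      if (all(nonsig[s, s])) {
        covered <- any(vapply(cliques, function(cl) all(s %in% cl), TRUE))
        if (!covered) cliques[[length(cliques) + 1L]] <- as.integer(s)
      }
    }
  }
  cliques <- cliques[order(vapply(cliques, min, 0L))]
  out <- setNames(rep("", k), groups)
  for (j in seq_along(cliques))
    out[cliques[[j]]] <- paste0(out[cliques[[j]]], letters[j])
  out
}

#' Compare bromeliad abundance or distribution among vegetation patches
#'
#' Fits a Poisson GLM of per-tree abundance (all trees) or a binomial GLM
#' of (trunk, branch) counts (hosts only) on the patch factor, reports the
#' likelihood-ratio chi-square, and performs all pairwise patch contrasts
#' with Holm adjustment, summarized as a compact letter display (patches
#' sharing a letter are statistically similar).
#'
#' @param dataset an `epihost_dataset`.
#' @param response `"abund"` or `"dist"`.
#' @param alpha significance level of the letter display.
#' @return list with `chi2`, `df`, `p`, `pairwise` (data.frame), `letters`
#'   and `patch_means`.
#' @export
patch_comparison <- function(dataset, response = c("abund", "dist"),
                             alpha = 0.05) {
  response <- match.arg(response)
  recs <- records(dataset, hosts_only = response == "dist")
  recs$patch <- droplevels(recs$patch)
  dropped <- setdiff(levels(dataset$trees$patch), levels(recs$patch))
  if (length(dropped))
    message("patch(es) without hosts dropped for dist: ",
            paste(dropped, collapse = ", "))
  if (nlevels(recs$patch) < 2) stop("need at least 2 patches")
  if (response == "abund") {
    y <- recs$a_total; family <- "poisson"
    means <- tapply(recs$a_total, recs$patch, mean)
  } else {
    y <- cbind(recs$a_trunk, recs$a_branch); family <- "binomial"
    means <- tapply(recs$ab_dst, recs$patch, mean)
  }
  overall <- lr_test(y, recs$patch, family)
  patches <- levels(recs$patch)
  pairs <- t(combn(patches, 2))
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sel <- recs$patch %in% pairs[i, ]
    ys <- if (is.matrix(y)) y[sel, , drop = FALSE] else y[sel]
    res <- lr_test(ys, droplevels(recs$patch[sel]), family)
    data.frame(g1 = pairs[i, 1], g2 = pairs[i, 2], chi2 = res$chi2, p = res$p)
  }))
  pw$p_adj <- p.adjust(pw$p, method = "holm")
  letters <- compact_letters(patches, pw, alpha)
  list(chi2 = overall$chi2, df = overall$df, p = overall$p,
       pairwise = pw, letters = letters, patch_means = means)
}

#' Per-plot summary of abundance, distribution and tree diversity
#'
#' @param dataset an `epihost_dataset`.
#' @return data.frame with one row per plot: patch, mean `ab_abund`, mean
#'   `ab_dst` over hosts (NA if the plot has none), host-species richness,
#'   Faith's PD and functional diversity.
#' @export
plot_summary <- function(dataset) {
  rep_ <- metrics_report(dataset, "plot")
  tr <- dataset$trees
  ab <- tapply(tr$a_total, tr$plot, mean)
  dst <- tapply(tr$ab_dst, tr$plot, mean, na.rm = TRUE)
  patch <- tapply(as.character(tr$patch), tr$plot, function(x) x[1])
  s <- rep_$samples
  data.frame(plot = s$sample, patch = patch[s$sample],
             ab_abund = as.numeric(ab[s$sample]),
             ab_dst = as.numeric(dst[s$sample]),
             richness = s$richness, pd = s$pd, fd = s$fd)
}

#' Simple linear models of abundance/distribution against tree diversity
#'
#' Ordinary least-squares regression of the response on each diversity
#' predictor separately, with ANOVA F-tests.
#'
#' @param summaries data.frame from [plot_summary()] (or any data.frame
#'   with the named columns).
#' @param response column name of the response (e.g. `"ab_abund"`).
#' @param predictors column names of the predictors.
#' @return data.frame with predictor, slope, F, p.
#' @export
diversity_regressions <- function(summaries, response = "ab_abund",
                                  predictors = c("richness", "pd", "fd")) {
  keep <- stats::complete.cases(summaries[c(response, predictors)])
  d <- summaries[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 complete samples")
  do.call(rbind, lapply(predictors, function(p) {
    if (sd(d[[p]]) == 0)
      stop_undefined(paste0("predictor '", p, "' is constant"))
    fit <- lm(d[[response]] ~ d[[p]])
    a <- anova(fit)
    data.frame(predictor = p, slope = unname(coef(fit)[2]),
               F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }))
}

#' PCA of host-pattern assignments
#'
#' Centered (covariance) principal component analysis of the trees-by-four
#' 0/1 pattern-assignment matrix, reducing the four correlated pattern
#' indicators to one axis. The component sign is fixed so the best-host
#' loading is negative.
#'
#' @param assignment output of [assign_patterns()].
#' @param subset `"all"` trees or `"hosts"` only.
#' @param is_host named logical vector (tree_id -> host status), required
#'   for `subset = "hosts"`.
#' @return object of class `pattern_pca`: list with `loadings` (PC1),
#'   `scores` (named by tree_id), `pct_variance`, `rotation`, `sdev`.
#' @export
pattern_pca <- function(assignment, subset = c("all", "hosts"),
                        is_host = NULL) {
  subset <- match.arg(subset)
  m <- as.matrix(assignment[c("best", "worst", "trunk", "branches")]) * 1
  rownames(m) <- assignment$tree_id
  if (subset == "hosts") {
    if (is.null(is_host)) stop("subset = 'hosts' needs the is_host vector")
    m <- m[is_host[rownames(m)], , drop = FALSE]
  }
  if (nrow(unique(m)) < 2) stop("pattern matrix has no variation")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- if (pc$rotation["best", 1] > 0) -1 else 1
  structure(list(loadings = flip * pc$rotation[, 1],
                 scores = setNames(flip * pc$x[, 1], rownames(m)),
                 pct_variance = 100 * pc$sdev[1]^2 / sum(pc$sdev^2),
                 rotation = pc$rotation, sdev = pc$sdev),
            class = "pattern_pca")
}

#' @export
print.pattern_pca <- function(x, ...) {
  cat(sprintf("Host-pattern PCA: PC1 explains %.1f%% of variance\n",
              x$pct_variance))
  print(round(x$loadings, 3))
  invisible(x)
}

#' GLM of abundance or trunk share on host-pattern PCA scores
#'
#' @param y response: counts (Poisson) or 2-column (trunk, branch) counts
#'   (binomial), aligned with `scores`.
#' @param scores PC1 scores from [pattern_pca()].
#' @param family `"poisson"` or `"binomial"`.
#' @return list with chi2, df, p, slope and deviance-explained r2.
#' @export
score_glm <- function(y, scores, family = c("poisson", "binomial")) {
  family <- match.arg(family)
  lr_test(y, as.numeric(scores), family)
}

#' Pairwise association between host-pattern assignments
#'
#' Binomial GLM (equivalently a 2x2 likelihood-ratio chi-square) of one
#' assignment on another, for the four trunk/branches vs best/worst
#' combinations: a positive slope means trees carrying the predictor
#' pattern are *likely* to carry the response pattern too.
#'
#' @param assignment output of [assign_patterns()].
#' @return data.frame with response, predictor, chi2, df, p, slope,
#'   direction (`likely`/`unlikely`) and `testable` (FALSE when a margin
#'   is degenerate).
#' @export
assignment_crosstab_tests <- function(assignment) {
  combos <- expand.grid(response = c("trunk", "branches"),
                        predictor = c("best", "worst"),
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    resp <- assignment[[combos$response[i]]] * 1
    pred <- assignment[[combos$predictor[i]]] * 1
    if (length(unique(resp)) < 2 || length(unique(pred)) < 2)
      return(data.frame(combos[i, ], chi2 = NA_real_, df = NA_integer_,
                        p = NA_real_, slope = NA_real_,
                        direction = NA_character_, testable = FALSE))
    res <- lr_test(resp, pred, "binomial")
    data.frame(combos[i, ], chi2 = res$chi2, df = res$df, p = res$p,
               slope = res$slope,
               direction = if (res$slope >= 0) "likely" else "unlikely",
               testable = TRUE)
  }))
}
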