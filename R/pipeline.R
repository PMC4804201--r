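#' Run the full host-trait analysis pipeline
#'
#' Executes the stages in dependency order -- data (simulate or read),
#' metrics, null models, hierarchical partitioning, trait trees with
#' host-pattern assignment, association statistics -- writing
#' machine-readable CSV/JSON artifacts plus a manifest with MD5 checksums
#' into the run directory. One global seed is expanded into independent
#' per-stage streams, so a rerun with the same config and seed reproduces
#' every stochastic output bit-exactly, and toggling one stage does not
#' shift another's draws. A stage failure aborts the downstream stages;
#' the manifest of artifacts written so far is still produced.
#'
#' @param config list or path to a YAML file. Recognized fields:
#'   `scenario` (a [named_scenarios()] name) or `inputs` (list with
#'   `trees`, `traits`, `phylo` paths), `out_dir`, `seed`, `stages`
#'   (subset of data/metrics/nullmodels/hierpart/traittree/association),
#'   `n_reps` (null-model replicates, default 1000), `n_rand`
#'   (permutations per partition test, default 199), `min_node`,
#'   `thresholds` (named list for [pattern_thresholds()]), `sample_by`.
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("data", "metrics", "nullmodels", "hierpart", "traittree", "association")
  n_reps <- config$n_reps %||% 1000
  n_rand <- config$n_rand %||% 199
  min_node <- config$min_node %||% 10
  thresholds <- do.call(pattern_thresholds, config$thresholds %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  artifacts <- character()
  log_path <- file.path(out_dir, "run.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                           append = TRUE)
  cat(sprintf("epihost pipeline | seed %d | %s\n", seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = log_path)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
  }
  emit_text <- function(txt, name) {
    path <- file.path(out_dir, name)
    writeLines(txt, path)
    artifacts <<- c(artifacts, path)
  }

  dataset <- NULL
  abund_tree <- dist_tree <- assignment <- NULL

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible())
    log("stage %s: start (seed %d)", name,
        derive_seed(seed, match(name, stages)))
    fn(derive_seed(seed, match(name, stages)))
    log("stage %s: done", name)
  }

  finish <- function() {
    manifest <- data.frame(artifact = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           seed = rep(seed, length(artifacts)))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    manifest
  }

  result <- tryCatch({
    run_stage("data", function(s) {
      if (!is.null(config$scenario)) {
        sc <- named_scenarios()[[config$scenario]]
        if (is.null(sc)) stop("unknown scenario '", config$scenario, "'")
        dataset <<- simulate_dataset(sc, seed = s)
        artifacts <<- c(artifacts,
                        write_dataset(dataset, file.path(out_dir, "data")))
      } else {
        inp <- config$inputs %||% stop("config needs 'scenario' or 'inputs'")
        dataset <<- read_dataset(inp$trees, inp$traits, inp$phylo,
                                 config = inp$config)
      }
    })
    if (is.null(dataset)) stop("the data stage is required")

    run_stage("metrics", function(s) {
      rep_ <- metrics_report(dataset, config$sample_by %||% "plot")
      emit_csv(rep_$trees, "metrics_trees.csv")
      emit_csv(rep_$samples, "metrics_samples.csv")
    })

    run_stage("nullmodels", function(s) {
      tabs <- list()
      for (p in levels(dataset$trees$patch)) {
        env <- tryCatch(
          randomize_individuals_null(dataset, p, n_reps = n_reps,
                                     seed = derive_seed(s, match(p, levels(dataset$trees$patch)))),
          error = function(e) { log("  individuals null skipped for %s: %s",
                                    p, conditionMessage(e)); NULL })
        if (!is.null(env)) {
          t1 <- envelope_table(env); t1$group <- p; tabs[[p]] <- t1
        }
      }
      if (length(tabs))
        emit_csv(do.call(rbind, tabs), "nullmodel_individuals.csv")
      comm <- community_from_records(dataset, "plot", "host_tree_species")
      comm <- comm[, colSums(comm) > 0, drop = FALSE]
      patch_of <- sub("_plot[0-9]+$", "", rownames(comm))
      psd <- tryCatch(
        psd_null_test(comm, dataset$phylo, pool = patch_of, n_reps = n_reps,
                      seed = derive_seed(s, 101L)),
        error = function(e) { log("  psd null skipped: %s",
                                  conditionMessage(e)); NULL })
      if (!is.null(psd)) emit_csv(envelope_table(psd), "nullmodel_psd.csv")
      tip <- tryCatch(
        tip_shuffle_test(comm, dataset$phylo, n_runs = n_reps,
                         seed = derive_seed(s, 102L)),
        error = function(e) { log("  tip shuffle skipped: %s",
                                  conditionMessage(e)); NULL })
      if (!is.null(tip))
        emit_csv(envelope_table(list(cooccurrence_cor = tip)),
                 "nullmodel_tipshuffle.csv")
    })

    run_stage("hierpart", function(s) {
      recs <- records(dataset)
      preds <- intersect(c("deciduousness", "bark", "needles", "dbh",
                           "height", "lai"), default_tree_predictors(recs))
      hp_a <- hier_part(recs$a_total, recs[preds], family = "poisson",
                        n_rand = n_rand, seed = derive_seed(s, 1L))
      emit_csv(summary(hp_a), "hierpart_abund.csv")
      hosts <- records(dataset, hosts_only = TRUE)
      if (nrow(hosts) > length(preds) + 3) {
        hp_d <- hier_part(cbind(hosts$a_trunk, hosts$a_branch), hosts[preds],
                          family = "binomial", n_rand = n_rand,
                          seed = derive_seed(s, 2L))
        emit_csv(summary(hp_d), "hierpart_dist.csv")
      } else log("  dist hierpart skipped: too few hosts")
    })

    run_stage("traittree", function(s) {
      abund_tree <<- trait_tree(dataset, "abund", min_node = min_node,
                                n_rand = n_rand, seed = derive_seed(s, 1L))
      dist_tree <<- trait_tree(dataset, "dist", min_node = min_node,
                               n_rand = n_rand, seed = derive_seed(s, 2L))
      emit_text(trait_tree_json(abund_tree), "traittree_abund.json")
      emit_text(trait_tree_json(dist_tree), "traittree_dist.json")
      emit_text(utils::capture.output(print(abund_tree)), "traittree_abund.txt")
      emit_text(utils::capture.output(print(dist_tree)), "traittree_dist.txt")
      assignment <<- assign_patterns(abund_tree, dist_tree, thresholds)
      emit_csv(assignment, "patterns.csv")
      sp_of <- setNames(dataset$trees$species, dataset$trees$tree_id)
      emit_csv(pattern_overlap_counts(assignment, sp_of), "euler_counts.csv")
    })

    run_stage("association", function(s) {
      rows <- list()
      for (resp in c("abund", "dist")) {
        pc <- tryCatch(patch_comparison(dataset, resp),
                       error = function(e) { log("  patch comparison (%s) skipped: %s",
                                                 resp, conditionMessage(e)); NULL })
        if (!is.null(pc))
          rows[[resp]] <- data.frame(
            response = resp, chi2 = pc$chi2, df = pc$df, p = pc$p,
            letters = paste(names(pc$letters), pc$letters, sep = ":",
                            collapse = ";"))
      }
      if (length(rows)) emit_csv(do.call(rbind, rows), "patch_comparison.csv")
      summ <- plot_summary(dataset)
      lm_rows <- lapply(c("ab_abund", "ab_dst"), function(resp) {
        out <- tryCatch(diversity_regressions(summ, resp),
                        error = function(e) NULL)
        if (!is.null(out)) cbind(response = resp, out)
      })
      lm_rows <- lm_rows[!vapply(lm_rows, is.null, TRUE)]
      if (length(lm_rows)) emit_csv(do.call(rbind, lm_rows), "diversity_lm.csv")

      if (!is.null(assignment)) {
        is_host <- setNames(dataset$trees$is_host, dataset$trees$tree_id)
        glm_rows <- list(); pca_rows <- list()
        for (sub in c("all", "hosts")) {
          pca <- tryCatch(pattern_pca(assignment, sub, is_host = is_host),
                          error = function(e) { log("  pattern PCA (%s) skipped: %s",
                                                    sub, conditionMessage(e)); NULL })
          if (is.null(pca)) next
          pca_rows[[sub]] <- data.frame(subset = sub,
                                        pct_variance = pca$pct_variance,
                                        t(pca$loadings))
          tr <- dataset$trees[match(names(pca$scores), dataset$trees$tree_id), ]
          res <- if (sub == "all")
            score_glm(tr$a_total, pca$scores, "poisson")
          else
            score_glm(cbind(tr$a_trunk, tr$a_branch), pca$scores, "binomial")
          glm_rows[[sub]] <- data.frame(
            response = if (sub == "all") "abund" else "dist", subset = sub,
            chi2 = res$chi2, df = res$df, p = res$p, slope = res$slope,
            r2 = res$r2)
        }
        if (length(pca_rows)) emit_csv(do.call(rbind, pca_rows), "pca.csv")
        if (length(glm_rows)) emit_csv(do.call(rbind, glm_rows), "glm.csv")
        emit_csv(assignment_crosstab_tests(assignment), "crosstabs.csv")
      } else log("  association pattern stages skipped: no trait tree run")
    })
    finish()
  }, error = function(e) {
    log("pipeline aborted: %s", conditionMessage(e))
    finish()
    stop(e)
  })
  invisible(result)
}
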