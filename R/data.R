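#' Default trait kinds for the standard host-tree trait set
#'
#' Trait kinds are always declared, never inferred from the data: silently
#' treating a categorical trait such as bark type as quantitative would
#' corrupt every downstream analysis. This helper returns the declaration
#' for the canonical trait set used in atmospheric-bromeliad host surveys.
#'
#' @return named character vector mapping trait name to one of
#'   `"categorical"`, `"binary"`, `"quantitative"`.
#' @export
default_trait_kinds <- function() {
  c(deciduousness = "categorical",
    bark          = "categorical",
    peeling       = "binary",
    light_guild   = "categorical",
    thorns        = "binary",
    needles       = "binary")
}

tree_level_columns <- function() {
  c("tree_id", "patch", "plot", "species", "dbh", "height", "lai")
}

#' Read a species-by-trait table
#'
#' @param path CSV file; first column `species`, remaining columns traits.
#' @param kinds named character vector declaring each trait's kind
#'   (`categorical`, `binary` or `quantitative`); see [default_trait_kinds()].
#' @return data.frame of traits (row names = species) with a `kinds`
#'   attribute. Categorical traits become factors whose level order is the
#'   order of first appearance in the file, so dummy coding and split
#'   ordering are deterministic.
#' @export
read_traits <- function(path, kinds = default_trait_kinds()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(raw, "species", "traits table")
  if (anyDuplicated(raw$species))
    stop("duplicate species in traits table: ",
         paste(unique(raw$species[duplicated(raw$species)]), collapse = ", "))
  traits <- raw[setdiff(names(raw), "species")]
  rownames(traits) <- raw$species
  unknown <- setdiff(names(traits), names(kinds))
  if (length(unknown))
    stop("trait kind not declared for: ", paste(unknown, collapse = ", "))
  as_trait_table(traits, kinds[names(traits)])
}

as_trait_table <- function(traits, kinds) {
  for (tr in names(traits)) {
    if (anyNA(traits[[tr]]))
      stop("missing value in trait '", tr, "'; missing traits are an error")
    traits[[tr]] <- switch(kinds[[tr]],
      categorical = factor(traits[[tr]], levels = unique(as.character(traits[[tr]]))),
      binary = {
        v <- traits[[tr]]
        if (is.character(v)) v <- v %in% c("TRUE", "true", "yes", "1")
        as.logical(v)
      },
      quantitative = as.numeric(traits[[tr]]),
      stop("unknown trait kind '", kinds[[tr]], "' for trait '", tr, "'"))
  }
  structure(traits, kinds = kinds)
}

count_columns <- function(nms) {
  trunk <- grep("_trunk$", nms, value = TRUE)
  branch <- grep("_branch$", nms, value = TRUE)
  epi_t <- sub("_trunk$", "", trunk)
  epi_b <- sub("_branch$", "", branch)
  if (!setequal(epi_t, epi_b))
    stop("unpaired trunk/branch count columns: ",
         paste(union(setdiff(epi_t, epi_b), setdiff(epi_b, epi_t)), collapse = ", "))
  epi_t[order(match(epi_t, sub("_trunk$", "", nms)))]
}

#' Read and validate a host-tree census dataset
#'
#' Reads the three files a survey produces -- a tree-individual table, a
#' species-by-trait table and a host-species phylogeny -- cross-validates
#' them, and computes the derived per-tree quantities: total bromeliad
#' abundance (`ab_abund`), trunk count (`a_trunk`) and the trunk share
#' `ab_dst = a_trunk / a_total` (NA for trees hosting nothing).
#'
#' The tree table must contain `tree_id`, `patch`, `plot`, `species`,
#' `dbh`, `height`, `lai` plus one `<epiphyte>_trunk` / `<epiphyte>_branch`
#' column pair per epiphyte species. A YAML sidecar config may rename
#' incoming columns (`columns:`) and declare trait kinds (`trait_kinds:`).
#'
#' @param trees_path CSV of tree individuals.
#' @param traits_path CSV of species-level traits.
#' @param phylo_path Newick file with branch lengths.
#' @param config optional list or path to a YAML file.
#' @return an object of class `epihost_dataset` with components `trees`
#'   (per-tree data.frame), `counts` (list of trunk and branch matrices,
#'   trees x epiphyte species), `traits`, `phylo` and `epiphytes`.
#' @export
read_dataset <- function(trees_path, traits_path, phylo_path, config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kinds <- unlist(config$trait_kinds) %||% default_trait_kinds()
  trees <- read.csv(trees_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(config$columns)) {
    m <- unlist(config$columns)
    names(trees)[match(m, names(trees))] <- names(m)[m %in% names(trees)]
  }
  assert_columns(trees, tree_level_columns(), "tree table")
  traits <- read_traits(traits_path, kinds)
  phylo <- ape::read.tree(phylo_path)
  build_dataset(trees, traits, phylo)
}

build_dataset <- function(trees, traits, phylo) {
  assert_columns(trees, tree_level_columns(), "tree table")
  trees$tree_id <- as.character(trees$tree_id)
  if (anyDuplicated(trees$tree_id))
    stop("duplicate tree_id: ",
         paste(unique(trees$tree_id[duplicated(trees$tree_id)]), collapse = ", "))
  epi <- count_columns(names(trees))
  if (!length(epi)) stop("tree table has no *_trunk/*_branch count columns")
  trunk <- as.matrix(trees[paste0(epi, "_trunk")])
  branch <- as.matrix(trees[paste0(epi, "_branch")])
  colnames(trunk) <- colnames(branch) <- epi
  rownames(trunk) <- rownames(branch) <- trees$tree_id
  for (m in list(trunk, branch)) {
    if (anyNA(m) || any(m < 0)) stop("negative or missing epiphyte count")
    if (any(m != round(m))) stop("non-integer epiphyte count")
  }

  no_trait <- setdiff(trees$species, rownames(traits))
  if (length(no_trait))
    stop("species present in tree table but absent from traits: ",
         paste(no_trait, collapse = ", "))
  no_tip <- setdiff(trees$species, phylo$tip.label)
  if (length(no_tip))
    stop("species present in tree table but absent from phylogeny: ",
         paste(no_tip, collapse = ", "))
  if (anyDuplicated(phylo$tip.label)) stop("duplicate phylogeny tip labels")
  if (!is.null(phylo$edge.length) && any(phylo$edge.length < 0))
    stop("negative branch length in phylogeny")

  core <- trees[tree_level_columns()]
  if (any(!is.finite(core$dbh)) || any(core$dbh <= 0)) stop("dbh must be > 0")
  if (any(!is.finite(core$height)) || any(core$height <= 0)) stop("height must be > 0")
  if (any(!is.finite(core$lai)) || any(core$lai < 0)) stop("lai must be >= 0")
  core$patch <- factor(core$patch, levels = unique(core$patch))
  core$plot <- factor(core$plot, levels = unique(core$plot))
  core$a_trunk <- as.integer(rowSums(trunk))
  core$a_branch <- as.integer(rowSums(branch))
  core$a_total <- core$a_trunk + core$a_branch
  core$ab_abund <- core$a_total
  core$is_host <- core$a_total > 0L
  core$ab_dst <- ifelse(core$is_host, core$a_trunk / core$a_total, NA_real_)

  structure(list(trees = core,
                 counts = list(trunk = trunk, branch = branch),
                 traits = traits, phylo = phylo, epiphytes = epi),
            class = "epihost_dataset")
}

#' @export
print.epihost_dataset <- function(x, ...) {
  cat("Host-tree census dataset\n")
  cat(sprintf("  %d trees (%d hosts) in %d patches / %d plots\n",
              nrow(x$trees), sum(x$trees$is_host),
              nlevels(x$trees$patch), nlevels(x$trees$plot)))
  cat(sprintf("  %d tree species, %d epiphyte species, %d bromeliad individuals\n",
              length(unique(x$trees$species)), length(x$epiphytes),
              sum(x$trees$a_total)))
  invisible(x)
}

#' Per-tree records with species traits merged in
#'
#' @param dataset an `epihost_dataset`.
#' @param hosts_only keep only trees with at least one bromeliad.
#' @return data.frame, one row per tree, tree-level fields plus the species
#'   traits and the derived abundance/distribution columns.
#' @export
records <- function(dataset, hosts_only = FALSE) {
  stopifnot(inherits(dataset, "epihost_dataset"))
  out <- cbind(dataset$trees,
               dataset$traits[dataset$trees$species, , drop = FALSE])
  rownames(out) <- out$tree_id
  if (hosts_only) out <- out[out$is_host, , drop = FALSE]
  out
}

#' Write a dataset back to its on-disk form
#'
#' Inverse of [read_dataset()]: writes `trees.csv`, `traits.csv`,
#' `phylogeny.nwk` and `config.yaml` (trait kinds and categorical level
#' orders) into `dir`. Reading the result back reproduces every cell.
#'
#' @param dataset an `epihost_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "epihost_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trees <- dataset$trees[tree_level_columns()]
  trunk <- dataset$counts$trunk
  branch <- dataset$counts$branch
  colnames(trunk) <- paste0(dataset$epiphytes, "_trunk")
  colnames(branch) <- paste0(dataset$epiphytes, "_branch")
  inter <- as.data.frame(cbind(trunk, branch))[
    as.vector(rbind(colnames(trunk), colnames(branch)))]
  paths <- c(trees = file.path(dir, "trees.csv"),
             traits = file.path(dir, "traits.csv"),
             phylo = file.path(dir, "phylogeny.nwk"),
             config = file.path(dir, "config.yaml"))
  write.csv(cbind(trees, inter), paths[["trees"]], row.names = FALSE)
  tt <- dataset$traits
  out_tt <- cbind(species = rownames(tt), as.data.frame(lapply(tt, as.character)))
  write.csv(out_tt, paths[["traits"]], row.names = FALSE)
  ape::write.tree(dataset$phylo, paths[["phylo"]])
  kinds <- attr(dataset$traits, "kinds")
  lvls <- lapply(tt[kinds[names(tt)] == "categorical"], levels)
  yaml::write_yaml(list(trait_kinds = as.list(kinds), levels = lvls),
                   paths[["config"]])
  invisible(paths)
}

#' Build a samples-by-species community matrix from tree records
#'
#' @param dataset an `epihost_dataset`.
#' @param sample_by aggregate rows by `"plot"` or `"patch"`.
#' @param count_of `"host_tree_species"` -- columns are tree species, cells
#'   are the summed bromeliad abundance carried by that species in the
#'   sample (every tree species in the dataset gets a column, even if it
#'   hosts nothing anywhere); `"epiphyte_species"` -- columns are bromeliad
#'   species, cells their summed abundance in the sample.
#' @return integer matrix with sample row names and species column names
#'   (column order deterministic: first appearance for tree species, count
#'   column order for epiphytes).
#' @export
community_from_records <- function(dataset,
                                   sample_by = c("plot", "patch"),
                                   count_of = c("host_tree_species",
                                                "epiphyte_species")) {
  stopifnot(inherits(dataset, "epihost_dataset"))
  sample_by <- match.arg(sample_by)
  count_of <- match.arg(count_of)
  tr <- dataset$trees
  if (!nrow(tr)) stop("dataset has no tree records")
  samples <- levels(tr[[sample_by]])
  if (count_of == "host_tree_species") {
    species <- unique(tr$species)
    m <- matrix(0L, length(samples), length(species),
                dimnames = list(samples, species))
    tot <- tapply(tr$a_total, list(tr[[sample_by]], factor(tr$species, species)),
                  sum, default = 0L)
    m[rownames(tot), colnames(tot)] <- tot
  } else {
    per <- dataset$counts$trunk + dataset$counts$branch
    m <- matrix(0L, length(samples), ncol(per),
                dimnames = list(samples, colnames(per)))
    rs <- rowsum(per, as.character(tr[[sample_by]]))
    m[rownames(rs), ] <- rs
  }
  storage.mode(m) <- "integer"
  m
}
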