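# fixtures built in code: a 3-tree toy census, and a census reproducing the
# printed per-patch epiphyte abundance table shipped in extdata

toy_traits <- function() {
  as_trait_table(
    data.frame(deciduousness = c("deciduous", "evergreen"),
               bark = c("smooth", "grooved"),
               row.names = c("A", "B")),
    c(deciduousness = "categorical", bark = "categorical"))
}

toy_phylo <- function() ape::read.tree(text = "(A:1,B:1);")

# counts per tree: (trunk, branch) = (2,0), (0,0), (1,4)
toy_trees <- function() {
  data.frame(tree_id = c("t1", "t2", "t3"),
             patch = "P1", plot = c("p1", "p1", "p2"),
             species = c("A", "B", "A"),
             dbh = c(10, 20, 30), height = c(5, 6, 7), lai = 1.2,
             e1_trunk = c(2L, 0L, 1L), e1_branch = c(0L, 0L, 3L),
             e2_trunk = c(0L, 0L, 0L), e2_branch = c(0L, 0L, 1L))
}

toy_dataset <- function() {
  epihost:::build_dataset(toy_trees(), toy_traits(), toy_phylo())
}

write_toy_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(toy_trees(), file.path(dir, "trees.csv"), row.names = FALSE)
  tt <- toy_traits()
  write.csv(cbind(species = rownames(tt), as.data.frame(lapply(tt, as.character))),
            file.path(dir, "traits.csv"), row.names = FALSE)
  ape::write.tree(toy_phylo(), file.path(dir, "phylogeny.nwk"))
  list(trees = file.path(dir, "trees.csv"),
       traits = file.path(dir, "traits.csv"),
       phylo = file.path(dir, "phylogeny.nwk"),
       config = list(trait_kinds = list(deciduousness = "categorical",
                                        bark = "categorical")))
}

patch_table_path <- function() {
  system.file("extdata", "patch_abundance_table.csv", package = "epihost")
}

# expand the printed patch x epiphyte abundance table into a tree-level
# census: each patch gets two host trees per species pair, counts split
# deterministically, so patch totals reproduce the printed table exactly
table_like_dataset <- function() {
  tab <- read.csv(patch_table_path(), check.names = FALSE)
  epi <- names(tab)[-1]
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (t in 1:2) {
      row <- list(tree_id = sprintf("%s_t%d", tab$patch[i], t),
                  patch = tab$patch[i], plot = paste0(tab$patch[i], "_p1"),
                  species = if (t == 1) "A" else "B",
                  dbh = 30, height = 8, lai = 1.5)
      for (e in epi) {
        k <- tab[[e]][i]
        share <- if (t == 1) k %/% 2 else k - k %/% 2
        row[[paste0(e, "_trunk")]] <- share %/% 2
        row[[paste0(e, "_branch")]] <- share - share %/% 2
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  epihost:::build_dataset(do.call(rbind, rows), toy_traits(), toy_phylo())
}
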