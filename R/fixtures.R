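#' Bundled 33-clone genome-size summary and companion tree
#'
#' The published summary of haploid ("1C") genome sizes for 33 clones of the
#' Brachionus plicatilis cryptic species complex: 12 species (labels
#' S.1-S.12), three major clades (A, B, C), and per clone the mean genome
#' size in Mbp, its s.e.m. and the number of flow-cytometry replicates.
#'
#' The companion tree (`inst/extdata/fixture_tree_approx.nwk`) honors the
#' clade and species grouping of the summary but is approximate below the
#' species level: within-species topology is an arbitrary ladder and all
#' branch lengths are 1, because the within-species structure is not
#' recoverable from the published material. Analyses that depend only on the
#' clade/species/clone labels (variance components, species means, ploidy
#' fits) are unaffected; tree-based analyses on this fixture are exercises of
#' the machinery, not reproductions.
#'
#' @return list with elements `table` (data.frame: clade, species,
#'   species_name, clone, mean_mbp, sem, n) and `tree` (a 33-tip bifurcating
#'   `phylo`, tips = clone labels).
#' @export
#' @examples
#' fx <- table1Fixture()
#' nrow(fx$table)                       # 33 clones
#' length(unique(fx$table$species))     # 12 species
table1Fixture <- function() {
  tsv <- system.file("extdata", "table1_genome_sizes.tsv",
                     package = "BrachioGS", mustWork = TRUE)
  nwk <- system.file("extdata", "fixture_tree_approx.nwk",
                     package = "BrachioGS", mustWork = TRUE)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  tab$species_name[is.na(tab$species_name)] <- ""
  tree <- parseNewick(file = nwk)
  stopifnot(setequal(tree$tip.label, tab$clone))
  list(table = tab, tree = tree)
}
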