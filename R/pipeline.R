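# End-to-end orchestration of the comparative analysis: log-transform,
# serial-independence tests before and after contrasts, raw and contrast
# correlations, optional taxon exclusion, and report rendering.

#' Run the comparative genome-size workflow
#'
#' Executes, in order: natural-log transform of the traits; a test for
#' serial independence (TFSI) on the tip data of every trait; Felsenstein's
#' independent contrasts per trait; a second TFSI on the contrasts (to check
#' that phylogenetic autocorrelation has been removed); Pearson correlation
#' of the first trait against each remaining trait on the ln tip data; and
#' the through-origin correlation of the corresponding contrast sets. When
#' `excludeTaxa` is non-empty the whole block is repeated on the pruned tree
#' (branch lengths preserved), mirroring the exclusion of a lineage whose
#' trait evolution deviates strongly from Brownian motion.
#'
#' @param tree a `phylo`; polytomies are resolved internally for the
#'   contrast stages.
#' @param traits data.frame with `tip_label` plus one column per trait
#'   (strictly positive raw values; the first column is the focal trait,
#'   e.g. genome size).
#' @param excludeTaxa tip labels to exclude in the reduced block.
#' @param nRotations,nPermutations TFSI settings (see [tfsiTest()]).
#' @param seed master seed; all per-test seeds derive from it.
#' @param zeroBranchPolicy passed to [computeContrasts()].
#' @return an [AnalysisReport-class] object.
#' @export
runComparativeWorkflow <- function(tree, traits, excludeTaxa = character(),
                                   nRotations = 1000L, nPermutations = 999L,
                                   seed,
                                   zeroBranchPolicy = "epsilon") {
  stopIfNot(!missing(seed), "a seed is mandatory")
  validatePhylogeny(tree)
  stopIfNot("tip_label" %in% names(traits),
            "trait table must have a `tip_label` column")
  traitNames <- setdiff(names(traits), "tip_label")
  stopIfNot(length(traitNames) >= 1L, "no trait columns found")
  extra <- setdiff(tree$tip.label, traits$tip_label)
  if (length(extra))
    stop("no trait row for tip(s): ", paste(extra, collapse = ", "),
         call. = FALSE)

  lnT <- traits
  for (tn in traitNames) {
    bad <- !is.finite(traits[[tn]]) | traits[[tn]] <= 0
    if (any(bad))
      stop("cannot ln-transform trait ", sQuote(tn), ": non-positive value ",
           "in row(s) ", paste(traits$tip_label[bad], collapse = ", "),
           call. = FALSE)
    lnT[[tn]] <- log(traits[[tn]])
  }

  full <- analyzeBlock(tree, lnT, traitNames, nRotations, nPermutations,
                       deriveSeed(seed, 100L), zeroBranchPolicy)

  reduced <- list()
  if (length(excludeTaxa)) {
    absent <- setdiff(excludeTaxa, tree$tip.label)
    if (length(absent))
      warning("excluded taxa not in tree: ", paste(absent, collapse = ", "),
              call. = FALSE)
    keepTree <- ape::drop.tip(tree, intersect(excludeTaxa, tree$tip.label))
    if (is.null(keepTree) || ape::Ntip(keepTree) < 3L)
      stop("fewer than 3 tips remain after exclusion", call. = FALSE)
    reduced <- analyzeBlock(keepTree,
                            lnT[!lnT$tip_label %in% excludeTaxa, ],
                            traitNames, nRotations, nPermutations,
                            deriveSeed(seed, 200L), zeroBranchPolicy)
  }

  new("AnalysisReport",
      full = full, reduced = reduced,
      excludedTaxa = as.character(excludeTaxa), traits = traitNames,
      seed = as.integer(seed),
      params = list(nRotations = nRotations, nPermutations = nPermutations,
                    zeroBranchPolicy = zeroBranchPolicy))
}

# one analysis block: TFSI tips -> PIC -> TFSI contrasts -> correlations
analyzeBlock <- function(tree, lnT, traitNames, nRotations, nPermutations,
                         seedBase, zeroBranchPolicy) {
  btree <- if (isBifurcating(tree)) tree else resolvePolytomies(tree)
  tfsiTips <- list(); contrastSets <- list(); tfsiContrasts <- list()
  for (i in seq_along(traitNames)) {
    tn <- traitNames[i]
    vals <- stats::setNames(lnT[[tn]], lnT$tip_label)
    tfsiTips[[tn]] <- tfsiTest(tree, vals, "tips", nRotations, nPermutations,
                               seed = deriveSeed(seedBase, 2L * i))
    contrastSets[[tn]] <- computeContrasts(btree, vals, trait = tn,
                                           zeroBranchPolicy = zeroBranchPolicy)
    tfsiContrasts[[tn]] <- tfsiTest(btree, contrastSets[[tn]], "contrasts",
                                    nRotations, nPermutations,
                                    seed = deriveSeed(seedBase, 2L * i + 1L))
  }
  rawCor <- picCor <- NULL
  if (length(traitNames) >= 2L) {
    focal <- traitNames[1L]
    rows <- lapply(traitNames[-1L], function(tn) {
      ct <- stats::cor.test(lnT[[focal]], lnT[[tn]])
      data.frame(pair = paste(focal, "vs", tn), r = unname(ct$estimate),
                 p = ct$p.value, n = nrow(lnT))
    })
    rawCor <- do.call(rbind, rows)
    rows <- lapply(traitNames[-1L], function(tn) {
      pc <- picCorrelation(contrastSets[[focal]], contrastSets[[tn]])
      data.frame(pair = paste(focal, "vs", tn), r = pc$r, p = pc$p, n = pc$n)
    })
    picCor <- do.call(rbind, rows)
  }
  list(tipLabels = tree$tip.label, tfsiTips = tfsiTips,
       contrastSets = contrastSets, tfsiContrasts = tfsiContrasts,
       rawCor = rawCor, picCor = picCor)
}

#' Run the variance-component workflow
#'
#' Accepts either replicate-level data (columns `clade`, `species`, `clone`,
#' `value`) or a published-style summary (columns `clade`, `species`,
#' `clone`, `mean`/`mean_mbp`, `sem`, `n`), in which case replicates are
#' first reconstructed with [reconstructReplicates()]. Values are
#' ln-transformed by default: on the log scale the percentage shares are
#' invariant to the measurement unit (pg vs Mbp shift the values by an
#' additive constant only).
#'
#' @param table the data (see above).
#' @param scale `"ln"` (default) or `"raw"`.
#' @return a [VarCompResult-class] object.
#' @export
#' @examples
#' fx <- table1Fixture()
#' vc <- runVarcompWorkflow(fx$table)
#' varPercentages(vc, rounded = TRUE)
runVarcompWorkflow <- function(table, scale = c("ln", "raw")) {
  scale <- match.arg(scale)
  stopIfNot(all(c("clade", "species", "clone") %in% names(table)),
            "table needs clade, species, clone columns")
  if ("value" %in% names(table)) {
    d <- table[, c("clade", "species", "clone", "value")]
  } else {
    mcol <- intersect(c("mean", "mean_mbp"), names(table))[1]
    stopIfNot(!is.na(mcol) && all(c("sem", "n") %in% names(table)),
              "summary table needs mean (or mean_mbp), sem and n columns")
    d <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
      data.frame(clade = table$clade[i], species = table$species[i],
                 clone = table$clone[i],
                 value = reconstructReplicates(table[[mcol]][i],
                                               table$sem[i], table$n[i]))
    }))
  }
  if (scale == "ln") {
    stopIfNot(all(d$value > 0), "ln scale requires strictly positive values")
    d$value <- log(d$value)
  }
  res <- fitNestedReml(d)
  res@scale <- scale
  res
}

#' Render an analysis report
#'
#' Deterministic serialization of an [AnalysisReport-class]: the same report
#' renders to byte-identical output. JSON carries the full structure
#' (statistics, p-values, seeds, counts); markdown lays the
#' serial-independence p-values and the correlation tables out in the shape
#' of the published tables; TSV writes the correlation tables.
#'
#' @param report an [AnalysisReport-class].
#' @param format `"json"`, `"tsv"` or `"markdown"`.
#' @param file output path.
#' @return the output path, invisibly.
#' @export
renderReport <- function(report, format = c("json", "tsv", "markdown"), file) {
  format <- match.arg(format)
  blocks <- list(full = report@full)
  if (length(report@reduced)) blocks$reduced <- report@reduced
  if (format == "json") {
    out <- list(
      traits = report@traits, seed = report@seed, params = report@params,
      excluded_taxa = report@excludedTaxa,
      blocks = lapply(blocks, blockAsList)
    )
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else if (format == "tsv") {
    rows <- do.call(rbind, lapply(names(blocks), function(bn) {
      b <- blocks[[bn]]
      rbind(
        if (!is.null(b$rawCor)) cbind(dataset = bn, kind = "raw", b$rawCor),
        if (!is.null(b$picCor)) cbind(dataset = bn, kind = "PIC", b$picCor)
      )
    }))
    utils::write.table(rows, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("# Comparative analysis report", "",
               paste0("Traits: ", paste(report@traits, collapse = ", "),
                      "; seed ", report@seed), "")
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      lines <- c(lines, paste0("## ", bn, " dataset (", length(b$tipLabels),
                               " tips)"), "",
                 "P-values of the tests for serial independence", "",
                 paste0("| | ", paste(report@traits, collapse = " | "), " |"),
                 paste0("|", paste(rep("---", length(report@traits) + 1),
                                   collapse = "|"), "|"),
                 paste0("| tip data | ",
                        paste(vapply(report@traits, function(tn)
                          format(pValue(b$tfsiTips[[tn]]), digits = 3),
                          character(1)), collapse = " | "), " |"),
                 paste0("| contrasts | ",
                        paste(vapply(report@traits, function(tn)
                          format(pValue(b$tfsiContrasts[[tn]]), digits = 3),
                          character(1)), collapse = " | "), " |"), "")
      if (!is.null(b$rawCor)) {
        lines <- c(lines, "Correlations", "",
                   "| pair | kind | r | p | n |", "|---|---|---|---|---|")
        for (i in seq_len(nrow(b$rawCor)))
          lines <- c(lines, sprintf("| %s | raw | %.3f | %.4g | %d |",
                                    b$rawCor$pair[i], b$rawCor$r[i],
                                    b$rawCor$p[i], b$rawCor$n[i]))
        for (i in seq_len(nrow(b$picCor)))
          lines <- c(lines, sprintf("| %s | PIC | %.3f | %.4g | %d |",
                                    b$picCor$pair[i], b$picCor$r[i],
                                    b$picCor$p[i], b$picCor$n[i]))
        lines <- c(lines, "")
      }
    }
    writeLines(lines, file)
  }
  invisible(file)
}

blockAsList <- function(b) {
  tfsiAsList <- function(x) list(statistic = testStatistic(x),
                                 p_value = pValue(x),
                                 n_rotations = x@nRotations,
                                 n_permutations = x@nPermutations,
                                 seed = x@seed, mode = x@mode)
  list(
    n_tips = length(b$tipLabels),
    tip_labels = b$tipLabels,
    tfsi_tips = lapply(b$tfsiTips, tfsiAsList),
    tfsi_contrasts = lapply(b$tfsiContrasts, tfsiAsList),
    raw_correlations = b$rawCor,
    pic_correlations = b$picCor
  )
}
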