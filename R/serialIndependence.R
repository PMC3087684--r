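#' First-order von Neumann serial ratio
#'
#' The statistic of the test for serial independence:
#' \deqn{\eta = \sum_i (x_{i+1} - x_i)^2 / \sum_i (x_i - \bar x)^2.}
#' Under serial independence \eqn{\eta} is close to 2; positive serial
#' (here: phylogenetic) autocorrelation of adjacent values pushes it toward
#' zero. The statistic is invariant to affine transforms of the values.
#'
#' @param x numeric vector (length >= 3, not all equal) in sequence order.
#' @return the ratio (a single number).
#' @export
#' @examples
#' vonNeumannRatio(c(1, 2, 3))               # 1
#' vonNeumannRatio(c(1, -1, 1, -1, 1, -1))   # 10/3, alternation maximizes it
vonNeumannRatio <- function(x) {
  stopIfNot(length(x) >= 3L, "need at least 3 ordered values")
  den <- sum((x - mean(x))^2)
  if (den == 0) stop("zero variance: all values equal", call. = FALSE)
  sum(diff(x)^2) / den
}

#' Abouheif's test for serial independence (TFSI)
#'
#' Randomization test for phylogenetic autocorrelation. The observed
#' statistic is the von Neumann ratio of the trait along the tree's tip
#' order, averaged over `nRotations` random rotations (independent reversal
#' of each internal node's child order with probability 1/2) — rotation
#' averaging removes the arbitrariness of the tip ordering. The null
#' distribution permutes the values across tips and recomputes the same
#' rotation-averaged statistic (the rotation set is drawn once and shared by
#' the observed statistic and all permutation replicates). The p-value is
#' one-tailed toward positive autocorrelation (observed ratio below the
#' null), with the +1 permutation correction, so p is never exactly 0.
#'
#' In `"contrasts"` mode the values are standardized contrasts attached to
#' internal nodes, ordered by the rotated traversal of internal nodes.
#' Contrast signs follow an arbitrary child-order convention, so each
#' rotation replicate additionally re-randomizes every contrast's sign with
#' probability 1/2, which removes the sign-convention artifact.
#'
#' @param tree a `phylo` object.
#' @param values named numeric vector (tip label -> value) in `"tips"` mode,
#'   or a [ContrastSet-class] in `"contrasts"` mode.
#' @param mode `"tips"` or `"contrasts"`.
#' @param nRotations rotations averaged per statistic (default 1000).
#' @param nPermutations permutation replicates (default 999).
#' @param seed integer seed; drives every random draw in the test.
#' @return a [TFSIResult-class] object.
#' @export
#' @examples
#' tr <- starTree(letters[1:8])
#' set.seed(1)
#' tfsiTest(tr, setNames(rnorm(8), letters[1:8]), "tips",
#'          nRotations = 50, nPermutations = 99, seed = 1)
tfsiTest <- function(tree, values, mode = c("tips", "contrasts"),
                     nRotations = 1000L, nPermutations = 999L, seed) {
  mode <- match.arg(mode)
  validatePhylogeny(tree)
  stopIfNot(!missing(seed), "a seed is mandatory")
  ntip <- ape::Ntip(tree)
  ch <- childrenList(tree)

  if (mode == "tips") {
    stopIfNot(ntip >= 3L, "too few observations: need at least 3 tips")
    if (is.data.frame(values)) {
      stopIfNot(ncol(values) == 2L && "tip_label" %in% names(values),
                "pass a named vector or a 2-column trait table")
      values <- stats::setNames(values[[setdiff(names(values), "tip_label")]],
                                values$tip_label)
    }
    missing <- setdiff(tree$tip.label, names(values))
    if (length(missing))
      stop("no value for tip(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    vals <- as.numeric(values[tree$tip.label])   # indexed by tip number
    itemOf <- function(nodeSeq) nodeSeq[nodeSeq <= ntip]
  } else {
    stopIfNot(is(values, "ContrastSet"),
              "contrasts mode expects a ContrastSet")
    stopIfNot(identical(values@tipLabels, tree$tip.label),
              "ContrastSet does not belong to this tree")
    stopIfNot(nContrasts(values) >= 3L,
              "too few observations: need at least 3 contrasts")
    vals <- values@contrast
    nodeIdx <- integer(ntip + tree$Nnode)
    nodeIdx[values@node] <- seq_along(values@node)
    itemOf <- function(nodeSeq) nodeIdx[nodeSeq[nodeSeq > ntip]]
  }
  if (sum((vals - mean(vals))^2) == 0)
    stop("zero variance: all values equal", call. = FALSE)

  n <- length(vals)
  set.seed(seed)
  ntot <- ntip + tree$Nnode
  # shared rotation set: nRotations tip (or internal-node) orderings
  ord <- matrix(0L, nRotations, n)
  for (r in seq_len(nRotations)) {
    flip <- rep(FALSE, ntot)
    flip[(ntip + 1L):ntot] <- stats::runif(tree$Nnode) < 0.5
    ord[r, ] <- itemOf(dfsNodes(tree, flip, ch))
  }
  signs <- if (mode == "contrasts")
    matrix(sample(c(-1, 1), nRotations * n, replace = TRUE), nRotations, n)
  else NULL

  rotStat <- function(v) {
    V <- matrix(v[ord], nrow = nRotations)   # elementwise lookup keeps shape
    if (!is.null(signs)) V <- V * signs
    num <- rowSums((V[, -1L, drop = FALSE] - V[, -n, drop = FALSE])^2)
    den <- rowSums((V - rowMeans(V))^2)
    mean(num / den)
  }

  observed <- rotStat(vals)
  nullStats <- vapply(seq_len(nPermutations),
                      function(b) rotStat(sample(vals)), numeric(1))
  p <- (1 + sum(nullStats <= observed)) / (nPermutations + 1)

  new("TFSIResult",
      statistic = observed, nullStatistics = nullStats, pValue = p,
      nRotations = as.integer(nRotations),
      nPermutations = as.integer(nPermutations),
      seed = as.integer(seed), mode = mode)
}
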