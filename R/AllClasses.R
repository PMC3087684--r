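#' @import methods
NULL

#' Standardized independent contrasts for one trait
#'
#' Container for Felsenstein's phylogenetically independent contrasts (PICs)
#' computed on a bifurcating tree: one standardized contrast per internal
#' node, together with the contrast variance (sum of adjusted child branch
#' lengths), the weighted ancestral state estimate and the adjusted branch
#' length of each internal node.
#'
#' @slot node integer, internal node numbers (ape numbering of the tree the
#'   contrasts were computed on).
#' @slot contrast numeric, standardized contrasts (difference of child values
#'   divided by the square root of the contrast variance).
#' @slot variance numeric, contrast variances (sums of adjusted child branch
#'   lengths, strictly positive).
#' @slot ancestorState numeric, weighted ancestral state estimates.
#' @slot adjustedLength numeric, branch length of each internal node after the
#'   pruning adjustment.
#' @slot trait character, name of the trait the contrasts belong to.
#' @slot tipLabels character, tip labels of the tree (for pairing checks).
#'
#' @seealso [computeContrasts()], [picCorrelation()]
#' @export
setClass("ContrastSet",
  representation(
    node = "integer",
    contrast = "numeric",
    variance = "numeric",
    ancestorState = "numeric",
    adjustedLength = "numeric",
    trait = "character",
    tipLabels = "character"
  )
)

setValidity("ContrastSet", function(object) {
  n <- length(object@contrast)
  msgs <- character()
  if (length(object@node) != n || length(object@variance) != n ||
      length(object@ancestorState) != n || length(object@adjustedLength) != n)
    msgs <- c(msgs, "slot lengths disagree")
  if (n != length(object@tipLabels) - 1L)
    msgs <- c(msgs, "a bifurcating tree yields exactly n_tips - 1 contrasts")
  if (any(!is.finite(object@variance)) || any(object@variance <= 0))
    msgs <- c(msgs, "contrast variances must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' Abouheif test-for-serial-independence result
#'
#' Result of the randomization test for phylogenetic autocorrelation: the
#' rotation-averaged first-order serial (von Neumann) statistic of the trait
#' along the tree's tip order, its permutation null distribution, and a
#' one-tailed p-value toward positive autocorrelation (small statistic).
#'
#' @slot statistic numeric, observed rotation-averaged von Neumann ratio.
#' @slot nullStatistics numeric, the permutation null values.
#' @slot pValue numeric in (0, 1], with the +1 permutation correction.
#' @slot nRotations integer, random rotations averaged per statistic.
#' @slot nPermutations integer, permutation replicates.
#' @slot seed integer, RNG seed the whole test was run under.
#' @slot mode character, `"tips"` or `"contrasts"`.
#'
#' @seealso [tfsiTest()], [vonNeumannRatio()]
#' @export
setClass("TFSIResult",
  representation(
    statistic = "numeric",
    nullStatistics = "numeric",
    pValue = "numeric",
    nRotations = "integer",
    nPermutations = "integer",
    seed = "integer",
    mode = "character"
  )
)

setValidity("TFSIResult", function(object) {
  msgs <- character()
  if (!object@mode %in% c("tips", "contrasts"))
    msgs <- c(msgs, "mode must be 'tips' or 'contrasts'")
  if (object@pValue <= 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  if (length(object@nullStatistics) != object@nPermutations)
    msgs <- c(msgs, "nullStatistics length must equal nPermutations")
  if (length(msgs)) msgs else TRUE
})

#' Nested variance-component estimates
#'
#' REML estimates of the four-level nested random-effects decomposition of a
#' trait (major clade / species within clade / clone within species /
#' residual among replicates), with unrounded percentage shares of the total.
#'
#' @slot components named numeric of length 4 (`clade`, `species`, `clone`,
#'   `residual`), all non-negative.
#' @slot percentages named numeric of length 4, unrounded shares of the total
#'   variance (NA when all components are zero).
#' @slot degenerate logical, TRUE when the total variance is zero (percentages
#'   undefined) or the design forced a component out of the model.
#' @slot scale character, `"ln"` or `"raw"` analysis scale.
#' @slot nObs integer, number of observations fitted.
#'
#' @seealso [fitNestedReml()], [componentPercentages()]
#' @export
setClass("VarCompResult",
  representation(
    components = "numeric",
    percentages = "numeric",
    degenerate = "logical",
    scale = "character",
    nObs = "integer"
  )
)

setValidity("VarCompResult", function(object) {
  msgs <- character()
  lv <- c("clade", "species", "clone", "residual")
  if (!identical(names(object@components), lv))
    msgs <- c(msgs, "components must be named clade/species/clone/residual")
  if (any(object@components < 0)) msgs <- c(msgs, "components must be >= 0")
  if (length(object@percentages) != 4L)
    msgs <- c(msgs, "percentages must have length 4")
  if (length(msgs)) msgs else TRUE
})

#' Ploidy-multiple (whole-genome duplication) fit
#'
#' Fit of a set of genome sizes as integer multiples of a common base size:
#' every size t gets the multiplier m_t = round(size_t / base) clamped at 1,
#' and the fit is scored by the mean absolute relative residual
#' (size_t - m_t base) / (m_t base).
#'
#' @slot baseSize numeric, the (fitted or fixed) base genome size.
#' @slot sizes numeric, the input genome sizes.
#' @slot multipliers integer, fitted ploidy multiples per size.
#' @slot relativeResiduals numeric, signed relative residuals per size.
#' @slot score numeric, mean absolute relative residual.
#' @slot labels character, taxon labels parallel to `sizes`.
#'
#' @seealso [fitPloidyMultiples()]
#' @export
setClass("PloidyFit",
  representation(
    baseSize = "numeric",
    sizes = "numeric",
    multipliers = "integer",
    relativeResiduals = "numeric",
    score = "numeric",
    labels = "character"
  )
)

setValidity("PloidyFit", function(object) {
  msgs <- character()
  n <- length(object@sizes)
  if (length(object@multipliers) != n || length(object@relativeResiduals) != n ||
      length(object@labels) != n)
    msgs <- c(msgs, "sizes, multipliers, relativeResiduals, labels must be parallel")
  if (any(object@multipliers < 1L)) msgs <- c(msgs, "multipliers must be >= 1")
  if (object@baseSize <= 0) msgs <- c(msgs, "baseSize must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Assembled comparative-analysis report
#'
#' End-to-end result of the comparative workflow: per-trait serial-independence
#' tests on tip data and on contrasts, raw Pearson and through-origin contrast
#' correlations of genome size against the morphometric traits, on the full
#' tree and (when taxa are excluded) on the pruned tree.
#'
#' @slot full list, results on the full data set (see [runComparativeWorkflow()]).
#' @slot reduced list, results after taxon exclusion (empty when no exclusion).
#' @slot excludedTaxa character, tip labels excluded in the reduced block.
#' @slot traits character, trait names analyzed (ln scale).
#' @slot seed integer, master seed.
#' @slot params list, workflow settings (rotation/permutation counts, policy).
#'
#' @seealso [runComparativeWorkflow()], [renderReport()]
#' @export
setClass("AnalysisReport",
  representation(
    full = "list",
    reduced = "list",
    excludedTaxa = "character",
    traits = "character",
    seed = "integer",
    params = "list"
  )
)
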