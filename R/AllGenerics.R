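#' @describeIn ContrastSet number of contrasts (one per internal node).
#' @param object a `ContrastSet`, `TFSIResult`, `VarCompResult` or `PloidyFit`.
#' @export
setGeneric("nContrasts", function(object) standardGeneric("nContrasts"))

#' @describeIn ContrastSet the standardized contrast values.
#' @export
setGeneric("contrastValues", function(object) standardGeneric("contrastValues"))

#' @describeIn ContrastSet the contrast variances.
#' @export
setGeneric("contrastVariances", function(object) standardGeneric("contrastVariances"))

#' @describeIn TFSIResult the observed rotation-averaged statistic.
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @describeIn TFSIResult the permutation p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @describeIn TFSIResult the permutation null distribution.
#' @export
setGeneric("nullDistribution", function(object) standardGeneric("nullDistribution"))

#' @describeIn VarCompResult the four variance components.
#' @export
setGeneric("varComponents", function(object) standardGeneric("varComponents"))

#' @describeIn VarCompResult percentage shares of total variance.
#' @param rounded logical, round to whole percent (half away from zero)?
#' @export
setGeneric("varPercentages", function(object, rounded = FALSE) standardGeneric("varPercentages"))

#' @describeIn PloidyFit the fitted (or fixed) base genome size.
#' @export
setGeneric("ploidyBase", function(object) standardGeneric("ploidyBase"))

#' @describeIn PloidyFit the integer ploidy multipliers.
#' @export
setGeneric("ploidyMultipliers", function(object) standardGeneric("ploidyMultipliers"))

#' @describeIn PloidyFit signed relative residuals of each size.
#' @export
setGeneric("ploidyResiduals", function(object) standardGeneric("ploidyResiduals"))

setMethod("nContrasts", "ContrastSet", function(object) length(object@contrast))
setMethod("contrastValues", "ContrastSet", function(object) {
  stats::setNames(object@contrast, object@node)
})
setMethod("contrastVariances", "ContrastSet", function(object) {
  stats::setNames(object@variance, object@node)
})

setMethod("testStatistic", "TFSIResult", function(object) object@statistic)
setMethod("pValue", "TFSIResult", function(object) object@pValue)
setMethod("nullDistribution", "TFSIResult", function(object) object@nullStatistics)

setMethod("varComponents", "VarCompResult", function(object) object@components)
setMethod("varPercentages", "VarCompResult", function(object, rounded = FALSE) {
  if (rounded) roundHalfAway(object@percentages) else object@percentages
})

setMethod("ploidyBase", "PloidyFit", function(object) object@baseSize)
setMethod("ploidyMultipliers", "PloidyFit", function(object) {
  stats::setNames(object@multipliers, object@labels)
})
setMethod("ploidyResiduals", "PloidyFit", function(object) {
  stats::setNames(object@relativeResiduals, object@labels)
})

setMethod("show", "ContrastSet", function(object) {
  cat("ContrastSet:", nContrasts(object), "standardized contrasts for trait",
      sQuote(object@trait), "\n")
  cat("  contrast range: [", format(min(object@contrast), digits = 4), ", ",
      format(max(object@contrast), digits = 4), "]\n", sep = "")
})

setMethod("show", "TFSIResult", function(object) {
  cat("Abouheif test for serial independence (", object@mode, " mode)\n", sep = "")
  cat("  rotation-averaged von Neumann ratio:", format(object@statistic, digits = 4), "\n")
  cat("  p =", format(object@pValue, digits = 4),
      sprintf("(%d rotations, %d permutations, seed %d)\n",
              object@nRotations, object@nPermutations, object@seed))
})

setMethod("show", "VarCompResult", function(object) {
  cat("Nested variance components (", object@scale, " scale, n = ",
      object@nObs, ")\n", sep = "")
  pct <- varPercentages(object, rounded = TRUE)
  for (i in seq_along(object@components)) {
    cat(sprintf("  %-9s %8.5f  %3s%%\n", names(object@components)[i],
                object@components[i],
                ifelse(is.na(pct[i]), "NA", format(pct[i]))))
  }
  if (object@degenerate) cat("  (degenerate fit: see ?fitNestedReml)\n")
})

setMethod("show", "PloidyFit", function(object) {
  cat("Ploidy-multiple fit: base =", format(object@baseSize, digits = 5),
      " score =", format(object@score, digits = 4), "\n")
  print(data.frame(label = object@labels, size = object@sizes,
                   multiplier = object@multipliers,
                   rel_residual = round(object@relativeResiduals, 4)))
})

setMethod("show", "AnalysisReport", function(object) {
  cat("Comparative analysis report (seed ", object@seed, ")\n", sep = "")
  cat("  traits:", paste(object@traits, collapse = ", "), "\n")
  cat("  tips (full):", length(object@full$tipLabels), "\n")
  if (length(object@excludedTaxa))
    cat("  excluded:", paste(object@excludedTaxa, collapse = ", "),
        "-> tips (reduced):", length(object@reduced$tipLabels), "\n")
})
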