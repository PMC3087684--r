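#' REML nested variance components
#'
#' Fits the four-level nested random-effects model
#' \deqn{y = \mu + a_{clade} + b_{species|clade} + c_{clone|species} + e}
#' by restricted maximum likelihood (the appropriate estimator for the
#' unbalanced sample sizes of the data set) and returns the four variance
#' components with their percentage shares of the total. Components are
#' constrained non-negative. The fit is delegated to \pkg{lme4}.
#'
#' Degenerate designs are handled explicitly: with a single clade (or a
#' single species per clade throughout) the corresponding component is not
#' identifiable, is dropped from the model, reported as 0, and a
#' reduced-model warning is raised. If all observations are equal, all four
#' components are 0 and the percentages are flagged undefined.
#'
#' @param data data.frame with columns `clade`, `species`, `clone`, `value`
#'   (one row per replicate measurement). Nesting must be consistent: each
#'   clone belongs to one species, each species to one clade.
#' @return a [VarCompResult-class] object.
#' @export
#' @examples
#' d <- simulateNestedDataset(design = c(3, 4, 3, 4),
#'                            components = c(0.175, 0.066, 0.019, 0.003),
#'                            grandMean = 5, seed = 1)
#' fitNestedReml(d)
fitNestedReml <- function(data) {
  need <- c("clade", "species", "clone", "value")
  stopIfNot(all(need %in% names(data)),
            "data needs columns clade, species, clone, value")
  stopIfNot(nrow(data) >= 2L, "need at least 2 observations")
  checkNesting(data)

  lv <- c("clade", "species", "clone", "residual")
  if (stats::var(data$value) == 0) {
    return(new("VarCompResult",
               components = stats::setNames(rep(0, 4), lv),
               percentages = stats::setNames(rep(NA_real_, 4), lv),
               degenerate = TRUE, scale = "as-given",
               nObs = nrow(data)))
  }

  d <- data.frame(value = data$value,
                  clade = factor(data$clade),
                  species = factor(paste(data$clade, data$species, sep = ":")),
                  clone = factor(paste(data$clade, data$species, data$clone,
                                       sep = ":")))
  terms <- c(clade = "(1 | clade)", species = "(1 | species)",
             clone = "(1 | clone)")
  usable <- c(clade = nlevels(d$clade) > 1L,
              species = nlevels(d$species) > nlevels(d$clade),
              clone = nlevels(d$clone) > nlevels(d$species))
  if (!all(usable)) {
    warning("reduced model: no replication at level(s) ",
            paste(names(usable)[!usable], collapse = ", "),
            "; their components are reported as 0", call. = FALSE)
    terms <- terms[usable]
  }
  if (!length(terms)) stop("degenerate design: no random level has >1 group",
                           call. = FALSE)
  form <- stats::as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(rep(0, 4), lv)
  comp["residual"] <- vc$vcov[vc$grp == "Residual"]
  for (nm in names(terms))
    comp[nm] <- vc$vcov[vc$grp == nm]
  tot <- sum(comp)
  pct <- if (tot > 0) 100 * comp / tot else stats::setNames(rep(NA_real_, 4), lv)
  new("VarCompResult", components = comp, percentages = pct,
      degenerate = !all(usable), scale = "as-given", nObs = nrow(data))
}

checkNesting <- function(data) {
  sp <- unique(data[, c("clade", "species")])
  if (any(table(sp$species) > 1))
    stop("invalid nesting: a species label maps to more than one clade",
         call. = FALSE)
  cl <- unique(data[, c("species", "clone")])
  if (any(table(cl$clone) > 1))
    stop("invalid nesting: a clone label maps to more than one species",
         call. = FALSE)
  invisible(TRUE)
}

#' Percentage shares of variance components
#'
#' @param components numeric vector of 4 non-negative components
#'   (clade, species, clone, residual).
#' @param rounded logical; round to whole percent, half away from zero.
#' @return numeric vector of 4 percentages (NA with a warning when all
#'   components are zero).
#' @export
#' @examples
#' componentPercentages(c(0.175, 0.066, 0.019, 0.003), rounded = TRUE)  # 67 25 7 1
componentPercentages <- function(components, rounded = FALSE) {
  stopIfNot(length(components) == 4L, "expected 4 components")
  stopIfNot(all(components >= 0), "components must be non-negative")
  nm <- if (is.null(names(components)))
    c("clade", "species", "clone", "residual") else names(components)
  tot <- sum(components)
  if (tot == 0) {
    warning("all components zero: percentages undefined", call. = FALSE)
    return(stats::setNames(rep(NA_real_, 4), nm))
  }
  pct <- 100 * components / tot
  if (rounded) pct <- roundHalfAway(pct)
  stats::setNames(pct, nm)
}

#' Reconstruct replicate values from a printed mean, s.e.m. and n
#'
#' Published tables report per-clone summaries (mean, standard error, number
#' of replicates). Nested sums of squares depend on the replicates only
#' through their first two moments, so a canonical deterministic set of n
#' values with exactly the printed mean and standard deviation
#' (sd = sem * sqrt(n)) reproduces the variance-component analysis without
#' access to the raw data. The construction is symmetric: for even n, n/2
#' pairs mean +/- delta; for odd n, one value at the mean plus (n-1)/2 pairs.
#'
#' @param mean the printed mean.
#' @param sem the printed standard error of the mean (>= 0).
#' @param n number of replicates (>= 2 when sem > 0).
#' @return numeric vector of n values; `mean()` returns `mean` exactly and
#'   `sd()/sqrt(n)` returns `sem` to machine precision.
#' @export
#' @examples
#' x <- reconstructReplicates(113, 1.291, 4)
#' c(mean(x), sd(x) / sqrt(4))
reconstructReplicates <- function(mean, sem, n) {
  stopIfNot(sem >= 0, "sem must be >= 0")
  stopIfNot(n >= 1L, "n must be >= 1")
  if (n < 2L && sem > 0)
    stop("cannot place sem > 0 on a single replicate", call. = FALSE)
  if (sem == 0) return(rep(mean, n))
  s <- sem * sqrt(n)            # sample sd (n - 1 denominator)
  if (n %% 2L == 0L) {
    d <- s * sqrt((n - 1) / n)
    rep(c(mean - d, mean + d), n / 2)
  } else {
    d <- s
    c(mean, rep(c(mean - d, mean + d), (n - 1) / 2))
  }
}
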