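# Seedable generators emulating every statistical structure the analysis
# assumes: Brownian-motion traits on trees (optionally correlated pairs),
# nested random-effects designs, and Gaussian fluorescence peaks. All
# generators require a seed and are bit-reproducible under it.

#' Simulate a Brownian-motion trait on a tree
#'
#' Recursive simulation under the model that underlies independent
#' contrasts: each child value is its parent value plus a
#' Normal(0, sigma2 x branch length) increment. Delegated to
#' \pkg{phytools}.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma2 BM rate (variance per unit branch length, >= 0).
#' @param rootValue trait value at the root.
#' @param seed integer seed (mandatory).
#' @return named numeric vector of tip values.
#' @export
#' @examples
#' tr <- simulateYuleTree(16, seed = 1)
#' x <- simulateBM(tr, sigma2 = 1, rootValue = 0, seed = 2)
simulateBM <- function(tree, sigma2, rootValue = 0, seed) {
  stopIfNot(!missing(seed), "a seed is mandatory")
  stopIfNot(sigma2 >= 0, "sigma2 must be >= 0")
  validatePhylogeny(tree)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  set.seed(seed)
  if (sigma2 == 0)
    return(stats::setNames(rep(rootValue, ape::Ntip(tree)), tree$tip.label))
  x <- phytools::fastBM(tree, a = rootValue, sig2 = sigma2)
  x[tree$tip.label]
}

#' Simulate a correlated pair of Brownian-motion traits
#'
#' BM is linear-Gaussian, so a bivariate BM with trait covariance `Sigma`
#' per unit branch length is obtained exactly as a matrix-square-root
#' transform of two independent unit-rate BM traits simulated on the same
#' tree. The eigendecomposition square root also handles singular (perfectly
#' correlated) covariances.
#'
#' @param tree a `phylo` with branch lengths.
#' @param Sigma 2x2 positive semi-definite trait covariance per unit branch
#'   length.
#' @param rootValues length-2 root values (default c(0, 0)).
#' @param seed integer seed (mandatory).
#' @return matrix with one row per tip (rownames = tip labels) and two
#'   columns `trait1`, `trait2`.
#' @export
simulateCorrelatedBM <- function(tree, Sigma, rootValues = c(0, 0), seed) {
  stopIfNot(!missing(seed), "a seed is mandatory")
  Sigma <- as.matrix(Sigma)
  stopIfNot(all(dim(Sigma) == c(2L, 2L)), "Sigma must be 2x2")
  stopIfNot(isTRUE(all.equal(Sigma, t(Sigma))), "Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
    stop("Sigma is not positive semi-definite", call. = FALSE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), 2) %*% t(ev$vectors)
  z1 <- simulateBM(tree, 1, 0, seed = deriveSeed(seed, 1L))
  z2 <- simulateBM(tree, 1, 0, seed = deriveSeed(seed, 2L))
  X <- cbind(z1, z2)[tree$tip.label, , drop = FALSE] %*% A
  X <- sweep(X, 2, rootValues, "+")
  colnames(X) <- c("trait1", "trait2")
  X
}

#' Simulate a Yule (pure-birth) tree
#'
#' Test-fixture tree generator for the comparative methods.
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate (default 1).
#' @param seed integer seed (mandatory).
#' @return a `phylo` with tip labels `t1..tn`.
#' @export
simulateYuleTree <- function(nTips, birthRate = 1, seed) {
  stopIfNot(!missing(seed), "a seed is mandatory")
  stopIfNot(nTips >= 2L, "need at least 2 tips")
  set.seed(seed)
  ape::rphylo(nTips, birth = birthRate, death = 0)
}

#' Simulate a nested four-level data set
#'
#' Draws clade, species-within-clade and clone-within-species effects
#' independently Normal(0, component) and adds Normal(0, residual) replicate
#' noise, emulating the taxonomic hierarchy of the genome-size data.
#'
#' @param design either a length-4 integer vector
#'   `c(nClades, nSpeciesPerClade, nClonesPerSpecies, nReplicates)` for a
#'   balanced design, or a data.frame with columns `clade`, `species`,
#'   `clone` (one row per replicate) for an arbitrary unbalanced one.
#' @param components length-4 non-negative variances
#'   (clade, species, clone, residual).
#' @param grandMean overall mean.
#' @param seed integer seed (mandatory).
#' @return data.frame with columns `clade`, `species`, `clone`, `value`.
#' @export
#' @examples
#' d <- simulateNestedDataset(c(3, 4, 3, 4), c(0.175, 0.066, 0.019, 0.003),
#'                            grandMean = 5, seed = 1)
simulateNestedDataset <- function(design, components, grandMean = 0, seed) {
  stopIfNot(!missing(seed), "a seed is mandatory")
  stopIfNot(length(components) == 4L && all(components >= 0),
            "components must be 4 non-negative variances")
  set.seed(seed)
  if (is.data.frame(design)) {
    skel <- design[, c("clade", "species", "clone")]
  } else {
    stopIfNot(length(design) == 4L && all(design >= 1),
              "balanced design must be 4 positive counts")
    g <- expand.grid(rep = seq_len(design[4]), clone = seq_len(design[3]),
                     species = seq_len(design[2]), clade = seq_len(design[1]))
    skel <- data.frame(clade = paste0("C", g$clade),
                       species = paste0("C", g$clade, ".S", g$species),
                       clone = paste0("C", g$clade, ".S", g$species,
                                      ".K", g$clone))
  }
  cladeLv <- unique(skel$clade)
  spLv <- unique(skel[, c("clade", "species")])
  clLv <- unique(skel[, c("species", "clone")])
  a <- stats::setNames(stats::rnorm(length(cladeLv), 0, sqrt(components[1])),
                       cladeLv)
  b <- stats::setNames(stats::rnorm(nrow(spLv), 0, sqrt(components[2])),
                       spLv$species)
  cc <- stats::setNames(stats::rnorm(nrow(clLv), 0, sqrt(components[3])),
                        clLv$clone)
  skel$value <- grandMean + a[skel$clade] + b[skel$species] + cc[skel$clone] +
    stats::rnorm(nrow(skel), 0, sqrt(components[4]))
  rownames(skel) <- NULL
  skel
}

#' Simulate a fluorescence histogram
#'
#' Draws, for each peak, `events` channel values from
#' Normal(mean, cv x mean / 100), bins them into integer channels, and adds
#' a uniform noise floor, emulating a propidium-iodide FL2-A acquisition.
#'
#' @param peaks data.frame (or list coercible to one) with columns `mean`
#'   (channel), `cv` (percent, > 0) and `events`; may have zero rows.
#' @param noiseEvents events drawn uniformly over all channels (default 0).
#' @param nChannels number of channels (default 1024, channels 0..1023).
#' @param seed integer seed (mandatory).
#' @return data.frame with `channel` (0..nChannels-1) and `count`; counts sum
#'   to the total specified events.
#' @export
#' @examples
#' h <- simulateHistogram(data.frame(mean = 200, cv = 4, events = 7000),
#'                        seed = 1)
#' detectPeaks(h)
simulateHistogram <- function(peaks, noiseEvents = 0L, nChannels = 1024L,
                              seed) {
  stopIfNot(!missing(seed), "a seed is mandatory")
  peaks <- as.data.frame(peaks)
  set.seed(seed)
  draws <- integer(0)
  if (nrow(peaks)) {
    stopIfNot(all(c("mean", "cv", "events") %in% names(peaks)),
              "peaks need columns mean, cv, events")
    stopIfNot(all(peaks$cv > 0), "peak cv must be > 0")
    stopIfNot(all(peaks$mean >= 0 & peaks$mean < nChannels),
              "peak means must lie within the channel range")
    for (i in seq_len(nrow(peaks))) {
      v <- stats::rnorm(peaks$events[i], peaks$mean[i],
                        peaks$cv[i] * peaks$mean[i] / 100)
      draws <- c(draws, as.integer(pmin(pmax(round(v), 0), nChannels - 1L)))
    }
  }
  if (noiseEvents > 0)
    draws <- c(draws, as.integer(sample.int(nChannels, noiseEvents,
                                            replace = TRUE) - 1L))
  counts <- tabulate(draws + 1L, nbins = nChannels)
  data.frame(channel = 0:(nChannels - 1L), count = counts)
}
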