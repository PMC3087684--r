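# Independent oracles used across the suite.

# Closed-form nested ANOVA moment estimators for a BALANCED design
# (a clades x b species x c clones x r replicates). Independent route against
# which the REML fit is checked: on balanced data with all components
# interior (> 0) the two must agree.
nestedAnovaOracle <- function(d) {
  gm <- mean(d$value)
  cladeM <- tapply(d$value, d$clade, mean)
  spM <- tapply(d$value, paste(d$clade, d$species), mean)
  clM <- tapply(d$value, paste(d$clade, d$species, d$clone), mean)
  a <- length(cladeM); ab <- length(spM); abc <- length(clM); N <- nrow(d)
  b <- ab / a; cc <- abc / ab; r <- N / abc
  # sums of squares
  ssClade <- b * cc * r * sum((cladeM - gm)^2)
  cladeOfSp <- sub(" .*", "", names(spM))
  ssSp <- cc * r * sum((spM - cladeM[cladeOfSp])^2)
  spOfCl <- sub(" [^ ]*$", "", names(clM))
  ssCl <- r * sum((clM - spM[spOfCl])^2)
  clOfObs <- paste(d$clade, d$species, d$clone)
  ssRes <- sum((d$value - clM[clOfObs])^2)
  msClade <- ssClade / (a - 1)
  msSp <- ssSp / (a * (b - 1))
  msCl <- ssCl / (ab * (cc - 1))
  msRes <- ssRes / (abc * (r - 1))
  c(clade = (msClade - msSp) / (b * cc * r),
    species = (msSp - msCl) / (cc * r),
    clone = (msCl - msRes) / r,
    residual = msRes)
}

# random bifurcating tree with positive branch lengths (for property tests)
randomTestTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# patristic distance matrix straight from ape
patristic <- function(tree) ape::cophenetic.phylo(tree)
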