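#' Felsenstein's phylogenetically independent contrasts
#'
#' Computes standardized independent contrasts by the post-order pruning
#' recursion. For an internal node with child values x_i, x_j on (adjusted)
#' branch lengths b_i, b_j:
#' \deqn{u = (x_i - x_j) / \sqrt{b_i + b_j}}
#' the ancestral value is the precision-weighted mean
#' \eqn{(x_i/b_i + x_j/b_j) / (1/b_i + 1/b_j)}, and the ancestor's own branch
#' is lengthened by \eqn{b_i b_j / (b_i + b_j)}. A bifurcating n-tip tree
#' yields exactly n - 1 contrasts. Contrast sign follows the stored child
#' order (first child minus second); all reported statistics are
#' sign-invariant.
#'
#' Parsimony-step branch lengths can be zero, which would make a contrast
#' denominator vanish. `zeroBranchPolicy` controls the treatment:
#' \describe{
#'   \item{`"epsilon"` (default)}{only where both child branches at a node are
#'     zero, both are replaced by eps = 1e-6 x tree height, keeping contrasts
#'     finite without distorting nonzero branches;}
#'   \item{`"all_one"`}{every branch length is set to 1 before pruning (also
#'     the only policy usable when branch lengths are missing);}
#'   \item{`"raw"`}{zero denominators are an error naming the node.}
#' }
#'
#' @param tree a bifurcating `phylo` (apply [resolvePolytomies()] first).
#' @param traits data.frame with a `tip_label` column and one column per
#'   trait, or a named numeric vector when `trait` is omitted.
#' @param trait name of the trait column to contrast.
#' @param zeroBranchPolicy one of `"epsilon"`, `"all_one"`, `"raw"`.
#' @return a [ContrastSet-class] object.
#' @seealso [picCorrelation()], [simulateBM()]
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' x <- c(A = 1, B = 3, C = 6)
#' computeContrasts(tr, x)
computeContrasts <- function(tree, traits, trait = NULL,
                             zeroBranchPolicy = c("epsilon", "all_one", "raw")) {
  zeroBranchPolicy <- match.arg(zeroBranchPolicy)
  validatePhylogeny(tree)
  ntip <- ape::Ntip(tree)
  stopIfNot(ntip >= 2L, "need at least 2 tips")
  if (!isBifurcating(tree))
    stop("tree is not bifurcating; apply resolvePolytomies() first",
         call. = FALSE)

  if (is.data.frame(traits)) {
    stopIfNot("tip_label" %in% names(traits),
              "trait table must have a `tip_label` column")
    if (is.null(trait)) {
      cand <- setdiff(names(traits), "tip_label")
      stopIfNot(length(cand) == 1L,
                "several trait columns present; name one via `trait`")
      trait <- cand
    }
    x <- stats::setNames(traits[[trait]], traits$tip_label)
  } else {
    x <- traits
    if (is.null(trait)) trait <- "trait"
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing))
    stop("no trait value for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- as.numeric(x[tree$tip.label])
  if (any(!is.finite(vals)))
    stop("non-finite trait value for tip(s): ",
         paste(tree$tip.label[!is.finite(vals)], collapse = ", "),
         call. = FALSE)

  bl <- branchLengthTo(tree)
  if (zeroBranchPolicy == "all_one") {
    bl[] <- 1
    bl[rootNode(tree)] <- NA_real_
  } else if (anyNA(bl[-rootNode(tree)])) {
    stop("tree has missing branch lengths; use zeroBranchPolicy = \"all_one\"",
         call. = FALSE)
  }
  eps <- 1e-6 * max(treeHeight(tree, bl), 1e-30)

  ntot <- ntip + tree$Nnode
  ch <- childrenList(tree)
  xhat <- c(vals, rep(NA_real_, tree$Nnode))
  badj <- bl
  pre <- dfsNodes(tree)
  internals <- rev(pre[pre > ntip])   # reverse preorder = valid postorder

  contrast <- variance <- anc <- adjlen <- numeric(length(internals))
  for (k in seq_along(internals)) {
    nd <- internals[k]
    kids <- ch[[nd]]
    i <- kids[1L]; j <- kids[2L]
    bi <- badj[i]; bj <- badj[j]
    if (bi == 0 && bj == 0) {
      if (zeroBranchPolicy == "raw")
        stop("zero contrast variance at node ", nd,
             " under zeroBranchPolicy = \"raw\"", call. = FALSE)
      bi <- bj <- eps
    }
    v <- bi + bj
    contrast[k] <- (xhat[i] - xhat[j]) / sqrt(v)
    variance[k] <- v
    xhat[nd] <- if (bi == 0) xhat[i] else if (bj == 0) xhat[j] else
      (xhat[i] / bi + xhat[j] / bj) / (1 / bi + 1 / bj)
    anc[k] <- xhat[nd]
    if (!is.na(badj[nd])) badj[nd] <- badj[nd] + bi * bj / v
    adjlen[k] <- if (is.na(badj[nd])) 0 else badj[nd]
  }
  new("ContrastSet",
      node = as.integer(internals), contrast = contrast, variance = variance,
      ancestorState = anc, adjustedLength = adjlen,
      trait = trait, tipLabels = tree$tip.label)
}

# max root-to-tip distance using the given per-node branch lengths
treeHeight <- function(tree, bl = branchLengthTo(tree)) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  ch <- childrenList(tree)
  depth <- numeric(ntot)
  for (nd in dfsNodes(tree)) {
    for (kk in ch[[nd]]) depth[kk] <- depth[nd] + ifelse(is.na(bl[kk]), 0, bl[kk])
  }
  max(depth[seq_len(ape::Ntip(tree))])
}

#' Through-origin correlation of two contrast sets
#'
#' Contrasts have arbitrary sign, so their correlation is computed through
#' the origin: \eqn{r = \sum u_x u_y / \sqrt{\sum u_x^2 \sum u_y^2}}, with a
#' two-sided p-value from the t statistic on n_contrasts - 1 degrees of
#' freedom (one degree of freedom is spent on the constrained intercept).
#'
#' @param ux,uy [ContrastSet-class] objects from the same tree.
#' @return list with elements `r`, `p`, `n` (number of contrasts).
#' @export
picCorrelation <- function(ux, uy) {
  stopIfNot(is(ux, "ContrastSet") && is(uy, "ContrastSet"),
            "inputs must be ContrastSet objects")
  stopIfNot(identical(ux@tipLabels, uy@tipLabels) &&
              identical(ux@node, uy@node),
            "contrast sets must come from the same tree (paired by node)")
  a <- ux@contrast; b <- uy@contrast
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0)
    stop("all contrasts are zero in one trait; correlation undefined",
         call. = FALSE)
  r <- sum(a * b) / sqrt(sa * sb)
  n <- length(a)
  df <- n - 1L
  p <- if (1 - r^2 <= .Machine$double.eps) 0 else {
    tt <- r * sqrt(df) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = n)
}

#' Read a trait table
#'
#' Tab-separated file with header `tip_label` then one column per trait.
#'
#' @param file path to the TSV file.
#' @return a data.frame.
#' @export
readTraitTable <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot("tip_label" %in% names(tab),
            "trait table must have a `tip_label` column")
  tab
}

#' @describeIn computeContrasts coerce a ContrastSet to a data.frame
#'   (node id, contrast, variance, ancestral state).
#' @param x a `ContrastSet`.
#' @param ... ignored.
#' @export
as.data.frame.ContrastSet <- function(x, ...) {
  data.frame(node = x@node, contrast = x@contrast, variance = x@variance,
             ancestor_state = x@ancestorState,
             adjusted_length = x@adjustedLength)
}
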