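#' @importFrom ape read.tree write.tree drop.tip Ntip Nnode
NULL

# ---- internal tree helpers -------------------------------------------------

# children of every node, honoring the cladewise edge-row order (which is the
# Newick input order and defines the canonical tip ordering)
childrenList <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2L])
  }
  ch
}

rootNode <- function(tree) ape::Ntip(tree) + 1L

# strictly bifurcating in the rooted sense: every internal node has exactly
# two children (ape::is.binary treats a basal trichotomy as binary)
isBifurcating <- function(tree) {
  all(tabulate(tree$edge[, 1L]) [(ape::Ntip(tree) + 1L):
                                   (ape::Ntip(tree) + tree$Nnode)] == 2L)
}

# branch length leading to each node (NA for root / missing)
branchLengthTo <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  bl <- rep(NA_real_, n)
  if (!is.null(tree$edge.length)) bl[tree$edge[, 2L]] <- tree$edge.length
  bl
}

# depth-first traversal honoring children order, with optional per-node
# reversal (`flip` indexed by node number); returns node numbers in preorder.
# `ch` can be precomputed with childrenList() when called in a loop.
dfsNodes <- function(tree, flip = NULL, ch = childrenList(tree)) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  out <- integer(ntot)
  k <- 0L
  stack <- rootNode(tree)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- nd
    kids <- ch[[nd]]
    if (length(kids)) {
      if (!is.null(flip) && isTRUE(flip[nd])) kids <- rev(kids)
      stack <- c(stack, rev(kids))   # push so first child is visited first
    }
  }
  out
}

# ---- exported operations ---------------------------------------------------

#' Parse a Newick tree
#'
#' Reads a single rooted tree from a Newick string (or a file containing one),
#' via \pkg{ape}, and validates it for downstream use: tip labels must be
#' unique and non-empty, and branch lengths, where present, non-negative and
#' finite. Missing branch lengths are kept as missing (NA/absent), not zero;
#' downstream stages decide how to substitute them.
#'
#' @param text Newick string (must end in a semicolon), or NULL.
#' @param file path to a Newick file (used when `text` is NULL).
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parseNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopIfNot(!is.null(file), "supply either `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  # cheap structural pre-check so syntax errors carry a character position
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: ape could not parse the string",
                          call. = FALSE)
  validatePhylogeny(tree)
  tree
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when NULL the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the structural invariants assumed throughout the package: unique,
#' non-empty tip labels and non-negative finite branch lengths (NA allowed,
#' meaning "missing").
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validatePhylogeny <- function(tree) {
  stopIfNot(inherits(tree, "phylo"), "not a phylo object")
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs)))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  if (!is.null(tree$edge.length)) {
    bl <- tree$edge.length
    bad <- !is.na(bl) & (bl < 0 | is.infinite(bl))
    if (any(bad)) stop("branch lengths must be non-negative and finite",
                       call. = FALSE)
  }
  invisible(tree)
}

#' Tip labels in traversal order
#'
#' The canonical tip ordering is the depth-first traversal honoring each
#' node's child order (the order tips appear in the Newick string). This is
#' the order the serial-independence test consumes.
#'
#' @param tree a `phylo` object.
#' @return character vector of tip labels.
#' @export
tipOrder <- function(tree) {
  nodes <- dfsNodes(tree)
  tree$tip.label[nodes[nodes <= ape::Ntip(tree)]]
}

#' Resolve polytomies deterministically
#'
#' Replaces every multifurcation by left-to-right pairing of its children:
#' the first two children are joined into a cherry on a zero-length branch,
#' the cherry is joined with the third child, and so on, so a polytomy of k
#' children gains k - 2 new internal nodes connected by zero-length branches. The resolution is deterministic (input child order), so contrast
#' counts always equal n_tips - 1 and patristic distances are unchanged.
#'
#' @param tree a `phylo` object.
#' @return a strictly bifurcating `phylo` object.
#' @export
#' @examples
#' writeNewick(resolvePolytomies(parseNewick("(A:1,B:1,C:1);")))
resolvePolytomies <- function(tree) {
  validatePhylogeny(tree)
  ch <- childrenList(tree)
  bl <- branchLengthTo(tree)
  ntip <- ape::Ntip(tree)
  fmt <- function(x) if (is.na(x)) "" else paste0(":", sprintf("%.15g", x))
  build <- function(nd) {
    if (nd <= ntip) {
      lab <- tree$tip.label[nd]
      if (grepl("[ ():,;]", lab)) lab <- paste0("'", lab, "'")
      return(paste0(lab, fmt(bl[nd])))
    }
    kids <- vapply(ch[[nd]], build, character(1))
    # left-to-right pairing: fold children into nested cherries on 0-length
    while (length(kids) > 2L) {
      kids <- c(paste0("(", kids[1L], ",", kids[2L], "):0"), kids[-(1:2)])
    }
    paste0("(", paste(kids, collapse = ","), ")", fmt(bl[nd]))
  }
  out <- ape::read.tree(text = paste0(build(rootNode(tree)), ";"))
  validatePhylogeny(out)
  out
}

#' Random rotation of a tree's tip order
#'
#' Independently reverses each internal node's child order with probability
#' 1/2 and returns the resulting tip-label ordering. Rotations change the tip
#' order without changing the topology; they are the randomization device of
#' the Abouheif serial-independence test.
#'
#' @param tree a `phylo` object.
#' @param seed integer RNG seed (same seed, same order).
#' @return character vector: tip labels in rotated order.
#' @export
randomRotation <- function(tree, seed) {
  validatePhylogeny(tree)
  set.seed(seed)
  ntot <- ape::Ntip(tree) + tree$Nnode
  flip <- rep(FALSE, ntot)
  flip[(ape::Ntip(tree) + 1L):ntot] <- stats::runif(tree$Nnode) < 0.5
  nodes <- dfsNodes(tree, flip)
  tree$tip.label[nodes[nodes <= ape::Ntip(tree)]]
}

#' Star phylogeny
#'
#' A single root with every tip attached directly at equal branch length.
#' On such a tree, contrasts reduce to an orthogonal (Helmert) transform of
#' the centered tip values, so contrast statistics coincide with their
#' ordinary (non-phylogenetic) counterparts — a useful calibration case.
#'
#' @param labels character vector of at least 2 unique tip labels.
#' @param branchLength positive branch length shared by all tips.
#' @return a `phylo` object (root of degree `length(labels)`).
#' @export
starTree <- function(labels, branchLength = 1) {
  stopIfNot(length(labels) >= 2L, "need at least 2 tip labels")
  stopIfNot(!anyDuplicated(labels), "tip labels must be unique")
  stopIfNot(branchLength > 0, "branch length must be positive")
  s <- paste0("(", paste0(labels, ":", sprintf("%.15g", branchLength),
                          collapse = ","), ");")
  parseNewick(s)
}
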