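test_that("parseNewick reads structure and round-trips", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  root <- ape::Ntip(tr) + 1
  expect_equal(sum(tr$edge[, 1] == root), 2)  # root has 2 children
  expect_equal(writeNewick(tr), "((A:1,B:1):1,C:2);")
  expect_equal(tipOrder(tr), c("A", "B", "C"))
})

test_that("parseNewick rejects invalid input with diagnostics", {
  expect_error(parseNewick("((A:1,A:1):1,C:2);"), "duplicate tip labels")
  expect_error(parseNewick("((A:1,B:1):1,C:2"), "character")
  expect_error(parseNewick("(A:1,B:1)):1;"), "unmatched '\\)' at character")
  expect_error(parseNewick("((A:1,B:-1):1,C:2);"), "non-negative")
})

test_that("missing branch lengths are kept missing, not zero", {
  tr <- parseNewick("((A:1,B),C:2);")
  expect_true(anyNA(tr$edge.length))
  tr2 <- parseNewick("((A,B),C);")
  expect_null(tr2$edge.length)
})

test_that("polytomy resolution pairs children left to right on zero branches", {
  # bifurcating input untouched
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_equal(writeNewick(resolvePolytomies(tr)), writeNewick(tr))
  # trifurcation
  expect_equal(writeNewick(resolvePolytomies(parseNewick("(A:1,B:1,C:1);"))),
               "((A:1,B:1):0,C:1);")
  # 5-child polytomy: 3 new zero-length internal branches, 4 internal nodes
  tr5 <- resolvePolytomies(parseNewick("(A:1,B:1,C:1,D:1,E:1);"))
  expect_true(ape::is.binary.phylo(tr5))
  internalEdges <- tr5$edge[, 2] > ape::Ntip(tr5)
  expect_equal(sum(tr5$edge.length[internalEdges] == 0), 3)
  expect_equal(tr5$Nnode, 4)
})

test_that("polytomy resolution preserves patristic distances", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rtree(12)
    # collapse short internal branches into polytomies
    tr <- ape::di2multi(tr, tol = quantile(tr$edge.length, 0.4))
    res <- resolvePolytomies(tr)
    expect_true(ape::is.binary.phylo(res))
    lab <- tr$tip.label
    expect_equal(patristic(res)[lab, lab], patristic(tr)[lab, lab],
                 tolerance = 1e-12)
  }
})

test_that("random rotation yields only admissible orders at uniform rates", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  orders <- vapply(1:2000, function(s)
    paste(randomRotation(tr, s), collapse = ""), character(1))
  tab <- table(orders)
  expect_setequal(names(tab), c("ABC", "BAC", "CAB", "CBA"))
  expect_true(all(abs(tab / 2000 - 0.25) < 0.05))  # 1/4 +- MC error
  # determinism and label multiset preserved
  expect_identical(randomRotation(tr, 42), randomRotation(tr, 42))
  expect_setequal(randomRotation(tr, 7), c("A", "B", "C"))
})

test_that("rotation of a single-tip tree returns that tip", {
  tr <- ape::read.tree(text = "(A:1);")
  expect_equal(randomRotation(tr, 3), "A")
})

test_that("starTree builds equal-branch stars and validates input", {
  st <- starTree(c("A", "B"), 1)
  expect_equal(writeNewick(st), "(A:1,B:1);")
  st5 <- starTree(paste0("t", 1:5), 2)
  expect_equal(sum(st5$edge[, 1] == ape::Ntip(st5) + 1), 5)  # root degree 5
  expect_error(starTree("A"), "at least 2")
  expect_error(starTree(c("A", "A")), "unique")
  expect_error(starTree(c("A", "B"), 0), "positive")
})

test_that("parse/write is the identity on random trees", {
  for (seed in 1:8) {
    tr <- randomTestTree(sample(4:20, 1), seed)
    back <- parseNewick(writeNewick(tr))
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(patristic(back), patristic(tr), tolerance = 1e-8)
  }
})
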