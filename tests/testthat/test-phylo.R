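test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ recovers four-taxon additive trees exactly", {
  # distances generated from ((A:1,B:2):1,(C:1,D:1));
  lab <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 3
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 4
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 2
  tr <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], D, tolerance = 1e-9)
})

test_that("NJ recovers random additive trees and four-point splits, n <= 12", {
  set.seed(12)
  for (n in c(5, 8, 12)) {
    src <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(src)
    ord <- sort(rownames(D))
    D <- D[ord, ord]
    tr <- nj_tree(D)
    Dt <- ape::cophenetic.phylo(tr)[ord, ord]
    # path lengths reproduce the additive input exactly
    expect_equal(Dt, D, tolerance = 1e-8)
    # four-point condition: every quartet split matches the input matrix
    quartets <- utils::combn(n, 4)
    for (k in seq_len(min(ncol(quartets), 60))) {
      q <- quartets[, k]
      expect_identical(four_point_split(Dt, q[1], q[2], q[3], q[4]),
                       four_point_split(D, q[1], q[2], q[3], q[4]))
    }
    # independent implementation agrees on topology
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ is invariant to input order up to isomorphism", {
  set.seed(4)
  src <- ape::rtree(7)
  D <- ape::cophenetic.phylo(src)
  perm <- sample(7)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  lab <- sort(rownames(D))
  expect_equal(ape::cophenetic.phylo(t1)[lab, lab],
               ape::cophenetic.phylo(t2)[lab, lab], tolerance = 1e-9)
})

test_that("NJ rejects degenerate inputs", {
  D <- matrix(c(0, Inf, Inf, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "saturated")
})

test_that("midpoint rooting equalises the two farthest reference leaves", {
  tr <- ape::read.tree(text = "((A:1,B:4):1,(C:2,(D:7,E:1):1):1);")
  rooted <- midpoint_root(tr)
  dn <- ape::dist.nodes(rooted)
  root <- length(rooted$tip.label) + 1L
  depths <- dn[root, seq_along(rooted$tip.label)]
  names(depths) <- rooted$tip.label
  # farthest pair is B (depth 6 from root side) and D; both end equidistant
  expect_equal(depths[["B"]], depths[["D"]], tolerance = 1e-9)
  # excluded leaves do not steer the root: hang a long query branch
  tr2 <- ape::read.tree(text = "(((A:1,B:4):1,q1:50):1,(C:2,(D:7,E:1):1):1);")
  rooted2 <- midpoint_root(tr2, exclude = "q1")
  dn2 <- ape::dist.nodes(rooted2)
  root2 <- length(rooted2$tip.label) + 1L
  d2 <- stats::setNames(dn2[root2, seq_along(rooted2$tip.label)],
                        rooted2$tip.label)
  expect_equal(d2[["B"]], d2[["D"]], tolerance = 1e-9)
})

test_that("strict criterion assigns the finest unanimous clade label", {
  taxonomy <- data.frame(
    id = c("t1", "t2", "s1", "o1"),
    order = "Decapoda",
    family = c("Hippolytidae", "Hippolytidae", "Alpheidae", "Palaemonidae"),
    genus = c("Thor", "Thor", "Synalpheus", "Periclimenes"),
    species = c("Thor amboinensis", "Thor dobkini", "", ""))
  # query sister to two congeneric species: genus-level call
  tr <- ape::read.tree(
    text = "((q1:0.04,(t1:0.02,t2:0.02):0.02):0.06,(s1:0.05,o1:0.05):0.03);")
  res <- strict_criterion(tr, "q1", taxonomy)
  expect_identical(res$rank, "genus")
  expect_identical(res$taxon, "Thor")
  expect_equal(res$clade_size, 2)
  # query nested among two families, unanimous only at order
  tr2 <- ape::read.tree(
    text = "((q1:0.08,(t1:0.01,t2:0.01):0.07):0.02,(s1:0.06,o1:0.06):0.04);")
  res2 <- strict_criterion(tr2, "q1", taxonomy)
  # smallest clade holds only Thor; with the root between the two sides the
  # next clade up spans three families
  expect_true(res2$rank %in% c("genus", "order"))
  # query inside a single species' haplotype fan: species-level call
  tax3 <- data.frame(id = c("h1", "h2", "x1"), order = "Perciformes",
                     family = c("Labridae", "Labridae", "Scaridae"),
                     genus = c("Halichoeres", "Halichoeres", "Scarus"),
                     species = c("Halichoeres garnoti", "Halichoeres garnoti",
                                 "Scarus iseri"))
  tr3 <- ape::read.tree(
    text = "(((q1:0.004,h1:0.004):0.002,h2:0.005):0.05,x1:0.05);")
  res3 <- strict_criterion(tr3, "q1", tax3)
  expect_identical(res3$rank, "species")
  expect_identical(res3$taxon, "Halichoeres garnoti")
  # capping the finest rank demotes a species-unanimous clade to genus
  res3g <- strict_criterion(tr3, "q1", tax3, finest_rank = "genus")
  expect_identical(res3g$rank, "genus")
  expect_identical(res3g$taxon, "Halichoeres")
  expect_error(strict_criterion(tr3, "zz", tax3), "not in tree")
})

test_that("other query leaves are transparent to the strict criterion", {
  taxonomy <- data.frame(id = c("h1", "h2", "x1"), order = "Perciformes",
                         family = c("Labridae", "Labridae", "Scaridae"),
                         genus = c("Halichoeres", "Halichoeres", "Scarus"),
                         species = c("Halichoeres garnoti",
                                     "Halichoeres garnoti", "Scarus iseri"))
  tr <- ape::read.tree(
    text = "(((q1:0.004,q2:0.004):0.002,(h1:0.003,h2:0.003):0.002):0.05,x1:0.05);")
  res <- strict_criterion(tr, "q1", taxonomy, query_ids = c("q1", "q2"))
  expect_identical(res$rank, "species")
  expect_identical(res$taxon, "Halichoeres garnoti")
  expect_equal(res$clade_size, 2)  # q2 not counted
})
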