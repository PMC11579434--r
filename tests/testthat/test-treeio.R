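test_that("parse_newick builds rooted trees and rejects malformed input", {
  tr <- parse_newick("(O,(A,(B,C)));")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4L)
  root_kids <- tr$edge[tr$edge[, 1] == 5L, 2L]
  expect_length(root_kids, 2L)

  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("(A,B)"), "terminated")
  expect_error(parse_newick("(A,(B,A));"), "duplicate")
})

test_that("write -> parse round trip preserves topology, labels, lengths", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(4:40, 1)
      tr <- ape::rtree(n)
      tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
      back <- parse_newick(write_newick(tr))
      expect_equal(sort(back$tip.label), sort(tr$tip.label))
      expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
                   ignore_attr = TRUE)
      d1 <- ape::cophenetic.phylo(tr)
      d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
      expect_equal(d1, d2, tolerance = 1e-8)
    }
  })
})

test_that("root_with_outgroup separates the outgroup and is idempotent", {
  tr <- parse_newick("(A:1,B:1,(C:1,O:1):1);")
  rt <- root_with_outgroup(tr, "O")
  ntip <- 4L
  kids <- rt$edge[rt$edge[, 1] == ntip + 1L, 2L]
  expect_true(which(rt$tip.label == "O") %in% kids)

  again <- root_with_outgroup(rt, "O")
  expect_identical(write_newick(again), write_newick(rt))
  expect_error(root_with_outgroup(tr, "X"), "not present")
})

test_that("collapse_low_support contracts weak edges and is idempotent", {
  tr <- parse_newick("((A:1,B:1)100:1,(C:1,D:1)100:1);")
  expect_identical(write_newick(collapse_low_support(tr, 90)),
                   write_newick(tr))

  tr2 <- parse_newick("((A:1,B:1)85:1,(C:1,D:1)95:1);")
  c1 <- collapse_low_support(tr2, 90)
  expect_equal(c1$Nnode, 2L)  # star among A, B and the (C,D) clade
  expect_true(ape::is.monophyletic(c1, c("C", "D")))
  expect_identical(write_newick(collapse_low_support(c1, 90)),
                   write_newick(c1))

  # threshold 0 leaves everything; unsupported edges are never collapsed
  expect_identical(write_newick(collapse_low_support(tr2, 0)),
                   write_newick(tr2))
  tr3 <- parse_newick("((A:1,B:1):1,(C:1,D:1)50:1);")
  c3 <- collapse_low_support(tr3, 90)
  root <- 5L
  parent_of <- function(tr, tip)
    tr$edge[tr$edge[, 2] == which(tr$tip.label == tip), 1]
  expect_false(parent_of(c3, "A") == root)  # unlabeled edge kept
  expect_equal(parent_of(c3, "C"), root)    # weak edge contracted
  expect_equal(parent_of(c3, "D"), root)
})

test_that("triplet_topology classifies the four outcomes", {
  sp <- triplet_spec("P1", "P2", "P3", "O")
  expect_equal(triplet_topology(parse_newick("(((P1,P2),P3),O);"), sp), "P1P2")
  expect_equal(triplet_topology(parse_newick("(((P2,P3),P1),O);"), sp), "P2P3")
  expect_equal(triplet_topology(parse_newick("(((P1,P3),P2),O);"), sp), "P1P3")
  expect_equal(triplet_topology(parse_newick("((P1,P2,P3),O);"), sp),
               "UNRESOLVED")
  expect_error(triplet_topology(parse_newick("((P1,P2),O);"), sp), "missing")
})

test_that("triplet_topology is invariant under consistent relabeling", {
  withr::with_seed(5, {
    for (i in 1:25) {
      tr <- ape::rtree(8)
      tr$tip.label <- c("P1", "P2", "P3", "O", paste0("x", 1:4))
      sp <- triplet_spec("P1", "P2", "P3", "O")
      lab <- triplet_topology(tr, sp)
      # swapping the roles of P1 and P2 maps P1P3 <-> P2P3, fixes P1P2
      sp_sw <- triplet_spec("P2", "P1", "P3", "O")
      lab_sw <- triplet_topology(tr, sp_sw)
      expected <- c(P1P2 = "P1P2", P1P3 = "P2P3", P2P3 = "P1P3",
                    UNRESOLVED = "UNRESOLVED")[lab]
      expect_equal(lab_sw, unname(expected))
    }
  })
})

test_that("fast cached classification agrees with prune-and-root", {
  withr::with_seed(23, {
    net <- species_network(null10_tree())
    gts <- simulate_gene_trees(net, 40, seed = 77)
    cache <- introscan:::build_triplet_cache(gts, "O")
    for (trio in list(c("a", "b", "c"), c("c", "g", "j"), c("e", "f", "a"))) {
      sp <- triplet_spec(trio[1], trio[2], trio[3], "O")
      slow <- vapply(gts$trees, function(tr) triplet_topology(tr, sp), "")
      fast <- introscan:::cache_triplet_labels(cache, trio[1], trio[2],
                                               trio[3])
      fast <- c(AB = "P1P2", AC = "P1P3", BC = "P2P3",
                UNRESOLVED = "UNRESOLVED")[fast]
      expect_equal(unname(fast), unname(slow))
    }
  })
})

test_that("sister_pairs finds exactly the mutual sister tip pairs", {
  expect_equal(sister_pairs(parse_newick("((A,B),(C,D));")),
               list(c("A", "B"), c("C", "D")))
  expect_equal(sister_pairs(parse_newick("(A,(B,(C,D)));")),
               list(c("C", "D")))
  # brute-force oracle on random 50-tip trees: a pair is sister iff its
  # two tips' MRCA has exactly those two descendants
  withr::with_seed(31, {
    tr <- ape::rtree(50)
    got <- sister_pairs(tr)
    oracle <- list()
    for (i in 1:49) for (j in (i + 1):50) {
      m <- ape::getMRCA(tr, c(tr$tip.label[i], tr$tip.label[j]))
      desc <- ape::extract.clade(tr, m)$tip.label
      if (length(desc) == 2L)
        oracle[[length(oracle) + 1L]] <-
          sort(c(tr$tip.label[i], tr$tip.label[j]))
    }
    oracle <- oracle[order(vapply(oracle, paste, "", collapse = "\r"))]
    expect_equal(got, oracle)
  })
})

test_that("gene_tree_set enforces unique ids and tracks coverage", {
  trees <- list(parse_newick("((A,B),C);"), parse_newick("((A,C),D);"))
  expect_error(gene_tree_set(trees, c("x", "x")), "unique")
  gts <- gene_tree_set(trees, c("g1", "g2"))
  expect_equal(gts$coverage[["A"]], 2L)
  expect_equal(gts$coverage[["D"]], 1L)
  expect_identical(gts$coverage[sort(names(gts$coverage))],
                   recount_coverage(gts)[sort(names(gts$coverage))])
})

test_that("gene tree files round trip", {
  gts <- toy6_gene_trees()
  path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_trees(gts, path)
  back <- read_gene_trees(path, ids = gts$ids)
  expect_equal(length(back), length(gts))
  for (i in seq_along(gts$trees))
    expect_equal(ape::dist.topo(ape::unroot(back$trees[[i]]),
                                ape::unroot(gts$trees[[i]])), 0,
                 ignore_attr = TRUE)
})

test_that("gCF is 100 for fully concordant gene trees and NA when no tree
           is decisive", {
  st <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  gts <- gene_tree_set(rep(list(st), 5), paste0("L", 1:5))
  g <- gene_concordance_factor(st, gts)
  expect_true(all(g$gcf[!is.na(g$gcf)] == 100))

  # gene trees missing one whole side of a branch leave it undefined
  sub <- parse_newick("(((A:1,B:1):1,C:2):1,F:4);")  # no D, E
  gts2 <- gene_tree_set(rep(list(sub), 3), paste0("M", 1:3))
  g2 <- gene_concordance_factor(st, gts2)
  cd <- g2[g2$clade == "C+D", ]
  expect_true(is.na(cd$gcf))
})

test_that("gCF matches exhaustive split counting on mixed gene trees", {
  st <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  gts <- toy6_gene_trees()
  g <- gene_concordance_factor(st, gts)
  # independent oracle: for each branch bipartition, count gene trees whose
  # restricted split set contains it, among decisive trees (>=1 taxon in
  # each of the four surrounding subtrees); computed with phangorn splits
  oracle_counts <- function(clade_tips, groups) {
    nd <- nc <- 0L
    for (gt in gts$trees) {
      taxa <- gt$tip.label
      if (!all(vapply(groups, function(gr) any(gr %in% taxa), TRUE))) next
      nd <- nd + 1L
      x <- intersect(clade_tips, taxa)
      sp <- phangorn::as.splits(ape::unroot(gt))
      labs <- attr(sp, "labels")
      found <- FALSE
      for (s in sp) {
        side <- labs[s]
        if (setequal(side, x) || setequal(setdiff(taxa, side), x))
          found <- TRUE
      }
      if (found) nc <- nc + 1L
    }
    c(nd, nc)
  }
  # branch above clade {A,B}: groups A | B | CD | EF
  ab <- oracle_counts(c("A", "B"),
                      list("A", "B", c("C", "D"), c("E", "F")))
  row <- g[g$clade == "A+B", ]
  expect_equal(c(row$n_decisive, row$n_concordant), ab)
  # branch above clade {A,B,C,D}: groups AB | CD | E | F
  abcd <- oracle_counts(c("A", "B", "C", "D"),
                        list(c("A", "B"), c("C", "D"), "E", "F"))
  row2 <- g[g$clade == "A+B+C+D", ]
  expect_equal(c(row2$n_decisive, row2$n_concordant), abcd)
  expect_true(all(g$gcf[!is.na(g$gcf)] >= 0 & g$gcf[!is.na(g$gcf)] <= 100))
})

test_that("on a 4-taxon tree gCF equals the triplet major fraction", {
  st <- parse_newick("(((A:1,B:1):1,C:2):10,O:12);")
  withr::with_seed(9, {
    gts <- simulate_gene_trees(species_network(st), 300, seed = 12)
    g <- gene_concordance_factor(st, gts)
    cnt <- count_topologies(gts, triplet_spec("A", "B", "C", "O"))
    expected <- 100 * cnt$major / (cnt$major + cnt$minor1 + cnt$minor2)
    row <- g[g$clade == "A+B", ]
    expect_equal(row$gcf, expected, tolerance = 1e-9)
  })
})

test_that("taxon maps select deterministic representatives", {
  tm <- data.frame(sample = c("s2", "s1", "s3", "s4"),
                   species = c("sp1", "sp1", "sp2", "sp2"),
                   stringsAsFactors = FALSE)
  reps <- representative_samples(tm)
  expect_equal(unname(reps[c("sp1", "sp2")]), c("s1", "s3"))
})
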