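test_that("enumerate_triplets pairs each sister pair with every other tip", {
  st <- parse_newick("((A,B),(C,D));")
  specs <- enumerate_triplets(st, "O")
  expect_length(specs, 4L)  # 2 pairs x 2 remaining tips
  expect_length(enumerate_triplets(parse_newick("(A,(B,(C,D)));"), "O"), 2L)

  # count = (#sister pairs) x (n - 2) on random trees
  withr::with_seed(41, {
    for (i in 1:5) {
      tr <- ape::rtree(30)
      k <- length(sister_pairs(tr))
      expect_length(enumerate_triplets(tr, "OUT"), k * 28L)
    }
  })
  # an outgroup inside the tree is excluded from the ingroup
  st2 <- parse_newick("(((A,B),(C,D)),O);")
  expect_length(enumerate_triplets(st2, "O"), 4L)
})

test_that("count_topologies tallies loci and skips incomplete ones", {
  sp <- triplet_spec("P1", "P2", "P3", "O")
  conc <- parse_newick("(((P1,P2),P3),O);")
  gts <- gene_tree_set(rep(list(conc), 10), paste0("L", 1:10))
  cnt <- count_topologies(gts, sp)
  expect_equal(c(cnt$major, cnt$minor1, cnt$minor2, cnt$n_unresolved),
               c(10L, 0L, 0L, 0L))

  # hand-built mixture: 3 major, 2 P2P3, 1 P1P3, 1 unresolved + 1 lacking P3
  mix <- c(rep("(((P1,P2),P3),O);", 3), rep("(((P2,P3),P1),O);", 2),
           "(((P1,P3),P2),O);", "((P1,P2,P3),O);", "((P1,P2),O);")
  gts2 <- gene_tree_set(lapply(mix, parse_newick), paste0("M", 1:8))
  cnt2 <- count_topologies(gts2, sp)
  expect_equal(cnt2$major, 3L)
  expect_equal(cnt2$minor1, 1L)
  expect_equal(cnt2$minor2, 2L)
  expect_equal(cnt2$minor2_pairing, "P2P3")
  expect_equal(cnt2$n_unresolved, 1L)
  expect_equal(cnt2$n_loci_used, 7L)  # locus without P3 excluded entirely
  # counts satisfy the bookkeeping identity
  expect_equal(cnt2$major + cnt2$minor1 + cnt2$minor2 + cnt2$n_unresolved,
               cnt2$n_loci_used)
})

test_that("binomial_minor_test matches exact tail summation", {
  expect_equal(binomial_minor_test(list(minor1 = 50, minor2 = 50)), 1)
  expect_equal(binomial_minor_test(list(minor1 = 0, minor2 = 0)), 1)
  # frozen oracle: P(X <= 30) + P(X >= 70), X ~ Bin(100, 1/2)
  oracle <- sum(dbinom(0:30, 100, 0.5)) + sum(dbinom(70:100, 100, 0.5))
  expect_equal(binomial_minor_test(list(minor1 = 30, minor2 = 70)), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 7.85e-5, tolerance = 1e-2)
  # agrees with stats::binom.test on assorted splits
  for (m in list(c(3, 9), c(12, 20), c(0, 6), c(40, 41))) {
    expect_equal(binomial_minor_test(list(minor1 = m[1], minor2 = m[2])),
                 stats::binom.test(m[1], sum(m), 0.5)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("holm_adjust performs the step-down with monotonicity", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  # never reduces a p-value; bounded by Bonferroni
  withr::with_seed(3, {
    p <- runif(50)
    a <- holm_adjust(p)
    expect_true(all(a >= p))
    expect_true(all(a <= pmin(1, length(p) * p)))
    # hand step-down oracle
    o <- order(p)
    m <- length(p)
    stepdown <- cummax(pmin((m - seq_len(m) + 1) * p[o], 1))
    expect_equal(a[o], stepdown)
  })
})

test_that("gamma_from_counts applies the minor-excess formula", {
  expect_equal(gamma_from_counts(list(major = 100, minor1 = 20,
                                      minor2 = 60)), 40 / 180)
  expect_equal(gamma_from_counts(list(major = 5, minor1 = 7, minor2 = 7)), 0)
  expect_error(gamma_from_counts(list(major = 0, minor1 = 0, minor2 = 0)),
               "undefined")
})

test_that("gamma estimates track the closed-form pulse expectation", {
  net <- gamma_layout(gamma = 0.2, t_prime = 2.0)
  gams <- ses <- numeric(6)
  for (r in 1:6) {
    gts <- simulate_gene_trees(net, 2000, seed = 600 + r)
    x <- signed_gamma_terms(gts, "O", "P1", "P2", "P3")
    gams[r] <- mean(x)
    ses[r] <- stats::sd(x) / sqrt(length(x))
  }
  pooled_se <- sqrt(mean(ses^2) / length(ses))
  expect_lt(abs(mean(gams) - expected_rt_gamma(0.2, 2.0)), 3 * pooled_se)
})

test_that("rt_scan flags a planted pulse and nothing under the null", {
  st <- null10_tree()
  # planted c -> b pulse: only tests pairing b with c should fire
  he <- data.frame(donor = "c", recipient = "b", time = 0.2, gamma = 0.3)
  gts <- simulate_gene_trees(species_network(st, he), 1000, seed = 55)
  rt <- rt_scan(gts, st, "O")
  sig <- rt[rt$significant, ]
  expect_gt(nrow(sig), 0L)
  ab <- sig[sig$P1 == "a" & sig$P2 == "b", ]
  expect_true(any(ab$P3 == "c" & ab$partner == "b" & ab$gamma > 0))

  # under label swap P1 <-> P2, p is unchanged and gamma magnitude kept
  cache <- introscan:::build_triplet_cache(gts, "O")
  r1 <- introscan:::rt_test_specs(gts,
                                  list(triplet_spec("a", "b", "c", "O")),
                                  cache, 0.001)
  r2 <- introscan:::rt_test_specs(gts,
                                  list(triplet_spec("b", "a", "c", "O")),
                                  cache, 0.001)
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(abs(r1$gamma), abs(r2$gamma))
  expect_equal(r1$partner, r2$partner)

  expect_warning(rt_scan(gene_tree_set(list(), character(0)), st, "O"),
                 "empty")
})

test_that("type-I error of the minor test matches its nominal level", {
  # ILS-only: each test's p-value is exact, so rejections at alpha = 0.05
  # across many independent-ish tests stay within the binomial envelope
  st <- null10_tree()
  net <- species_network(st)
  pvals <- c()
  for (r in 1:13) {
    gts <- simulate_gene_trees(net, 400, seed = 700 + r)
    rt <- rt_scan(gts, st, "O")
    pvals <- c(pvals, rt$p_raw)
  }
  n <- length(pvals)
  expect_gte(n, 500)
  rate <- mean(pvals < 0.05)
  # exact binomial tests are conservative at small counts; the rejection
  # rate must not exceed the nominal level beyond binomial noise
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("collapse_to_events groups clade-sharing tests and keeps
           disjoint events apart", {
  st <- parse_newick("(((A,B),(C,D)),((E,F),(X,Y)));")
  mk <- function(p1, p2, p3, m1, m2, p_adj, partner) {
    data.frame(P1 = p1, P2 = p2, P3 = p3, outgroup = "O", major = 500,
               minor1 = m1, minor2 = m2, n_unresolved = 0,
               n_loci_used = 500 + m1 + m2, p_raw = p_adj, p_adj = p_adj,
               gamma = (m2 - m1) / (500 + m1 + m2), partner = partner,
               significant = p_adj < 0.001, stringsAsFactors = FALSE)
  }
  # X implicated with both C and D (tests from pair (X,Y)) -> one event
  # at the branch ancestral to {C,D}; E-F signal with A stays separate
  res <- rbind(mk("X", "Y", "C", 10, 80, 1e-8, "X"),
               mk("X", "Y", "D", 12, 78, 1e-8, "X"),
               mk("X", "Y", "A", 40, 44, 0.9, "X"),
               mk("E", "F", "A", 11, 70, 1e-6, "E"))
  attr(res, "alpha") <- 0.001
  ev <- collapse_to_events(res, st)
  expect_equal(nrow(ev), 2L)
  expect_true(any(ev$lineage1 == "X" & ev$lineage2 == "anc(C+D)"))
  expect_true(any(ev$lineage1 == "E" & ev$lineage2 == "A"))

  # a testable-but-nonsignificant descendant blocks clade promotion
  res2 <- rbind(mk("X", "Y", "C", 10, 80, 1e-8, "X"),
                mk("X", "Y", "D", 40, 42, 0.9, "X"))
  attr(res2, "alpha") <- 0.001
  ev2 <- collapse_to_events(res2, st)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$lineage2, "C")

  expect_equal(nrow(collapse_to_events(res[res$p_adj > 0.5, ], st)), 0L)
})

test_that("a planted ancestral-recipient edge collapses to one stem event", {
  pre <- costus_like_preset()
  gts <- simulate_gene_trees(pre$network, 756, seed = 1)
  st_in <- ape::drop.tip(pre$network$tree, "OUT")
  rt <- rt_scan(gts, pre$network$tree, "OUT")
  ev <- collapse_to_events(rt, st_in)
  hit <- ev[ev$lineage1 == "t09b" & ev$lineage2 == "anc(t13a+t13b)", ]
  expect_equal(nrow(hit), 1L)  # one stem event, not two tip events
  expect_false(any(ev$lineage1 == "t09b" & ev$lineage2 %in%
                     c("t13a", "t13b")))
})
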