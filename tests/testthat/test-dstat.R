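# small helper: locus_set from named character matrices
loci_from_chars <- function(...) {
  mats <- list(...)
  aln <- lapply(mats, function(ch) {
    m <- matrix(0L, nrow(ch), ncol(ch), dimnames = dimnames(ch))
    for (b in 1:4) m[ch == c("A", "C", "G", "T")[b]] <- b
    m
  })
  names(aln) <- names(mats)
  structure(list(aln = aln,
                 locus_length = max(vapply(aln, ncol, 1L))),
            class = "locus_set")
}

cmat <- function(rows) {
  do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
}

test_that("concatenate pads missing taxa and records partitions", {
  l1 <- cmat(c(P1 = "AAAA", P2 = "AACA", P3 = "AAAA", O = "AAAA"))
  rownames(l1) <- c("P1", "P2", "P3", "O")
  l2 <- cmat(c(P1 = "GGGGGG", P2 = "GGGGGG", O = "GGGGGG"))
  rownames(l2) <- c("P1", "P2", "O")
  cc <- concatenate(loci_from_chars(locA = l1, locB = l2))
  expect_equal(ncol(cc$mat), 10L)
  expect_equal(cc$partitions$start, c(0L, 4L))
  expect_equal(cc$partitions$end, c(4L, 10L))
  # P3 absent from locB -> gap codes across its columns
  expect_true(all(cc$mat["P3", 5:10] == as.raw(0)))
  # single locus concatenation is the identity
  cc1 <- concatenate(loci_from_chars(locA = l1))
  expect_equal(ncol(cc1$mat), 4L)
})

test_that("biallelic extraction keeps exactly two-allele ungapped columns", {
  m <- cmat(c("ACAAC-",   # P1
              "ACCGCA",   # P2
              "AGCCCA",   # P3
              "AACCAA"))  # O
  rownames(m) <- c("P1", "P2", "P3", "O")
  cc <- concatenate(loci_from_chars(L = m))
  snp <- extract_biallelic_snps(cc, c("P1", "P2", "P3", "O"))
  # col1 monomorphic, col2 triallelic (C,C,G,A), col3 A/C biallelic,
  # col4 A/G/C triallelic, col5 A/C biallelic, col6 gap in P1
  expect_equal(snp$positions, c(2L, 4L))
  expect_equal(snp$alleles[, 1], c(1L, 2L, 2L, 2L))
})

test_that("thinning is greedy, idempotent and never grows", {
  tb <- structure(list(positions = c(0L, 100L, 600L),
                       alleles = matrix(1L, 4, 3),
                       taxa = c("a", "b", "c", "O")), class = "snp_table")
  th <- thin_snps(tb, 500)
  expect_equal(th$positions, c(0L, 600L))
  expect_equal(thin_snps(th, 500)$positions, th$positions)

  empty <- structure(list(positions = integer(0),
                          alleles = matrix(1L, 4, 0),
                          taxa = letters[1:4]), class = "snp_table")
  expect_equal(length(thin_snps(empty, 500)$positions), 0L)

  dense <- structure(list(positions = 0:400,
                          alleles = matrix(1L, 4, 401),
                          taxa = letters[1:4]), class = "snp_table")
  expect_equal(length(thin_snps(dense, 500)$positions), 1L)

  withr::with_seed(2, {
    pos <- sort(sample.int(10000, 300)) - 1L
    tb2 <- structure(list(positions = pos,
                          alleles = matrix(1L, 4, 300),
                          taxa = letters[1:4]), class = "snp_table")
    th2 <- thin_snps(tb2, 137)
    expect_lte(length(th2$positions), length(pos))
    expect_true(all(diff(th2$positions) >= 137))
    expect_equal(thin_snps(th2, 137)$positions, th2$positions)
  })
})

test_that("site patterns classify against the outgroup ancestral state", {
  mk <- function(...) {
    a <- matrix(unlist(list(...)), nrow = 4)
    structure(list(positions = seq_len(ncol(a)) - 1L, alleles = a,
                   taxa = c("P1", "P2", "P3", "O")), class = "snp_table")
  }
  # (P1,P2,P3,O) = (A,C,C,A) -> ABBA; (C,A,C,A) -> BABA; (C,C,A,A) -> BBAA
  cnt <- count_patterns(mk(c(1, 2, 2, 1), c(2, 1, 2, 1), c(2, 2, 1, 1),
                           c(2, 1, 1, 1)))
  expect_equal(c(cnt$abba, cnt$baba, cnt$bbaa), c(1L, 1L, 1L))
  expect_equal(cnt$n_snps_used, 4L)  # the singleton column still counts
})

test_that("D-statistic formula and degenerate input", {
  expect_equal(d_statistic(list(abba = 30, baba = 10)), 0.5)
  expect_equal(d_statistic(list(abba = 7, baba = 7)), 0)
  expect_equal(d_statistic(list(abba = 0, baba = 25)), -1)
  expect_error(d_statistic(list(abba = 0, baba = 0)), "undefined")
})

test_that("block jackknife matches the hand formula on a 4-block table", {
  # 8 SNPs, 2 per block; pattern codes chosen by allele configurations
  pats <- list(c(1, 2, 2, 1), c(2, 1, 2, 1),  # block 1: ABBA, BABA
               c(1, 2, 2, 1), c(1, 2, 2, 1),  # block 2: ABBA, ABBA
               c(2, 1, 2, 1), c(1, 2, 2, 1),  # block 3: BABA, ABBA
               c(1, 2, 2, 1), c(2, 2, 1, 1))  # block 4: ABBA, BBAA
  a <- do.call(cbind, pats)
  tb <- structure(list(positions = seq_len(8) - 1L, alleles = a,
                       taxa = c("P1", "P2", "P3", "O")), class = "snp_table")
  bj <- block_jackknife(tb, n_blocks = 4)
  # totals: ABBA 5, BABA 2 -> D = 3/7
  expect_equal(bj$D, 3 / 7)
  abba_b <- c(1, 2, 1, 1); baba_b <- c(1, 0, 1, 0)
  dj <- (5 - abba_b - (2 - baba_b)) / (5 - abba_b + 2 - baba_b)
  v <- (3 / 4) * sum((dj - mean(dj))^2)
  expect_equal(bj$SE, sqrt(v), tolerance = 1e-12)
  expect_equal(bj$Z, bj$D / bj$SE)

  # identical blocks -> SE 0, infinite Z, p 0, no crash
  same <- do.call(cbind, rep(list(c(1, 2, 2, 1)), 8))
  tb2 <- structure(list(positions = seq_len(8) - 1L, alleles = same,
                        taxa = c("P1", "P2", "P3", "O")),
                   class = "snp_table")
  bj2 <- block_jackknife(tb2, n_blocks = 4)
  expect_equal(bj2$SE, 0)
  expect_true(is.infinite(bj2$Z))
  expect_equal(bj2$p, 0)

  expect_error(block_jackknife(tb, n_blocks = 40), "fewer SNPs")
})

test_that("arrange_trio matches brute-force MRCA comparison", {
  st <- parse_newick("((A,B),C);")
  sp <- arrange_trio(triplet_spec("A", "C", "B", "O"), st)
  expect_equal(c(sp$p1, sp$p2, sp$p3), c("A", "B", "C"))
  sp2 <- arrange_trio(triplet_spec("A", "B", "C", "O"), st)
  expect_equal(c(sp2$p1, sp2$p2, sp2$p3), c("A", "B", "C"))

  withr::with_seed(19, {
    tr <- ape::rtree(10)
    tips <- tr$tip.label
    for (i in 1:20) {
      trio <- sample(tips, 3)
      sp <- arrange_trio(triplet_spec(trio[1], trio[2], trio[3], "OUT"), tr)
      # oracle: the sister pair excludes the taxon whose MRCA with the
      # others is the root of the trio subtree
      sub <- ape::keep.tip(tr, trio)
      out3 <- sapply(trio, function(t) {
        pair <- setdiff(trio, t)
        m <- ape::getMRCA(sub, pair)
        length(ape::extract.clade(sub, m)$tip.label) == 2L
      })
      expect_equal(sort(c(sp$p1, sp$p2)), sort(setdiff(trio, trio[out3])))
      expect_equal(sp$p3, trio[out3][1])
    }
  })
})

test_that("dstat_scan enumerates C(n,3) trios and matches the R path", {
  st8 <- parse_newick(paste0("((((a:.4,b:.4):.4,(c:.4,d:.4):.4):.4,",
                             "((e:.4,f:.4):.4,(g:.4,h:.4):.4):.4):10.8,",
                             "O:12);"))
  net <- species_network(st8)
  gts <- simulate_gene_trees(net, 150, seed = 5)
  aln <- simulate_alignments(gts, 600, 0.02, seed = 5)
  cc <- concatenate(aln)
  d <- dstat_scan(cc, st8, "O", min_spacing = 100, n_blocks = 10)
  expect_equal(nrow(d), choose(8, 3))

  # compiled scan equals the reference extract -> thin -> count -> D ->
  # jackknife path for every trio (up to the D >= 0 orientation flip)
  for (i in seq_len(nrow(d))) {
    trio <- c(d$P1[i], d$P2[i], d$P3[i])
    snp <- thin_snps(extract_biallelic_snps(cc, c(trio, "O")), 100)
    expect_equal(d$nSNPs[i], length(snp$positions))
    bj <- block_jackknife(snp, n_blocks = 10)
    expect_equal(d$Dstatistic[i], bj$D)
    expect_equal(d$SE[i], bj$SE, tolerance = 1e-12)
    cnt <- count_patterns(snp)
    expect_equal(c(d$ABBA[i], d$BABA[i], d$BBAA[i]),
                 c(cnt$abba, cnt$baba, cnt$bbaa))
    expect_gte(d$Dstatistic[i], 0)  # orientation convention
  }
})

test_that("swapping P1 and P2 negates D and preserves |Z| in the R path", {
  st8 <- null10_tree()
  gts <- simulate_gene_trees(species_network(st8), 200, seed = 6)
  aln <- simulate_alignments(gts, 500, 0.02, seed = 6)
  cc <- concatenate(aln)
  s1 <- thin_snps(extract_biallelic_snps(cc, c("a", "b", "c", "O")), 200)
  s2 <- thin_snps(extract_biallelic_snps(cc, c("b", "a", "c", "O")), 200)
  b1 <- block_jackknife(s1, n_blocks = 8)
  b2 <- block_jackknife(s2, n_blocks = 8)
  expect_equal(b1$D, -b2$D)
  expect_equal(abs(b1$Z), abs(b2$Z), tolerance = 1e-9)
})

test_that("a planted hybrid edge concentrates significant D in trios
           containing its players", {
  st <- null10_tree()
  he <- data.frame(donor = "g", recipient = "b", time = 0.2, gamma = 0.35)
  gts <- simulate_gene_trees(species_network(st, he), 1000, seed = 66)
  aln <- simulate_alignments(gts, 1000, 0.02, seed = 66)
  d <- dstat_scan(concatenate(aln), st, "O")
  sig <- d[d$significant & is.finite(d$Zscore), ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$P3 %in% c("b", "g", "h", "a") |
                    sig$P2 %in% c("b", "g") | sig$P1 %in% c("b", "g")))
  top <- d[which.max(abs(d$Zscore) * is.finite(d$Zscore)), ]
  expect_true(all(c("b", "g") %in% c(top$P1, top$P2, top$P3)))
})
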