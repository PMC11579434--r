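#' Concatenate per-locus alignments
#'
#' Taxa absent from a locus are padded with gaps across that locus's columns.
#' Coordinates are 0-based half-open internally (1-based in reports).
#'
#' @param loci A `locus_set` (named list of integer matrices, codes 0..4).
#' @return An object of class `concat_alignment`: `mat` (raw matrix,
#'   taxa x total sites, values 0..4), `taxa`, and `partitions` (data frame
#'   locus/start/end, 0-based half-open).
#' @export
concatenate <- function(loci) {
  aln <- loci$aln
  if (!length(aln)) stop("no loci to concatenate", call. = FALSE)
  for (i in seq_along(aln)) {
    if (!is.matrix(aln[[i]]) || is.null(rownames(aln[[i]])))
      stop("locus ", names(aln)[i],
           ": alignment must be a matrix with named rows (ragged or ",
           "unnamed sequences)", call. = FALSE)
  }
  taxa <- sort(unique(unlist(lapply(aln, rownames))))
  lens <- vapply(aln, ncol, 1L)
  total <- sum(lens)
  mat <- matrix(as.raw(0L), length(taxa), total,
                dimnames = list(taxa, NULL))
  start <- cumsum(c(0L, lens[-length(lens)]))
  for (i in seq_along(aln)) {
    m <- aln[[i]]
    cols <- (start[i] + 1L):(start[i] + lens[i])
    mat[rownames(m), cols] <- as.raw(m)
  }
  partitions <- data.frame(locus = names(aln), start = start,
                           end = start + lens, stringsAsFactors = FALSE)
  structure(list(mat = mat, taxa = taxa, partitions = partitions),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat("concat_alignment:", length(x$taxa), "taxa x", ncol(x$mat), "sites (",
      nrow(x$partitions), "loci )\n")
  invisible(x)
}

#' Read a concatenated FASTA plus partition TSV
#'
#' @param fasta_path Multi-FASTA of the concatenated alignment.
#' @param partition_path TSV with columns locus, start, end (0-based
#'   half-open); `NULL` treats the whole alignment as one locus.
#' @return A `concat_alignment`.
#' @export
read_concat_fasta <- function(fasta_path, partition_path = NULL) {
  d <- ape::read.FASTA(fasta_path)
  ch <- toupper(do.call(rbind, lapply(as.character(d), identity)))
  m <- matrix(0L, nrow(ch), ncol(ch), dimnames = list(names(d), NULL))
  for (b in 1:4) m[ch == c("A", "C", "G", "T")[b]] <- b
  taxa <- sort(names(d))
  mat <- matrix(as.raw(0L), length(taxa), ncol(m),
                dimnames = list(taxa, NULL))
  mat[rownames(m), ] <- as.raw(m)
  partitions <- if (is.null(partition_path)) {
    data.frame(locus = "all", start = 0L, end = ncol(m),
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(partition_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  structure(list(mat = mat, taxa = taxa, partitions = partitions),
            class = "concat_alignment")
}

#' Extract biallelic SNPs for four taxa
#'
#' Restricts the concatenated alignment to the four taxa; a column is kept
#' iff it shows exactly two distinct alleles among A/C/G/T and no
#' gap/ambiguity in any of the four.
#'
#' @param concat A `concat_alignment`.
#' @param taxa Character vector of 4 taxon labels (P1, P2, P3, outgroup).
#' @return An object of class `snp_table`: `positions` (0-based, strictly
#'   increasing) and `alleles` (4 x n integer matrix, rows in `taxa` order).
#' @export
extract_biallelic_snps <- function(concat, taxa) {
  stopifnot(length(taxa) == 4L)
  miss <- setdiff(taxa, concat$taxa)
  if (length(miss))
    stop("taxa absent from alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sub <- matrix(as.integer(concat$mat[taxa, , drop = FALSE]), nrow = 4L)
  nz <- colSums(sub == 0L) == 0L
  shl <- function(x) bitwShiftL(1L, pmax(x, 1L) - 1L)
  mask <- bitwOr(bitwOr(shl(sub[1L, ]), shl(sub[2L, ])),
                 bitwOr(shl(sub[3L, ]), shl(sub[4L, ])))
  popcnt <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)
  keep <- nz & popcnt[mask + 1L] == 2L
  structure(list(positions = which(keep) - 1L,
                 alleles = sub[, keep, drop = FALSE],
                 taxa = taxa),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", length(x$positions), "biallelic sites for (",
      paste(x$taxa, collapse = ", "), ")\n")
  invisible(x)
}

#' Thin a SNP table to a minimum spacing
#'
#' Greedy left-to-right retention: a row is kept iff its position is at
#' least `min_spacing` beyond the last kept position (the first row is
#' always kept). Idempotent; never increases the SNP count.
#'
#' @param table A `snp_table` with sorted positions.
#' @param min_spacing Minimum spacing in bp (default 500).
#' @return A thinned `snp_table`.
#' @export
thin_snps <- function(table, min_spacing = 500) {
  if (!length(table$positions)) return(table)
  keep <- cpp_thin_keep(as.integer(table$positions),
                        as.integer(min_spacing))
  structure(list(positions = table$positions[keep],
                 alleles = table$alleles[, keep, drop = FALSE],
                 taxa = table$taxa),
            class = "snp_table")
}

#' Classify ABBA/BABA/BBAA site patterns
#'
#' The outgroup allele defines the ancestral state A; the other allele of
#' each biallelic row is derived (B). Rows are classified over
#' (P1, P2, P3, outgroup) as ABBA, BABA or BBAA; singleton and
#' triple-derived configurations are tallied in `n_snps_used` but otherwise
#' ignored.
#'
#' @param table A `snp_table` whose taxa are ordered (P1, P2, P3, outgroup).
#' @param spec Optional [triplet_spec()] for bookkeeping.
#' @return Object of class `pattern_counts`: `abba`, `baba`, `bbaa`,
#'   `n_snps_used`.
#' @export
count_patterns <- function(table, spec = NULL) {
  a <- table$alleles
  n <- ncol(a)
  if (n == 0L) {
    return(structure(list(abba = 0L, baba = 0L, bbaa = 0L, n_snps_used = 0L,
                          spec = spec), class = "pattern_counts"))
  }
  anc <- a[4L, ]
  b1 <- a[1L, ] != anc
  b2 <- a[2L, ] != anc
  b3 <- a[3L, ] != anc
  structure(list(abba = sum(!b1 & b2 & b3),
                 baba = sum(b1 & !b2 & b3),
                 bbaa = sum(b1 & b2 & !b3),
                 n_snps_used = n, spec = spec),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("patterns: ABBA=%d BABA=%d BBAA=%d of %d SNPs\n",
              x$abba, x$baba, x$bbaa, x$n_snps_used))
  invisible(x)
}

#' ABBA-BABA D-statistic
#'
#' D = (ABBA - BABA) / (ABBA + BABA).
#'
#' @param counts A `pattern_counts` object (or list with `abba`, `baba`).
#' @return D in \[-1, 1\].
#' @export
d_statistic <- function(counts) {
  denom <- counts$abba + counts$baba
  if (denom == 0L)
    stop("D undefined: ABBA + BABA = 0", call. = FALSE)
  (counts$abba - counts$baba) / denom
}

#' Block-jackknife significance for the D-statistic
#'
#' SNPs are partitioned into `n_blocks` contiguous blocks with sizes
#' differing by at most one. Delete-one-block estimates D_(-j) give the
#' jackknife variance ((n-1)/n) * sum_j (D_(-j) - mean)^2 with n = number of
#' blocks; Z = D/SE and a two-sided normal p-value. A zero SE (all blocks
#' identical) yields Z = Inf (sign of D) and p = 0, flagged rather than an
#' error.
#'
#' @param table A thinned `snp_table` ordered (P1, P2, P3, outgroup).
#' @param spec Optional [triplet_spec()] carried through.
#' @param n_blocks Number of jackknife blocks (default 40).
#' @return List: `D`, `SE`, `Z`, `p`, `n_blocks`, `counts`.
#' @export
block_jackknife <- function(table, spec = NULL, n_blocks = 40) {
  n <- length(table$positions)
  if (n < n_blocks)
    stop("fewer SNPs (", n, ") than jackknife blocks (", n_blocks, ")",
         call. = FALSE)
  cnt <- count_patterns(table, spec)
  D <- d_statistic(cnt)
  sizes <- rep(n %/% n_blocks, n_blocks) +
    rep(c(1L, 0L), c(n %% n_blocks, n_blocks - n %% n_blocks))
  block_id <- rep(seq_len(n_blocks), sizes)
  a <- table$alleles
  anc <- a[4L, ]
  cls <- integer(n)
  cls[a[1L, ] == anc & a[2L, ] != anc & a[3L, ] != anc] <- 1L
  cls[a[1L, ] != anc & a[2L, ] == anc & a[3L, ] != anc] <- 2L
  ab_b <- tapply(cls == 1L, block_id, sum)
  ba_b <- tapply(cls == 2L, block_id, sum)
  dj <- (cnt$abba - ab_b - (cnt$baba - ba_b)) /
        (cnt$abba - ab_b + cnt$baba - ba_b)
  if (any(!is.finite(dj)))
    stop("jackknife undefined: a delete-one block removes all ABBA+BABA sites",
         call. = FALSE)
  v <- ((n_blocks - 1) / n_blocks) * sum((dj - mean(dj))^2)
  se <- sqrt(v)
  z <- if (se > 0) D / se else sign(D) * Inf
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  list(D = D, SE = se, Z = z, p = p, n_blocks = n_blocks, counts = cnt)
}

#' Arrange a trio consistently with the species tree
#'
#' Reorders the three ingroup taxa so the species-tree sister pairing
#' occupies the (P1, P2) slots; the pair itself is placed in lexicographic
#' order (the scan then reports D >= 0 by swapping P1 and P2 when needed, so
#' P2 labels the taxon sharing excess derived alleles with P3).
#'
#' @param spec A [triplet_spec()].
#' @param species_tree Rooted species tree containing all three ingroups.
#' @return A tree-arranged [triplet_spec()].
#' @export
arrange_trio <- function(spec, species_tree) {
  trio <- c(spec$p1, spec$p2, spec$p3)
  miss <- setdiff(trio, species_tree$tip.label)
  if (length(miss))
    stop("trio taxa absent from species tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  D <- mrca_depth_matrix(species_tree)
  d12 <- D[trio[1L], trio[2L]]
  d13 <- D[trio[1L], trio[3L]]
  d23 <- D[trio[2L], trio[3L]]
  if (d12 >= d13 && d12 >= d23) pair <- trio[c(1L, 2L)]
  else if (d13 >= d12 && d13 >= d23) pair <- trio[c(1L, 3L)]
  else pair <- trio[c(2L, 3L)]
  p3 <- setdiff(trio, pair)
  pair <- sort(pair)
  triplet_spec(pair[1L], pair[2L], p3, spec$outgroup)
}

#' ABBA-BABA scan over all ingroup trios
#'
#' Enumerates every unordered trio of ingroup taxa, arranges each against
#' the species tree, and runs extract -> thin -> count -> D -> jackknife per
#' trio (in compiled code). Trios are reported with D >= 0 (P1/P2 swapped
#' when needed). p-values are Holm-adjusted over the scan; the
#' `abba_gt_bbaa` flag marks trios in which the ABBA pattern is more common
#' than the BBAA pattern expected under vertical inheritance.
#'
#' @param concat A `concat_alignment`.
#' @param species_tree Rooted species tree.
#' @param outgroup Outgroup taxon label (must be in the alignment).
#' @param alpha Significance threshold on adjusted p-values.
#' @param min_spacing Thinning spacing in bp.
#' @param n_blocks Jackknife blocks.
#' @return Data frame of class `dstat_scan` with columns P1, P2, P3,
#'   Dstatistic, Zscore, SE, p_value, p_adj, ABBA, BABA, BBAA, nSNPs,
#'   abba_gt_bbaa, significant.
#' @export
dstat_scan <- function(concat, species_tree, outgroup, alpha = 0.001,
                       min_spacing = 500, n_blocks = 40) {
  if (!outgroup %in% concat$taxa)
    stop("outgroup absent from alignment", call. = FALSE)
  ingroup <- sort(intersect(setdiff(concat$taxa, outgroup),
                            species_tree$tip.label))
  if (length(ingroup) < 3L)
    stop("need at least 3 ingroup taxa shared by tree and alignment",
         call. = FALSE)
  trios <- utils::combn(ingroup, 3L)
  Dm <- mrca_depth_matrix(species_tree)

  # arrange: sister pair into slots 1,2 (lexicographic), P3 last
  arr <- apply(trios, 2L, function(tr) {
    d12 <- Dm[tr[1L], tr[2L]]; d13 <- Dm[tr[1L], tr[3L]]
    d23 <- Dm[tr[2L], tr[3L]]
    if (d12 >= d13 && d12 >= d23) c(sort(tr[c(1L, 2L)]), tr[3L])
    else if (d13 >= d12 && d13 >= d23) c(sort(tr[c(1L, 3L)]), tr[2L])
    else c(sort(tr[c(2L, 3L)]), tr[1L])
  })
  if (!is.matrix(arr)) arr <- matrix(arr, nrow = 3L)

  ridx <- match(c(arr), rownames(concat$mat))
  trio_idx <- t(matrix(ridx, nrow = 3L))
  out_row <- match(outgroup, rownames(concat$mat))

  core <- cpp_dstat_trios(concat$mat, trio_idx - 1L, out_row - 1L,
                          as.integer(min_spacing), as.integer(n_blocks))

  res <- data.frame(P1 = arr[1L, ], P2 = arr[2L, ], P3 = arr[3L, ],
                    ABBA = core[, 1L], BABA = core[, 2L], BBAA = core[, 3L],
                    nSNPs = core[, 4L], Dstatistic = core[, 5L],
                    SE = core[, 6L], stringsAsFactors = FALSE)
  # orient so D >= 0: swapping P1/P2 exchanges ABBA and BABA and negates D
  flip <- !is.na(res$Dstatistic) & res$Dstatistic < 0
  if (any(flip)) {
    tmp <- res$P1[flip]; res$P1[flip] <- res$P2[flip]; res$P2[flip] <- tmp
    tmp <- res$ABBA[flip]; res$ABBA[flip] <- res$BABA[flip]
    res$BABA[flip] <- tmp
    res$Dstatistic[flip] <- -res$Dstatistic[flip]
  }
  ok <- core[, 7L] == 1
  res$Zscore <- NA_real_
  res$Zscore[ok & res$SE > 0] <-
    res$Dstatistic[ok & res$SE > 0] / res$SE[ok & res$SE > 0]
  degen <- ok & res$SE == 0 & !is.na(res$Dstatistic) & res$Dstatistic != 0
  res$Zscore[degen] <- Inf  # all jackknife blocks identical: flagged
  res$p_value <- ifelse(is.finite(res$Zscore),
                        2 * stats::pnorm(-abs(res$Zscore)),
                        ifelse(is.infinite(res$Zscore), 0, NA_real_))
  res$p_adj <- NA_real_
  okp <- !is.na(res$p_value)
  res$p_adj[okp] <- holm_adjust(res$p_value[okp])
  res$abba_gt_bbaa <- res$ABBA > res$BBAA
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res <- res[, c("P1", "P2", "P3", "Dstatistic", "Zscore", "SE", "p_value",
                 "p_adj", "ABBA", "BABA", "BBAA", "nSNPs", "abba_gt_bbaa",
                 "significant")]
  attr(res, "alpha") <- alpha
  class(res) <- c("dstat_scan", "data.frame")
  res
}
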