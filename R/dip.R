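#' Per-locus pairwise divergences and topology classes for a triplet
#'
#' For each locus containing all four taxa of `spec`, computes the three
#' pairwise p-distances among P1, P2 and P3 (proportion of differing sites
#' over columns ungapped in both taxa of a pair) and the locus's rooted
#' topology class from its gene tree: `C` (concordant, P1-P2 sister), `D23`
#' (P2-P3 sister), `D13` (P1-P3 sister), or `UNRESOLVED`. With
#' `distance = "patristic"` the divergences are path lengths on the gene
#' tree instead, for workflows without alignments.
#'
#' @param alignments A `locus_set`, or `NULL` with `distance = "patristic"`.
#' @param spec A [triplet_spec()].
#' @param gene_trees A [gene_tree_set()] aligned with `alignments` by locus
#'   id.
#' @param distance `"p"` (default) or `"patristic"`.
#' @param cache Optional precomputed triplet cache (internal; shared across
#'   calls by [run_scan()]).
#' @return Data frame of class `divergence_records`: locus, d12, d13, d23,
#'   class. Loci with zero comparable sites for any pair are dropped and
#'   tallied in attribute `n_dropped`.
#' @export
locus_divergences <- function(alignments, spec, gene_trees,
                              distance = c("p", "patristic"),
                              cache = NULL) {
  distance <- match.arg(distance)
  need <- c(spec$p1, spec$p2, spec$p3, spec$outgroup)
  if (is.null(cache)) cache <- build_triplet_cache(gene_trees,
                                                   spec$outgroup)
  empty <- data.frame(locus = character(0), d12 = numeric(0),
                      d13 = numeric(0), d23 = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (!all(c(spec$p1, spec$p2, spec$p3) %in% cache$taxa)) {
    attr(empty, "n_dropped") <- 0L
    attr(empty, "spec") <- spec
    class(empty) <- c("divergence_records", "data.frame")
    return(empty)
  }
  labels <- cache_triplet_labels(cache, spec$p1, spec$p2, spec$p3)
  rows <- list()
  n_dropped <- 0L
  for (li in seq_along(gene_trees$ids)) {
    lid <- gene_trees$ids[li]
    gt <- gene_trees$trees[[lid]]
    if (is.na(labels[li]) || !spec$outgroup %in% gt$tip.label) next
    cls <- c(AB = "C", BC = "D23", AC = "D13",
             UNRESOLVED = "UNRESOLVED")[labels[li]]
    if (distance == "p") {
      m <- alignments$aln[[lid]]
      if (is.null(m) || !all(need[1:3] %in% rownames(m))) next
      d12 <- p_distance(m[spec$p1, ], m[spec$p2, ])
      d13 <- p_distance(m[spec$p1, ], m[spec$p3, ])
      d23 <- p_distance(m[spec$p2, ], m[spec$p3, ])
    } else {
      pd <- gene_tree_path_lengths(gt, c(spec$p1, spec$p2, spec$p3))
      d12 <- pd["p1p2"]; d13 <- pd["p1p3"]; d23 <- pd["p2p3"]
    }
    if (any(is.na(c(d12, d13, d23)))) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = lid, d12 = d12, d13 = d13, d23 = d23, class = cls,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), d12 = numeric(0), d13 = numeric(0),
               d23 = numeric(0), class = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "spec") <- spec
  class(out) <- c("divergence_records", "data.frame")
  out
}

# p-distance between two coded sequences (codes 1..4; 0 = gap/ambiguity,
# excluded pairwise). NA when no comparable site.
p_distance <- function(x, y) {
  ok <- x > 0L & y > 0L
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(x[ok] != y[ok]) / n
}

# patristic distances among three tips of a gene tree
gene_tree_path_lengths <- function(tree, tips) {
  tr <- ape::keep.tip(tree, tips)
  dm <- ape::cophenetic.phylo(tr)
  c(p1p2 = dm[tips[1L], tips[2L]],
    p1p3 = dm[tips[1L], tips[3L]],
    p2p3 = dm[tips[2L], tips[3L]])
}

# stratum means; NA when the stratum is smaller than min_loci
stratum_mean <- function(records, cls, col, min_loci) {
  v <- records[[col]][records$class == cls]
  if (length(v) < min_loci) NA_real_ else mean(v)
}

#' Uncorrected divergence contrasts (basic DIP)
#'
#' Delta12 = mean(d12 | D23) - mean(d12 | C): elevated sister-pair
#' divergence among loci whose gene trees join P2 with P3, relative to
#' concordant loci. Delta13 = mean(d13 | C) - mean(d13 | D23). Both are
#' inflated by incomplete lineage sorting alone (discordant loci coalesce
#' deeper), which is why the corrected contrasts of [dip_corrected()] are
#' used for inference; the uncorrected form is reported for diagnostics.
#'
#' @param records A `divergence_records` data frame.
#' @param min_loci Minimum loci per stratum (default 20); smaller strata
#'   flag the statistic as undefined (NA).
#' @return Object of class `dip_result` with `delta12`, `delta13`,
#'   `corrected = FALSE`, per-class locus counts, `spec`.
#' @export
dip_statistics <- function(records, min_loci = 20) {
  n <- table(factor(records$class, c("C", "D23", "D13", "UNRESOLVED")))
  structure(list(
    delta12 = stratum_mean(records, "D23", "d12", min_loci) -
      stratum_mean(records, "C", "d12", min_loci),
    delta13 = stratum_mean(records, "C", "d13", min_loci) -
      stratum_mean(records, "D23", "d13", min_loci),
    corrected = FALSE, n_by_class = n, min_loci = min_loci,
    spec = attr(records, "spec")),
    class = "dip_result")
}

#' ILS-corrected divergence contrasts (corrected DIP)
#'
#' Contrasts the two discordant strata, which are exchangeable under
#' P1 <-> P2 relabeling when only incomplete lineage sorting acts, so both
#' statistics have expectation 0 under the null:
#' Delta12_corr = mean(d12 | D23) - mean(d12 | D13) and
#' Delta13_corr = mean(d13 | D23) - mean(d23 | D13).
#' A strongly negative Delta12_corr arises when the D23 stratum is enriched
#' with introgressed loci whose sister-pair divergence is ordinary (the
#' donor is P2 and the recipient P3: P2's own lineage never leaves its
#' branch, so d12 stays shallow at introgressed loci); the relabeled mirror
#' (significantly positive) implicates P1 as donor into P3. Gene flow in
#' the opposite direction (P3 into P2) perturbs d12 only weakly, which is
#' why direction calls compare the contrast across the two candidate
#' recipient framings (see [polarize()]).
#'
#' @inheritParams dip_statistics
#' @return Object of class `dip_result` with `delta12`, `delta13`,
#'   `corrected = TRUE`, per-class locus counts, `spec`.
#' @export
dip_corrected <- function(records, min_loci = 20) {
  n <- table(factor(records$class, c("C", "D23", "D13", "UNRESOLVED")))
  structure(list(
    delta12 = stratum_mean(records, "D23", "d12", min_loci) -
      stratum_mean(records, "D13", "d12", min_loci),
    delta13 = stratum_mean(records, "D23", "d13", min_loci) -
      stratum_mean(records, "D13", "d23", min_loci),
    corrected = TRUE, n_by_class = n, min_loci = min_loci,
    spec = attr(records, "spec")),
    class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip_result (%s): delta12=%s delta13=%s\n",
              if (x$corrected) "corrected" else "uncorrected",
              format(x$delta12, digits = 4), format(x$delta13, digits = 4)))
  if (!is.null(x$p12)) cat(sprintf("  bootstrap p12=%g p13=%g (%d reps)\n",
                                   x$p12, x$p13, x$n_reps))
  invisible(x)
}

#' Bootstrap p-value for a DIP statistic
#'
#' Loci are resampled with replacement; the two-sided p-value is twice the
#' fraction of replicates whose statistic has the opposite sign to the
#' observed value, floored at 1/n_reps and capped at 1.
#'
#' @param records A `divergence_records` data frame.
#' @param statistic Function `records -> numeric` (e.g.
#'   `function(r) dip_corrected(r)$delta12`).
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List: `p`, `se` (bootstrap SE), `observed`, `n_reps`.
#' @export
dip_bootstrap <- function(records, statistic, n_reps = 1000, seed = 1) {
  obs <- statistic(records)
  if (is.na(obs)) return(list(p = NA_real_, se = NA_real_, observed = obs,
                              n_reps = n_reps))
  set.seed(derive_seed(seed, 97L))
  n <- nrow(records)
  d12 <- records$d12; d13 <- records$d13; d23 <- records$d23
  cls <- records$class
  reps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    rec <- list(d12 = d12[idx], d13 = d13[idx], d23 = d23[idx],
                class = cls[idx])
    reps[r] <- statistic(rec)
  }
  opp <- sum(!is.na(reps) & sign(reps) != sign(obs) & reps != 0) +
    sum(!is.na(reps) & reps == 0) / 2
  p <- min(1, max(1 / n_reps, 2 * opp / sum(!is.na(reps))))
  list(p = p, se = stats::sd(reps, na.rm = TRUE), observed = obs,
       n_reps = n_reps)
}

#' Recipient-enriched direction contrast
#'
#' Restricts the D23 stratum to its recent half (loci whose P2-P3 cherry
#' divergence d23 is at or below the stratum median), which is enriched for
#' introgressed rather than deep-coalescing loci, and contrasts the
#' sister-pair divergence there against the D13 control:
#' `mean(d12 | D23, d23 <= median) - mean(d12 | D13)`. When the candidate
#' recipient P3 received from P2 these recent-cherry loci have ordinary
#' (shallow) d12 and the contrast is strongly negative; under gene flow in
#' the other direction d12 at introgressed loci remains deep and the
#' contrast stays near the incomplete-lineage-sorting level. Used only for
#' comparing candidate recipient framings in [polarize()]; under the pure
#' coalescent null the conditioning makes it slightly negative, so it
#' carries no significance claim of its own.
#'
#' @param records A `divergence_records` data frame.
#' @param min_loci Minimum loci in the D13 control (the purified D23 half
#'   must hold at least `min_loci / 2`).
#' @return The contrast, or NA when a stratum is too small.
#' @export
dip_direction_contrast <- function(records, min_loci = 20) {
  d23s <- records$d23[records$class == "D23"]
  if (length(d23s) < min_loci) return(NA_real_)
  q <- stats::median(d23s)
  recent <- records$class == "D23" & records$d23 <= q
  ctrl <- records$d12[records$class == "D13"]
  if (sum(recent) < min_loci / 2 || length(ctrl) < min_loci)
    return(NA_real_)
  mean(records$d12[recent]) - mean(ctrl)
}

#' Attach bootstrap p-values to a DIP result
#'
#' @param records A `divergence_records` data frame.
#' @param corrected Use the corrected contrasts (default TRUE).
#' @param min_loci,n_reps,seed See [dip_statistics()], [dip_bootstrap()].
#' @return A `dip_result` with `p12`, `p13`, `se12`, `se13`, and (when
#'   `corrected`) the direction contrast `delta_dir` with bootstrap
#'   `se_dir`; `n_reps`.
#' @export
dip_test <- function(records, corrected = TRUE, min_loci = 20,
                     n_reps = 1000, seed = 1) {
  maker <- if (corrected) dip_corrected else dip_statistics
  res <- maker(records, min_loci)
  stat12 <- if (corrected) {
    function(r) stratum_mean(r, "D23", "d12", min_loci) -
      stratum_mean(r, "D13", "d12", min_loci)
  } else {
    function(r) stratum_mean(r, "D23", "d12", min_loci) -
      stratum_mean(r, "C", "d12", min_loci)
  }
  stat13 <- if (corrected) {
    function(r) stratum_mean(r, "D23", "d13", min_loci) -
      stratum_mean(r, "D13", "d23", min_loci)
  } else {
    function(r) stratum_mean(r, "C", "d13", min_loci) -
      stratum_mean(r, "D23", "d13", min_loci)
  }
  b12 <- dip_bootstrap(records, stat12, n_reps, seed)
  b13 <- dip_bootstrap(records, stat13, n_reps, derive_seed(seed, 2L))
  res$p12 <- b12$p; res$se12 <- b12$se
  res$p13 <- b13$p; res$se13 <- b13$se
  if (corrected) {
    bd <- dip_bootstrap(records,
                        function(r) dip_direction_contrast(r, min_loci),
                        n_reps, derive_seed(seed, 3L))
    res$delta_dir <- bd$observed
    res$se_dir <- bd$se
  }
  res$n_reps <- n_reps
  res
}

#' Call the direction of introgression from corrected DIP contrasts
#'
#' With a single framing (P1, P2; P3): a significantly negative
#' Delta12_corr calls `"P2->P3"` (P2 donated into P3); a significantly
#' positive one implicates the other sister and calls `"P1->P3"`;
#' conflicting significant primary and auxiliary contrasts give
#' `"bidirectional/unresolved"`; nothing significant gives `"none"`.
#'
#' With a second framing `result_rev` — the corrected contrast recomputed
#' with the roles of the introgressing pair exchanged, i.e. (sister(P3),
#' P3; P2) — the two contrasts are compared: the framing with the clearly
#' stronger negative signal names the recipient (its third taxon). This is
#' the double-framing strategy for polarizing donor and recipient, and is
#' what the pipeline uses for event arrows.
#'
#' @param result A corrected `dip_result` from [dip_test()] for framing
#'   (P1, P2; P3).
#' @param result_rev Optional corrected `dip_result` for the reversed
#'   framing (sister(P3), P3; P2).
#' @param alpha Significance level for the bootstrap p-values.
#' @return A direction string: with one framing, one of `"P2->P3"`,
#'   `"P1->P3"`, `"bidirectional/unresolved"`, `"none"`; with two framings,
#'   one of `"P3->P2"`, `"P2->P3"`, `"bidirectional/unresolved"`, `"none"`
#'   (directions named between the introgressing pair P2, P3).
#' @export
polarize <- function(result, result_rev = NULL, alpha = 0.05) {
  sig <- function(r) !is.null(r$p12) && !is.na(r$p12) && !is.na(r$delta12) &&
    r$p12 < alpha
  if (is.null(result_rev)) {
    if (!sig(result)) return("none")
    primary <- if (result$delta12 < 0) "P2->P3" else "P1->P3"
    if (!is.null(result$p13) && !is.na(result$p13) &&
        result$p13 < alpha && !is.na(result$delta13) &&
        sign(result$delta13) != sign(result$delta12))
      return("bidirectional/unresolved")
    return(primary)
  }
  sA <- sig(result) && result$delta12 < 0      # recipient = this framing's P3
  sB <- sig(result_rev) && result_rev$delta12 < 0  # recipient = P2
  if (!sA && !sB) return("none")
  # compare the recipient-enriched direction contrasts across framings
  dA <- result$delta_dir %||% NA_real_
  dB <- result_rev$delta_dir %||% NA_real_
  seA <- result$se_dir %||% NA_real_
  seB <- result_rev$se_dir %||% NA_real_
  if (!any(is.na(c(dA, dB, seA, seB))) &&
      abs(dA - dB) > 2 * sqrt(seA^2 + seB^2))
    return(if (dA < dB) "P2->P3" else "P3->P2")
  if (sA && !sB) return("P2->P3")
  if (sB && !sA) return("P3->P2")
  "bidirectional/unresolved"
}
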