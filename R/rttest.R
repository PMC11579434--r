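#' Enumerate rooted-triplet specifications from a species tree
#'
#' Each sister pair of tips (P1, P2) is combined with every other ingroup
#' tip P3 and the designated outgroup, giving (#sister pairs) x
#' (#ingroup tips - 2) specifications in a deterministic order.
#'
#' @param species_tree Rooted `phylo` with at least 4 tips (the outgroup may
#'   be included in the tree or external).
#' @param outgroup Outgroup taxon label.
#' @return List of [triplet_spec()] objects.
#' @export
enumerate_triplets <- function(species_tree, outgroup) {
  ingroup_tree <- species_tree
  if (outgroup %in% species_tree$tip.label)
    ingroup_tree <- ape::drop.tip(species_tree, outgroup)
  pairs <- sister_pairs(ingroup_tree)
  if (!length(pairs)) {
    warning("species tree has no sister pair of tips; no triplet tests")
    return(list())
  }
  tips <- sort(ingroup_tree$tip.label)
  specs <- list()
  for (pr in pairs) {
    for (p3 in setdiff(tips, pr)) {
      specs[[length(specs) + 1L]] <-
        triplet_spec(pr[1L], pr[2L], p3, outgroup)
    }
  }
  specs
}

#' Count gene-tree topologies for one triplet
#'
#' Loci lacking any of the four taxa are skipped. The count concordant with
#' the putative sister pair (P1,P2) of `spec` is `major`; the two others are
#' assigned `minor1`/`minor2` with `minor2 >= minor1`, retaining which
#' ingroup pairing each refers to. Loci in which the three ingroup taxa form
#' a polytomy are tallied as unresolved and excluded from the three counts.
#'
#' @param gene_trees A [gene_tree_set()].
#' @param spec A [triplet_spec()].
#' @param cache Optional precomputed cache (internal use by [rt_scan()]).
#' @return An object of class `triplet_counts`: list with `major`, `minor1`,
#'   `minor2`, `minor1_pairing`, `minor2_pairing` (`"P1P3"`/`"P2P3"`),
#'   `n_unresolved`, `n_loci_used` (loci containing all four taxa), `spec`.
#' @export
count_topologies <- function(gene_trees, spec, cache = NULL) {
  if (is.null(cache)) {
    labels <- character(length(gene_trees$trees))
    for (l in seq_along(gene_trees$trees)) {
      tr <- gene_trees$trees[[l]]
      need <- c(spec$p1, spec$p2, spec$p3, spec$outgroup)
      if (!all(need %in% tr$tip.label)) {
        labels[l] <- NA_character_
        next
      }
      labels[l] <- triplet_topology(tr, spec)
    }
  } else {
    lab <- cache_triplet_labels(cache, spec$p1, spec$p2, spec$p3)
    labels <- c(AB = "P1P2", AC = "P1P3", BC = "P2P3",
                UNRESOLVED = "UNRESOLVED")[lab]
  }
  n_used <- sum(!is.na(labels))
  if (n_used == 0L)
    stop("no usable loci for triplet (", spec$p1, ",", spec$p2, ",",
         spec$p3, ")", call. = FALSE)
  major <- sum(labels == "P1P2", na.rm = TRUE)
  c13 <- sum(labels == "P1P3", na.rm = TRUE)
  c23 <- sum(labels == "P2P3", na.rm = TRUE)
  unres <- sum(labels == "UNRESOLVED", na.rm = TRUE)
  if (c23 >= c13) {
    minor1 <- c13; minor2 <- c23
    minor1_pairing <- "P1P3"; minor2_pairing <- "P2P3"
  } else {
    minor1 <- c23; minor2 <- c13
    minor1_pairing <- "P2P3"; minor2_pairing <- "P1P3"
  }
  structure(list(major = major, minor1 = minor1, minor2 = minor2,
                 minor1_pairing = minor1_pairing,
                 minor2_pairing = minor2_pairing,
                 n_unresolved = unres, n_loci_used = n_used, spec = spec),
            class = "triplet_counts")
}

#' @export
print.triplet_counts <- function(x, ...) {
  cat(sprintf("triplet counts: major=%d minor1=%d minor2=%d (%s) unresolved=%d of %d loci\n",
              x$major, x$minor1, x$minor2, x$minor2_pairing,
              x$n_unresolved, x$n_loci_used))
  invisible(x)
}

#' Exact binomial test of minor-topology balance
#'
#' Under incomplete lineage sorting alone the two minor topologies are
#' equally frequent; the two-sided exact probability of a split at least as
#' extreme as (minor1, minor2) under Binomial(minor1+minor2, 1/2) is
#' returned. Defined as 1 when minor1 + minor2 = 0.
#'
#' @param counts A `triplet_counts` object (or a list with `minor1`,
#'   `minor2`).
#' @return Two-sided p-value.
#' @export
binomial_minor_test <- function(counts) {
  m1 <- counts$minor1; m2 <- counts$minor2
  n <- m1 + m2
  if (n == 0L) return(1)
  min(1, 2 * stats::pbinom(min(m1, m2), n, 0.5))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement, capped at 1,
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "holm")
}

#' Introgression proportion from triplet counts
#'
#' gamma = (minor2 - minor1) / (major + minor1 + minor2): the estimated
#' fraction of the genome inherited through the hybrid edge, attributed to
#' the pairing of P3 with the sister-pair member named by `minor2_pairing`.
#'
#' @param counts A `triplet_counts` object.
#' @return Gamma in \[0, 1).
#' @export
gamma_from_counts <- function(counts) {
  denom <- counts$major + counts$minor1 + counts$minor2
  if (denom == 0L)
    stop("gamma undefined: no resolved loci", call. = FALSE)
  (counts$minor2 - counts$minor1) / denom
}

# The sister-pair member implicated by the excess minor pairing.
partner_tip <- function(counts) {
  if (counts$minor2_pairing == "P2P3") counts$spec$p2 else counts$spec$p1
}

# Run counts + binomial test over an arbitrary list of triplet specs; shared
# by rt_scan and the f-branch score provider. Works directly on the MRCA
# depth cache for speed.
rt_test_specs <- function(gene_trees, specs, cache, alpha) {
  k <- length(specs)
  P1 <- P2 <- P3 <- OG <- partner <- character(k)
  major <- minor1 <- minor2 <- unres <- used <- integer(k)
  gam <- p_raw <- numeric(k)
  ok <- logical(k)
  for (i in seq_len(k)) {
    sp <- specs[[i]]
    if (!all(c(sp$p1, sp$p2, sp$p3) %in% cache$taxa)) next
    lab <- cache_triplet_labels(cache, sp$p1, sp$p2, sp$p3)
    n_used <- sum(!is.na(lab))
    if (n_used == 0L) next
    mj <- sum(lab == "AB", na.rm = TRUE)
    c13 <- sum(lab == "AC", na.rm = TRUE)
    c23 <- sum(lab == "BC", na.rm = TRUE)
    nu <- n_used - mj - c13 - c23
    m1 <- min(c13, c23); m2 <- max(c13, c23)
    denom <- mj + m1 + m2
    ok[i] <- TRUE
    P1[i] <- sp$p1; P2[i] <- sp$p2; P3[i] <- sp$p3; OG[i] <- sp$outgroup
    major[i] <- mj; minor1[i] <- m1; minor2[i] <- m2
    unres[i] <- nu; used[i] <- n_used
    p_raw[i] <- if (m1 + m2 == 0L) 1 else
      min(1, 2 * stats::pbinom(m1, m1 + m2, 0.5))
    gam[i] <- if (denom > 0L) (m2 - m1) / denom else NA_real_
    partner[i] <- if (c23 >= c13) sp$p2 else sp$p1
  }
  if (!any(ok)) return(NULL)
  res <- data.frame(
    P1 = P1[ok], P2 = P2[ok], P3 = P3[ok], outgroup = OG[ok],
    major = major[ok], minor1 = minor1[ok], minor2 = minor2[ok],
    n_unresolved = unres[ok], n_loci_used = used[ok], p_raw = p_raw[ok],
    p_adj = holm_adjust(p_raw[ok]), gamma = gam[ok], partner = partner[ok],
    stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  res
}

#' Rooted-triplet introgression scan
#'
#' Enumerates one test per (sister pair, other ingroup tip), counts gene-tree
#' topologies per test, applies the exact binomial minor test, adjusts
#' p-values by Holm-Bonferroni over the whole scan family, and reports the
#' gamma estimate and the implicated partner tip for each test.
#'
#' @param gene_trees A [gene_tree_set()].
#' @param species_tree Rooted species tree (`phylo`).
#' @param outgroup Outgroup taxon label (used to root gene trees).
#' @param alpha Family-wise significance threshold on adjusted p-values.
#' @return Data frame of class `rt_scan` with one row per test: P1, P2, P3,
#'   outgroup, major, minor1, minor2, n_unresolved, n_loci_used, p_raw,
#'   p_adj, gamma, partner, significant.
#' @export
rt_scan <- function(gene_trees, species_tree, outgroup, alpha = 0.001) {
  if (length(gene_trees) == 0L) {
    warning("empty gene-tree set: no tests run")
    return(structure(data.frame(), class = c("rt_scan", "data.frame")))
  }
  specs <- enumerate_triplets(species_tree, outgroup)
  if (!length(specs))
    return(structure(data.frame(), class = c("rt_scan", "data.frame")))
  cache <- build_triplet_cache(gene_trees, outgroup)
  res <- rt_test_specs(gene_trees, specs, cache, alpha)
  if (is.null(res))
    return(structure(data.frame(), class = c("rt_scan", "data.frame")))
  attr(res, "alpha") <- alpha
  class(res) <- c("rt_scan", "data.frame")
  res
}

# Maximal-clade grouping used by collapse_to_events: given a set of flagged
# tips and the set of tips that were testable at all, return a list of
# events, each a character vector of tips forming a clade in which >= 2
# flagged tips occur and no testable-but-unflagged tip does; remaining
# flagged tips become singleton events.
group_into_clades <- function(tree, flagged, testable, sets, parent, ntip) {
  flagged <- unique(flagged)
  qualifying <- integer(0)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    desc <- sets[[v]]
    t_in <- intersect(desc, testable)
    f_in <- intersect(desc, flagged)
    if (length(f_in) >= 2L && length(setdiff(t_in, flagged)) == 0L &&
        length(f_in) == length(intersect(desc, flagged)))
      qualifying <- c(qualifying, v)
  }
  # keep maximal qualifying nodes only
  maximal <- qualifying[!vapply(qualifying, function(v)
    any(vapply(qualifying, function(w)
      w != v && all(sets[[v]] %in% sets[[w]]), TRUE)), TRUE)]
  events <- list()
  used <- character(0)
  for (v in maximal) {
    members <- intersect(sets[[v]], flagged)
    events[[length(events) + 1L]] <-
      list(node = v, tips = sets[[v]], flagged = members)
    used <- c(used, members)
  }
  for (tp in setdiff(flagged, used))
    events[[length(events) + 1L]] <-
      list(node = NA_integer_, tips = tp, flagged = tp)
  events
}

branch_name <- function(tips) {
  if (length(tips) == 1L) tips else paste0("anc(", paste(sort(tips), collapse = "+"), ")")
}

#' Collapse correlated significant triplet tests into hybridization events
#'
#' Significant tests implicate unordered taxon pairs (the sister-pair member
#' named by the excess minor pairing, and P3). Pairs sharing one side are
#' merged into an ancestral event when the tips on the other side form a
#' clade of the species tree with at least two of them independently
#' significant with the same partner (tips of the clade that were testable
#' against the partner but not significant block the merge). Event gamma is
#' an f-branch-style summary: the median over recipients of the minimum
#' gamma across partner tips. Events whose signal may be a bridge artifact
#' (A-B and B-C significant, A-C significant with the smallest gamma of the
#' three) are flagged, not removed. Direction is `"unpolarized"` here;
#' divergence-based polarization assigns arrows downstream.
#'
#' @param results An `rt_scan` data frame.
#' @param species_tree Rooted species tree used for the scan.
#' @param alpha Significance threshold on adjusted p-values (defaults to the
#'   scan's own).
#' @return Data frame of class `event_table`: lineage1, lineage2, direction,
#'   gamma, n_tests, bridge_candidate, tests (semicolon-joined test labels).
#' @export
collapse_to_events <- function(results, species_tree,
                               alpha = attr(results, "alpha") %||% 0.001) {
  empty <- data.frame(lineage1 = character(0), lineage2 = character(0),
                      direction = character(0), gamma = numeric(0),
                      n_tests = integer(0), bridge_candidate = logical(0),
                      tests = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("event_table", "data.frame")
  if (nrow(results) == 0L) return(empty)
  sig <- results[results$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)

  st <- species_tree
  if (any(!sig$partner %in% st$tip.label))
    stop("scan results reference taxa absent from the species tree",
         call. = FALSE)
  ntip <- length(st$tip.label)
  sets <- node_tip_sets(st)
  parent <- integer(ntip + st$Nnode)
  parent[st$edge[, 2L]] <- st$edge[, 1L]

  test_label <- function(rows) paste0("(", rows$P1, ",", rows$P2, ";",
                                      rows$P3, ")")
  sig$pair_a <- pmin(sig$partner, sig$P3)
  sig$pair_b <- pmax(sig$partner, sig$P3)
  all_res <- results
  all_res$pa <- pmin(all_res$partner, all_res$P3)

  # stage 1: for each partner (sister-side tip), group significant P3 tips
  # into clades
  gamma_of <- function(a, b) {
    i <- which((sig$partner == a & sig$P3 == b) |
               (sig$partner == b & sig$P3 == a))
    if (!length(i)) NA_real_ else max(sig$gamma[i])
  }
  stage1 <- list()
  for (a in unique(sig$partner)) {
    p3s <- unique(sig$P3[sig$partner == a])
    testable <- unique(results$P3[results$partner == a |
                                  results$P1 == a | results$P2 == a])
    grp <- group_into_clades(st, p3s, testable, sets, parent, ntip)
    for (g in grp)
      stage1[[length(stage1) + 1L]] <- list(side_a = a, side_b = g$tips)
  }
  # stage 2: merge side_a tips that share an identical side_b clade
  keyb <- vapply(stage1, function(g) set_key(g$side_b), "")
  events <- list()
  for (kb in unique(keyb)) {
    grp <- stage1[keyb == kb]
    a_tips <- unique(vapply(grp, `[[`, "", "side_a"))
    side_b <- grp[[1L]]$side_b
    if (length(a_tips) >= 2L) {
      testable_a <- unique(unlist(lapply(side_b, function(b) {
        r <- results[results$P3 == b, , drop = FALSE]
        c(r$P1, r$P2)
      })))
      agrp <- group_into_clades(st, a_tips, testable_a, sets, parent, ntip)
      for (g in agrp)
        events[[length(events) + 1L]] <- list(A = g$tips, B = side_b)
    } else {
      events[[length(events) + 1L]] <- list(A = a_tips, B = side_b)
    }
  }

  # drop events whose significant pair set is contained in another's (the
  # same edge seen from the other orientation)
  pair_sets <- lapply(events, function(ev) {
    keep <- (sig$partner %in% ev$A & sig$P3 %in% ev$B) |
            (sig$partner %in% ev$B & sig$P3 %in% ev$A)
    unique(paste(pmin(sig$partner, sig$P3)[keep],
                 pmax(sig$partner, sig$P3)[keep]))
  })
  subsumed <- vapply(seq_along(events), function(i) {
    any(vapply(seq_along(events), function(j) {
      if (i == j) return(FALSE)
      si <- pair_sets[[i]]; sj <- pair_sets[[j]]
      all(si %in% sj) && (length(sj) > length(si) || j < i)
    }, TRUE))
  }, TRUE)
  events <- events[!subsumed]

  rows <- lapply(events, function(ev) {
    gm <- vapply(ev$B, function(b)
      suppressWarnings(min(vapply(ev$A, function(a) gamma_of(a, b), 0),
                           na.rm = TRUE)), 0)
    gm <- gm[is.finite(gm)]
    idx <- which((sig$partner %in% ev$A & sig$P3 %in% ev$B) |
                 (sig$partner %in% ev$B & sig$P3 %in% ev$A))
    data.frame(lineage1 = branch_name(ev$A), lineage2 = branch_name(ev$B),
               direction = "unpolarized",
               gamma = if (length(gm)) stats::median(gm) else NA_real_,
               n_tests = length(idx), bridge_candidate = FALSE,
               tests = paste(test_label(sig[idx, ]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  # bridge flag: pairs (A,B), (B,C), (A,C) all significant with gamma(A,C)
  # smallest -> the (A,C) signal may be indirect
  pair_set <- unique(sig[, c("pair_a", "pair_b", "gamma")])
  has_pair <- function(x, y)
    any(pair_set$pair_a == min(x, y) & pair_set$pair_b == max(x, y))
  pg <- function(x, y) max(pair_set$gamma[pair_set$pair_a == min(x, y) &
                                          pair_set$pair_b == max(x, y)])
  for (i in seq_len(nrow(out))) {
    a_tips <- strsplit(gsub("^anc\\(|\\)$", "", out$lineage1[i]), "+",
                       fixed = TRUE)[[1L]]
    b_tips <- strsplit(gsub("^anc\\(|\\)$", "", out$lineage2[i]), "+",
                       fixed = TRUE)[[1L]]
    for (a in a_tips) for (b in b_tips) {
      if (!has_pair(a, b)) next
      bridges <- unique(c(sig$pair_a, sig$pair_b))
      for (m in setdiff(bridges, c(a, b))) {
        if (has_pair(a, m) && has_pair(m, b) &&
            pg(a, b) <= min(pg(a, m), pg(m, b)))
          out$bridge_candidate[i] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write an rt scan or event table as TSV
#'
#' @param x Data frame (`rt_scan` or `event_table`).
#' @param path Output path.
#' @export
write_scan_tsv <- function(x, path) write_tsv(as.data.frame(x), path)
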