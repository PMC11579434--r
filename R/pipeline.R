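#' Scan configuration
#'
#' Collects all tunable parameters of an end-to-end scan with the defaults
#' used throughout: triplet and D-statistic family-wise thresholds 0.001,
#' SNP thinning to one per 500 bp, 40 jackknife blocks, optional gene-tree
#' support collapsing, DIP settings, and an f-branch concordance threshold
#' of 0.04 below which allele-sharing signal is treated as weak.
#'
#' Serializes losslessly to YAML via [write_scan_config()] /
#' [read_scan_config()].
#'
#' @param species_tree Path to a rooted species tree (Newick) or a `phylo`.
#' @param gene_trees Path to a gene-tree file (one Newick per line) or a
#'   [gene_tree_set()].
#' @param alignments Optional path (directory of per-locus FASTA) or
#'   `locus_set`; `NULL` skips the site-pattern scan and uses patristic
#'   distances for DIP.
#' @param outgroup Outgroup taxon label.
#' @param taxon_map Optional path to a sample-to-species TSV or a data
#'   frame; scans then run on one representative sample per species.
#' @param alpha_rt,alpha_d Significance thresholds (adjusted p).
#' @param min_spacing Thinning spacing, bp.
#' @param n_blocks Jackknife blocks.
#' @param collapse_support Support threshold below which gene-tree branches
#'   are collapsed before counting (`NULL` = no collapsing).
#' @param dip_min_loci,dip_n_reps,dip_alpha DIP settings.
#' @param fbranch_threshold Concordance threshold on f-branch cells.
#' @param seed Integer seed (bootstrap streams).
#' @param out_dir Output directory for TSV/YAML reports (`NULL` = no files).
#' @return List of class `scan_config`.
#' @export
scan_config <- function(species_tree, gene_trees, alignments = NULL,
                        outgroup, taxon_map = NULL,
                        alpha_rt = 0.001, alpha_d = 0.001,
                        min_spacing = 500, n_blocks = 40,
                        collapse_support = NULL,
                        dip_min_loci = 20, dip_n_reps = 1000,
                        dip_alpha = 0.05,
                        fbranch_threshold = 0.04, seed = 1,
                        out_dir = NULL) {
  stopifnot(alpha_rt > 0, alpha_rt <= 1, alpha_d > 0, alpha_d <= 1,
            min_spacing >= 1, n_blocks >= 2,
            is.null(collapse_support) ||
              (collapse_support >= 0 && collapse_support <= 100))
  structure(list(species_tree = species_tree, gene_trees = gene_trees,
                 alignments = alignments, outgroup = outgroup,
                 taxon_map = taxon_map, alpha_rt = alpha_rt,
                 alpha_d = alpha_d, min_spacing = min_spacing,
                 n_blocks = n_blocks, collapse_support = collapse_support,
                 dip_min_loci = dip_min_loci, dip_n_reps = dip_n_reps,
                 dip_alpha = dip_alpha,
                 fbranch_threshold = fbranch_threshold, seed = seed,
                 out_dir = out_dir),
            class = "scan_config")
}

#' Write / read a scan configuration as YAML
#'
#' Only path-valued and scalar fields serialize; in-memory objects
#' (`phylo`, `gene_tree_set`, `locus_set`) cannot be written and raise an
#' error.
#'
#' @param config A [scan_config()].
#' @param path YAML file path.
#' @export
write_scan_config <- function(config, path) {
  ser <- unclass(config)
  for (f in c("species_tree", "gene_trees", "alignments", "taxon_map")) {
    if (!is.null(ser[[f]]) && !is.character(ser[[f]]))
      stop("config field '", f, "' holds an in-memory object; ",
           "only path-valued configs serialize", call. = FALSE)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  ser <- yaml::read_yaml(path)
  do.call(scan_config, ser)
}

resolve_inputs <- function(config) {
  st <- config$species_tree
  if (is.character(st)) st <- parse_newick(paste(readLines(st), collapse = ""))
  gts <- config$gene_trees
  if (is.character(gts)) gts <- read_gene_trees(gts)
  aln <- config$alignments
  if (is.character(aln)) aln <- read_locus_alignments(aln)
  tm <- config$taxon_map
  if (is.character(tm)) tm <- read_taxon_map(tm)

  if (!is.null(tm)) {
    reps <- representative_samples(tm)
    keep <- unname(reps)
    ren <- stats::setNames(names(reps), reps)  # sample -> species
    prune_rename <- function(tr) {
      tr <- ape::keep.tip(tr, intersect(tr$tip.label, keep))
      tr$tip.label <- unname(ren[tr$tip.label])
      tr
    }
    st <- prune_rename(st)
    gts$trees <- lapply(gts$trees, function(tr) {
      if (sum(tr$tip.label %in% keep) < 2L) return(NULL)
      prune_rename(tr)
    })
    ok <- !vapply(gts$trees, is.null, TRUE)
    gts <- gene_tree_set(gts$trees[ok], gts$ids[ok])
    if (!is.null(aln)) {
      aln$aln <- lapply(aln$aln, function(m) {
        m <- m[intersect(rownames(m), keep), , drop = FALSE]
        rownames(m) <- unname(ren[rownames(m)])
        m
      })
    }
  }
  list(species_tree = st, gene_trees = gts, alignments = aln)
}

# Representative "sister" tip for x, to fill the P1 slot of a framing
# (P1, x; partner): must branch off below the MRCA of x and the partner
# side, i.e. the climb stops as soon as a sibling clade touches
# `other_side`. Tips outside x's own event clade are preferred (their
# divergences are unperturbed); a co-member of x's clade is the fallback
# (valid, and the perturbations it carries are symmetric between the two
# discordant strata). NA when no valid representative exists.
sister_representative <- function(species_tree, x, other_side,
                                  own_side = character(0)) {
  st <- species_tree
  ntip <- length(st$tip.label)
  sets <- node_tip_sets(st)
  parent <- integer(ntip + st$Nnode)
  parent[st$edge[, 2L]] <- st$edge[, 1L]
  v <- match(x, st$tip.label)
  fallback <- NA_character_
  repeat {
    p <- parent[v]
    if (p == 0L) break
    sibs <- setdiff(st$edge[st$edge[, 1L] == p, 2L], v)
    sib_tips <- unlist(sets[sibs])
    if (any(sib_tips %in% other_side)) break
    clean <- setdiff(sib_tips, c(x, own_side))
    if (length(clean)) return(sort(clean)[1L])
    inside <- setdiff(sib_tips, x)
    if (is.na(fallback) && length(inside)) fallback <- sort(inside)[1L]
    v <- p
  }
  fallback
}

#' Run the full introgression scan end to end
#'
#' Executes, in order: gene-tree rooting (and optional support collapsing),
#' the rooted-triplet scan, the ABBA-BABA scan (when alignments are
#' supplied), the f-branch summary driven by triplet-based gamma scores over
#' all tree-arranged trios, collapsing of correlated significant triplet
#' tests into events, divergence-based direction polarization for each
#' event, and a cross-method concordance table. All tables are written as
#' TSV under `config$out_dir` together with a YAML manifest (config, seed,
#' package version) sufficient to reproduce every output byte for byte.
#'
#' @param config A [scan_config()].
#' @return Invisible list: `rt`, `dstat` (or NULL), `fbranch`, `events`,
#'   `dip`, `concordance`, `manifest`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  inp <- resolve_inputs(config)
  st <- inp$species_tree
  gts <- inp$gene_trees
  aln <- inp$alignments
  outgroup <- config$outgroup

  message("stage: preparing gene trees (", length(gts), " loci)")
  n_skipped <- 0L
  gts$trees <- lapply(gts$trees, function(tr) {
    if (!outgroup %in% tr$tip.label) {
      n_skipped <<- n_skipped + 1L
      return(tr)
    }
    tr <- root_with_outgroup(tr, outgroup)
    if (!is.null(config$collapse_support))
      tr <- collapse_low_support(tr, config$collapse_support)
    tr
  })
  if (n_skipped > 0L)
    message("  ", n_skipped, " loci lack the outgroup (skipped in tests)")

  message("stage: rooted-triplet scan")
  rt <- rt_scan(gts, st, outgroup, alpha = config$alpha_rt)

  dst <- NULL
  if (!is.null(aln)) {
    message("stage: ABBA-BABA scan")
    concat <- concatenate(aln)
    dst <- tryCatch(
      dstat_scan(concat, st, outgroup, alpha = config$alpha_d,
                 min_spacing = config$min_spacing,
                 n_blocks = config$n_blocks),
      error = function(e) {
        message("  D-statistic scan failed: ", conditionMessage(e))
        NULL
      })
  }

  message("stage: f-branch")
  ingroup <- sort(setdiff(st$tip.label, outgroup))
  st_in <- if (outgroup %in% st$tip.label) ape::drop.tip(st, outgroup) else st
  cache <- build_triplet_cache(gts, outgroup)
  trios <- utils::combn(ingroup, 3L)
  Dm <- mrca_depth_matrix(st_in)
  all_specs <- lapply(seq_len(ncol(trios)), function(i) {
    tr <- trios[, i]
    d12 <- Dm[tr[1L], tr[2L]]; d13 <- Dm[tr[1L], tr[3L]]
    d23 <- Dm[tr[2L], tr[3L]]
    if (d12 >= d13 && d12 >= d23) pair <- tr[c(1L, 2L)]
    else if (d13 >= d12 && d13 >= d23) pair <- tr[c(1L, 3L)]
    else pair <- tr[c(2L, 3L)]
    pair <- sort(pair)
    triplet_spec(pair[1L], pair[2L], setdiff(tr, pair), outgroup)
  })
  rt_all <- rt_test_specs(gts, all_specs, cache, config$alpha_rt)
  fb <- if (is.null(rt_all)) {
    fbranch_matrix(function(A, B, P3) NA_real_, st_in)
  } else {
    fbranch_matrix(gamma_score_provider(rt_all), st_in)
  }

  message("stage: event collapsing")
  events <- collapse_to_events(rt, st_in, alpha = config$alpha_rt)

  message("stage: direction polarization (DIP)")
  dip_rows <- list()
  if (nrow(events)) {
    dist_mode <- if (is.null(aln)) "patristic" else "p"
    for (i in seq_len(nrow(events))) {
      tips1 <- strsplit(gsub("^anc\\(|\\)$", "", events$lineage1[i]), "+",
                        fixed = TRUE)[[1L]]
      tips2 <- strsplit(gsub("^anc\\(|\\)$", "", events$lineage2[i]), "+",
                        fixed = TRUE)[[1L]]
      x <- sort(tips1)[1L]; y <- sort(tips2)[1L]
      sx <- sister_representative(st_in, x, other_side = tips2,
                                  own_side = tips1)
      sy <- sister_representative(st_in, y, other_side = tips1,
                                  own_side = tips2)
      res_xy <- res_yx <- NULL
      if (!is.na(sx)) {
        rec <- locus_divergences(aln, triplet_spec(sx, x, y, outgroup),
                                 gts, distance = dist_mode, cache = cache)
        res_xy <- dip_test(rec, corrected = TRUE,
                           min_loci = config$dip_min_loci,
                           n_reps = config$dip_n_reps,
                           seed = derive_seed(config$seed, 1000L + i))
      }
      if (!is.na(sy)) {
        rec <- locus_divergences(aln, triplet_spec(sy, y, x, outgroup),
                                 gts, distance = dist_mode, cache = cache)
        res_yx <- dip_test(rec, corrected = TRUE,
                           min_loci = config$dip_min_loci,
                           n_reps = config$dip_n_reps,
                           seed = derive_seed(config$seed, 2000L + i))
      }
      dir_call <- if (!is.null(res_xy) && !is.null(res_yx)) {
        d <- polarize(res_xy, res_yx, alpha = config$dip_alpha)
        # polarize's pair naming: P2 = x, P3 = y
        switch(d, "P2->P3" = paste0(events$lineage1[i], "->",
                                    events$lineage2[i]),
               "P3->P2" = paste0(events$lineage2[i], "->",
                                 events$lineage1[i]),
               d)
      } else "none"
      events$direction[i] <- if (dir_call %in% c("none",
                                                 "bidirectional/unresolved"))
        "bidirectional" else dir_call
      dip_rows[[i]] <- data.frame(
        event = i, lineage1 = events$lineage1[i],
        lineage2 = events$lineage2[i],
        delta12_into2 = if (!is.null(res_xy)) res_xy$delta12 else NA_real_,
        p_into2 = if (!is.null(res_xy)) res_xy$p12 else NA_real_,
        delta12_into1 = if (!is.null(res_yx)) res_yx$delta12 else NA_real_,
        p_into1 = if (!is.null(res_yx)) res_yx$p12 else NA_real_,
        direction = events$direction[i], stringsAsFactors = FALSE)
    }
  }
  dip_tab <- if (length(dip_rows)) do.call(rbind, dip_rows) else
    data.frame(event = integer(0), lineage1 = character(0),
               lineage2 = character(0), delta12_into2 = numeric(0),
               p_into2 = numeric(0), delta12_into1 = numeric(0),
               p_into1 = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)

  message("stage: concordance")
  conc <- cross_method_concordance(events, fb, dip_tab,
                                   threshold = config$fbranch_threshold)

  manifest <- list(
    package = "introscan",
    version = as.character(utils::packageVersion("introscan")),
    seed = config$seed,
    outgroup = outgroup,
    n_loci = length(gts),
    n_taxa = length(st$tip.label),
    parameters = list(
      alpha_rt = config$alpha_rt, alpha_d = config$alpha_d,
      min_spacing = config$min_spacing, n_blocks = config$n_blocks,
      collapse_support = config$collapse_support,
      dip_min_loci = config$dip_min_loci,
      dip_n_reps = config$dip_n_reps, dip_alpha = config$dip_alpha,
      fbranch_threshold = config$fbranch_threshold))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_tsv(as.data.frame(rt), file.path(od, "rt_tests.tsv"))
    if (!is.null(dst))
      write_tsv(as.data.frame(dst), file.path(od, "dstat_trios.tsv"))
    write_fbranch_tsv(fb, file.path(od, "fbranch_matrix.tsv"),
                      file.path(od, "fbranch_long.tsv"))
    write_tsv(as.data.frame(events), file.path(od, "events.tsv"))
    write_tsv(dip_tab, file.path(od, "dip_results.tsv"))
    write_tsv(conc, file.path(od, "concordance.tsv"))
    yaml::write_yaml(manifest, file.path(od, "manifest.yaml"))
  }

  invisible(list(rt = rt, dstat = dst, fbranch = fb, events = events,
                 dip = dip_tab, concordance = conc, manifest = manifest))
}

#' Cross-method concordance of events with the f-branch matrix
#'
#' For each event, the f-branch cells linking one side's branch to the
#' other side's tips (both orientations) are compared with a threshold:
#' `"Yes"` when all defined cells exceed it, `"Partial"` when some do,
#' `"No"` when none does (annotated when no cell is defined at all). The
#' DIP direction call is appended.
#'
#' @param rt_events An `event_table` from [collapse_to_events()].
#' @param fb An `fbranch_matrix`.
#' @param dip Data frame of per-event DIP calls (or NULL).
#' @param threshold f-branch concordance threshold (default 0.04).
#' @return Data frame: event, lineage1, lineage2, fbranch_detected,
#'   n_cells, n_above, dip_direction.
#' @export
cross_method_concordance <- function(rt_events, fb, dip = NULL,
                                     threshold = 0.04) {
  if (nrow(rt_events) == 0L)
    return(data.frame(event = integer(0), lineage1 = character(0),
                      lineage2 = character(0),
                      fbranch_detected = character(0), n_cells = integer(0),
                      n_above = integer(0), dip_direction = character(0),
                      stringsAsFactors = FALSE))
  M <- fb$matrix
  rows <- lapply(seq_len(nrow(rt_events)), function(i) {
    l1 <- rt_events$lineage1[i]; l2 <- rt_events$lineage2[i]
    tips1 <- strsplit(gsub("^anc\\(|\\)$", "", l1), "+", fixed = TRUE)[[1L]]
    tips2 <- strsplit(gsub("^anc\\(|\\)$", "", l2), "+", fixed = TRUE)[[1L]]
    cells <- c()
    if (l1 %in% rownames(M))
      cells <- c(cells, M[l1, intersect(tips2, colnames(M))])
    if (l2 %in% rownames(M))
      cells <- c(cells, M[l2, intersect(tips1, colnames(M))])
    cells <- cells[!is.na(cells)]
    status <- if (!length(cells)) "No (no defined cell)"
      else if (all(cells > threshold)) "Yes"
      else if (any(cells > threshold)) "Partial"
      else "No"
    data.frame(event = i, lineage1 = l1, lineage2 = l2,
               fbranch_detected = status, n_cells = length(cells),
               n_above = sum(cells > threshold),
               dip_direction = if (!is.null(dip) && nrow(dip) >= i)
                 dip$direction[i] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
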