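#' Parse a Newick string into a rooted tree
#'
#' Trees are represented as `ape::phylo` objects. Support values are read
#' from internal-node labels (the IQ-TREE/RAxML convention); branch lengths
#' follow `:`; quoted labels are allowed. Malformed input (unbalanced
#' parentheses, missing terminal `;`, duplicate tip labels, empty input)
#' raises an error naming the offending position where possible.
#'
#' @param text A single Newick statement terminated by `";"`.
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty Newick input", call. = FALSE)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at position %d in Newick input", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("unbalanced parentheses in Newick input (%d unclosed '(')",
                 depth), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("Newick statement not terminated by ';' (position %d)",
                 nchar(text)), call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  tr
}

#' Serialize a tree to Newick
#'
#' Inverse of [parse_newick()]: write→parse round trips preserve topology,
#' labels, branch lengths and support labels to printed precision.
#'
#' @param tree A `phylo` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read gene trees from a file (one Newick per line)
#'
#' @param path File with one Newick statement per line.
#' @param ids Optional locus identifiers; defaults to `locus_1 ... locus_n`.
#' @return A [gene_tree_set()].
#' @export
read_gene_trees <- function(path, ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  if (is.null(ids)) ids <- paste0("locus_", seq_along(trees))
  gene_tree_set(trees, ids)
}

#' Write gene trees to a file, one Newick per line
#'
#' @param gts A [gene_tree_set()].
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @export
write_gene_trees <- function(gts, path, digits = 10) {
  writeLines(vapply(gts$trees, write_newick, "", digits = digits), path)
  invisible(path)
}

#' Ordered collection of per-locus gene trees
#'
#' Bundles rooted gene trees with locus identifiers and a taxon-coverage map
#' (taxon -> number of loci containing it). Locus ids must be unique.
#'
#' @param trees List of `phylo` objects (one per locus).
#' @param ids Character vector of unique locus identifiers.
#' @return An object of class `gene_tree_set` with elements `trees` (named
#'   list), `ids`, and `coverage` (named integer vector).
#' @export
gene_tree_set <- function(trees, ids = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  if (is.null(ids)) ids <- names(trees)
  if (is.null(ids)) ids <- paste0("locus_", seq_along(trees))
  ids <- as.character(ids)
  if (length(ids) != length(trees))
    stop("length of ids must match number of trees", call. = FALSE)
  if (anyDuplicated(ids))
    stop("locus ids must be unique", call. = FALSE)
  stopifnot(all(vapply(trees, inherits, TRUE, "phylo")))
  names(trees) <- ids
  cov <- table(unlist(lapply(trees, function(t) unique(t$tip.label))))
  structure(list(trees = trees, ids = ids,
                 coverage = stats::setNames(as.integer(cov), names(cov))),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("gene_tree_set:", length(x$trees), "loci,",
      length(x$coverage), "taxa\n")
  invisible(x)
}

#' @export
length.gene_tree_set <- function(x) length(x$trees)

#' Recount taxon coverage of a gene tree set
#'
#' Used to verify that the stored coverage map is consistent with the trees.
#' @param gts A [gene_tree_set()].
#' @return Named integer vector, taxon -> number of loci containing it.
#' @export
recount_coverage <- function(gts) {
  cov <- table(unlist(lapply(gts$trees, function(t) unique(t$tip.label))))
  stats::setNames(as.integer(cov), names(cov))
}

#' Rooted-triplet specification
#'
#' Four distinct taxon labels: the putative sister pair (P1, P2), the third
#' ingroup taxon P3, and the outgroup used for rooting/polarization.
#'
#' @param p1,p2,p3,outgroup Taxon labels (all distinct).
#' @return An object of class `triplet_spec`.
#' @export
triplet_spec <- function(p1, p2, p3, outgroup) {
  labs <- c(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup)
  if (anyDuplicated(labs))
    stop("all four taxon labels of a triplet spec must be distinct",
         call. = FALSE)
  structure(as.list(labs), class = "triplet_spec")
}

#' @export
print.triplet_spec <- function(x, ...) {
  cat(sprintf("triplet: ((%s,%s),%s) out: %s\n", x$p1, x$p2, x$p3, x$outgroup))
  invisible(x)
}

#' Root a tree on an outgroup taxon
#'
#' The returned tree's root separates the outgroup from all other taxa; the
#' unrooted topology is preserved. A tree already rooted this way is returned
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param outgroup Tip label to root on.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup taxon '", outgroup, "' not present in tree", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (ape::is.rooted(tree)) {
    root <- ntip + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    og <- which(tree$tip.label == outgroup)
    if (og %in% kids) return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Collapse poorly supported internal branches into polytomies
#'
#' Every internal edge whose support (read from internal-node labels) is
#' strictly below `threshold` is contracted. Edges with no support annotation
#' are never collapsed (absence of evidence is not low support). The
#' contracted edge's length is discarded; child branch lengths are kept.
#' The operation is idempotent at a fixed threshold.
#'
#' @param tree A `phylo` with numeric internal-node labels in \[0,100\]
#'   (missing/empty labels allowed).
#' @param threshold Support threshold in \[0,100\].
#' @return A `phylo`, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(threshold >= 0, threshold <= 100)
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  # internal nodes (excluding root) whose incoming edge is to be contracted
  drop_nodes <- which(!is.na(sup) & sup < threshold) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) return(tree)

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  climb <- function(v) { while (v %in% drop_nodes) v <- parent[v]; v }

  keep <- !(tree$edge[, 2L] %in% drop_nodes)
  edge <- tree$edge[keep, , drop = FALSE]
  len <- if (!is.null(tree$edge.length)) tree$edge.length[keep] else NULL
  edge[, 1L] <- vapply(edge[, 1L], climb, 1L)

  # renumber remaining internal nodes
  kept_internal <- sort(unique(edge[, 1L]))
  kept_internal <- union(root, kept_internal)  # root always kept
  new_id <- integer(ntip + tree$Nnode)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[sort(kept_internal)] <- ntip + seq_along(kept_internal)
  # root keeps position ntip+1 because it sorts first among internals
  edge[, 1L] <- new_id[edge[, 1L]]
  int_mask <- edge[, 2L] > ntip
  edge[int_mask, 2L] <- new_id[edge[int_mask, 2L]]

  out <- list(edge = edge, tip.label = tree$tip.label,
              Nnode = length(kept_internal))
  if (!is.null(len)) out$edge.length <- len
  old_internal <- sort(kept_internal) - ntip
  out$node.label <- tree$node.label[old_internal]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Classify the rooted topology of a gene tree for one triplet
#'
#' The gene tree is pruned to the four taxa of `spec` and rooted on the
#' outgroup; the returned label names the ingroup pair that is sister:
#' `"P1P2"`, `"P2P3"`, `"P1P3"`, or `"UNRESOLVED"` when the three ingroup
#' taxa form a polytomy. Polytomies present before pruning propagate to
#' `"UNRESOLVED"` rather than being resolved arbitrarily.
#'
#' @param gene_tree A `phylo` containing all four taxa of `spec`.
#' @param spec A [triplet_spec()].
#' @return One of `"P1P2"`, `"P2P3"`, `"P1P3"`, `"UNRESOLVED"`.
#' @export
triplet_topology <- function(gene_tree, spec) {
  labs <- c(spec$p1, spec$p2, spec$p3, spec$outgroup)
  miss <- setdiff(labs, gene_tree$tip.label)
  if (length(miss))
    stop("missing taxa in gene tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr <- ape::keep.tip(gene_tree, labs)
  tr <- root_with_outgroup(tr, spec$outgroup)
  tr <- ape::drop.tip(tr, spec$outgroup)
  if (tr$Nnode < 2L) return("UNRESOLVED")
  ntip <- 3L
  root <- ntip + 1L
  # the cherry is the pair whose MRCA is not the root
  inner <- setdiff(unique(tr$edge[, 1L]), root)
  cherry_tips <- tr$edge[tr$edge[, 1L] == inner & tr$edge[, 2L] <= ntip, 2L]
  pair <- sort(tr$tip.label[cherry_tips])
  if (setequal(pair, c(spec$p1, spec$p2))) return("P1P2")
  if (setequal(pair, c(spec$p2, spec$p3))) return("P2P3")
  if (setequal(pair, c(spec$p1, spec$p3))) return("P1P3")
  "UNRESOLVED"
}

#' Tip pairs that are mutual sisters in a rooted species tree
#'
#' @param species_tree Rooted `phylo`.
#' @return List of length-2 character vectors (unordered pairs, each sorted).
#' @export
sister_pairs <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  edge <- species_tree$edge
  out <- list()
  for (v in unique(edge[, 1L])) {
    kids <- edge[edge[, 1L] == v, 2L]
    if (length(kids) == 2L && all(kids <= ntip))
      out[[length(out) + 1L]] <- sort(species_tree$tip.label[kids])
  }
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

# ---- internal branch/clade helpers ------------------------------------------

# descendant tip labels for every node of a tree
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    sets[[edge[k, 1L]]] <- c(sets[[edge[k, 1L]]], sets[[edge[k, 2L]]])
  lapply(sets, sort)
}

# canonical string key for a taxon set
set_key <- function(x) paste(sort(x), collapse = "\r")

# all clades (as tip-label sets) of a tree, rooted view, including tips
tree_clades <- function(tree) node_tip_sets(tree)

#' Gene concordance factors for species-tree internal branches
#'
#' For each internal branch, gCF = 100 x (number of decisive gene trees
#' containing that branch's bipartition) / (number of decisive gene trees).
#' A gene tree is decisive for a branch iff it contains at least one taxon
#' from each of the four subtrees the branch induces (the two child subtrees
#' below, and the two components on the other side). A gene tree contains the
#' bipartition iff, restricted to the gene tree's taxa, the species branch's
#' split is a split of the gene tree. Branches with zero decisive trees get
#' `NA` (flagged, not 0).
#'
#' @param species_tree Rooted binary `phylo`.
#' @param gene_trees A [gene_tree_set()]; gene-tree tips must be a subset of
#'   species-tree tips.
#' @return A data frame with one row per internal non-root branch: `node`
#'   (child node id of the branch), `clade` (readable tip-set label), `gcf`,
#'   `n_decisive`, `n_concordant`.
#' @export
gene_concordance_factor <- function(species_tree, gene_trees) {
  st <- species_tree
  ntip <- length(st$tip.label)
  root <- ntip + 1L
  all_taxa <- st$tip.label
  sets <- node_tip_sets(st)
  parent <- integer(ntip + st$Nnode)
  parent[st$edge[, 2L]] <- st$edge[, 1L]
  children <- function(v) st$edge[st$edge[, 1L] == v, 2L]

  internal <- setdiff(unique(st$edge[, 2L]), seq_len(ntip))

  # per gene tree: clade key set and tip set
  g_info <- lapply(gene_trees$trees, function(gt) {
    list(taxa = sort(gt$tip.label),
         keys = unique(vapply(tree_clades(gt), set_key, "")))
  })

  res <- data.frame(node = integer(0), clade = character(0), gcf = numeric(0),
                    n_decisive = integer(0), n_concordant = integer(0),
                    stringsAsFactors = FALSE)
  for (v in internal) {
    below <- sets[[v]]
    kids <- children(v)
    grp1 <- sets[[kids[1L]]]
    grp2 <- if (length(kids) > 1L) sets[[kids[2L]]] else character(0)
    u <- parent[v]
    if (u == root) {
      sib <- setdiff(children(root), v)
      # other side of the root: split the sister subtree at its children
      if (length(sib) == 1L && sib > ntip) {
        sibkids <- children(sib)
        grp3 <- sets[[sibkids[1L]]]
        grp4 <- if (length(sibkids) > 1L)
          unlist(lapply(sibkids[-1L], function(k) sets[[k]])) else character(0)
      } else {
        grp3 <- unlist(lapply(sib, function(k) sets[[k]]))
        grp4 <- character(0)
      }
    } else {
      sib <- setdiff(children(u), v)
      grp3 <- unlist(lapply(sib, function(k) sets[[k]]))
      grp4 <- setdiff(all_taxa, sets[[u]])
    }
    groups <- list(grp1, grp2, grp3, grp4)
    groups <- groups[vapply(groups, length, 1L) > 0L]
    if (length(groups) < 4L) {
      # trivial in the unrooted sense (e.g. root-adjacent with tip sister)
      res <- rbind(res, data.frame(
        node = v, clade = paste(below, collapse = "+"), gcf = NA_real_,
        n_decisive = NA_integer_, n_concordant = NA_integer_,
        stringsAsFactors = FALSE))
      next
    }
    nd <- 0L; nc <- 0L
    for (g in g_info) {
      if (!all(vapply(groups, function(gr) any(gr %in% g$taxa), TRUE))) next
      nd <- nd + 1L
      x <- intersect(below, g$taxa)
      y <- setdiff(g$taxa, x)
      if (set_key(x) %in% g$keys || set_key(y) %in% g$keys) nc <- nc + 1L
    }
    res <- rbind(res, data.frame(
      node = v, clade = paste(below, collapse = "+"),
      gcf = if (nd > 0L) 100 * nc / nd else NA_real_,
      n_decisive = nd, n_concordant = nc, stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

#' Read a sample-to-species taxon map
#'
#' Two-column TSV (sample, species), no header. When a scan is run at species
#' level, one representative sample per species is selected deterministically
#' (lexicographically first).
#'
#' @param path TSV path.
#' @return Data frame with columns `sample`, `species`.
#' @export
read_taxon_map <- function(path) {
  tm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "species"),
                          stringsAsFactors = FALSE)
  tm
}

#' Choose one representative sample per species
#'
#' @param taxon_map Data frame from [read_taxon_map()].
#' @return Named character vector species -> representative sample
#'   (lexicographically first).
#' @export
representative_samples <- function(taxon_map) {
  sp <- split(taxon_map$sample, taxon_map$species)
  vapply(sp, function(x) sort(x)[1L], "")
}
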