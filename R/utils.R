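# Internal helpers shared across modules.

# Topological depth (edges from root) of the MRCA of every tip pair.
# Returns an ntip x ntip matrix (dimnames = tip labels); diagonal = tip depth.
mrca_depth_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  # root path (root ... tip) per tip
  paths <- vector("list", ntip)
  maxd <- 0L
  for (i in seq_len(ntip)) {
    p <- i
    path <- i
    while (p != root) {
      p <- parent[p]
      path <- c(p, path)
    }
    paths[[i]] <- path
    maxd <- max(maxd, length(path))
  }
  # pad row i with -i so padded cells never match across rows
  M <- matrix(rep(-seq_len(ntip), maxd), nrow = ntip)
  for (i in seq_len(ntip)) M[i, seq_along(paths[[i]])] <- paths[[i]]
  # number of shared prefix nodes minus one = depth of MRCA
  D <- matrix(-1L, ntip, ntip)
  for (k in seq_len(maxd)) {
    col <- M[, k]
    D <- D + outer(col, col, "==")
  }
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# Cache of MRCA depths across a gene tree set, as a 3D array
# [taxon, taxon, locus] of topological MRCA depths (NA where either taxon is
# absent from the locus). Trees are first rooted on `outgroup`.
# Stored (memoized) as an attribute on the gene_tree_set environment-free copy
# is not possible, so callers keep the returned cache object.
build_triplet_cache <- function(gts, outgroup, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(names(gts$coverage))
  nt <- length(taxa)
  L <- length(gts$trees)
  arr <- array(NA_integer_, dim = c(nt, nt, L),
               dimnames = list(taxa, taxa, gts$ids))
  for (l in seq_len(L)) {
    tr <- gts$trees[[l]]
    if (!outgroup %in% tr$tip.label) next
    tr <- root_with_outgroup(tr, outgroup)
    D <- mrca_depth_matrix(tr)
    present <- intersect(taxa, rownames(D))
    arr[present, present, l] <- D[present, present]
  }
  structure(list(depth = arr, taxa = taxa, outgroup = outgroup),
            class = "triplet_cache")
}

# Vectorized triplet topology labels across loci for taxa (a, b, c) with the
# cache's outgroup. Returns factor-ish character vector of length n_loci with
# values "AB", "BC", "AC", "UNRESOLVED", or NA when any taxon is missing.
cache_triplet_labels <- function(cache, a, b, c) {
  dab <- cache$depth[a, b, ]
  dac <- cache$depth[a, c, ]
  dbc <- cache$depth[b, c, ]
  out <- rep(NA_character_, length(dab))
  ok <- !is.na(dab) & !is.na(dac) & !is.na(dbc)
  ab <- ok & dab > dac & dab > dbc
  ac <- ok & dac > dab & dac > dbc
  bc <- ok & dbc > dab & dbc > dac
  out[ok] <- "UNRESOLVED"
  out[ab] <- "AB"
  out[ac] <- "AC"
  out[bc] <- "BC"
  out
}

# Deterministic integer seed stream: derive a per-task seed from a base seed
# and an index, staying below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# Write a data frame as TSV with fixed formatting (deterministic bytes).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
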