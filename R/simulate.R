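#' Species network: species tree plus hybrid edges
#'
#' The base tree is a rooted ultrametric `phylo` with branch lengths in
#' coalescent units. Hybrid edges are instantaneous admixture pulses: at the
#' pulse time, each gene lineage present on the recipient branch moves to the
#' donor branch independently with probability `gamma` (tracing backwards in
#' time; forward in time this is gene flow donor -> recipient). Bidirectional
#' edges carry a second proportion `gamma_rev` for the simultaneous reverse
#' pulse.
#'
#' Branches are identified by a tip label, or by `"a+b+c"` meaning the branch
#' above the MRCA of those tips.
#'
#' @param tree Rooted ultrametric `phylo`, lengths in coalescent units.
#' @param hybrid_edges Data frame with columns `donor`, `recipient`, `time`
#'   (age before present, coalescent units), `gamma` in \[0,1\], and optional
#'   `gamma_rev` (NA for unidirectional). May be `NULL`/empty: the network is
#'   then exactly its base tree.
#' @return An object of class `species_network`.
#' @export
species_network <- function(tree, hybrid_edges = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("base tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("base tree needs nonnegative branch lengths", call. = FALSE)
  ages <- node_ages(tree)
  if (is.null(hybrid_edges) || NROW(hybrid_edges) == 0L) {
    hybrid_edges <- data.frame(donor = character(0), recipient = character(0),
                               time = numeric(0), gamma = numeric(0),
                               gamma_rev = numeric(0),
                               stringsAsFactors = FALSE)
  } else {
    hybrid_edges <- as.data.frame(hybrid_edges, stringsAsFactors = FALSE)
    if (is.null(hybrid_edges$gamma_rev))
      hybrid_edges$gamma_rev <- NA_real_
    for (i in seq_len(nrow(hybrid_edges))) {
      he <- hybrid_edges[i, ]
      if (is.na(he$gamma) || he$gamma < 0 || he$gamma > 1)
        stop("hybrid edge ", i, ": gamma must be in [0,1]", call. = FALSE)
      if (!is.na(he$gamma_rev) && (he$gamma_rev < 0 || he$gamma_rev > 1))
        stop("hybrid edge ", i, ": gamma_rev must be in [0,1]", call. = FALSE)
      for (role in c("donor", "recipient")) {
        v <- resolve_branch(tree, he[[role]])
        span <- branch_span(tree, v, ages)
        if (he$time <= span[1L] || he$time >= span[2L])
          stop(sprintf(
            "hybrid edge %d: time %.4g outside %s branch span (%.4g, %.4g)",
            i, he$time, role, span[1L], span[2L]), call. = FALSE)
      }
    }
  }
  structure(list(tree = tree, hybrid_edges = hybrid_edges, ages = ages),
            class = "species_network")
}

#' @export
print.species_network <- function(x, ...) {
  cat("species_network:", length(x$tree$tip.label), "tips,",
      nrow(x$hybrid_edges), "hybrid edge(s)\n")
  invisible(x)
}

# Ages (time above the tips) of all nodes of an ultrametric rooted tree.
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ntip <- length(tree$tip.label)
  tip_ages <- ages[seq_len(ntip)]
  if (any(tip_ages > 1e-8 * max(depth)))
    stop("base tree must be ultrametric (contemporaneous tips)",
         call. = FALSE)
  ages[seq_len(ntip)] <- 0
  ages
}

# Resolve a branch identifier (tip label or "a+b" MRCA form) to the node id
# whose parent edge is the branch.
resolve_branch <- function(tree, label) {
  tips <- strsplit(label, "+", fixed = TRUE)[[1L]]
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("unknown taxa in branch identifier '", label, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# [age_child, age_parent] span of the branch above node v (root: Inf top).
branch_span <- function(tree, v, ages = node_ages(tree)) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (v == root) return(c(ages[v], Inf))
  parent <- tree$edge[tree$edge[, 2L] == v, 1L]
  c(ages[v], ages[parent])
}

#' Simulate gene trees under the multispecies coalescent with hybrid pulses
#'
#' Lineages are traced tipward-to-rootward. Within each species-tree branch,
#' each pair of co-resident lineages coalesces at rate 1 per coalescent time
#' unit. At a hybrid pulse on the recipient branch, each lineage present
#' moves to the donor branch independently with probability `gamma`
#' (simultaneous exchange for bidirectional edges). Output gene trees carry
#' coalescent-unit branch lengths.
#'
#' Random streams are keyed per locus by (`seed`, locus index), so a subset
#' of loci reproduces identically regardless of `n_loci`.
#'
#' @param network A [species_network()].
#' @param n_loci Number of loci.
#' @param seed Integer seed.
#' @return A [gene_tree_set()] of `n_loci` rooted gene trees.
#' @export
simulate_gene_trees <- function(network, n_loci, seed) {
  stopifnot(inherits(network, "species_network"), n_loci >= 1)
  tree <- network$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ages <- network$ages
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  # event schedule: speciations (children merge into node v at age[v]) and
  # hybrid pulses, ascending in time; pulses strictly inside branch spans so
  # ties with speciations cannot occur.
  internal <- order(ages[(ntip + 1L):(ntip + tree$Nnode)]) + ntip
  ev_time <- ages[internal]
  events <- lapply(seq_along(internal), function(i)
    list(type = "spec", time = ev_time[i], node = internal[i]))
  he <- network$hybrid_edges
  if (nrow(he)) {
    for (i in seq_len(nrow(he))) {
      events[[length(events) + 1L]] <- list(
        type = "pulse", time = he$time[i],
        donor = resolve_branch(tree, he$donor[i]),
        recipient = resolve_branch(tree, he$recipient[i]),
        gamma = he$gamma[i], gamma_rev = he$gamma_rev[i])
    }
  }
  events <- events[order(vapply(events, `[[`, 0, "time"))]
  kids_of <- lapply(seq_len(ntip + tree$Nnode), function(v)
    tree$edge[tree$edge[, 1L] == v, 2L])

  trees <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    set.seed(derive_seed(seed, l))
    trees[[l]] <- msc_one_locus(tree, events, kids_of, ntip, root)
  }
  gene_tree_set(trees, paste0("locus_", seq_len(n_loci)))
}

# One MSC genealogy. Populations are indexed by species-tree node id (the
# branch above that node); lazily advanced to event times.
msc_one_locus <- function(stree, events, kids_of, ntip, root) {
  nn <- ntip + stree$Nnode
  pops <- vector("list", nn)          # lineage ids per active population
  pop_time <- numeric(nn)             # time up to which pop has been advanced
  for (i in seq_len(ntip)) pops[[i]] <- i
  h <- numeric(2L * ntip - 1L)        # node heights of the gene tree
  par <- integer(2L * ntip - 1L)      # gene-tree parent pointers
  nxt <- ntip                         # last allocated gene node id

  advance <- function(v, t_end) {
    lin <- pops[[v]]
    k <- length(lin)
    t <- pop_time[v]
    while (k >= 2L) {
      t <- t + stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t > t_end) break
      pr <- sample.int(k, 2L)
      nxt <<- nxt + 1L
      h[nxt] <<- t
      par[lin[pr]] <<- nxt
      lin <- c(lin[-pr], nxt)
      k <- k - 1L
    }
    pops[[v]] <<- lin
    pop_time[v] <<- t_end
  }

  for (ev in events) {
    if (ev$type == "spec") {
      v <- ev$node
      for (k in kids_of[[v]]) advance(k, ev$time)
      pops[[v]] <- unlist(pops[kids_of[[v]]])
      pop_time[v] <- ev$time
    } else {
      advance(ev$recipient, ev$time)
      advance(ev$donor, ev$time)
      rlin <- pops[[ev$recipient]]
      dlin <- pops[[ev$donor]]
      mv_r <- rlin[stats::runif(length(rlin)) < ev$gamma]
      mv_d <- if (!is.na(ev$gamma_rev))
        dlin[stats::runif(length(dlin)) < ev$gamma_rev] else integer(0)
      pops[[ev$recipient]] <- c(setdiff(rlin, mv_r), mv_d)
      pops[[ev$donor]] <- c(setdiff(dlin, mv_d), mv_r)
    }
  }
  # final coalescence in the root population
  lin <- pops[[root]]
  t <- pop_time[root]
  k <- length(lin)
  while (k >= 2L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1L) / 2)
    pr <- sample.int(k, 2L)
    nxt <- nxt + 1L
    h[nxt] <- t
    par[lin[pr]] <- nxt
    lin <- c(lin[-pr], nxt)
    k <- k - 1L
  }

  # assemble a phylo: tips 1..ntip, root = ntip+1, other internals follow
  n_nodes <- nxt
  grootid <- n_nodes
  map <- integer(n_nodes)
  map[seq_len(ntip)] <- seq_len(ntip)
  map[grootid] <- ntip + 1L
  others <- setdiff((ntip + 1L):n_nodes, grootid)
  map[others] <- ntip + 1L + seq_along(others)
  child <- setdiff(seq_len(n_nodes), grootid)
  edge <- cbind(map[par[child]], map[child])
  elen <- h[par[child]] - h[child]
  phy <- list(edge = edge, edge.length = elen,
              tip.label = stree$tip.label, Nnode = ntip - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate sequence alignments along gene trees (JC69)
#'
#' Sites evolve i.i.d. under Jukes-Cantor along each gene tree. Gene-tree
#' branch lengths (coalescent units) are multiplied by `rate` (substitutions
#' per site per coalescent unit) to give substitution branch lengths — one
#' knob controls overall divergence.
#'
#' @param gene_trees A [gene_tree_set()] with branch lengths.
#' @param locus_length Sites per locus (bp).
#' @param rate Substitutions per site per coalescent unit.
#' @param seed Integer seed (per-locus streams keyed by seed and locus index).
#' @return A `locus_set`: list with `aln` (named list of integer matrices,
#'   taxa x sites, codes 1..4 = A,C,G,T) and `locus_length`.
#' @export
simulate_alignments <- function(gene_trees, locus_length, rate, seed) {
  stopifnot(rate >= 0, locus_length >= 1)
  aln <- vector("list", length(gene_trees$trees))
  for (l in seq_along(gene_trees$trees)) {
    tr <- ape::reorder.phylo(gene_trees$trees[[l]], "cladewise")
    set.seed(derive_seed(seed, 500000L + l))
    m <- cpp_jc_evolve(tr$edge, tr$edge.length * rate,
                       length(tr$tip.label), as.integer(locus_length))
    rownames(m) <- tr$tip.label
    aln[[l]] <- m
  }
  names(aln) <- gene_trees$ids
  structure(list(aln = aln, locus_length = locus_length),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", length(x$aln), "loci\n")
  invisible(x)
}

#' Write per-locus alignments as FASTA files
#'
#' @param loci A `locus_set` from [simulate_alignments()] or
#'   [read_locus_alignments()].
#' @param dir Output directory (one FASTA per locus).
#' @return Paths written, invisibly.
#' @export
write_locus_fasta <- function(loci, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  paths <- character(length(loci$aln))
  for (i in seq_along(loci$aln)) {
    m <- loci$aln[[i]]
    ch <- matrix("-", nrow(m), ncol(m))
    ok <- m >= 1L & m <= 4L
    ch[ok] <- bases[m[ok]]
    p <- file.path(dir, paste0(names(loci$aln)[i], ".fasta"))
    con <- file(p, "w")
    for (r in seq_len(nrow(m))) {
      writeLines(paste0(">", rownames(m)[r]), con)
      writeLines(paste(ch[r, ], collapse = ""), con)
    }
    close(con)
    paths[i] <- p
  }
  invisible(paths)
}

#' Read per-locus FASTA alignments into a locus set
#'
#' Characters other than A/C/G/T (case-insensitive) — gaps, N, IUPAC
#' ambiguity codes — are coded 0 and excluded from downstream site filters.
#'
#' @param paths FASTA file paths (one per locus) or a directory of `.fasta`
#'   files.
#' @param ids Optional locus ids (default: file names without extension).
#' @return A `locus_set`.
#' @export
read_locus_alignments <- function(paths, ids = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
  if (is.null(ids)) ids <- sub("\\.fa(sta)?$", "", basename(paths))
  aln <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    d <- ape::read.FASTA(paths[i])
    ch <- toupper(do.call(rbind, lapply(as.character(d), identity)))
    m <- matrix(0L, nrow(ch), ncol(ch), dimnames = list(names(d), NULL))
    for (b in 1:4) m[ch == c("A", "C", "G", "T")[b]] <- b
    aln[[i]] <- m
  }
  names(aln) <- ids
  structure(list(aln = aln,
                 locus_length = max(vapply(aln, ncol, 1L))),
            class = "locus_set")
}

#' Costus-like simulation preset
#'
#' A deterministic study-scale configuration: 54 ingroup tips (27 cherries on
#' a caterpillar backbone with short internal branches, i.e. pervasive
#' incomplete lineage sorting) plus one distant outgroup at 15 coalescent
#' units, 756 loci of 1951 bp, and three hybrid edges with inheritance
#' proportions 0.10, 0.22 and 0.45 (two tip-to-tip, one with an ancestral
#' recipient branch).
#'
#' @param hybrid_edges Override the default hybrid edges (`NULL` keeps the
#'   defaults; pass an empty data frame for a plain species tree).
#' @return List with elements `network` ([species_network()]) and `config`
#'   (n_loci, locus_length, rate, outgroup).
#' @export
costus_like_preset <- function(hybrid_edges = NULL) {
  n_cherry <- 27L
  cherry_h <- rep(0.3, n_cherry)
  cherry_h[c(9L, 18L)] <- 1.5  # taller cherries host hybrid-edge donors
  join_age <- c(2.0, 2.0 + 0.25 * seq_len(n_cherry - 2L))  # joins 2..27

  tipnames <- function(i) sprintf("t%02d%s", i, c("a", "b"))
  nwk_cherry <- function(i, stem_top) {
    sprintf("(%s:%.6f,%s:%.6f):%.6f", tipnames(i)[1L], cherry_h[i],
            tipnames(i)[2L], cherry_h[i], stem_top - cherry_h[i])
  }
  # caterpillar: ((C1,C2),C3),C4 ... with join ages join_age[1..26]
  s <- sprintf("(%s,%s):%.6f", nwk_cherry(1L, join_age[1L]),
               nwk_cherry(2L, join_age[1L]), join_age[2L] - join_age[1L])
  for (i in 3L:n_cherry) {
    top <- if (i < n_cherry) join_age[i] else 15.0
    s <- sprintf("(%s,%s):%.6f", s, nwk_cherry(i, join_age[i - 1L]),
                 top - join_age[i - 1L])
  }
  nwk <- sprintf("(%s,OUT:15.0);", s)
  tree <- parse_newick(nwk)

  if (is.null(hybrid_edges)) {
    hybrid_edges <- data.frame(
      donor     = c("t09a", "t18a", "t09b"),
      recipient = c("t02a", "t05a", "t13a+t13b"),
      time      = c(0.2, 0.2, 0.5),
      gamma     = c(0.10, 0.22, 0.45),
      gamma_rev = NA_real_,
      stringsAsFactors = FALSE)
  }
  net <- species_network(tree, hybrid_edges)
  list(network = net,
       config = list(n_loci = 756L, locus_length = 1951L, rate = 0.005,
                     outgroup = "OUT"))
}

#' Write / read a species network as YAML
#'
#' The base tree is stored as a Newick string and hybrid edges as a list
#' of records (donor, recipient, time, gamma, gamma_rev), so the file is
#' both human-editable and lossless.
#'
#' @param network A [species_network()].
#' @param path YAML file path.
#' @export
write_species_network <- function(network, path) {
  he <- network$hybrid_edges
  yaml::write_yaml(list(
    tree = write_newick(network$tree),
    hybrid_edges = if (nrow(he)) lapply(seq_len(nrow(he)), function(i)
      list(donor = he$donor[i], recipient = he$recipient[i],
           time = he$time[i], gamma = he$gamma[i],
           gamma_rev = if (is.na(he$gamma_rev[i])) NULL else
             he$gamma_rev[i])) else list()), path)
  invisible(path)
}

#' @rdname write_species_network
#' @export
read_species_network <- function(path) {
  y <- yaml::read_yaml(path)
  he <- if (length(y$hybrid_edges)) {
    do.call(rbind, lapply(y$hybrid_edges, function(e)
      data.frame(donor = e$donor, recipient = e$recipient, time = e$time,
                 gamma = e$gamma,
                 gamma_rev = e$gamma_rev %||% NA_real_,
                 stringsAsFactors = FALSE)))
  } else NULL
  species_network(parse_newick(y$tree), he)
}

#' Closed-form expectation of the rooted-triplet gamma estimator
#'
#' For a pulse of proportion `gamma` whose moved lineage spends `t_prime`
#' coalescent units alone with the donor lineage, the expected excess of the
#' donor-pairing minor topology is `gamma * (1 - exp(-t_prime))` of all loci.
#'
#' @param gamma Inheritance proportion of the hybrid edge.
#' @param t_prime Length (coalescent units) of the donor-branch window
#'   between the pulse and the donor branch's parent node.
#' @return Expected value of the gamma estimator.
#' @export
expected_rt_gamma <- function(gamma, t_prime) gamma * (1 - exp(-t_prime))
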