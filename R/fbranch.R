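#' Expanded branch list of a rooted species tree
#'
#' Depth-first ordering of all branches (terminal and internal), each
#' annotated with its descendant tip set and its sister branch. The root
#' itself has no branch; the root's two child branches are each other's
#' sisters.
#'
#' @param species_tree Rooted binary `phylo`.
#' @return Data frame: `node` (child node id of the branch), `label`
#'   (tip label or `anc(...)`), `is_tip`, `sister_node`; attribute
#'   `tip_sets` holds descendant tip labels per node id.
#' @export
expand_branches <- function(species_tree) {
  st <- ape::reorder.phylo(species_tree, "cladewise")
  ntip <- length(st$tip.label)
  root <- ntip + 1L
  sets <- node_tip_sets(st)
  parent <- integer(ntip + st$Nnode)
  parent[st$edge[, 2L]] <- st$edge[, 1L]
  nodes <- st$edge[, 2L]  # cladewise = depth-first branch order
  sister <- vapply(nodes, function(v) {
    sibs <- st$edge[st$edge[, 1L] == parent[v], 2L]
    s <- setdiff(sibs, v)
    if (length(s) == 1L) s else NA_integer_
  }, 1L)
  out <- data.frame(
    node = nodes,
    label = vapply(nodes, function(v) branch_name(sets[[v]]), ""),
    is_tip = nodes <= ntip,
    sister_node = sister,
    stringsAsFactors = FALSE)
  attr(out, "tip_sets") <- sets
  out
}

#' f-branch matrix from a per-trio score function
#'
#' Assigns excess-allele-sharing (or gamma-based) signal to every branch b
#' of the species tree for every candidate donor/partner tip P3:
#' fb(b, P3) = median over A in descendants(sister(b)) of
#' \[ min over B in descendants(b) of score(A, B, P3) \].
#' Cells are defined only when P3 lies outside both b's clade and its sister
#' clade. NA scores are skipped inside the min/median; a cell with no
#' defined term, or a branch with no sister, is NA.
#'
#' @param score Function `(A, B, P3) -> numeric or NA`: the per-trio signal
#'   that taxon B (inside branch b) shares excess alleles with P3, measured
#'   against A from the sister clade. See [gamma_score_provider()].
#' @param species_tree Rooted binary `phylo`.
#' @param taxa Optional P3 column set (default: all tips).
#' @return Object of class `fbranch_matrix`: `matrix` (branches x taxa),
#'   `branches` (from [expand_branches()]), `n_trios` matrix of contributing
#'   trio counts.
#' @export
fbranch_matrix <- function(score, species_tree, taxa = NULL) {
  br <- expand_branches(species_tree)
  sets <- attr(br, "tip_sets")
  if (is.null(taxa)) taxa <- sort(species_tree$tip.label)
  M <- matrix(NA_real_, nrow(br), length(taxa),
              dimnames = list(br$label, taxa))
  Nt <- matrix(0L, nrow(br), length(taxa),
               dimnames = list(br$label, taxa))
  for (i in seq_len(nrow(br))) {
    if (is.na(br$sister_node[i])) next
    descB <- sets[[br$node[i]]]
    descA <- sets[[br$sister_node[i]]]
    for (j in seq_along(taxa)) {
      p3 <- taxa[j]
      if (p3 %in% descB || p3 %in% descA) next
      mins <- rep(NA_real_, length(descA))
      ntr <- 0L
      for (ai in seq_along(descA)) {
        vals <- vapply(descB, function(b) score(descA[ai], b, p3),
                       numeric(1))
        ok <- !is.na(vals)
        ntr <- ntr + sum(ok)
        if (any(ok)) mins[ai] <- min(vals[ok])
      }
      if (any(!is.na(mins))) M[i, j] <- stats::median(mins, na.rm = TRUE)
      Nt[i, j] <- ntr
    }
  }
  structure(list(matrix = M, branches = br, n_trios = Nt),
            class = "fbranch_matrix")
}

#' @export
print.fbranch_matrix <- function(x, ...) {
  cat("fbranch_matrix:", nrow(x$matrix), "branches x", ncol(x$matrix),
      "taxa;", sum(!is.na(x$matrix)), "defined cells\n")
  invisible(x)
}

#' Gamma score provider backed by rooted-triplet results
#'
#' Returns a score function for [fbranch_matrix()]: `score(A, B, P3)` looks
#' up the triplet test with sister slots \{A, B\} and third taxon P3 and
#' returns its gamma, signed toward B — positive when the excess minor
#' pairing joins B with P3, negative when it joins A with P3. Trios tested
#' but not significant score 0 (configurable to NA); untested trios are NA.
#'
#' @param rt_results Data frame from [rt_scan()] or `rt_test_specs`-style
#'   results (columns P1, P2, P3, gamma, partner, significant).
#' @param nonsignificant Value for tested, non-significant trios: `"zero"`
#'   (default, conservative imputation) or `"na"` (skip in min/median).
#' @return Function `(A, B, P3) -> numeric or NA`.
#' @export
gamma_score_provider <- function(rt_results, nonsignificant = c("zero", "na")) {
  nonsignificant <- match.arg(nonsignificant)
  if (nrow(rt_results) == 0L) return(function(A, B, P3) NA_real_)
  key <- paste(pmin(rt_results$P1, rt_results$P2),
               pmax(rt_results$P1, rt_results$P2), rt_results$P3,
               sep = "\r")
  tab <- new.env(parent = emptyenv(), size = length(key))
  for (i in seq_along(key))
    assign(key[i], list(gamma = rt_results$gamma[i],
                        partner = rt_results$partner[i],
                        significant = isTRUE(rt_results$significant[i])),
           envir = tab)
  function(A, B, P3) {
    k <- paste(min(A, B), max(A, B), P3, sep = "\r")
    rec <- tab[[k]]
    if (is.null(rec)) return(NA_real_)
    if (!rec$significant)
      return(if (nonsignificant == "zero") 0 else NA_real_)
    if (is.na(rec$gamma)) return(NA_real_)
    if (rec$partner == B) rec$gamma else -rec$gamma
  }
}

#' Export an f-branch matrix as TSV
#'
#' Writes the wide matrix (branches x taxa, NA markers) and a long-format
#' table (branch, P3, fb, n_trios) suitable for heatmap plotting.
#'
#' @param fb An `fbranch_matrix`.
#' @param path_wide,path_long Output paths (`NULL` skips either).
#' @export
write_fbranch_tsv <- function(fb, path_wide = NULL, path_long = NULL) {
  if (!is.null(path_wide)) {
    df <- data.frame(branch = rownames(fb$matrix), fb$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, path_wide)
  }
  if (!is.null(path_long)) {
    long <- data.frame(
      branch = rep(rownames(fb$matrix), ncol(fb$matrix)),
      P3 = rep(colnames(fb$matrix), each = nrow(fb$matrix)),
      fb = as.vector(fb$matrix),
      n_trios = as.vector(fb$n_trios),
      stringsAsFactors = FALSE)
    write_tsv(long, path_long)
  }
  invisible(fb)
}
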