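# Shared fixtures: small trees, networks and simulated data built in code.

# 10-ingroup-taxon species tree with pervasive ILS and a distant outgroup.
null10_tree <- function() {
  parse_newick(paste0(
    "(((((a:.5,b:.5):.8,(c:.5,d:.5):.8):.3,((e:.5,f:.5):.8,",
    "(g:.5,h:.5):.8):.3):.3,(i:.5,j:.5):1.4):13.1,O:15);"))
}

# 5-taxon tree used for direction-recovery experiments: two cherries so
# both candidate recipient framings are well defined.
dip5_tree <- function() {
  parse_newick("(((P1:1,P2:1):1,(P3:1,S3:1):1):10,O:12);")
}

# gamma-estimator consistency layout: pulse P3 -> P2 with a donor-branch
# window of `t_prime` coalescent units above the pulse.
gamma_layout <- function(gamma = 0.2, t_prime = 2.0, tm = 0.5) {
  t2 <- tm + t_prime
  nwk <- sprintf("(((P1:1,P2:1):%.4f,P3:%.4f):%.4f,O:15);",
                 t2 - 1, t2, 15 - t2)
  species_network(parse_newick(nwk),
                  data.frame(donor = "P3", recipient = "P2", time = tm,
                             gamma = gamma))
}

# signed per-locus gamma contributions for a triplet: +1 when the locus
# shows the (b, c) pairing, -1 for (a, c), 0 for the major topology
signed_gamma_terms <- function(gts, outgroup, a, b, c) {
  cc <- introscan:::build_triplet_cache(gts, outgroup)
  lab <- introscan:::cache_triplet_labels(cc, a, b, c)
  x <- ifelse(lab == "BC", 1, ifelse(lab == "AC", -1, 0))
  x[!is.na(x)]
}

# deterministic toy gene-tree set over 6 taxa for gCF / counting tests
toy6_gene_trees <- function() {
  nwks <- c(
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);",
    "(((A:1,C:1):1,(B:1,D:1):1):1,(E:1,F:1):2);",
    "(((A:1,B:1):1,(C:1,E:1):1):1,(D:1,F:1):2);",
    "((((A:1,B:1):1,C:2):1,(D:1,E:1):2):1,F:4);",
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  gene_tree_set(lapply(nwks, parse_newick), paste0("g", seq_along(nwks)))
}
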