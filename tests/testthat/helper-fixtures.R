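# Small fixtures built in code.

balanced4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Random bifurcating tree with positive branch lengths.
rand_tree <- function(n, min_len = 0.1, max_len = 2) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(length(tr$edge.length), min_len, max_len)
  tr
}

# Two deep clades (short within-clade, long stems): strong structure for
# clustering checks.
two_clade_tree <- function(per_clade = 5, stem = 10, twig = 1) {
  a <- paste0("(", paste0("A", seq_len(per_clade), ":", twig,
                          collapse = ","), "):", stem)
  b <- paste0("(", paste0("B", seq_len(per_clade), ":", twig,
                          collapse = ","), "):", stem)
  read_newick(paste0("(", a, ",", b, ");"))
}
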