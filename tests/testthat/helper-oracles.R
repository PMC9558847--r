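# Shared oracles and generators for the test suite. Everything here is
# deliberately independent of the package's own computational paths:
# brute-force enumerations and closed forms only.

# JC69 transition probability between two specific states
jc_p <- function(same, d) {
  e <- exp(-4 * d / 3)
  if (same) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

# Brute-force JC69 likelihood of one site by enumerating every internal
# node state assignment (4^Nnode terms), uniform root frequencies.
brute_site_lik <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (g in seq_len(nrow(grid))) {
    assign <- c(states, grid[g, ])
    p <- 1 / 4  # root frequency
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign[tree$edge[e, 1]]
      b <- assign[tree$edge[e, 2]]
      p <- p * jc_p(a == b, tree$edge.length[e])
    }
    total <- total + p
  }
  total
}

brute_loglik <- function(tree, aln) {
  code <- matrix(match(aln, c("A", "C", "G", "T")), nrow(aln), ncol(aln),
                 dimnames = dimnames(aln))
  code <- code[tree$tip.label, , drop = FALSE]
  sum(log(apply(code, 2, function(s) brute_site_lik(tree, s))))
}

# Random binary rooted tree with branch lengths, for metric tests.
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = sample(LETTERS[seq_len(n)]))
  tr
}

# A no-ILS species tree model: internal branches enormously long in
# coalescent units, so every gene tree matches the species tree.
no_ils_model <- function() {
  nwk <- "((((A:0.1,B:0.1):0.1,C:0.2):0.1,D:0.3):0.1,E:0.4);"
  species_tree_model(parse_newick(nwk), theta = 1e-4,
                     wgd_mrca = c("A", "B", "C", "D"), outgroup = "E",
                     root_theta = 1e-4)
}

# Mean normalized RF between true pruned gene trees and their ML
# re-estimates for a fixture/pattern cell.
gene_tree_error <- function(model, n_genes, pattern, seed, sites = 1000) {
  sim <- simulate_single_copy_genes(model, n_genes, pattern, sites = sites,
                                    seed = seed)
  mean(mapply(function(tr, a) rf_distance(ml_gene_tree(a, model$outgroup), tr),
              sim$true_trees, sim$alignments))
}
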