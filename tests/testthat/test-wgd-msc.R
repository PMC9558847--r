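test_that("fixtures have the documented geometry", {
  for (nm in c("S1", "S2", "S3", "S4")) {
    m <- fixture_species_tree(nm)
    h <- ape::node.depth.edgelength(m$tree)
    expect_equal(max(h), 0.06, tolerance = 1e-12)
    expect_lt(diff(range(h[1:5])), 1e-9)  # ultrametric
  }
  s1 <- fixture_species_tree("S1")
  expect_identical(topology_key(s1$tree), "((((A,B),C),D),E);")
  s4 <- fixture_species_tree("S4")
  expect_identical(topology_key(s4$tree), "(((A,B),(C,D)),E);")
  # post-WGD internal branch lengths and theta
  internal <- s1$tree$edge[, 2] > 5 & s1$tree$edge[, 2] != s1$wgd_node
  expect_true(all(abs(s1$tree$edge.length[internal] - 0.015) < 1e-12))
  expect_true(all(abs(s1$theta[internal] - 0.015) < 1e-12))
  expect_equal(fixture_species_tree("S4")$theta[internal][1], 0.2)
  expect_error(fixture_species_tree("S9"), "arg")
})

test_that("the duplicated tree has two complete copy subclades", {
  for (nm in c("S1", "S2")) {
    dup <- build_duplicated_tree(fixture_species_tree(nm))
    expect_length(dup$tree$tip.label, 9)
    for (copy in 1:2) {
      sub <- prune_tips(dup$tree,
                        paste0(c("A", "B", "C", "D"), "_", copy))
      sub$tip.label <- sub("_[12]$", "", sub$tip.label)
      ing <- prune_tips(fixture_species_tree(nm)$tree, c("A", "B", "C", "D"))
      expect_identical(topology_key(sub), topology_key(ing))
    }
  }
  # WGD on a terminal branch is rejected
  expect_error(
    species_tree_model(parse_newick("((A:1,B:1):1,C:2);"), theta = 0.1,
                       wgd_mrca = "A", outgroup = "C"),
    "terminal")
})

test_that("gene trees are ultrametric, taller than the species tree, and keep copies apart below the WGD", {
  dup <- build_duplicated_tree(fixture_species_tree("S3"))
  set.seed(21)
  pt <- pseudoortho:::build_poptree(dup)
  for (i in 1:40) {
    sim <- pseudoortho:::sim_coal_merges(pt)
    g <- pseudoortho:::merges_to_phylo(sim)
    d <- ape::node.depth.edgelength(g)
    expect_lt(diff(range(d[1:9])), 1e-9)        # contemporaneous tips
    expect_gt(max(d), 0.06)                      # deeper than species tree
    # merges mixing the two copies cannot predate the WGD point
    masks <- sim$masks[-(1:9)]
    heights <- sim$merges[, 3]
    labs <- pt$labels
    copy1 <- sum(2^(grep("_1$", labs) - 1))
    copy2 <- sum(2^(grep("_2$", labs) - 1))
    mixed <- bitwAnd(as.integer(masks), as.integer(copy1)) > 0 &
      bitwAnd(as.integer(masks), as.integer(copy2)) > 0
    expect_true(all(heights[mixed] >= dup$wgd_height - 1e-12))
  }
})

test_that("within-branch coalescence follows the exponential waiting time", {
  # two lineages entering a branch of length t with parameter theta
  # coalesce with probability 1 - exp(-conv * t / theta)
  nwk <- "((A:0.02,B:0.02):0.03,C:0.05);"
  m <- species_tree_model(parse_newick(nwk), theta = 0.04, wgd_mrca = c("A", "B"),
                          outgroup = "C", root_theta = 0.04)
  pt <- pseudoortho:::build_poptree(m, conv = 2)
  set.seed(5)
  n <- 30000
  hit <- 0L
  for (i in seq_len(n)) {
    sim <- pseudoortho:::sim_coal_merges(pt)
    ab <- which(sim$masks[4:5] == 3)          # merge of exactly {A,B}
    if (length(ab) && sim$merges[ab[1], 3] <= 0.05) hit <- hit + 1L
  }
  p_expected <- 1 - exp(-2 * 0.03 / 0.04)
  expect_lt(abs(hit / n - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / n))
})

test_that("rooted-triplet concordance matches the closed form", {
  # 3-taxon tree with an internal branch of T coalescent units:
  # P(match) = 1 - (2/3) exp(-T)
  T <- 1
  theta <- 0.05
  blen <- T * theta / 2                       # conv = 2
  nwk <- sprintf("((A:0.01,B:0.01):%0.6f,C:%0.6f);", blen, 0.01 + blen)
  m <- species_tree_model(parse_newick(nwk), theta = theta,
                          wgd_mrca = c("A", "B"), outgroup = "C",
                          root_theta = theta)
  set.seed(31)
  n <- 20000
  hit <- 0L
  pt <- pseudoortho:::build_poptree(m, conv = 2)
  for (i in seq_len(n)) {
    sim <- pseudoortho:::sim_coal_merges(pt)
    if (sim$masks[4] == 3) hit <- hit + 1L     # first merge is {A,B}
  }
  p <- 1 - 2 / 3 * exp(-T)
  expect_lt(abs(hit / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("single-lineage branches pass through unchanged and divergence exceeds the species tree", {
  dup <- build_duplicated_tree(fixture_species_tree("S1"))
  g <- simulate_gene_tree(dup, seed = 77)
  # pairwise divergence of gene copies is at least the species divergence
  dg <- ape::cophenetic.phylo(g)
  expect_true(all(dg["A_1", "B_1"] >= 2 * 0.015 - 1e-12))
  expect_gt(mean(dg[upper.tri(dg)]),
            mean(ape::cophenetic.phylo(dup$tree)[upper.tri(dg)]))
})

test_that("topology frequency reaches 1 in the no-ILS limit", {
  r <- topology_frequency(no_ils_model(), n = 300, seed = 4)
  expect_equal(r$proportion, 1)
})

test_that("identical seeds reproduce identical gene trees", {
  dup <- build_duplicated_tree(fixture_species_tree("S2"))
  g1 <- simulate_gene_tree(dup, seed = 9)
  g2 <- simulate_gene_tree(dup, seed = 9)
  expect_identical(write_newick(g1), write_newick(g2))
})
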