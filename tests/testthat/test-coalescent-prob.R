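test_that("coalescent topology probabilities are exact on rooted triplets", {
  for (T in c(0.2, 1, 3)) {
    nwk <- sprintf("((A:1,B:1):%g,C:%g);", T, 1 + T)
    p <- coalescent_topology_prob(parse_newick(nwk))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p["((A,B),C);"]), 1 - 2 / 3 * exp(-T),
                 tolerance = 1e-12)
    # the two discordant triplets are equally likely
    expect_equal(unname(p["((A,C),B);"]), unname(p["(A,(B,C));"]),
                 tolerance = 1e-12)
  }
  # T = 1 evaluates to 1 - (2/3) e^{-1} = 0.754747
  p1 <- coalescent_topology_prob(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(p1["((A,B),C);"]), 0.754747, tolerance = 1e-6)
})

test_that("four-taxon topology probabilities sum to one and hit the no-ILS limit", {
  for (s in 1:4) {
    set.seed(s)
    L <- stats::runif(2, 0.1, 2)
    nwk <- sprintf("(((A:1,B:1):%g,C:2):%g,D:3);", L[1], L[2])
    p <- coalescent_topology_prob(parse_newick(nwk))
    expect_length(p, 15)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  t4 <- parse_newick("(((A:1,B:1):40,C:2):40,D:3);")
  expect_equal(unname(coalescent_topology_prob(t4)[topology_key(t4)]), 1,
               tolerance = 1e-12)
  # symmetric shape
  t4s <- parse_newick("((A:1,B:1):40,(C:1,D:1):40);")
  expect_equal(unname(coalescent_topology_prob(t4s)[topology_key(t4s)]), 1,
               tolerance = 1e-12)
  expect_error(coalescent_topology_prob(parse_newick("((A:-1,B:1):1,C:2);")),
               "nonnegative")
})

test_that("topology probabilities agree with Monte-Carlo coalescent draws", {
  # pectinate 4-taxon tree, moderate ILS, simulated via the MSC engine
  theta <- 0.05
  b <- 0.5 * theta / 2
  nwk <- sprintf("(((A:0.01,B:0.01):%g,C:%g):%g,D:%g);",
                 b, 0.01 + b, b, 0.01 + 2 * b)
  m <- species_tree_model(parse_newick(nwk), theta = theta,
                          wgd_mrca = c("A", "B", "C"), outgroup = "D",
                          root_theta = theta)
  p <- coalescent_topology_prob(
    pseudoortho:::dup_coalescent_tree(
      list(tree = m$tree, theta = m$theta), conv = 2))
  pt <- pseudoortho:::build_poptree(m, conv = 2)
  set.seed(8)
  n <- 8000
  counts <- stats::setNames(numeric(length(p)), names(p))
  for (i in seq_len(n)) {
    g <- pseudoortho:::merges_to_phylo(pseudoortho:::sim_coal_merges(pt))
    k <- topology_key(g)
    counts[k] <- counts[k] + 1
  }
  freq <- counts / n
  se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
  expect_true(all(abs(freq - p) < 3 * se + 1e-9))
})

test_that("the root-loss identity holds exactly for any theta", {
  for (nm in c("S1", "S3")) {
    m <- fixture_species_tree(nm)
    mix <- gene_tree_distribution(m, loss_spec(tau = c(Inf, rep(0.05, 6))))
    dup <- build_duplicated_tree(m)
    direct <- coalescent_topology_prob(
      pseudoortho:::subtree_geometry(dup, c(A = 1, B = 1, C = 1, D = 1)))
    expect_equal(mix[names(direct)], direct, tolerance = 1e-12)
  }
})

test_that("the gene-tree mixture behaves correctly in the ILS limits", {
  # high-ILS limit: internal lengths near zero -> the pseudoortholog
  # distribution converges to the ortholog coalescent distribution
  m <- species_tree_model(parse_newick(
    paste0("((((A:0.001,B:0.001):0.000005,C:0.001005):0.000005,",
           "D:0.00101):0.000005,E:0.001015);")),
    theta = 0.1, wgd_mrca = c("A", "B", "C", "D"), outgroup = "E",
    root_theta = 0.1)
  mix <- gene_tree_distribution(m, loss_spec(p = rep(0.5, 4)))
  dup <- build_duplicated_tree(m)
  ortho <- coalescent_topology_prob(
    pseudoortho:::subtree_geometry(dup, c(A = 1, B = 1, C = 1, D = 1)))
  expect_lt(max(abs(mix[names(ortho)] - ortho)), 1e-3)

  # low-ILS limit: long internal branches -> the mixture converges to the
  # subtree distribution itself
  ml <- no_ils_model()
  mix_l <- gene_tree_distribution(ml, loss_spec(p = rep(0.5, 4)))
  sd_l <- subtree_distribution(ml, loss_spec(p = rep(0.5, 4)))
  keys <- vapply(sd_l$trees, topology_key, "")
  implied <- stats::setNames(numeric(length(mix_l)), names(mix_l))
  for (i in seq_along(keys))
    implied[keys[i]] <- implied[keys[i]] + sd_l$prob[i]
  expect_lt(max(abs(mix_l - implied)), 1e-6)
})

test_that("biased retention favors the species-tree subtree", {
  m <- fixture_species_tree("S1")
  sd8 <- subtree_distribution(m, loss_spec(p = rep(0.8, 4)))
  top2 <- sd8$prob["T1"] + sd8$prob["T2"]
  expect_true(all(top2 > sd8$prob[3:8]))
  expect_gt(sd8$prob["T1"], max(sd8$prob[2:8]))
})

test_that("the mixture agrees with full pipeline Monte-Carlo under pattern 2", {
  m <- fixture_species_tree("S2")
  mix <- gene_tree_distribution(m, loss_spec(p = rep(0.5, 4)))
  dup <- build_duplicated_tree(m)
  pt <- pseudoortho:::build_poptree(dup)
  set.seed(12)
  n <- 4000
  counts <- stats::setNames(numeric(length(mix)), names(mix))
  for (i in seq_len(n)) {
    g <- pseudoortho:::merges_to_phylo(pseudoortho:::sim_coal_merges(pt))
    sc <- apply_loss_pattern(g, 2)
    ing <- prune_tips(sc, c("A", "B", "C", "D"))
    counts[topology_key(ing)] <- counts[topology_key(ing)] + 1
  }
  freq <- counts / n
  se <- sqrt(pmax(mix * (1 - mix), 1e-12) / n)
  expect_true(all(abs(freq - mix) < 3 * se + 2e-3))
})
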