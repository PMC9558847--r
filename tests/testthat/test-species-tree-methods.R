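test_that("STAR reproduces the hand-averaged rank example", {
  mk <- function(nwk) parse_newick(nwk)
  gts <- c(replicate(70, mk("(((A,B),C),E);"), simplify = FALSE),
           replicate(15, mk("(((A,C),B),E);"), simplify = FALSE),
           replicate(15, mk("(((B,C),A),E);"), simplify = FALSE))
  st <- star_tree(gts, "E")
  expect_equal(rf_distance(st, mk("(((A,B),C),E);")), 0)
  avg <- attr(st, "average_distances")
  # hand computation: root rank 4, child 3, grandchild 2;
  # d(A,B) = .70*4 + .15*6 + .15*6 = 4.6; d(A,C) = .70*6 + .15*4 + .15*6 = 5.7
  expect_equal(avg["A", "B"], 4.6)
  expect_equal(avg["A", "C"], 5.7)
  expect_equal(avg["A", "E"], 8)
  # all gene trees identical -> that topology
  same <- replicate(10, mk("((((A,B),C),D),E);"), simplify = FALSE)
  expect_equal(rf_distance(star_tree(same, "E"), same[[1]]), 0)
  expect_error(star_tree(list(ape::unroot(mk("(((A,B),C),E);"))), "E"),
               "rooted")
})

test_that("quartet scores equal the brute-force double loop", {
  set.seed(15)
  gts <- lapply(1:12, function(i) rand_tree(5, 300 + i))
  labels <- sort(gts[[1]]$tip.label)
  gts <- lapply(gts, function(g) { g$tip.label <- labels[match(g$tip.label, sort(g$tip.label))]; g })
  est <- quartet_species_tree(gts)
  # brute force: count agreements over genes x quartets for the winner
  brute_score <- function(cand, gts) {
    total <- 0
    for (g in gts) for (q in utils::combn(labels, 4, simplify = FALSE)) {
      qg <- prune_tips(g, q); qc <- prune_tips(cand, q)
      if (rf_distance(ape::unroot(qg), ape::unroot(qc)) == 0)
        total <- total + 1
    }
    total
  }
  expect_equal(attr(est, "score"), brute_score(est, gts))
  # no candidate beats the winner
  for (cand in pseudoortho:::all_unrooted_topologies(labels)[c(2, 9, 14)])
    expect_lte(brute_score(cand, gts), attr(est, "score"))
  # single gene tree: that tree, score = choose(5,4)
  one <- quartet_species_tree(gts[1])
  expect_equal(rf_distance(one, gts[[1]]), 0)
  expect_equal(attr(one, "score"), 5)
})

test_that("a dominant topology wins the quartet score", {
  maj <- parse_newick("((((A,B),C),D),E);")
  alt1 <- parse_newick("((((A,C),B),D),E);")
  alt2 <- parse_newick("((((B,C),A),D),E);")
  gts <- c(replicate(10, maj, simplify = FALSE),
           replicate(3, alt1, simplify = FALSE),
           replicate(3, alt2, simplify = FALSE))
  expect_equal(rf_distance(quartet_species_tree(gts, "E"), maj), 0)
})

test_that("MP-EST recovers parameters from analytic triple counts", {
  gen <- parse_newick("((((A,B),C),D),E);")
  same <- replicate(50, gen, simplify = FALSE)
  fit <- mpest_tree(same)
  expect_equal(rf_distance(fit, gen), 0)
  # all trees identical pushes internal lengths to the upper bound
  expect_true(all(fit$edge.length[fit$edge[, 2] > 5] >= 10 - 1e-6))

  # parameter recovery: simulate true coalescent gene trees on a tree
  # with internal branches of 1 coalescent unit and check the estimated
  # lengths are near 1
  theta <- 0.05
  b <- theta / 2
  nwk <- sprintf("((((A:0.01,B:0.01):%g,C:%g):%g,D:%g):0.05,E:%g);",
                 b, 0.01 + b, b, 0.01 + 2 * b, 0.06 + 2 * b)
  m <- species_tree_model(parse_newick(nwk), theta = theta,
                          wgd_mrca = c("A", "B", "C", "D"), outgroup = "E",
                          root_theta = theta)
  pt <- pseudoortho:::build_poptree(m, conv = 2)
  set.seed(16)
  gts <- replicate(4000, pseudoortho:::merges_to_phylo(
    pseudoortho:::sim_coal_merges(pt)), simplify = FALSE)
  fit2 <- mpest_tree(gts)
  expect_equal(rf_distance(fit2, m$tree), 0)
  ing_edges <- which(fit2$edge[, 2] > 5)
  lens <- sort(fit2$edge.length[ing_edges])
  # the two ingroup internal branches were 1 coalescent unit
  expect_lt(abs(lens[1] - 1), 0.2)
  expect_lt(abs(lens[2] - 1), 0.2)
})

test_that("Fitch parsimony matches hand scores and phangorn", {
  taxa <- LETTERS[1:5]
  a <- matrix(c("A", "A", "C", "C", "C"), 5, 1, dimnames = list(taxa, NULL))
  res <- ca_mp_tree(a)
  expect_equal(res$score, 1)
  # every topology separating {A,B} from the rest attains score 1
  sep <- parse_newick("(((A,B),C),(D,E));")
  expect_true(any(sapply(res$trees, function(t)
    rf_distance(t, sep, normalized = FALSE) == 0)))
  # constant columns contribute nothing
  a2 <- cbind(a, matrix("G", 5, 7))
  expect_equal(ca_mp_tree(a2)$score, 1)
  # random alignments agree with phangorn's Fitch implementation
  set.seed(17)
  for (i in 1:4) {
    al <- simulate_jc69(rand_tree(5, 500 + i), 60, seed = i)
    cp <- pseudoortho:::compress_patterns(al)
    cands <- pseudoortho:::all_unrooted_topologies(rownames(al))
    ours <- sapply(cands, pseudoortho:::fitch_score, cp = cp)
    pd <- phangorn::phyDat(al)
    theirs <- sapply(cands, function(t) phangorn::parsimony(t, pd))
    expect_equal(unname(ours), unname(theirs))
  }
  expect_error(ca_mp_tree(matrix("X", 5, 2, dimnames = list(taxa, NULL))),
               "non-nucleotide")
})

test_that("CA-ML is internally consistent and exact on clean data", {
  gen <- parse_newick("((((A:0.05,B:0.05):0.05,C:0.1):0.05,D:0.15):0.05,E:0.2);")
  a <- simulate_jc69(gen, 4000, seed = 18)
  ml <- ca_ml_tree(a, "E")
  expect_equal(rf_distance(ml, gen), 0)
  # reported likelihood equals an independent evaluation of the tree
  expect_equal(attr(ml, "loglik"), jc69_loglik(ml, a), tolerance = 1e-6)
})

test_that("all methods recover the species tree without ILS", {
  m <- no_ils_model()
  sim <- simulate_single_copy_genes(m, 25, 1, sites = 600, seed = 19)
  gts <- lapply(sim$alignments, ml_gene_tree, outgroup = "E")
  conc <- concat_alignments(sim$alignments)$alignment
  expect_equal(rf_distance(quartet_species_tree(gts, "E"), m$tree), 0)
  expect_equal(rf_distance(mpest_tree(gts), m$tree), 0)
  expect_equal(rf_distance(star_tree(gts, "E"), m$tree), 0)
  expect_equal(rf_distance(ca_mp_tree(conc)$consensus, m$tree), 0)
  expect_equal(rf_distance(ca_ml_tree(conc, "E"), m$tree), 0)
})

test_that("reciprocal internal loss drives every method to the symmetric subtree", {
  m <- fixture_species_tree("S1")
  t6 <- parse_newick("(((A,B),(C,D)),E);")
  sim <- simulate_single_copy_genes(m, 40, 3, sites = 1000, seed = 20)
  gts <- lapply(sim$alignments, ml_gene_tree, outgroup = "E")
  conc <- concat_alignments(sim$alignments)$alignment
  for (est in list(quartet_species_tree(gts, "E"), mpest_tree(gts),
                   star_tree(gts, "E"), ca_mp_tree(conc)$consensus,
                   ca_ml_tree(conc, "E")))
    expect_equal(rf_distance(est, t6), 0)
})
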