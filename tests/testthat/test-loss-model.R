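test_that("loss patterns implement the documented procedures", {
  dup <- build_duplicated_tree(fixture_species_tree("S1"))
  g <- simulate_gene_tree(dup, seed = 2)
  set.seed(10)
  for (i in 1:20) {
    r1 <- attr(apply_loss_pattern(g, 1), "retained")
    expect_true(all(r1 == r1[1]))                       # whole subclade kept
    r3 <- attr(apply_loss_pattern(g, 3), "retained")
    expect_true(r3["A"] == r3["B"] && r3["C"] == r3["D"] &&
                  r3["A"] != r3["C"])                   # reciprocal 2+2
    r12 <- attr(apply_loss_pattern(g, 12), "retained")
    expect_true(r12["A"] == r12["B"] && r12["B"] == r12["C"])  # D free
  }
  sc <- apply_loss_pattern(g, 2)
  expect_setequal(sc$tip.label, c("A", "B", "C", "D", "E"))
  expect_error(apply_loss_pattern(g, 15), "unknown")
})

test_that("pattern coin structure matches the catalog", {
  cat <- pattern_catalog()
  expect_equal(nrow(cat), 14)
  expect_equal(cat$p_A[1], 1)
  expect_equal(unname(unlist(cat[2, c("p_A", "p_B", "p_C", "p_D")])),
               rep(0.5, 4))
  expect_equal(cat$coin_retained[3], "CD")
  expect_equal(cat$independent[10], "BD")
})

test_that("pseudoortholog classification and closed-form fractions agree", {
  expect_false(is_pseudoortholog(c(1, 1, 1, 1)))
  expect_true(is_pseudoortholog(c(1, 1, 2, 1)))
  expect_equal(expected_pseudoortholog_fraction(1), 0)
  expect_equal(expected_pseudoortholog_fraction(2), 0.875)
  for (p in 3:8) expect_equal(expected_pseudoortholog_fraction(p), 1)
  for (p in 9:11) expect_equal(expected_pseudoortholog_fraction(p), 0.75)
  for (p in 12:14) expect_equal(expected_pseudoortholog_fraction(p), 0.5)
})

test_that("empirical pseudoortholog fractions match the closed forms", {
  set.seed(14)
  n <- 20000
  for (pat in c(2, 6, 10, 13)) {
    frac <- mean(replicate(n, is_pseudoortholog(draw_retention(pat))))
    p <- expected_pseudoortholog_fraction(pat)
    tol <- 3 * sqrt(max(p * (1 - p), 1e-12) / n)
    expect_lt(abs(frac - p), tol + 1e-12)
  }
})

test_that("subtree enumeration lists the eight pruned topologies", {
  trees <- enumerate_subtrees(fixture_species_tree("S1"))
  expect_length(trees, 8)
  expect_identical(topology_key(trees$T3), "(((A,B),D),C);")
  expect_identical(topology_key(trees$T6), "((A,B),(C,D));")
  expect_identical(topology_key(trees$T7), "((A,C),(B,D));")
  expect_identical(topology_key(trees$T8), "((A,D),(B,C));")
  expect_identical(topology_key(trees$T1), topology_key(trees$T2))
  keys <- vapply(trees, topology_key, "")
  expect_length(unique(keys), 7)   # T1 and T2 coincide as shapes
  m3 <- fixture_species_tree("S1")
  m3$post_wgd <- c("A", "B", "C")  # force a malformed model
  expect_error(enumerate_subtrees(m3), "4 post-WGD")
})

test_that("subtree distribution reproduces the degenerate and uniform cases", {
  for (nm in c("S1", "S2")) {
    m <- fixture_species_tree(nm)
    u <- subtree_distribution(m, loss_spec(p = rep(0.5, 4)))
    expect_equal(unname(u$prob), rep(1 / 8, 8), tolerance = 1e-12)
    expect_equal(sum(u$prob), 1, tolerance = 1e-12)
  }
  m <- fixture_species_tree("S1")
  # root loss -> T1 with probability 1
  rl <- subtree_distribution(m, loss_spec(tau = c(Inf, rep(0.01, 6))))
  expect_equal(unname(rl$prob["T1"]), 1)
  # pA=pB=1, pC=pD=0 -> T6
  t6 <- subtree_distribution(m, loss_spec(p = c(1, 1, 0, 0)))
  expect_equal(unname(t6$prob["T6"]), 1)
  # pA=pB=pC=1, pD=0 -> T2 (species topology, longer internal branches)
  t2 <- subtree_distribution(m, loss_spec(p = c(1, 1, 1, 0)))
  expect_equal(unname(t2$prob["T2"]), 1)
  # all-or-nothing retention -> T1
  t1 <- subtree_distribution(m, loss_spec(p = c(1, 1, 1, 1)))
  expect_equal(unname(t1$prob["T1"]), 1)
})

test_that("pattern-mode subtree distribution matches the coin procedures", {
  m <- fixture_species_tree("S1")
  p1 <- subtree_distribution(m, loss_spec(pattern = 1))
  expect_equal(unname(p1$prob["T1"]), 1)
  p3 <- subtree_distribution(m, loss_spec(pattern = 3))
  expect_equal(unname(p3$prob["T6"]), 1)
  p9 <- subtree_distribution(m, loss_spec(pattern = 9))
  # A,B tied; C,D free: (1/4 each on the four compatible configs)
  expect_equal(sum(p9$prob), 1, tolerance = 1e-12)
  expect_equal(unname(p9$prob[c("T1", "T2", "T3", "T6")]),
               rep(0.25, 4), tolerance = 1e-12)
})

test_that("branch-rate mode agrees with terminal-probability mode on terminal-only loss", {
  m <- fixture_species_tree("S1")
  # terminal intensities only: each species independently retains the
  # copy whose branch escaped loss; conditioning makes retention a fair
  # coin per species regardless of the intensity
  br <- subtree_distribution(m, loss_spec(tau = c(0, 0, 0, rep(0.7, 4))))
  expect_equal(unname(br$prob), rep(1 / 8, 8), tolerance = 1e-12)
  # loss certain everywhere: in the limit a single subclade survives
  allinf <- subtree_distribution(m, loss_spec(tau = rep(Inf, 7)))
  expect_equal(unname(allinf$prob["T1"]), 1)
  # no loss at all cannot produce single-copy genes
  expect_error(subtree_distribution(m, loss_spec(tau = rep(0, 7))), "no retention")
})
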