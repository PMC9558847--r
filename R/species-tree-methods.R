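# Exact small-scale implementations of the five species-tree estimators
# under comparison: STAR (average ranks of coalescences + NJ),
# quartet-score maximization (the ASTRAL objective, optimized exactly by
# exhaustive enumeration), MP-EST's pseudo-likelihood of rooted triple
# frequencies, concatenated parsimony (CA-MP, exhaustive Fitch), and
# concatenated maximum likelihood (CA-ML, exhaustive JC69).

check_gene_trees <- function(gts, rooted = TRUE) {
  stopifnot(is.list(gts), length(gts) >= 1L)
  labels <- sort(gts[[1L]]$tip.label)
  for (g in gts) {
    if (!inherits(g, "phylo")) stop("gene trees must be phylo objects")
    if (!identical(sort(g$tip.label), labels))
      stop("gene trees must share one species label set")
    if (rooted && !ape::is.rooted(g))
      stop("this method requires rooted gene trees")
  }
  labels
}

#' STAR species tree from average coalescence ranks
#'
#' For each rooted gene tree, internal nodes are ranked from the root
#' down (root rank `n`, each internal child one less than its parent,
#' floored at 2 under the default rule), the distance between two
#' species is twice the rank of their most recent common ancestor,
#' distances are averaged across genes, and the species tree is built by
#' neighbor joining on the average matrix, rooted with the outgroup.
#' A root rank of `n` keeps every level of a binary outgroup-rooted tree
#' distinguishable (with root rank `n - 1` the floor collapses the two
#' deepest ingroup levels of a 5-taxon tree onto rank 2, discarding the
#' within-ingroup signal).
#'
#' @param gts List of rooted `phylo` gene trees on one species set.
#' @param outgroup Outgroup label used to root the result.
#' @param rank_rule `"floor2"` (default, rank never drops below 2) or
#'   `"uniform"` (plain decrement).
#' @return Rooted `phylo` species tree with attribute
#'   `"average_distances"`.
#' @export
star_tree <- function(gts, outgroup, rank_rule = c("floor2", "uniform")) {
  rank_rule <- match.arg(rank_rule)
  labels <- check_gene_trees(gts, rooted = TRUE)
  if (!outgroup %in% labels) stop("outgroup not among species")
  n <- length(labels)
  acc <- matrix(0, n, n, dimnames = list(labels, labels))
  for (g in gts) {
    ntip <- length(g$tip.label)
    ranks <- numeric(ntip + g$Nnode)
    root <- root_node(g)
    ranks[root] <- n
    for (e in rev(ape::postorder(g))) {
      p <- g$edge[e, 1L]; ch <- g$edge[e, 2L]
      if (ch > ntip) {
        r <- ranks[p] - 1
        ranks[ch] <- if (rank_rule == "floor2") max(r, 2) else r
      }
    }
    mr <- ape::mrca(g)
    idx <- match(labels, g$tip.label)
    acc <- acc + 2 * matrix(ranks[mr[idx, idx]], n, n)
  }
  avg <- acc / length(gts)
  diag(avg) <- 0
  tr <- nj_tree(avg)
  out <- root_with_outgroup(tr, outgroup)
  attr(out, "average_distances") <- avg
  out
}

# Quartet topology of four sorted labels induced by a binary tree,
# encoded 1/2/3: 1 = (q1,q2)|(q3,q4), 2 = (q1,q3)|(q2,q4),
# 3 = (q1,q4)|(q2,q3).
induced_quartets <- function(tree, labels, quartets) {
  splits <- tree_splits(tree, labels)
  bits <- 2^(seq_along(labels) - 1)
  out <- integer(ncol(quartets))
  for (k in seq_len(ncol(quartets))) {
    q <- quartets[, k]
    qbits <- bits[q]
    for (s in splits) {
      inq <- (s %/% qbits) %% 2 == 1
      if (sum(inq) == 2L) {
        pairq <- which(inq)
        out[k] <- if (all(pairq == c(1L, 2L)) || all(pairq == c(3L, 4L))) 1L
        else if (all(pairq == c(1L, 3L)) || all(pairq == c(2L, 4L))) 2L
        else 3L
        break
      }
    }
  }
  out
}

#' Species tree by exact quartet-score maximization
#'
#' The ASTRAL objective computed exactly: for every candidate unrooted
#' binary topology on the species set, the score is the number of
#' (gene, four-species subset) pairs whose induced quartet topologies
#' agree; the maximum-scoring candidate is returned. The outgroup plays
#' no role in scoring and only roots the output.
#'
#' @param gts List of `phylo` gene trees (rooted or not) on one species
#'   set.
#' @param outgroup Optional outgroup to root the returned tree.
#' @return `phylo` species tree with attributes `"score"` and `"tie"`.
#' @export
quartet_species_tree <- function(gts, outgroup = NULL) {
  labels <- check_gene_trees(gts, rooted = FALSE)
  n <- length(labels)
  quartets <- utils::combn(n, 4L)
  counts <- matrix(0, 3L, ncol(quartets))
  for (g in gts) {
    iq <- induced_quartets(g, labels, quartets)
    res <- iq > 0L
    counts[cbind(iq[res], which(res))] <- counts[cbind(iq[res], which(res))] + 1
  }
  cands <- all_unrooted_topologies(labels)
  scores <- vapply(cands, function(cand) {
    cq <- induced_quartets(cand, labels, quartets)
    sum(counts[cbind(cq, seq_len(ncol(quartets)))])
  }, 0)
  best <- which.max(scores)
  tie <- sum(scores == scores[best]) > 1L
  out <- cands[[best]]
  if (!is.null(outgroup)) out <- root_with_outgroup(out, outgroup)
  attr(out, "score") <- scores[best]
  attr(out, "tie") <- tie
  out
}

# Rooted-triple cherry of three labels in a rooted tree: returns 1, 2 or
# 3 for cherry (x,y), (x,z), (y,z).
triple_cherries <- function(tree, labels, triples) {
  mr <- ape::mrca(tree)
  idx <- match(labels, tree$tip.label)
  out <- integer(ncol(triples))
  for (k in seq_len(ncol(triples))) {
    t3 <- idx[triples[, k]]
    m12 <- mr[t3[1L], t3[2L]]; m13 <- mr[t3[1L], t3[3L]]
    m23 <- mr[t3[2L], t3[3L]]
    # two of the pairwise MRCAs coincide at the triple MRCA; the odd one
    # is the cherry
    out[k] <- if (m12 != m13 && m12 != m23) 1L
    else if (m13 != m12 && m13 != m23) 2L
    else 3L
  }
  out
}

# For each triple, the internal branch length (sum of candidate internal
# edge parameters) separating the cherry MRCA from the triple MRCA:
# a 0/1 coefficient matrix (ntriples x nparams).
triple_coefficients <- function(cand, labels, triples, param_edges) {
  ntip <- length(cand$tip.label)
  parent <- integer(ntip + cand$Nnode)
  parent[cand$edge[, 2L]] <- cand$edge[, 1L]
  edge_ix <- integer(ntip + cand$Nnode)
  edge_ix[cand$edge[, 2L]] <- seq_len(nrow(cand$edge))
  mr <- ape::mrca(cand)
  idx <- match(labels, cand$tip.label)
  cherries <- triple_cherries(cand, labels, triples)
  coef <- matrix(0, ncol(triples), length(param_edges))
  for (k in seq_len(ncol(triples))) {
    t3 <- idx[triples[, k]]
    m <- c(mr[t3[1L], t3[2L]], mr[t3[1L], t3[3L]], mr[t3[2L], t3[3L]])
    mc <- m[cherries[k]]            # the odd (cherry) MRCA
    mt <- m[-cherries[k]][1L]       # the duplicated value: triple MRCA
    v <- mc
    while (v != mt) {
      j <- match(edge_ix[v], param_edges)
      if (!is.na(j)) coef[k, j] <- coef[k, j] + 1
      v <- parent[v]
    }
  }
  list(coef = coef, cherries = cherries)
}

#' MP-EST species tree by maximum pseudo-likelihood
#'
#' Tallies the rooted-triple topologies of every species triple across
#' the gene trees and, for every candidate rooted binary species tree,
#' maximizes the product over triples of trinomial probabilities: a
#' triple matching the candidate has probability `1 - (2/3) exp(-T)` and
#' each alternative `(1/3) exp(-T)`, where `T` is the internal branch
#' length (in coalescent units) separating the cherry from the triple
#' ancestor. Internal branch lengths are optimized within
#' `[1e-6, 10]`; the search over candidates is exhaustive.
#'
#' @param gts List of rooted `phylo` gene trees (outgroup included).
#' @return Rooted `phylo` with optimized internal branch lengths
#'   (coalescent units) and attributes `"logpl"` and `"tie"`.
#' @export
mpest_tree <- function(gts) {
  labels <- check_gene_trees(gts, rooted = TRUE)
  n <- length(labels)
  triples <- utils::combn(n, 3L)
  counts <- matrix(0, 3L, ncol(triples))
  for (g in gts) {
    tc <- triple_cherries(g, labels, triples)
    counts[cbind(tc, seq_len(ncol(triples)))] <-
      counts[cbind(tc, seq_len(ncol(triples)))] + 1
  }
  cands <- phangorn::allTrees(n, rooted = TRUE, tip.label = labels)
  best <- NULL; best_ll <- -Inf; tie <- FALSE
  for (ci in seq_along(cands)) {
    cand <- stats::reorder(cands[[ci]], "cladewise")  # [[ restores labels
    ntip <- length(cand$tip.label)
    internal_child <- cand$edge[, 2L] > ntip
    param_edges <- which(internal_child)
    tcf <- triple_coefficients(cand, labels, triples, param_edges)
    match_count <- counts[cbind(tcf$cherries, seq_len(ncol(triples)))]
    other_count <- colSums(counts) - match_count
    negll <- function(x) {
      T <- as.vector(tcf$coef %*% x)
      eT <- exp(-T)
      -sum(match_count * log(1 - 2 / 3 * eT) + other_count * log(eT / 3))
    }
    opt <- stats::optim(rep(1, length(param_edges)), negll,
                        method = "L-BFGS-B", lower = 1e-6, upper = 10)
    ll <- -opt$value
    if (ll > best_ll + 1e-9) {
      cand$edge.length <- rep(0, nrow(cand$edge))
      cand$edge.length[param_edges] <- opt$par
      best <- cand; best_ll <- ll; tie <- FALSE
    } else if (ll > best_ll - 1e-9) tie <- TRUE
  }
  attr(best, "logpl") <- best_ll
  attr(best, "tie") <- tie
  best
}

# Fitch parsimony score of one unrooted topology on compressed patterns.
fitch_score <- function(topo, cp) {
  rooted <- ape::root(topo, outgroup = cp$taxa[1L], resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  npat <- nrow(cp$states)
  ord <- match(rooted$tip.label, cp$taxa)
  sets <- vector("list", ntip + rooted$Nnode)
  for (j in seq_len(ntip)) {
    s <- cp$states[, ord[j]]
    sets[[j]] <- ifelse(s < 0L, 15L, bitwShiftL(1L, s))
  }
  score <- numeric(npat)
  po <- ape::postorder(rooted)
  for (e in po) {
    p <- rooted$edge[e, 1L]; ch <- rooted$edge[e, 2L]
    if (is.null(sets[[p]])) { sets[[p]] <- sets[[ch]]; next }
    inter <- bitwAnd(sets[[p]], sets[[ch]])
    zero <- inter == 0L
    score <- score + zero
    sets[[p]] <- ifelse(zero, bitwOr(sets[[p]], sets[[ch]]), inter)
  }
  sum(score * cp$weights)
}

#' Concatenated-parsimony species tree (CA-MP)
#'
#' Fitch parsimony scores computed for every unrooted binary topology on
#' the concatenated alignment (exhaustive search, a superset of
#' branch-and-bound); all minimum-score topologies are returned together
#' with their strict consensus, which is what downstream RF evaluation
#' uses when the optimum is not unique.
#'
#' @param a Concatenated character-matrix alignment (nucleotides; 4-6
#'   taxa).
#' @return List with `trees` (all best topologies), `consensus` (strict
#'   consensus `phylo`), and `score`.
#' @export
ca_mp_tree <- function(a) {
  check_alignment(a)
  if (nrow(a) > 6L) stop("exhaustive search supports at most 6 taxa")
  if (!all(toupper(a) %in% c(DNA_STATES, "-", "N", "?")))
    stop("non-nucleotide states in alignment")
  cp <- compress_patterns(a)
  cands <- all_unrooted_topologies(rownames(a))
  scores <- vapply(cands, fitch_score, 0, cp = cp)
  best <- which(scores == min(scores))
  trees <- cands[best]
  consensus <- if (length(trees) == 1L) trees[[1L]]
  else ape::consensus(trees, p = 1)
  list(trees = trees, consensus = consensus, score = min(scores))
}

#' Concatenated maximum-likelihood species tree (CA-ML)
#'
#' Exhaustive JC69 maximum likelihood on the concatenated,
#' pattern-compressed alignment: every unrooted binary topology is
#' scored with per-topology branch-length optimization and the best is
#' returned.
#'
#' @param a Concatenated character-matrix alignment (4-6 taxa).
#' @param outgroup Optional outgroup label to root the result.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return `phylo` with attributes `"loglik"` and `"tie"`.
#' @export
ca_ml_tree <- function(a, outgroup = NULL, tol = 1e-6) {
  out <- ml_gene_tree(a, outgroup = if (is.null(outgroup)) rownames(a)[1L]
                      else outgroup, tol = tol)
  if (is.null(outgroup)) out <- ape::unroot(out)
  out
}
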