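# Exact gene-tree topology probabilities under the multispecies
# coalescent, by enumeration of coalescent histories, and the mixture
# distribution of single-copy gene trees over the eight pruned subtrees:
#
#   P(G | S, theta, lambda) = sum_i P(G | T_i, theta) P(T_i | S, lambda)
#
# All branch lengths entering these functions are in coalescent units
# (pairwise coalescence rate 1); conversion from mutation units is
# conv * length / theta, applied segment-wise when subtree branches
# traverse several species-tree populations.

# Probability that, in a population of duration T entered by k lineages,
# a specific ordered sequence of c merges occurs and the survivors do
# not coalesce further:
#   I = int_{0<t1<...<tc<T} prod_i exp(-r_i dt_i) * exp(-r_{c+1} dt_last)
# with r_i = choose(k-i+1, 2) (total rate while i-1 merges have
# happened; the specific pair contributes rate 1). The rates are
# strictly decreasing, so the closed form for distinct rates applies:
#   I = sum_j exp(-r_j T) * prod_{i != j} 1 / (r_i - r_j).
ordered_merge_prob <- function(k, c, T) {
  rates <- choose(seq(k, k - c), 2)   # r_1 .. r_{c+1}
  if (c == 0L) return(exp(-rates[1L] * T))
  if (!is.finite(T)) {
    # only possible when the survivors cannot coalesce (rate 0)
    if (rates[c + 1L] > 0) return(0)
    return(prod(1 / rates[seq_len(c)]))
  }
  total <- 0
  for (j in seq_along(rates))
    total <- total + exp(-rates[j] * T) / prod(rates[-j] - rates[j])
  total
}

# All rooted binary topologies on a label set, as phylo objects.
# ([[ indexing restores the tip labels that multiPhylo stores once.)
all_rooted_topologies <- function(labels) {
  trees <- phangorn::allTrees(length(labels), rooted = TRUE,
                              tip.label = labels)
  lapply(seq_along(trees), function(i) trees[[i]])
}

#' Canonical topology key of a tree
#'
#' The canonical Newick string of the topology (lengths dropped,
#' children rotated lexicographically); equal keys mean equal rooted
#' topologies. Used as names for topology distributions.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @export
topology_key <- function(tree) write_newick(drop_lengths(tree))

#' Exact coalescent gene-tree topology distribution
#'
#' Computes the probability of every rooted labeled gene-tree topology
#' for lineages (one per tip) coalescing along a rooted species tree
#' whose branch lengths are in coalescent units, with an unbounded root
#' population. Probabilities are obtained by enumerating coalescent
#' histories (the assignment of each gene-tree coalescence to a
#' species-tree branch) and evaluating the exponential waiting-time
#' integrals in closed form.
#'
#' @param tree Rooted binary `phylo` with nonnegative branch lengths in
#'   coalescent units (3-8 tips; intended for the 4-taxon subtrees).
#' @return Named numeric vector over all rooted topologies (15 for four
#'   tips), names being canonical Newick strings; sums to 1.
#' @examples
#' t4 <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' p <- coalescent_topology_prob(t4)
#' p[topology_key(t4)]
#' @export
coalescent_topology_prob <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("species tree must be rooted and binary")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and nonnegative")
  ntip <- length(tree$tip.label)
  if (ntip < 3L || ntip > 8L) stop("supported for 3 to 8 tips")
  labels <- sort(tree$tip.label)
  gts <- all_rooted_topologies(labels)
  p <- vapply(gts, function(g) gene_topology_prob(g, tree), 0)
  stats::setNames(p, vapply(gts, topology_key, ""))
}

# Populations of a species tree: one per node (the branch above it),
# plus the root population (id = root node, duration Inf).
pop_structure <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- rep(Inf, n)
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- root_node(tree)
  # ancestor lists (population id v refers to the branch above node v;
  # the root population is above everything)
  anc <- vector("list", n)
  for (v in seq_len(n)) {
    a <- v
    u <- v
    while (u != root) { u <- parent[u]; a <- c(a, u) }
    anc[[v]] <- a
  }
  masks <- node_masks(tree, sort(tree$tip.label))
  list(ntip = ntip, n = n, parent = parent, elen = elen, root = root,
       anc = anc, masks = masks, kids = child_list(tree),
       labels = sort(tree$tip.label))
}

# Probability of one rooted gene topology g given species tree sp.
gene_topology_prob <- function(g, sp) {
  ps <- pop_structure(sp)
  ntip <- ps$ntip
  gm <- node_masks(g, ps$labels)
  g_kids <- child_list(g)
  g_root <- root_node(g)
  g_internal <- (ntip + 1L):(ntip + g$Nnode)
  g_parent <- integer(ntip + g$Nnode)
  g_parent[g$edge[, 2L]] <- g$edge[, 1L]

  # minimal population for each gene internal node: the species node
  # whose clade covers the gene clade (the MRCA population)
  min_pop <- vapply(g_internal, function(v) {
    cand <- which(vapply(seq_len(ps$n), function(u)
      bitwAnd(as.integer(ps$masks[u]), as.integer(gm[v])) == as.integer(gm[v]),
      TRUE))
    cand[which.min(vapply(cand, function(u) popcount(ps$masks[u]), 0))]
  }, 0L)

  # allowed populations: ancestors (inclusive) of the minimal one
  allowed <- lapply(seq_along(g_internal), function(i) ps$anc[[min_pop[i]]])

  total <- 0
  assign <- integer(length(g_internal))
  recurse <- function(i) {
    if (i > length(g_internal)) {
      total <<- total + history_prob(assign, g_internal, g_parent, ps, ntip)
      return()
    }
    for (pop in allowed[[i]]) {
      assign[i] <<- pop
      # parent/child population consistency is enforced in history_prob
      recurse(i + 1L)
    }
  }
  recurse(1L)
  total
}

# Probability of a specific assignment of gene merges to populations.
# Invalid assignments (a merge more rootward than its parent merge's
# population, inconsistent orderings) contribute 0.
history_prob <- function(assign, g_internal, g_parent, ps, ntip) {
  # check parent-population consistency: pop(parent merge) must be an
  # ancestor (inclusive) of pop(child merge)
  for (i in seq_along(g_internal)) {
    par <- g_parent[g_internal[i]]
    if (par == 0L) next
    j <- match(par, g_internal)
    if (!(assign[j] %in% ps$anc[[assign[i]]])) return(0)
  }
  # entering lineage counts per population, by flow from the tips
  enter <- integer(ps$n + 1L)          # per population id
  merges_in <- split(seq_along(g_internal), assign)
  nmerge <- integer(ps$n)
  for (pop in names(merges_in)) nmerge[as.integer(pop)] <-
      length(merges_in[[pop]])
  # process species nodes from tips rootward
  ord <- order(vapply(seq_len(ps$n), function(v) popcount(ps$masks[v]), 0))
  exit <- integer(ps$n)
  for (v in ord) {
    k <- if (v <= ntip) 1L else sum(exit[ps$kids[[v]]])
    enter[v] <- k
    c_v <- nmerge[v]
    if (c_v > k - 1L) return(0)
    if (v == ps$root && k - c_v != 1L) return(0)
    exit[v] <- k - c_v
  }
  prob <- 1
  for (v in seq_len(ps$n)) {
    c_v <- nmerge[v]
    if (v != ps$root && c_v == 0L) {
      if (enter[v] >= 2L)
        prob <- prob * ordered_merge_prob(enter[v], 0L, ps$elen[v])
      next
    }
    if (c_v == 0L) next
    ids <- g_internal[merges_in[[as.character(v)]]]
    prob <- prob * branch_merge_prob(ids, g_parent, enter[v], ps$elen[v])
    if (prob == 0) return(0)
  }
  prob
}

# Sum over linear orders of the merges in one population consistent with
# the gene-tree partial order (children before parents).
branch_merge_prob <- function(ids, g_parent, k, T) {
  c_v <- length(ids)
  perms <- permutations_of(c_v)
  total <- 0
  base <- ordered_merge_prob(k, c_v, T)
  for (pi in perms) {
    ord <- ids[pi]
    pos <- match(ids, ord)
    ok <- TRUE
    for (i in seq_along(ids)) {
      par <- g_parent[ids[i]]
      j <- match(par, ids)
      if (!is.na(j) && pos[j] <= pos[i]) { ok <- FALSE; break }
    }
    if (ok) total <- total + base
    # note: the integral value is the same for every order because the
    # rates depend only on how many merges have happened, not which
  }
  total
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <-
        c(i, ifelse(r >= i, r + 1L, r))
  }
  out
}

# ---------------------------------------------------------------------

# Duplicated tree with edge lengths converted to coalescent units.
dup_coalescent_tree <- function(dup, conv = conv_default()) {
  tr <- dup$tree
  tr$edge.length <- conv * tr$edge.length / dup$theta
  tr
}

# Pruned subtree (coalescent units) for one retention configuration.
subtree_geometry <- function(dup, retention, conv = conv_default()) {
  tr <- dup_coalescent_tree(dup, conv)
  keep <- paste0(names(retention), "_", retention)
  sub <- prune_tips(tr, keep)
  sub$tip.label <- sub("_[12]$", "", sub$tip.label)
  sub
}

#' Gene-tree topology distribution under coalescence plus gene loss
#'
#' The mixture distribution of rooted single-copy gene-tree topologies
#' on the four post-WGD species: the subtree distribution
#' `P(T_i | S, lambda)` weights the exact coalescent distribution
#' `P(G | T_i, theta)` of each pruned subtree, whose internal branch
#' lengths (in coalescent units) follow from the pruning geometry of the
#' duplicated tree — the subtree `T2` retains the duplication-depth
#' segment as extra internal length.
#'
#' @param model A `species_tree_model` with 4 post-WGD species.
#' @param loss A [loss_spec()].
#' @param conv Unit-conversion constant.
#' @return Named numeric vector over the 15 rooted 4-taxon topologies,
#'   summing to 1, with attribute `"subtree_prob"`.
#' @examples
#' m <- fixture_species_tree("S1")
#' d <- gene_tree_distribution(m, loss_spec(p = rep(0.5, 4)))
#' sum(d)
#' @export
gene_tree_distribution <- function(model, loss, conv = conv_default()) {
  stopifnot(inherits(model, "species_tree_model"))
  dup <- build_duplicated_tree(model)
  sd <- subtree_distribution(model, loss)
  reps <- attr(enumerate_subtrees(model), "representative_retention")
  labels <- sort(model$post_wgd)
  keys <- vapply(all_rooted_topologies(labels), topology_key, "")
  mix <- stats::setNames(numeric(length(keys)), keys)
  for (i in 1:8) {
    if (sd$prob[i] <= 0) next
    geom <- subtree_geometry(dup, reps[[i]], conv)
    p <- coalescent_topology_prob(geom)
    mix[names(p)] <- mix[names(p)] + sd$prob[i] * p
  }
  attr(mix, "subtree_prob") <- sd$prob
  mix
}
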