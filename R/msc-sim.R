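# Multispecies-coalescent simulation of gene trees on a species tree
# model. One lineage is sampled per tip of the (possibly duplicated)
# tree; within the branch above node v, k co-occurring lineages coalesce
# pairwise at rate conv / theta_v per mutation-time unit, and all
# surviving lineages coalesce in the unbounded root population. Times
# (and therefore gene-tree branch lengths) are in mutation units.

# Unit-conversion constant: pairwise coalescence rate = conv / theta per
# mutation unit, i.e. a branch of x mutation units spans conv * x / theta
# coalescent units. conv = 2 reproduces the standard diploid
# interpretation of theta = 4*mu*Ne (expected pairwise coalescence time
# theta/2), and is the package default after calibration against the
# published gene-tree concordance frequencies; see the methods vignette.
#' @export
conv_default <- function() getOption("pseudoortho.conv", 2)

# Compact simulation structure derived from a species_tree_model.
build_poptree <- function(model, conv = conv_default()) {
  tree <- model$tree
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  elen <- numeric(n); elen[tree$edge[, 2L]] <- tree$edge.length
  theta <- rep(model$root_theta, n)
  theta[tree$edge[, 2L]] <- model$theta
  list(ntip = ntip, n = n, root = root_node(tree),
       kids = child_list(tree), elen = elen,
       rate = conv / theta, root_rate = conv / model$root_theta,
       heights = node_heights(tree), labels = tree$tip.label)
}

# Simulate one coalescent gene tree; returns merge records.
# merges: (ntip-1) x 3 matrix of (child id a, child id b, height);
# lineage ids are 1..ntip for tips, then ntip+1, ... in merge order.
# masks: tip-bit unions per merge (bit i = tip i), used for fast
# topology tests.
sim_coal_merges <- function(pt) {
  ntip <- pt$ntip
  merges <- matrix(0, ntip - 1L, 3L)
  masks <- numeric(2L * ntip - 1L)
  masks[seq_len(ntip)] <- 2^(seq_len(ntip) - 1)
  nid <- ntip
  nmerge <- 0L

  coalesce <- function(lin, t0, tmax, rate) {
    # lin: integer ids entering a population at height t0 that persists
    # until tmax (Inf at the root); returns surviving ids
    k <- length(lin)
    t <- t0
    while (k >= 2L) {
      t <- t + stats::rexp(1L, k * (k - 1L) / 2 * rate)
      if (t > tmax) break
      ij <- sample.int(k, 2L)
      nid <<- nid + 1L
      nmerge <<- nmerge + 1L
      merges[nmerge, ] <<- c(lin[ij[1L]], lin[ij[2L]], t)
      masks[nid] <<- masks[lin[ij[1L]]] + masks[lin[ij[2L]]]
      lin <- c(lin[-ij], nid)
      k <- k - 1L
    }
    lin
  }

  walk <- function(v) {
    lin <- if (v <= ntip) v else unlist(lapply(pt$kids[[v]], walk))
    if (v == pt$root) return(lin)
    coalesce(lin, pt$heights[v], pt$heights[v] + pt$elen[v], pt$rate[v])
  }
  lin <- walk(pt$root)
  root_h <- pt$heights[pt$root]
  coalesce(lin, root_h, Inf, pt$root_rate)
  list(merges = merges, masks = masks, ntip = ntip, labels = pt$labels)
}

# Convert merge records to a rooted, ultrametric phylo object.
merges_to_phylo <- function(sim) {
  ntip <- sim$ntip
  nmerge <- ntip - 1L
  # merge j (id ntip+j) -> phylo internal node ntip + (nmerge - j + 1),
  # so the last merge (the root) becomes ntip+1 as ape requires
  ph_id <- function(id) ifelse(id <= ntip, id, ntip + (nmerge - (id - ntip) + 1L))
  heights <- c(numeric(ntip), sim$merges[, 3L])
  edge <- matrix(0L, 2L * nmerge, 2L)
  elen <- numeric(2L * nmerge)
  r <- 0L
  for (j in seq_len(nmerge)) {
    p <- ntip + j
    for (ch in sim$merges[j, 1:2]) {
      r <- r + 1L
      edge[r, ] <- c(ph_id(p), ph_id(ch))
      elen[r] <- heights[p] - heights[ch]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = sim$labels, Nnode = nmerge),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Simulate a coalescent gene tree under the MSC
#'
#' Samples one allele per tip of the model's tree (for a duplicated tree,
#' two alleles per post-WGD species plus one outgroup allele) and runs
#' the multispecies coalescent: within each branch, lineage pairs
#' coalesce at rate `conv / theta` per mutation-time unit, and all
#' remaining lineages coalesce in the root population. The returned gene
#' tree is rooted, binary, ultrametric, and at least as tall as the
#' species tree.
#'
#' @param model A `species_tree_model` (typically from
#'   [build_duplicated_tree()]).
#' @param seed Optional integer seed for reproducibility.
#' @param conv Unit-conversion constant (see [conv_default()]).
#' @return A `phylo` gene tree with branch lengths in mutation units.
#' @examples
#' dup <- build_duplicated_tree(fixture_species_tree("S1"))
#' g <- simulate_gene_tree(dup, seed = 1)
#' sort(g$tip.label)
#' @export
simulate_gene_tree <- function(model, seed = NULL, conv = conv_default()) {
  stopifnot(inherits(model, "species_tree_model"))
  if (!is.null(seed)) set.seed(seed)
  pt <- build_poptree(model, conv)
  merges_to_phylo(sim_coal_merges(pt))
}

# Clade masks (tip-bit order of dup$tree$tip.label) that the E-rooted
# gene tree must contain for each copy-subclade to replicate the rooted
# ingroup species-tree topology.
required_clade_masks <- function(dup) {
  sp <- dup$species_model
  if (is.null(sp)) stop("model does not record its originating species tree")
  ing <- prune_tips(sp$tree, sp$post_wgd)
  labels <- dup$tree$tip.label
  lapply(1:2, function(copy) {
    bits <- 2^(match(paste0(ing$tip.label, "_", copy), labels) - 1)
    ntip <- length(ing$tip.label)
    masks <- numeric(ntip + ing$Nnode)
    masks[seq_len(ntip)] <- bits
    for (e in ape::postorder(ing)) {
      p <- ing$edge[e, 1L]; ch <- ing$edge[e, 2L]
      masks[p] <- masks[p] + masks[ch]
    }
    masks[-seq_len(ntip)]  # internal clades incl. the subclade root
  })
}

# Does the simulated gene tree, rooted with the outgroup, contain clade X
# for every required mask? X is a clade of the outgroup-rooted tree iff
# the unrooted split {X, rest} exists, i.e. some merge mask equals X or
# equals full - X (the side holding the outgroup).
matches_required <- function(merge_masks, req, full) {
  all(req %in% merge_masks | (full - req) %in% merge_masks)
}

#' Frequency of gene trees matching the species tree
#'
#' Monte-Carlo estimate of the probability that a gene tree simulated on
#' the duplicated tree of `model` matches the species-tree topology when
#' rooted with the outgroup. Under the default `"both"` criterion a gene
#' tree matches when each copy-subclade is monophyletic and, after
#' mapping tips back to species, replicates the rooted ingroup
#' species-tree topology; `"either"` requires this of at least one
#' subclade.
#'
#' @param model A 5-taxon `species_tree_model` fixture (or any model with
#'   a root-adjacent WGD).
#' @param n Number of simulated gene trees.
#' @param match_criterion `"both"` (default) or `"either"`.
#' @param seed Optional integer seed.
#' @param conv Unit-conversion constant.
#' @return A list with elements `proportion`, `se` (binomial standard
#'   error), and `n`.
#' @examples
#' topology_frequency(fixture_species_tree("S1"), n = 200, seed = 1)$proportion
#' @export
topology_frequency <- function(model, n, match_criterion = c("both", "either"),
                               seed = NULL, conv = conv_default()) {
  stopifnot(inherits(model, "species_tree_model"), n >= 1)
  match_criterion <- match.arg(match_criterion)
  if (!is.null(seed)) set.seed(seed)
  dup <- if (is.null(model$species_model)) build_duplicated_tree(model) else model
  pt <- build_poptree(dup, conv)
  req <- required_clade_masks(dup)
  full <- sum(2^(seq_len(pt$ntip) - 1))
  hits <- 0L
  for (i in seq_len(n)) {
    sim <- sim_coal_merges(pt)
    mm <- sim$masks[-seq_len(pt$ntip)]
    ok1 <- matches_required(mm, req[[1L]], full)
    ok2 <- if (match_criterion == "both" || !ok1)
      matches_required(mm, req[[2L]], full) else TRUE
    hit <- if (match_criterion == "both") ok1 && ok2 else ok1 || ok2
    if (hit) hits <- hits + 1L
  }
  p <- hits / n
  list(proportion = p, se = sqrt(p * (1 - p) / n), n = n)
}
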