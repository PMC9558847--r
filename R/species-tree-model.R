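# Species tree model: a rooted ultrametric tree in mutation units with
# per-branch population size parameters (theta = 4 * mu * Ne) and an
# annotated whole-genome duplication (WGD) branch. The four simulation
# fixtures and the construction of the duplicated (two copies per
# post-WGD species) tree live here.

#' Construct a species tree model
#'
#' @param tree Rooted, ultrametric `phylo` with branch lengths in
#'   mutation units (expected substitutions per site).
#' @param theta Population size parameter `4*mu*Ne` per edge, in the
#'   order of `tree$edge` rows, or a single value recycled to all edges.
#' @param wgd_mrca Character vector of tip labels; the WGD is placed on
#'   the branch subtending their most recent common ancestor.
#' @param outgroup Tip label used for rooting gene trees; must not be
#'   among the post-WGD species.
#' @param root_theta Theta of the (infinitely long) root population;
#'   defaults to the maximum edge theta.
#' @return An object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree, theta, wgd_mrca, outgroup,
                               root_theta = max(theta)) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  nE <- nrow(tree$edge)
  theta <- rep_len(theta, nE)
  if (any(theta <= 0) || root_theta <= 0) stop("theta must be positive")
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  if (diff(range(depths[seq_len(ntip)])) > 1e-9)
    stop("species tree must be ultrametric (tolerance 1e-9)")
  if (!outgroup %in% tree$tip.label) stop("outgroup not found among tips")
  if (!all(wgd_mrca %in% tree$tip.label)) stop("wgd_mrca tips not in tree")
  if (length(wgd_mrca) < 2L)
    stop("WGD on a terminal branch has no duplication structure to evaluate")
  mrca <- ape::getMRCA(tree, wgd_mrca)
  wgd_edge <- which(tree$edge[, 2L] == mrca)
  if (length(wgd_edge) != 1L)
    stop("WGD clade spans the root; place it on a proper branch")
  post <- ape::extract.clade(tree, mrca)$tip.label
  if (outgroup %in% post) stop("outgroup must not descend from the WGD branch")
  structure(list(tree = tree, theta = theta, root_theta = root_theta,
                 wgd_edge = wgd_edge, wgd_node = mrca,
                 post_wgd = sort(post), outgroup = outgroup),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Species tree model (", length(x$tree$tip.label), " tips)\n", sep = "")
  cat("  topology : ", write_newick(drop_lengths(x$tree)), "\n", sep = "")
  cat("  height   : ", format(tree_height(x)), " mutation units\n", sep = "")
  cat("  theta    : ", paste(format(sort(unique(x$theta))), collapse = ", "),
      " (root ", format(x$root_theta), ")\n", sep = "")
  cat("  WGD      : branch above {",
      paste(x$post_wgd, collapse = ","), "}\n", sep = "")
  cat("  outgroup : ", x$outgroup, "\n", sep = "")
  invisible(x)
}

drop_lengths <- function(tree) {
  tree$edge.length <- NULL
  tree
}

tree_height <- function(model) {
  max(ape::node.depth.edgelength(model$tree))
}

# Node heights above the tips (ultrametric), indexed by phylo node id.
node_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' Simulation fixtures S1-S4
#'
#' Four 5-taxon species trees (ingroup A-D, outgroup E) used throughout
#' the simulation study. All have height 0.06 mutation units and a WGD on
#' the branch ancestral to A-D. The pectinate trees S1/S3 are
#' `((((A,B),C),D),E)` with post-WGD internal branches of 0.015; the
#' symmetric trees S2/S4 are `(((A,B),(C,D)),E)` with internal branches
#' of 0.02. Theta on the post-WGD internal branches is 0.015 (S1), 0.02
#' (S2), 0.15 (S3), and 0.2 (S4), i.e. internal branches of 1 coalescent
#' unit (low ILS, S1/S2) or 0.1 coalescent units (high ILS, S3/S4) under
#' the convention that coalescent length = mutation length / theta.
#' The WGD branch (the stem of the ingroup) carries theta = stem
#' length / 10 (0.0015 for S1/S3, 0.002 for S2/S4), making the stem 10
#' coalescent units long, which keeps the two paralog subclades
#' monophyletic in essentially every gene tree; the root population and
#' the terminal branches (which never hold more than one lineage) carry
#' the same theta as the internal branches, so the outgroup lineage
#' joins the ingroup after a theta-scaled, typically long, waiting time.
#' Under these settings the simulator reproduces the reference gene-tree
#' concordance frequencies (about 68% for S1/S2, 2.5% for S3, and 4.3%
#' for S4) and the qualitative method behavior (notably the
#' concatenated-parsimony plateau at normalized RF 0.5 on S4); see the
#' methods vignette for the calibration.
#'
#' @param name One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return A `species_tree_model`.
#' @examples
#' fixture_species_tree("S1")
#' @export
fixture_species_tree <- function(name = c("S1", "S2", "S3", "S4")) {
  name <- match.arg(name)
  pect <- paste0("((((A:0.015,B:0.015):0.015,C:0.03):0.015,",
                 "D:0.045):0.015,E:0.06);")
  symm <- paste0("(((A:0.02,B:0.02):0.02,(C:0.02,D:0.02):0.02):0.02,",
                 "E:0.06);")
  nwk <- switch(name, S1 = pect, S3 = pect, S2 = symm, S4 = symm)
  th <- switch(name, S1 = 0.015, S2 = 0.02, S3 = 0.15, S4 = 0.2)
  m <- species_tree_model(parse_newick(nwk), theta = th,
                          wgd_mrca = c("A", "B", "C", "D"), outgroup = "E",
                          root_theta = th)
  stem_len <- m$tree$edge.length[m$wgd_edge]
  m$theta[m$wgd_edge] <- stem_len / 10
  m$root_theta <- th
  m
}

#' Build the duplicated species tree implied by the WGD
#'
#' Every species descending from the WGD branch is represented twice,
#' once per paralog copy (tips `X_1` and `X_2`); the two copy-subtrees
#' are topologically identical to the post-WGD part of the species tree
#' and diverge at the WGD point, which is placed at the rootward end of
#' the WGD branch (a WGD in the ancestral population at the moment it
#' splits from the rest of the tree). Each copy-subtree therefore carries
#' the full length of the WGD branch as its stem. Theta values are
#' inherited branchwise.
#'
#' @param model A `species_tree_model` whose WGD branch is a child of the
#'   root (the configuration of all fixtures).
#' @return A `species_tree_model` over the duplicated tip set, with the
#'   WGD recorded on the zero-length branch above the copy divergence.
#' @examples
#' dup <- build_duplicated_tree(fixture_species_tree("S1"))
#' sort(dup$tree$tip.label)
#' @export
build_duplicated_tree <- function(model) {
  stopifnot(inherits(model, "species_tree_model"))
  tree <- model$tree
  ntip <- length(tree$tip.label)
  kids <- child_list(tree)
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  eth <- numeric(ntip + tree$Nnode)
  eth[tree$edge[, 2L]] <- model$theta
  wgd_child <- model$wgd_node

  serialize <- function(node, copy = NULL) {
    # returns newick fragment without branch length suffix
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      if (!is.null(copy)) lab <- paste0(lab, "_", copy)
      return(lab)
    }
    parts <- vapply(kids[[node]], function(ch) {
      if (is.null(copy) && ch == wgd_child) {
        s1 <- serialize(ch, copy = 1L)
        s2 <- serialize(ch, copy = 2L)
        stem <- format(elen[ch], digits = 12)
        paste0("(", s1, ":", stem, ",", s2, ":", stem, "):0")
      } else {
        paste0(serialize(ch, copy), ":", format(elen[ch], digits = 12))
      }
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  dup <- parse_newick(paste0(serialize(root_node(tree)), ";"))

  # per-edge theta: map each duplicated edge to the species edge with the
  # same species-level clade; the two stem copies and the zero-length WGD
  # edge all map to the WGD branch.
  sp_labels <- sort(tree$tip.label)
  sp_masks <- node_masks(tree, sp_labels)
  sp_theta <- numeric(length(sp_masks))
  sp_theta[tree$edge[, 2L]] <- model$theta
  dup_species <- sub("_[12]$", "", dup$tip.label)
  dm <- node_masks_species(dup, dup_species, sp_labels)
  theta_dup <- vapply(seq_len(nrow(dup$edge)), function(i) {
    child <- dup$edge[i, 2L]
    hit <- which(sp_masks == dm[child])
    hit <- hit[hit != root_node(tree)]
    if (length(hit) == 0L) stop("internal error: unmapped duplicated edge")
    if (length(hit) > 1L) hit <- hit[1L]
    sp_theta[hit]
  }, 0)

  m <- species_tree_model(dup, theta = theta_dup,
                          wgd_mrca = dup$tip.label[grepl("_[12]$", dup$tip.label)],
                          outgroup = model$outgroup,
                          root_theta = model$root_theta)
  m$wgd_height <- node_heights(tree)[model$wgd_node] + elen[model$wgd_node]
  m$species_model <- model
  m
}

# Clade masks of `tree` computed at the species level: tips are first
# mapped to species names, then to bits in `sp_labels` order; both copies
# of a species share a bit.
node_masks_species <- function(tree, tip_species, sp_labels) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  bit <- 2^(match(tip_species, sp_labels) - 1)
  masks <- numeric(n)
  masks[seq_len(ntip)] <- bit
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    # bitwise-or on species bits: a parent may see the same species bit
    # from both copy subtrees
    masks[p] <- bitw_or_num(masks[p], masks[ch])
  }
  masks
}

# bitwise OR for small nonnegative doubles (< 2^53)
bitw_or_num <- function(a, b) {
  r <- 0; p <- 1
  while (a > 0 || b > 0) {
    da <- a %% 2; db <- b %% 2
    if (da + db > 0) r <- r + p
    a <- a %/% 2; b <- b %/% 2; p <- p * 2
  }
  r
}
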