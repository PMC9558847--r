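# Tree container, Newick I/O, bipartitions and the normalized
# Robinson-Foulds distance. Trees are ape "phylo" objects throughout;
# this file adds the validation, canonicalization and metric conventions
# used by the rest of the package.

#' Parse a Newick string into a phylogenetic tree
#'
#' Wraps [ape::read.tree()] with stricter validation: unbalanced
#' parentheses are reported with the character offset of the first
#' imbalance, and duplicate tip labels are an error (every downstream
#' operation assumes unique tips).
#'
#' @param text A single Newick string, terminated by `;`.
#' @return An object of class `phylo`. The tree is rooted if the Newick
#'   string has a bifurcating outermost clause, unrooted-style
#'   (trifurcating root) otherwise; `ape` conventions apply.
#' @examples
#' tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing terminating ';'")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: could not be parsed")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label))) stop("empty tip label")
  tr
}

#' Write a tree as canonical Newick
#'
#' Children are rotated so that the lexicographically smallest descendant
#' tip comes first, which makes output reproducible regardless of the
#' internal edge ordering. Branch lengths are written with 10 significant
#' digits.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- child_list(tree)
  has_len <- !is.null(tree$edge.length)
  elen <- numeric(ntip + tree$Nnode)
  if (has_len) elen[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      str <- lab
    } else {
      parts <- lapply(kids[[node]], rec)
      key <- vapply(parts, function(p) p$min, "")
      parts <- parts[order(key)]
      str <- paste0("(", paste(vapply(parts, function(p) p$str, ""),
                               collapse = ","), ")")
      lab <- min(key)
    }
    if (has_len && node != root_node(tree))
      str <- paste0(str, ":", format(elen[node], digits = 10))
    list(str = str, min = lab)
  }
  paste0(rec(root_node(tree))$str, ";")
}

root_node <- function(tree) {
  ntip <- length(tree$tip.label)
  setdiff(seq_len(ntip + tree$Nnode), tree$edge[, 2L])[1L]
}

child_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

# Bitmask of descendant tips for every node, relative to `labels`
# (a character vector defining bit order). Returns a numeric vector of
# masks indexed by node number; tips get their own bit. Masks are stored
# as doubles (exact up to 2^53, far beyond any tree handled here).
node_masks <- function(tree, labels = tree$tip.label) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  bit <- 2^(match(tree$tip.label, labels) - 1)
  if (anyNA(bit)) stop("tree tips not contained in label set")
  masks <- numeric(n)
  masks[seq_len(ntip)] <- bit
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    masks[p] <- masks[p] + masks[ch]
  }
  masks
}

# Nontrivial splits of the unrooted form of `tree`, canonicalized as the
# side that does NOT contain the first label. Returns a numeric vector of
# masks (possibly empty).
tree_splits <- function(tree, labels = sort(tree$tip.label)) {
  ntip <- length(tree$tip.label)
  full <- sum(2^(seq_len(ntip) - 1))
  masks <- node_masks(tree, labels)
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  s <- masks[internal]
  # canonicalize: side without bit 1 (the first label)
  s <- ifelse(s %% 2 == 1, full - s, s)
  sizes <- vapply(s, function(m) popcount(m), 0)
  unique(s[sizes >= 2 & sizes <= ntip - 2])
}

popcount <- function(m) {
  n <- 0
  while (m > 0) {
    n <- n + m %% 2
    m <- m %/% 2
  }
  n
}

#' Robinson-Foulds distance between two trees
#'
#' Computes the symmetric-difference (Robinson-Foulds) metric over the
#' nontrivial bipartitions of the unrooted forms of the two trees.
#' The normalized variant divides by `2 * (n - 3)`, the maximum value for
#' two fully resolved unrooted trees on `n` tips; the same denominator is
#' used when either input contains polytomies, so a star-like consensus
#' compared with any binary tree gives `(n - 3) / (2 * (n - 3)) = 0.5`.
#' Rootedness of the inputs is ignored: distances are always computed on
#' the unrooted forms.
#'
#' @param t1,t2 `phylo` objects with identical tip label sets (n >= 4).
#' @param normalized If `TRUE` (default) divide by `2 * (n - 3)`.
#' @return A single nonnegative number.
#' @examples
#' a <- parse_newick("((((A,B),C),D),E);")
#' b <- parse_newick("(((A,B),(C,D)),E);")
#' rf_distance(a, b)            # 0.5
#' rf_distance(a, b, normalized = FALSE)  # 2
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d1 <- setdiff(l1, l2); d2 <- setdiff(l2, l1)
    stop("tip label sets differ; only in t1: {",
         paste(d1, collapse = ","), "}, only in t2: {",
         paste(d2, collapse = ","), "}")
  }
  n <- length(l1)
  if (n < 4L) stop("RF distance requires at least 4 tips")
  s1 <- tree_splits(t1, l1)
  s2 <- tree_splits(t2, l1)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) rf / (2 * (n - 3)) else rf
}

#' Root a tree with an outgroup
#'
#' Places the root on the pendant edge of `outgroup`, so that the
#' outgroup is a direct child of the root. Already-correctly-rooted trees
#' are returned unchanged (idempotent).
#'
#' @param tree A `phylo` object.
#' @param outgroup A tip label present in the tree.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("outgroup label '", outgroup, "' not found among tips")
  if (ape::is.rooted(tree)) {
    rk <- child_list(tree)[[root_node(tree)]]
    og <- match(outgroup, tree$tip.label)
    if (og %in% rk) return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Prune a tree to a set of tips
#'
#' Returns the subtree induced by `keep`: all other tips are removed,
#' degree-2 nodes are suppressed, and branch lengths are summed across
#' suppressed nodes, so path lengths among kept tips are conserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `phylo` object on the tips in `keep`.
#' @export
prune_tips <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(keep %in% tree$tip.label))
    stop("keep is not a subset of tip labels: missing ",
         paste(setdiff(keep, tree$tip.label), collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}
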