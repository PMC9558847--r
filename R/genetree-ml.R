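# Exact small-scale gene tree estimation: JC69 pruning likelihood
# (compiled), exhaustive topology search with per-topology branch-length
# optimization, outgroup rooting, and neighbor joining.

# Site-pattern compression: returns list(states = npat x ntaxa integer
# matrix (0..3, -1 for non-ACGT), weights, taxa).
compress_patterns <- function(a, taxa = sort(rownames(a))) {
  check_alignment(a)
  a <- a[taxa, , drop = FALSE]
  code <- matrix(match(a, DNA_STATES, nomatch = 0L) , nrow(a), ncol(a))
  key <- as.vector(crossprod(code, 5L^(seq_len(nrow(a)) - 1L)))
  tab <- table(key)
  uniq <- as.numeric(names(tab))
  npat <- length(uniq)
  states <- matrix(0L, npat, nrow(a))
  rem <- uniq
  for (j in seq_len(nrow(a))) {
    states[, j] <- as.integer(rem %% 5L) - 1L
    rem <- rem %/% 5L
  }
  list(states = states, weights = as.numeric(tab), taxa = taxa)
}

#' JC69 log-likelihood of a tree given an alignment
#'
#' Felsenstein pruning with uniform root frequencies and site-pattern
#' compression, under the JC69 substitution model. Non-ACGT characters
#' are treated as missing data.
#'
#' @param tree `phylo` (rooted or unrooted) with branch lengths in
#'   expected substitutions per site.
#' @param a Character matrix alignment whose rownames equal the tree's
#'   tip labels.
#' @return Log-likelihood (natural log).
#' @export
jc69_loglik <- function(tree, a) {
  stopifnot(inherits(tree, "phylo"))
  check_alignment(a)
  if (!setequal(rownames(a), tree$tip.label))
    stop("alignment taxa and tree tips differ")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and nonnegative")
  if (ncol(a) == 0L) stop("alignment has no sites")
  cp <- compress_patterns(a, taxa = tree$tip.label)
  jc69_loglik_cpp(tree$edge, tree$edge.length, cp$states, cp$weights)
}

# Cache of unrooted binary topologies per sorted label set.
topology_cache <- new.env(parent = emptyenv())

all_unrooted_topologies <- function(labels) {
  labels <- sort(labels)
  key <- paste(labels, collapse = "\r")
  if (is.null(topology_cache[[key]])) {
    trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                                tip.label = labels)
    # [[ indexing restores the tip labels multiPhylo stores only once
    topology_cache[[key]] <- lapply(seq_along(trees), function(i) trees[[i]])
  }
  topology_cache[[key]]
}

# Fit one topology: optimized branch lengths + loglik.
fit_topology <- function(topo, cp, tol = 1e-6, init = 0.05) {
  ne <- nrow(topo$edge)
  fit <- jc69_optimize_cpp(topo$edge, rep(init, ne), cp$states, cp$weights,
                           tol = tol)
  topo$edge.length <- fit$lengths
  list(tree = topo, loglik = fit$loglik)
}

#' Maximum-likelihood gene tree by exhaustive search
#'
#' Evaluates every unrooted binary topology on the alignment's taxa (15
#' for five taxa), optimizing branch lengths per topology under JC69 by
#' coordinate-wise search (bounds `[1e-9, 10]`, convergence when the
#' log-likelihood improves by less than `1e-6` between sweeps), and
#' returns the best topology rooted with the outgroup. Exact at the
#' 4-6 taxon scale; larger problems are refused.
#'
#' @param a Character matrix alignment (4-6 taxa).
#' @param outgroup Tip used to root the returned tree.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return Rooted `phylo` with attributes `"loglik"` and `"tie"` (TRUE
#'   if another topology ties within `tol`).
#' @examples
#' tr <- parse_newick("(((A:0.05,B:0.05):0.05,C:0.1):0.05,E:0.15);")
#' a <- simulate_jc69(tr, 2000, seed = 1)
#' ml <- ml_gene_tree(a, "E")
#' @export
ml_gene_tree <- function(a, outgroup, tol = 1e-6) {
  check_alignment(a)
  n <- nrow(a)
  if (n < 4L || n > 6L)
    stop("exhaustive search supports 4-6 taxa (got ", n, "); a heuristic ",
         "search would be required beyond that")
  if (ncol(a) == 0L) stop("alignment has no sites")
  if (!outgroup %in% rownames(a)) stop("outgroup not among taxa")
  cp <- compress_patterns(a)
  topos <- all_unrooted_topologies(rownames(a))
  best <- NULL; best_ll <- -Inf; tie <- FALSE
  for (topo in topos) {
    f <- fit_topology(topo, cp, tol)
    if (f$loglik > best_ll + tol) {
      best <- f; best_ll <- f$loglik; tie <- FALSE
    } else if (f$loglik > best_ll - tol) {
      tie <- TRUE  # canonical order keeps the earlier topology
    }
  }
  out <- root_with_outgroup(best$tree, outgroup)
  attr(out, "loglik") <- best_ll
  attr(out, "tie") <- tie
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin validated wrapper around [ape::nj()], used as the final
#' agglomeration step of the STAR method.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names.
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) stop("distance matrix must carry taxon names")
  ape::nj(d)
}
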