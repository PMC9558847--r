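# The distribution P(T_i | S, lambda) of the eight pruned paralog
# subtrees given a 4-ingroup-taxon species tree and a loss
# specification, together with the subtree geometries (branch lengths in
# coalescent units) needed by the gene-tree mixture distribution.

#' Loss specification
#'
#' Exactly one mode is active: a named procedural `pattern` (1-14),
#' per-branch loss intensities `tau` (tau_i = lambda_i * t_i for the
#' seven branches of the 4-taxon species tree; `Inf` means loss is
#' certain), or per-species retention-flip probabilities `p` (p_x = the
#' probability that species x loses its copy in the first subclade).
#'
#' Branch numbering for `tau`: 1 is the WGD (root/stem) branch; 2 and 3
#' are the internal branches in decreasing height order (for the
#' pectinate tree, 2 is the branch above the ABC ancestor and 3 the
#' branch above the AB ancestor; for the symmetric tree, 2 is above AB
#' and 3 above CD); 4-7 are the terminal branches of A, B, C, D.
#'
#' @param pattern Integer 1-14, or `NULL`.
#' @param tau Numeric vector of 7 nonnegative intensities, or `NULL`.
#' @param p Numeric vector of 4 probabilities (named or in A-D order), or
#'   `NULL`.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(pattern = NULL, tau = NULL, p = NULL) {
  modes <- c(!is.null(pattern), !is.null(tau), !is.null(p))
  if (sum(modes) != 1L)
    stop("exactly one of pattern, tau, p must be given")
  if (!is.null(pattern)) {
    check_pattern(pattern)
    spec <- list(mode = "pattern", pattern = as.integer(pattern))
  } else if (!is.null(tau)) {
    stopifnot(length(tau) == 7L)
    if (any(tau < 0)) stop("loss intensities must be nonnegative")
    spec <- list(mode = "branch_rates", tau = as.numeric(tau))
  } else {
    stopifnot(length(p) == 4L)
    if (any(p < 0 | p > 1)) stop("retention-flip probabilities must be in [0,1]")
    spec <- list(mode = "terminal_probs", p = as.numeric(p))
  }
  structure(spec, class = "loss_spec")
}

# Shape of a 4-ingroup model: "pectinate" or "symmetric", with species
# mapped to roles A-D. For the pectinate shape ((A,B),C),D), roles follow
# the nesting; for the symmetric shape, (A,B) and (C,D) are the cherries.
ingroup_shape <- function(model) {
  ing <- prune_tips(model$tree, model$post_wgd)
  if (length(ing$tip.label) != 4L)
    stop("the subtree model is derived for 4 post-WGD species, found ",
         length(ing$tip.label))
  key <- write_newick(drop_lengths(ing))
  labs <- sort(ing$tip.label)
  masks <- node_masks(ing, labs)
  ntip <- 4L
  sizes <- vapply(masks, popcount, 0)
  two <- masks[-seq_len(ntip)][sizes[-seq_len(ntip)] == 2]
  three <- masks[-seq_len(ntip)][sizes[-seq_len(ntip)] == 3]
  bit_labels <- function(m) labs[bitwAnd(rep(as.integer(m), 4L),
                                         as.integer(2^(0:3))) > 0]
  if (length(three) == 1L) {        # pectinate (((A,B),C),D)
    ab <- bit_labels(two)
    c_sp <- setdiff(bit_labels(three), ab)
    d_sp <- setdiff(labs, bit_labels(three))
    list(shape = "pectinate", roles = c(ab, c_sp, d_sp), tree = ing)
  } else {                          # symmetric ((A,B),(C,D))
    ab <- bit_labels(min(two))      # deterministic role assignment
    cd <- setdiff(labs, ab)
    list(shape = "symmetric", roles = c(ab, cd), tree = ing)
  }
}

#' Enumerate the eight candidate pruned subtrees
#'
#' Lists, in a fixed order, the eight 4-taxon subtrees that single-copy
#' retention can produce on a 4-ingroup species tree. For the pectinate
#' shape `(((A,B),C),D)` the order is `T1 = (((A,B),C),D)` (whole-subclade
#' retention), `T2` = the same topology with longer internal branches
#' (the odd copy is D's), `T3 = (((A,B),D),C)`, `T4 = (((A,C),D),B)`,
#' `T5 = (((B,C),D),A)`, `T6 = ((A,B),(C,D))`, `T7 = ((A,C),(B,D))`,
#' `T8 = ((A,D),(B,C))`. For the symmetric shape `((A,B),(C,D))`:
#' `T1` (pure), `T2` = same topology via reciprocal cherry retention,
#' then `(((A,B),C),D)`, `(((A,B),D),C)`, `(((C,D),A),B)`, `(((C,D),B),A)`,
#' `((A,C),(B,D))`, `((A,D),(B,C))`.
#'
#' @param model A `species_tree_model` with 4 post-WGD species.
#' @return A list of 8 `phylo` topologies (no branch lengths), named
#'   `T1`-`T8`, with attribute `"representative_retention"`: for each
#'   subtree one retention vector producing it.
#' @export
enumerate_subtrees <- function(model) {
  sh <- ingroup_shape(model)
  reps <- subtree_representatives(sh$shape)
  roles <- sh$roles
  trees <- lapply(reps, function(ret) {
    names(ret) <- roles
    subtree_topology(sh, ret)
  })
  names(trees) <- paste0("T", 1:8)
  attr(trees, "representative_retention") <-
    lapply(reps, function(r) stats::setNames(r, roles))
  trees
}

# One representative retention vector (roles A-D) per subtree class.
subtree_representatives <- function(shape) {
  if (shape == "pectinate")
    list(c(1,1,1,1), c(1,1,1,2), c(1,1,2,1), c(1,2,1,1),
         c(2,1,1,1), c(1,1,2,2), c(1,2,1,2), c(1,2,2,1))
  else
    list(c(1,1,1,1), c(1,1,2,2), c(1,1,1,2), c(1,1,2,1),
         c(1,2,1,1), c(2,1,1,1), c(1,2,1,2), c(1,2,2,1))
}

# Map a retention vector (named by species) to its subtree index 1..8.
classify_retention <- function(shape, roles, ret) {
  r <- ret[roles] - 1L                # 0/1 per role A-D
  if (all(r == r[1L])) return(1L)
  ones <- sum(r)
  if (ones == 1L || ones == 3L) {
    odd <- if (ones == 1L) which(r == 1L) else which(r == 0L)
    if (shape == "pectinate") return(c(5L, 4L, 3L, 2L)[odd])
    return(c(6L, 5L, 4L, 3L)[odd])
  }
  # 2-2 split: identify the partition
  pair <- which(r == r[1L])           # roles sharing A's copy
  key <- paste(pair, collapse = "")
  if (shape == "pectinate")
    switch(key, "12" = 6L, "13" = 7L, "14" = 8L)
  else
    switch(key, "12" = 2L, "13" = 7L, "14" = 8L)
}

# Rooted topology of the pruned subtree for a retention vector, derived
# by actually pruning the duplicated tree (no branch lengths).
subtree_topology <- function(sh, ret) {
  # build from the ingroup topology directly: retained tips of one copy
  # follow the pruned species tree; the two groups join at the WGD point
  ing <- sh$tree
  g1 <- names(ret)[ret == 1L]
  g2 <- names(ret)[ret == 2L]
  part <- function(g) {
    if (length(g) == 1L) return(g)
    sub <- prune_tips(ing, g)
    sub(";", "", write_newick(drop_lengths(sub)), fixed = TRUE)
  }
  nwk <- if (length(g1) == 0L || length(g2) == 0L)
    paste0(part(c(g1, g2)), ";")
  else
    paste0("(", part(g1), ",", part(g2), ");")
  parse_newick(nwk)
}

#' Distribution of the pruned subtree given the loss specification
#'
#' Computes `P(T_i | S, lambda)` for the eight subtrees.
#'
#' In `terminal_probs` mode the 2^4 retention configurations are
#' enumerated exactly, each with probability `prod(p_x or 1 - p_x)`, and
#' aggregated by subtree class. In `branch_rates` mode every copy is
#' independently lost on branch i with probability `1 - exp(-tau_i)`
#' (`Inf` intensities mean certain loss); configurations are conditioned
#' on exactly one copy surviving per species. `pattern` mode uses the
#' pattern's procedural coin structure.
#'
#' @param model A `species_tree_model` with 4 post-WGD species.
#' @param loss A [loss_spec()].
#' @return Object of class `subtree_distribution`: list with `prob`
#'   (named numeric of length 8, summing to 1), `trees` (the topologies),
#'   `shape`, and `roles`.
#' @examples
#' m <- fixture_species_tree("S1")
#' subtree_distribution(m, loss_spec(p = c(.5, .5, .5, .5)))$prob
#' @export
subtree_distribution <- function(model, loss) {
  stopifnot(inherits(model, "species_tree_model"), inherits(loss, "loss_spec"))
  sh <- ingroup_shape(model)
  roles <- sh$roles
  prob <- numeric(8L)

  add_config <- function(ret, w) {
    if (w <= 0) return()
    idx <- classify_retention(sh$shape, roles, ret)
    prob[idx] <<- prob[idx] + w
  }

  if (loss$mode == "terminal_probs" || loss$mode == "pattern") {
    pcfg <- retention_config_probs(loss, roles)
    for (i in seq_len(nrow(pcfg$configs)))
      add_config(stats::setNames(pcfg$configs[i, ], roles), pcfg$w[i])
  } else {
    cfg <- branch_rates_configs(sh, loss$tau)
    if (nrow(cfg$configs) == 0L || sum(cfg$w) <= 0)
      stop("no retention configuration has positive probability after ",
           "conditioning on single-copy survival")
    for (i in seq_len(nrow(cfg$configs)))
      add_config(stats::setNames(cfg$configs[i, ], roles), cfg$w[i])
  }
  if (sum(prob) <= 0)
    stop("no retention configuration has positive probability after ",
         "conditioning on single-copy survival")
  prob <- prob / sum(prob)
  structure(list(prob = stats::setNames(prob, paste0("T", 1:8)),
                 trees = enumerate_subtrees(model),
                 shape = sh$shape, roles = roles),
            class = "subtree_distribution")
}

#' @export
print.subtree_distribution <- function(x, ...) {
  cat("Subtree distribution (", x$shape, " species tree)\n", sep = "")
  for (i in 1:8)
    cat(sprintf("  %-3s %-18s %.6g\n", names(x$prob)[i],
                write_newick(x$trees[[i]]), x$prob[i]))
  invisible(x)
}

# Probabilities of the 16 retention configurations. For terminal_probs,
# p_x is the probability the first-subclade copy is lost (copy 2
# retained). For a pattern, the shared coin correlates the tied species.
retention_config_probs <- function(loss, roles) {
  configs <- as.matrix(expand.grid(rep(list(1:2), 4L)))
  colnames(configs) <- NULL
  if (loss$mode == "terminal_probs") {
    p <- loss$p  # P(retain copy 2)
    w <- apply(configs, 1L, function(ret)
      prod(ifelse(ret == 2L, p, 1 - p)))
  } else {
    pat <- pattern_table()[[loss$pattern]]
    role_names <- c("A", "B", "C", "D")
    w <- apply(configs, 1L, function(ret) {
      names(ret) <- role_names
      total <- 0
      for (s in 1:2) {  # subclade removed by the coin
        ok <- all(ret[pat$sel] == 3L - s) && all(ret[pat$oth] == s)
        if (ok) total <- total + 0.5 * 0.5^length(pat$ind)
      }
      total
    })
  }
  list(configs = configs, w = w)
}

# branch_rates mode: enumerate loss indicators for each copy on each of
# the 7 branches; a copy survives for species x iff no loss occurred on
# any branch of x's root-to-tip path; condition on exactly one survivor
# per species. Branch order: 1 stem, 2-3 internal (decreasing height),
# 4-7 terminals A-D.
#
# Infinite intensities ("loss certain") are evaluated in the limit
# tau -> Inf: a no-loss event on such a branch carries a vanishing
# factor eps, so after conditioning only the configurations with the
# minimal number of eps factors retain mass; their finite-branch weights
# are normalized among themselves.
branch_rates_configs <- function(sh, tau) {
  inf <- !is.finite(tau)
  ploss <- 1 - exp(-tau)
  paths <- if (sh$shape == "pectinate")
    list(A = c(1L, 2L, 3L, 4L), B = c(1L, 2L, 3L, 5L),
         C = c(1L, 2L, 6L), D = c(1L, 7L))
  else
    list(A = c(1L, 2L, 4L), B = c(1L, 2L, 5L),
         C = c(1L, 3L, 6L), D = c(1L, 3L, 7L))
  grid <- as.matrix(expand.grid(rep(list(0:1), 14L)))
  pw <- rbind(1 - ploss, ploss)        # row 1: no loss, row 2: loss
  pw[1L, inf] <- 1                     # eps factor tracked separately
  cfgs <- vector("list", nrow(grid))
  ws <- numeric(nrow(grid))
  pows <- integer(nrow(grid))
  kept <- 0L
  for (i in seq_len(nrow(grid))) {
    ind <- grid[i, ]
    w <- prod(pw[cbind(ind + 1L, rep(1:7, 2L))])
    if (w == 0) next
    pow <- sum(ind[c(which(inf), which(inf) + 7L)] == 0L)
    ret <- integer(4L)
    ok <- TRUE
    for (sidx in 1:4) {
      path <- paths[[sidx]]
      s1 <- all(ind[path] == 0L)        # copy 1 survives
      s2 <- all(ind[path + 7L] == 0L)   # copy 2 survives
      if (s1 == s2) { ok <- FALSE; break }
      ret[sidx] <- if (s1) 1L else 2L
    }
    if (!ok) next
    kept <- kept + 1L
    cfgs[[kept]] <- ret
    ws[kept] <- w
    pows[kept] <- pow
  }
  if (kept == 0L)
    return(list(configs = matrix(0L, 0L, 4L), w = numeric(0L)))
  keep <- seq_len(kept)
  dominant <- pows[keep] == min(pows[keep])   # surviving limit order
  list(configs = do.call(rbind, cfgs[keep])[dominant, , drop = FALSE],
       w = ws[keep][dominant])
}
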