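# Orchestration of the simulation study: species tree x loss pattern x
# gene count x method x replicate -> normalized RF to the truth; plus
# the empirical-style two-subclade family generator and the <p_t> loss
# workflows.

# Deterministic per-task seed stream derived from a master seed.
seed_stream <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 75011) %% 2147483629)
}

#' Simulate single-copy genes for one experiment cell
#'
#' Runs the full per-gene pipeline: a coalescent gene tree on the
#' duplicated tree, a loss pattern reducing it to one copy per species,
#' and a JC69 alignment simulated on the pruned (true) gene tree -
#' equivalent to simulating on the full two-copy tree and discarding the
#' lost sequences.
#'
#' @param model A `species_tree_model` fixture.
#' @param n_genes Number of genes.
#' @param pattern Loss pattern 1-14.
#' @param sites Sites per gene (default 1000).
#' @param seed Optional integer seed.
#' @param conv Unit-conversion constant.
#' @return List with `true_trees` (pruned rooted gene trees, species
#'   labels plus outgroup), `alignments`, and `retained` (matrix of
#'   retained copy indices).
#' @export
simulate_single_copy_genes <- function(model, n_genes, pattern, sites = 1000,
                                       seed = NULL, conv = conv_default()) {
  stopifnot(inherits(model, "species_tree_model"), n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  dup <- build_duplicated_tree(model)
  pt <- build_poptree(dup, conv)
  species <- sort(model$post_wgd)
  true_trees <- vector("list", n_genes)
  alignments <- vector("list", n_genes)
  retained <- matrix(0L, n_genes, length(species),
                     dimnames = list(NULL, species))
  for (i in seq_len(n_genes)) {
    g <- merges_to_phylo(sim_coal_merges(pt))
    ret <- draw_retention(pattern, species)
    sc <- apply_loss_pattern(g, pattern, outgroup = model$outgroup,
                             retention = ret)
    true_trees[[i]] <- sc
    retained[i, ] <- ret
    alignments[[i]] <- simulate_jc69(sc, sites)
  }
  list(true_trees = true_trees, alignments = alignments, retained = retained)
}

#' Experiment configuration
#'
#' @param fixtures Character vector of fixture names (subset of S1-S4).
#' @param patterns Integer vector of loss patterns (1-14).
#' @param n_genes Integer vector of gene counts.
#' @param n_replicates Replicates per cell; the full design uses 100
#'   (`preset = "paper"`), the desk preset 20.
#' @param methods Subset of `c("astral", "mpest", "star", "camp",
#'   "caml")`.
#' @param sites Sites per gene.
#' @param seed Master seed; every cell and replicate derives its own
#'   stream from it.
#' @param conv Unit-conversion constant.
#' @param preset `"desk"` (20 replicates) or `"paper"` (100); ignored if
#'   `n_replicates` is given.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(fixtures = c("S1", "S2", "S3", "S4"),
                              patterns = 1:14,
                              n_genes = c(50, 100, 200, 500, 1000),
                              n_replicates = NULL,
                              methods = c("astral", "mpest", "star",
                                          "camp", "caml"),
                              sites = 1000, seed = 1,
                              conv = conv_default(),
                              preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(n_replicates))
    n_replicates <- if (preset == "paper") 100L else 20L
  stopifnot(n_replicates >= 1L, all(n_genes >= 1L), length(methods) >= 1L)
  methods <- match.arg(methods, c("astral", "mpest", "star", "camp", "caml"),
                       several.ok = TRUE)
  structure(list(fixtures = fixtures, patterns = patterns,
                 n_genes = n_genes, n_replicates = n_replicates,
                 methods = methods, sites = sites, seed = seed,
                 conv = conv),
            class = "experiment_config")
}

#' Run the simulation grid
#'
#' For every cell (fixture x pattern x gene count) and replicate:
#' simulate single-copy genes, estimate maximum-likelihood gene trees
#' (needed by the coalescent methods), run each species-tree method, and
#' record the normalized RF distance between the estimate and the true
#' species tree. Deterministic under a fixed master seed.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-cell progress to stderr.
#' @return Data frame of class `experiment_result` with one row per
#'   (cell, replicate, method).
#' @export
run_grid <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  cell <- 0L
  for (fx in cfg$fixtures) {
    model <- fixture_species_tree(fx)
    truth <- model$tree
    for (pat in cfg$patterns) for (ng in cfg$n_genes) {
      cell <- cell + 1L
      t0 <- Sys.time()
      for (rep in seq_len(cfg$n_replicates)) {
        seed <- seed_stream(cfg$seed, cell * 1000L + rep)
        res <- run_replicate(model, truth, pat, ng, cfg, seed)
        for (r in res)
          rows[[length(rows) + 1L]] <-
            data.frame(fixture = fx, pattern = pat, n_genes = ng,
                       method = r$method, replicate = rep,
                       topology = r$topology, rf = r$rf)
      }
      if (verbose)
        message(sprintf("cell %s pattern %d genes %d: %.1fs", fx, pat, ng,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_result", "data.frame")
  out
}

run_replicate <- function(model, truth, pattern, n_genes, cfg, seed) {
  sim <- simulate_single_copy_genes(model, n_genes, pattern,
                                    sites = cfg$sites, seed = seed,
                                    conv = cfg$conv)
  out <- list()
  need_gts <- any(c("astral", "mpest", "star") %in% cfg$methods)
  if (need_gts)
    gts <- lapply(sim$alignments, ml_gene_tree, outgroup = model$outgroup)
  if ("astral" %in% cfg$methods)
    out$astral <- quartet_species_tree(gts, outgroup = model$outgroup)
  if ("mpest" %in% cfg$methods)
    out$mpest <- mpest_tree(gts)
  if ("star" %in% cfg$methods)
    out$star <- star_tree(gts, outgroup = model$outgroup)
  if (any(c("camp", "caml") %in% cfg$methods))
    conc <- concat_alignments(sim$alignments)$alignment
  if ("camp" %in% cfg$methods)
    out$camp <- ca_mp_tree(conc)$consensus
  if ("caml" %in% cfg$methods)
    out$caml <- ca_ml_tree(conc, outgroup = model$outgroup)
  lapply(names(out), function(m)
    list(method = m,
         topology = write_newick(drop_lengths(out[[m]])),
         rf = rf_distance(out[[m]], truth)))
}

#' Aggregate grid results
#'
#' @param res An `experiment_result` data frame from [run_grid()].
#' @return Data frame with mean and standard deviation of the normalized
#'   RF per (fixture, pattern, gene count, method).
#' @export
summarize_grid <- function(res) {
  stopifnot(nrow(res) >= 1L)
  agg <- stats::aggregate(rf ~ fixture + pattern + n_genes + method,
                          data = res,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(agg[, 1:4], mean_rf = agg$rf[, "mean"],
                    sd_rf = agg$rf[, "sd"], n = agg$rf[, "n"])
  out$sd_rf[is.na(out$sd_rf)] <- 0
  out[order(out$fixture, out$pattern, out$n_genes, out$method), ]
}

#' Plot grid results
#'
#' Mean normalized RF against gene count, one panel per fixture and
#' pattern, one line per method. Requires ggplot2.
#'
#' @param summary A data frame from [summarize_grid()].
#' @return A ggplot object.
#' @export
plot_grid_results <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  summary$lo <- pmax(summary$mean_rf - summary$sd_rf, 0)
  summary$hi <- pmin(summary$mean_rf + summary$sd_rf, 1)
  ggplot2::ggplot(summary, ggplot2::aes(x = n_genes, y = mean_rf,
                                        colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.02) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(pattern ~ fixture) +
    ggplot2::labs(x = "number of genes", y = "mean normalized RF")
}

# ---------------------------------------------------------------------
# Empirical-style two-subclade gene families

#' Generate a synthetic two-subclade gene family set
#'
#' Emulates the structure of the empirical post-WGD data sets: `n_genes`
#' gene families on a random ultrametric species tree with a
#' root-adjacent WGD, each family carrying two complete paralog
#' subclades (one copy per ingroup species each) plus an outgroup
#' sequence. The default theta makes the mean normalized RF between the
#' two (true) subclade gene trees about 0.3, the discordance level of
#' the empirical 11-species data set.
#'
#' @param n_genes Number of gene families (default 130).
#' @param n_ingroup Number of ingroup species (default 11; at least 4).
#' @param sites Alignment length per gene.
#' @param theta Population size parameter applied to all ingroup
#'   branches; the default is calibrated so the mean normalized RF
#'   between the two subclade trees of a gene is about 0.3.
#' @param seed Optional integer seed.
#' @param conv Unit-conversion constant.
#' @return List of class `two_subclade_family_set`: `model`, `dup`,
#'   `gene_trees` (each with two copies per ingroup species plus
#'   outgroup), and `alignments`.
#' @export
make_two_subclade_fixture <- function(n_genes = 130, n_ingroup = 11,
                                      sites = 1000, theta = 0.015,
                                      seed = NULL, conv = conv_default()) {
  stopifnot(n_ingroup >= 4L, n_genes >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ing <- ape::rcoal(n_ingroup,
                    tip.label = sprintf("s%02d", seq_len(n_ingroup)))
  # keep the random topology but space the coalescences evenly between
  # the tips and the ingroup crown at 0.05, so the level of ILS is
  # governed by theta rather than by the luck of the topology draw
  ntip <- length(ing$tip.label)
  h <- node_heights(ing)
  inner <- order(h[(ntip + 1L):(ntip + ing$Nnode)]) + ntip
  h[inner] <- seq_len(ing$Nnode) / ing$Nnode * 0.05
  ing$edge.length <- h[ing$edge[, 1L]] - h[ing$edge[, 2L]]
  ing_str <- sub(";", "", write_newick(ing), fixed = TRUE)
  nwk <- paste0("(", ing_str, ":0.01,OUT:0.06);")
  tree <- parse_newick(nwk)
  model <- species_tree_model(tree, theta = theta,
                              wgd_mrca = ing$tip.label, outgroup = "OUT",
                              root_theta = theta)
  # like the fixtures, keep the subclades separated: a long stem in
  # coalescent units (0.01 mutation units / 0.001 = 10 units at conv 1)
  model$theta[model$wgd_edge] <- 0.001
  dup <- build_duplicated_tree(model)
  pt <- build_poptree(dup, conv)
  gene_trees <- vector("list", n_genes)
  alignments <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- merges_to_phylo(sim_coal_merges(pt))
    gene_trees[[i]] <- g
    alignments[[i]] <- simulate_jc69(g, sites)
  }
  structure(list(model = model, dup = dup, gene_trees = gene_trees,
                 alignments = alignments),
            class = "two_subclade_family_set")
}

#' Apply whole-subclade or per-species paralog loss to a family set
#'
#' The two loss regimes of the empirical analyses: under `pt1`
#' (`<p_t = 1>`) one of the two subclades is selected at random per gene
#' and removed entirely, leaving pure orthologs; under `pt_half`
#' (`<p_t = 1/2>`) one copy of each paralog pair is removed
#' independently per ingroup species, producing pseudoorthologs in a
#' fraction `1 - 2 (1/2)^n` of genes.
#'
#' @param fam A `two_subclade_family_set`.
#' @param mode `"pt1"` or `"pt_half"`.
#' @param seed Optional integer seed.
#' @return List with `trees` (single-copy gene trees on species labels),
#'   `alignments`, `retained` (matrix), and `pseudoortholog` (logical
#'   vector per gene).
#' @export
apply_pt_loss <- function(fam, mode = c("pt1", "pt_half"), seed = NULL) {
  stopifnot(inherits(fam, "two_subclade_family_set"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  species <- sort(fam$model$post_wgd)
  outgroup <- fam$model$outgroup
  n <- length(fam$gene_trees)
  trees <- vector("list", n)
  alns <- vector("list", n)
  retained <- matrix(0L, n, length(species),
                     dimnames = list(NULL, species))
  pseudo <- logical(n)
  for (i in seq_len(n)) {
    ret <- if (mode == "pt1")
      rep(sample.int(2L, 1L), length(species))
    else
      sample.int(2L, length(species), replace = TRUE)
    names(ret) <- species
    keep <- c(paste0(species, "_", ret), outgroup)
    g <- fam$gene_trees[[i]]
    if (!all(keep %in% g$tip.label))
      stop("gene ", i, " is incomplete: missing ",
           paste(setdiff(keep, g$tip.label), collapse = ", "))
    tr <- prune_tips(g, keep)
    tr$tip.label <- sub("_[12]$", "", tr$tip.label)
    a <- fam$alignments[[i]][keep, , drop = FALSE]
    rownames(a) <- sub("_[12]$", "", rownames(a))
    trees[[i]] <- tr
    alns[[i]] <- a
    retained[i, ] <- ret
    pseudo[i] <- is_pseudoortholog(ret)
  }
  list(trees = trees, alignments = alns, retained = retained,
       pseudoortholog = pseudo)
}
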