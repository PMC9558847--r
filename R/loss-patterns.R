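# The fourteen procedural gene-loss patterns applied to two-subclade
# gene families, single-copy pruning, and pseudoortholog classification.
#
# Every pattern reduces a gene with two paralog copies per ingroup
# species (tips "X_1"/"X_2" plus an outgroup) to a single-copy gene by
# drawing, per gene, a "retention vector": which copy survives for each
# species. Species with loss probability 1 or 0 are tied to a single
# per-gene coin (the randomly selected subclade whose sequences are
# removed); species with probability 1/2 flip independent fair coins.

# Pattern table: 'sel' species are removed from the randomly selected
# subclade (they retain the other copy); 'oth' species are removed from
# the other subclade (they retain the selected copy); 'ind' species
# retain an independently chosen copy.
pattern_table <- function() {
  list(
    list(sel = c("A", "B", "C", "D"), oth = character(), ind = character()),
    list(sel = character(), oth = character(), ind = c("A", "B", "C", "D")),
    list(sel = c("A", "B"), oth = c("C", "D"), ind = character()),
    list(sel = c("A", "C"), oth = c("B", "D"), ind = character()),
    list(sel = c("A", "D"), oth = c("B", "C"), ind = character()),
    list(sel = c("A", "B", "C"), oth = "D", ind = character()),
    list(sel = c("A", "B", "D"), oth = "C", ind = character()),
    list(sel = c("A", "C", "D"), oth = "B", ind = character()),
    list(sel = c("A", "B"), oth = character(), ind = c("C", "D")),
    list(sel = c("A", "C"), oth = character(), ind = c("B", "D")),
    list(sel = c("A", "D"), oth = character(), ind = c("B", "C")),
    list(sel = c("A", "B", "C"), oth = character(), ind = "D"),
    list(sel = c("A", "B", "D"), oth = character(), ind = "C"),
    list(sel = c("A", "C", "D"), oth = character(), ind = "B")
  )
}

#' Catalog of the fourteen gene-loss patterns
#'
#' @return A data frame with one row per pattern: the per-species loss
#'   probabilities of the copy in the randomly selected subclade, which
#'   species share the per-gene subclade coin, and which flip independent
#'   coins.
#' @export
pattern_catalog <- function() {
  tab <- pattern_table()
  data.frame(
    pattern = seq_along(tab),
    p_A = vapply(tab, function(p) pat_p(p, "A"), 0),
    p_B = vapply(tab, function(p) pat_p(p, "B"), 0),
    p_C = vapply(tab, function(p) pat_p(p, "C"), 0),
    p_D = vapply(tab, function(p) pat_p(p, "D"), 0),
    coin_removed = vapply(tab, function(p) paste(p$sel, collapse = ""), ""),
    coin_retained = vapply(tab, function(p) paste(p$oth, collapse = ""), ""),
    independent = vapply(tab, function(p) paste(p$ind, collapse = ""), "")
  )
}

pat_p <- function(p, x) {
  if (x %in% p$sel) 1 else if (x %in% p$oth) 0 else 0.5
}

#' Draw a retention vector for a loss pattern
#'
#' @param pattern Integer 1-14.
#' @param species Ingroup species names mapped (in order) to the pattern
#'   roles A, B, C, D.
#' @return Named integer vector: the copy (1 or 2) retained per species.
#' @export
draw_retention <- function(pattern, species = c("A", "B", "C", "D")) {
  pat <- check_pattern(pattern)
  stopifnot(length(species) == 4L)
  names(species) <- c("A", "B", "C", "D")
  ret <- integer(4L)
  names(ret) <- species
  s <- sample.int(2L, 1L)  # subclade whose sequences are removed
  ret[species[pat$sel]] <- 3L - s
  ret[species[pat$oth]] <- s
  if (length(pat$ind))
    ret[species[pat$ind]] <- sample.int(2L, length(pat$ind), replace = TRUE)
  ret
}

check_pattern <- function(pattern) {
  if (!is.numeric(pattern) || length(pattern) != 1L ||
      !pattern %in% 1:14)
    stop("unknown loss pattern: ", paste(pattern, collapse = ","),
         " (must be 1..14)")
  pattern_table()[[pattern]]
}

#' Reduce a two-copy gene tree to a single-copy gene tree
#'
#' Applies one of the fourteen loss patterns: a retention vector is drawn
#' (shared per-gene subclade coin for the tied species, independent fair
#' coins otherwise), the tips of the lost copies are pruned, and the
#' retained tips are relabeled to their species names. The result has
#' one tip per ingroup species plus the outgroup, with no missing data
#' by construction.
#'
#' @param gene_tree A `phylo` with tips `X_1`, `X_2` per ingroup species
#'   and one outgroup tip.
#' @param pattern Integer 1-14.
#' @param outgroup Outgroup tip label (default `"E"`).
#' @param retention Optional pre-drawn retention vector (named by
#'   species), bypassing the random draw.
#' @return A `phylo` on the species labels plus outgroup, with attribute
#'   `"retained"` holding the retention vector.
#' @examples
#' dup <- build_duplicated_tree(fixture_species_tree("S1"))
#' g <- simulate_gene_tree(dup, seed = 1)
#' sc <- apply_loss_pattern(g, 2)
#' attr(sc, "retained")
#' @export
apply_loss_pattern <- function(gene_tree, pattern, outgroup = "E",
                               retention = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  copies <- grepl("_[12]$", gene_tree$tip.label)
  species <- sort(unique(sub("_[12]$", "", gene_tree$tip.label[copies])))
  if (is.null(retention)) {
    check_pattern(pattern)
    if (length(species) != 4L)
      stop("loss patterns are defined for 4 ingroup species, found ",
           length(species))
    retention <- draw_retention(pattern, species)
  }
  keep <- c(paste0(names(retention), "_", retention), outgroup)
  if (!all(keep %in% gene_tree$tip.label))
    stop("gene tree lacks tips: ",
         paste(setdiff(keep, gene_tree$tip.label), collapse = ", "))
  out <- prune_tips(gene_tree, keep)
  out$tip.label <- sub("_[12]$", "", out$tip.label)
  attr(out, "retained") <- retention
  out
}

#' Is a retained-copy configuration a pseudoortholog set?
#'
#' A single-copy gene is pseudoorthologous when its retained copies do
#' not all descend from the same paralog subclade.
#'
#' @param retained Integer vector of retained copy indices (1 or 2), one
#'   per ingroup species.
#' @return `TRUE` if the copies span both subclades.
#' @export
is_pseudoortholog <- function(retained) {
  stopifnot(length(retained) >= 1L, all(retained %in% 1:2))
  !all(retained == retained[1L])
}

#' Expected fraction of pseudoortholog genes under a loss pattern
#'
#' Closed-form probability that the retained copies of a gene span both
#' paralog subclades. Species tied to the per-gene subclade coin always
#' agree with (or always oppose) each other; only the independent fair
#' coins can break uniformity. With `k` independent species and both
#' coin-tied groups empty on one side, the retained set is uniform iff
#' all `k` coins land on the coin group's subclade.
#'
#' @param pattern Integer 1-14.
#' @return A probability in `[0, 1]`.
#' @examples
#' expected_pseudoortholog_fraction(2)  # 0.875
#' @export
expected_pseudoortholog_fraction <- function(pattern) {
  pat <- check_pattern(pattern)
  k <- length(pat$ind)
  if (length(pat$sel) && length(pat$oth)) return(1)  # reciprocal loss
  if (k == 4L) return(1 - 2 * 0.5^4)                 # all independent
  if (k == 0L) return(0)                             # whole-subclade loss
  1 - 0.5^k                                          # convergent loss
}
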