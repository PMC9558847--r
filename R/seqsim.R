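# JC69 sequence simulation on gene trees, the JC69 distance correction,
# and alignment input/output (FASTA, relaxed PHYLIP, concatenation with
# a gene-boundary sidecar).

DNA_STATES <- c("A", "C", "G", "T")

#' Simulate a nucleotide alignment under JC69
#'
#' Root states are uniform on A/C/G/T; each site evolves independently
#' down the tree, and along a branch of length `d` (expected
#' substitutions per site) a state is retained with probability
#' `1/4 + 3/4 exp(-4d/3)` and replaced by each alternative with
#' probability `1/4 - 1/4 exp(-4d/3)`.
#'
#' @param tree Rooted `phylo` with nonnegative branch lengths.
#' @param n_sites Number of sites (default 1000, the simulation design's gene
#'   length).
#' @param seed Optional integer seed.
#' @return Character matrix (taxa x sites) with tip labels as rownames,
#'   in the tree's tip order.
#' @examples
#' a <- simulate_jc69(parse_newick("((A:0.1,B:0.1):0.1,C:0.2);"), 100, seed = 1)
#' dim(a)
#' @export
simulate_jc69 <- function(tree, n_sites = 1000, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("all branch lengths must be present and nonnegative")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  states <- matrix(0L, n, n_sites)
  root <- root_node(tree)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  # preorder: parents before children
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    d <- tree$edge.length[e]
    stay <- 0.25 + 0.75 * exp(-4 * d / 3)
    mut <- stats::runif(n_sites) > stay
    s <- states[p, ]
    if (any(mut)) {
      # draw a different state uniformly among the other three
      shift <- sample.int(3L, sum(mut), replace = TRUE)
      s[mut] <- (s[mut] - 1L + shift[seq_len(sum(mut))]) %% 4L + 1L
    }
    states[ch, ] <- s
  }
  out <- matrix(DNA_STATES[states[seq_len(ntip), , drop = FALSE]],
                ntip, n_sites)
  rownames(out) <- tree$tip.label
  out
}

#' JC69 distance correction
#'
#' Converts an observed proportion of differing sites into the JC69
#' maximum-likelihood distance `-3/4 log(1 - 4p/3)`.
#'
#' @param p Proportion(s) of differing sites, `0 <= p < 3/4`.
#' @return Distance(s) in expected substitutions per site.
#' @export
jc69_correct <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= 0.75))
    stop("saturation: JC69 distance undefined for p >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

check_alignment <- function(a) {
  if (!is.matrix(a) || !is.character(a) || is.null(rownames(a)))
    stop("alignment must be a character matrix with taxa as rownames")
  if (anyDuplicated(rownames(a))) stop("duplicate taxon names")
  invisible(a)
}

#' Read and write FASTA alignments
#'
#' Plain sequential FASTA; sequences must be equal length (an
#' alignment).
#'
#' @param file Path.
#' @param a Character matrix (taxa x sites).
#' @return `read_fasta` returns a character matrix.
#' @export
read_fasta <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  names <- sub("^>\\s*", "", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[seq(starts[i], ends[i])], collapse = ""), "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths; not an alignment")
  m <- t(vapply(seqs, function(s)
    toupper(strsplit(s, "", fixed = TRUE)[[1L]]), character(lens[1L])))
  rownames(m) <- names
  check_alignment(m)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(a, file) {
  check_alignment(a)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a)))
    writeLines(c(paste0(">", rownames(a)[i]),
                 paste(a[i, ], collapse = "")), con)
  invisible(file)
}

#' Read and write relaxed PHYLIP alignments
#'
#' Sequential PHYLIP with whitespace-delimited (relaxed, untruncated)
#' names.
#'
#' @param file Path.
#' @param a Character matrix (taxa x sites).
#' @return `read_phylip` returns a character matrix.
#' @export
read_phylip <- function(file) {
  lines <- readLines(file)
  hd <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != hd[1L]) stop("expected ", hd[1L], " sequences")
  parts <- strsplit(trimws(body), "\\s+")
  names <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
  if (any(nchar(seqs) != hd[2L])) stop("sequence length mismatch with header")
  m <- t(vapply(seqs, function(s)
    toupper(strsplit(s, "", fixed = TRUE)[[1L]]), character(hd[2L])))
  rownames(m) <- names
  check_alignment(m)
}

#' @rdname read_phylip
#' @export
write_phylip <- function(a, file) {
  check_alignment(a)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(nrow(a), ncol(a)), con)
  for (i in seq_len(nrow(a)))
    writeLines(paste(rownames(a)[i],
                     paste(a[i, ], collapse = ""), sep = "  "), con)
  invisible(file)
}

#' Concatenate gene alignments
#'
#' Binds gene alignments column-wise after matching taxa by name, and
#' records gene boundaries for partition-aware consumers.
#'
#' @param alignments List of character matrices over the same taxa.
#' @return List with `alignment` (concatenated matrix, taxa sorted by
#'   name) and `boundaries` (data frame gene/start/end).
#' @export
concat_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(rownames(alignments[[1L]]))
  for (a in alignments)
    if (!setequal(rownames(a), taxa))
      stop("all gene alignments must cover the same taxa")
  mats <- lapply(alignments, function(a) a[taxa, , drop = FALSE])
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  list(alignment = do.call(cbind, mats),
       boundaries = data.frame(gene = seq_along(mats),
                               start = ends - widths + 1L, end = ends))
}
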