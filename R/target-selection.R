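## Target-group selection.
##
## A "phylogenetic tree of cis-regulatory systems" is built from
## TF-presence bit vectors: each genome is encoded by the presence/absence
## of TF families, pairwise Hamming distances feed a neighbour-joining
## tree, and a group of target genomes is the largest clade around a seed
## genome in which every genome pair still shares at least half of its
## TFs.

#' TF-presence bit matrix
#'
#' @param tf_table data frame of `(genome_id, tf_family_id)` pairs (see
#'   [read_tf_table()]).
#' @param genome_ids genomes to include (rows); genomes absent from the
#'   table get an all-zero row with a warning.
#' @return binary matrix, genomes x TF families.
#' @export
tf_presence_matrix <- function(tf_table, genome_ids) {
  fams <- sort(unique(tf_table$tf_family_id))
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(fams),
              dimnames = list(genome_ids, fams))
  hit <- tf_table$genome_id %in% genome_ids
  m[cbind(match(tf_table$genome_id[hit], genome_ids),
          match(tf_table$tf_family_id[hit], fams))] <- 1L
  missing <- setdiff(genome_ids, unique(tf_table$genome_id))
  if (length(missing) > 0L)
    warning("no TF families recorded for: ",
            paste(missing, collapse = ", "))
  m
}

#' Pairwise Hamming distance matrix of TF-presence vectors
#'
#' @param m TF-presence matrix (see [tf_presence_matrix()]).
#' @return symmetric integer distance matrix with zero diagonal.
#' @export
hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sum(m[i, ] != m[j, ])
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via [ape::nj()]); negative
#' branch lengths are clamped to zero.
#'
#' @param d symmetric distance matrix with row/column names (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fraction of shared TF families between two genomes
#'
#' `|TF(g1) n TF(g2)| / min(|TF(g1)|, |TF(g2)|)`; 1 (with a warning) when
#' either genome has no TFs at all.
#'
#' @param g1,g2 genome ids (rows of `m`).
#' @param m TF-presence matrix.
#' @return fraction in `[0, 1]`.
#' @export
shared_tf_fraction <- function(g1, g2, m) {
  v1 <- m[g1, ] > 0
  v2 <- m[g2, ] > 0
  lo <- min(sum(v1), sum(v2))
  if (lo == 0L) {
    warning("genome with empty TF set: treating shared fraction as 1")
    return(1)
  }
  sum(v1 & v2) / lo
}

#' Select a group of target genomes around a seed
#'
#' The tree is midpoint-rooted and the clades on the path from the seed
#' leaf towards the root are examined in order of increasing depth; the
#' largest clade in which every genome pair shares at least `min_shared`
#' of its TF families is returned, stopping before the first violating
#' clade.
#'
#' @param tree a `phylo` tree with genome-id tip labels.
#' @param m TF-presence matrix covering all tips.
#' @param seed_genome the seed genome (must be a tip).
#' @param min_shared minimum pairwise [shared_tf_fraction()] (default
#'   0.5).
#' @return character vector of genome ids (always contains the seed).
#' @export
select_target_group <- function(tree, m, seed_genome, min_shared = 0.5) {
  if (!seed_genome %in% tree$tip.label)
    stop("seed genome ", seed_genome, " is not a tip of the tree")
  rooted <- phangorn::midpoint(tree)
  tip <- match(seed_genome, rooted$tip.label)
  ## walk ancestors of the seed leaf towards the root
  parent <- function(node) {
    e <- rooted$edge[rooted$edge[, 2L] == node, 1L]
    if (length(e) == 0L) NA_integer_ else e[[1L]]
  }
  ok_group <- function(tips) {
    if (length(tips) < 2L) return(TRUE)
    for (i in seq_along(tips))
      for (j in seq_along(tips))
        if (j > i &&
            shared_tf_fraction(tips[[i]], tips[[j]], m) < min_shared)
          return(FALSE)
    TRUE
  }
  best <- seed_genome
  node <- parent(tip)
  while (!is.na(node)) {
    tips <- ape::extract.clade(rooted, node)$tip.label
    if (!ok_group(tips)) break
    best <- tips
    node <- parent(node)
  }
  sort(best)
}
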