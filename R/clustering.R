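## The graph-clustering cascade.
##
## Input motifs are filtered through a sequence of motif-similarity graphs:
## G1 (permissive cutoff alpha) and G2 (stringent cutoff beta) are built
## over the input motifs; G2 is cut into dense subgraphs by MCL; G3
## reconnects those clusters with the motifs present only in G1; its
## clusters induce subgraphs of G1 in which quasi-cliques are detected;
## quasi-clique-specific motifs form G4, extended (22 bp) motifs form G5,
## and the surviving sites are partitioned per genome, refined over widths
## 8-22, scored and ranked.  Every stage only merges or discards sites, so
## spurious predictions are progressively filtered out.

#' Clustering configuration
#'
#' @param alpha,beta similarity cutoffs for G1 and G2 (`alpha < beta`).
#'   The defaults sit above the bulk of the similarity distribution of
#'   unrelated sampler motifs; on very large motif pools, where the
#'   graphs are relatively much sparser, lower values (alpha 0.2-0.3,
#'   beta 0.35-0.45) are appropriate and can be chosen by density with
#'   [autotune_cutoffs()].
#' @param gamma cutoff for the later-stage graphs (defaults to `beta`).
#' @param tau per-column alignment threshold of the similarity metric.
#' @param inflation,expansion,prune,max_iter MCL parameters.
#' @param min_overlap sites overlapping by strictly more than this many
#'   bases are merged (default 8).
#' @param pad extension pad in bases for the extended-motif stage.
#' @param extended_width width of extended motifs (default 22).
#' @param refine_widths widths tried in the final refinement (default
#'   8:22, i.e. up to 15 motifs).
#' @param gs_widths widths tried when auto-detecting length in the
#'   genome-specific stage.
#' @param background,delta background composition and pseudocount mass.
#' @param seed seed governing the stage finders.
#' @return clustering configuration object.
#' @export
clustering_config <- function(alpha = 0.35, beta = 0.45, gamma = NULL,
                              tau = 0.5, inflation = 2.0, expansion = 2L,
                              prune = 1e-5, max_iter = 100L,
                              min_overlap = 8L, pad = 10L,
                              extended_width = 22L, refine_widths = 8:22,
                              gs_widths = seq(8L, 22L, by = 2L),
                              background = uniform_background(),
                              delta = 1.0, seed = 1L) {
  if (alpha >= beta) stop("alpha must be smaller than beta")
  if (is.null(gamma)) gamma <- beta
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                 inflation = inflation, expansion = as.integer(expansion),
                 prune = prune, max_iter = as.integer(max_iter),
                 min_overlap = as.integer(min_overlap),
                 pad = as.integer(pad),
                 extended_width = as.integer(extended_width),
                 refine_widths = as.integer(refine_widths),
                 gs_widths = as.integer(gs_widths),
                 background = background, delta = delta,
                 seed = as.integer(seed)),
            class = "pf_clustering_config")
}

## --- similarity graphs -----------------------------------------------------

graph_from_simmat <- function(S, cutoff, keep_isolated = FALSE) {
  n <- nrow(S)
  ids <- rownames(S)
  if (n == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  hit <- which(upper.tri(S) & S > cutoff, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(hit) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(hit)),
                           weight = S[hit])
  }
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  g
}

#' Build a motif similarity graph
#'
#' Two motifs are connected iff their similarity score is strictly greater
#' than `cutoff`; the score becomes the edge weight.  By default motifs
#' without any connection are dropped from the graph (they are the
#' presumed-spurious ones); `keep_isolated = TRUE` retains them as
#' isolated vertices.
#'
#' @param motifs list of `pf_motif` objects.
#' @param cutoff similarity cutoff in (0, 1).
#' @param keep_isolated retain degree-zero vertices.
#' @inheritParams motif_similarity
#' @return an `igraph` graph with vertex names = motif ids.
#' @export
build_similarity_graph <- function(motifs, cutoff, keep_isolated = FALSE,
                                   tau = 0.5,
                                   background = uniform_background(),
                                   delta = 1.0) {
  stopifnot(cutoff > 0, cutoff <= 1)
  S <- similarity_matrix(motifs, tau, background, delta)
  graph_from_simmat(S, cutoff, keep_isolated)
}

#' Density of a graph
#'
#' Number of edges divided by number of nodes (the convention used for
#' picking the cutoffs alpha and beta).
#'
#' @param g an `igraph` graph.
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph has no nodes")
  igraph::ecount(g) / n
}

#' Auto-tune the similarity cutoffs alpha and beta
#'
#' Bisection on the cutoff against the density of the resulting graph
#' (nodes = motifs with at least one edge).  `alpha` targets a G1 density
#' of about `target_g1` within `alpha_range`; `beta` targets the middle of
#' `target_g2` within `beta_range`.  When a target is not attainable
#' inside its range the range midpoint is returned with a warning.
#'
#' @param motifs list of `pf_motif` objects.
#' @param target_g1 target density for G1 (default 500).
#' @param target_g2 target density interval for G2 (default 15-20).
#' @param alpha_range,beta_range admissible cutoff ranges.
#' @inheritParams motif_similarity
#' @return list with `alpha` and `beta`.
#' @export
autotune_cutoffs <- function(motifs, target_g1 = 500,
                             target_g2 = c(15, 20),
                             alpha_range = c(0.2, 0.3),
                             beta_range = c(0.35, 0.45),
                             tau = 0.5,
                             background = uniform_background(),
                             delta = 1.0) {
  S <- similarity_matrix(motifs, tau, background, delta)
  su <- S[upper.tri(S)]
  density_at <- function(cut) {
    deg <- rowSums(S > cut) - 1L  # diagonal is 1
    nodes <- sum(deg > 0L)
    if (nodes == 0L) return(0)
    sum(su > cut) / nodes
  }
  tune_one <- function(range, target, label) {
    d_lo <- density_at(range[[1L]])
    d_hi <- density_at(range[[2L]])
    if (target > d_lo || target < d_hi) {
      warning("target density ", target, " for ", label,
              " not attainable in [", range[[1L]], ", ", range[[2L]],
              "]; falling back to the midpoint")
      return(mean(range))
    }
    lo <- range[[1L]]
    hi <- range[[2L]]
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (density_at(mid) >= target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  list(alpha = tune_one(alpha_range, target_g1, "G1"),
       beta = tune_one(beta_range, mean(target_g2), "G2"))
}

## --- Markov clustering -----------------------------------------------------

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL: a column-stochastic flow matrix is built from the edge
#' weights plus unit self-loops, then expansion (matrix power) and
#' inflation (element-wise power followed by column renormalisation) with
#' pruning are iterated until the flow matrix stabilises.  Clusters are
#' read off the attractor rows; overlapping attractor systems are merged,
#' and every node is assigned to the cluster receiving most of its flow
#' (ties to the smallest cluster id).
#'
#' @param g an `igraph` graph (possibly with isolated vertices; weights
#'   taken from the `weight` edge attribute, 1 when absent).
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param prune entries below this are dropped each iteration.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with a warning and `attr(, "converged") = FALSE`.
#' @return list of character vectors of vertex names, a partition of the
#'   vertex set.
#' @export
mcl <- function(g, inflation = 2.0, expansion = 2L, prune = 1e-5,
                max_iter = 100L) {
  n <- igraph::vcount(g)
  if (n == 0L) return(structure(list(), converged = TRUE))
  nms <- igraph::V(g)$name
  if (is.null(nms)) nms <- as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(
    g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight"
              else NULL,
    sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  Matrix::diag(A) <- 1
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mn <- M
    for (e in seq_len(expansion - 1L)) Mn <- Mn %*% M
    Mn <- methods::as(Mn, "CsparseMatrix")
    Mn@x <- Mn@x^inflation
    Mn <- normalize(Mn)
    Mn <- methods::as(Mn, "CsparseMatrix")
    Mn@x[Mn@x < prune] <- 0
    Mn <- Matrix::drop0(Mn)
    Mn <- normalize(Mn)
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < 1e-6) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")

  ## cluster extraction from attractor rows
  tm <- Matrix::summary(methods::as(M, "TsparseMatrix"))
  tm <- tm[tm$x > 1e-6, , drop = FALSE]
  attractors <- sort(unique(tm$i[tm$i == tm$j]))
  clusters <- integer(0)
  if (length(attractors) > 0L) {
    arows <- tm[tm$i %in% attractors, , drop = FALSE]
    ## union-find over attractors sharing any member column
    uf <- seq_along(attractors)
    find <- function(i) {
      while (uf[[i]] != i) i <- uf[[i]]
      i
    }
    member_lists <- split(arows$j, factor(arows$i, levels = attractors))
    node_owner <- new.env(parent = emptyenv())
    for (ai in seq_along(attractors)) {
      for (j in member_lists[[ai]]) {
        key <- as.character(j)
        prev <- node_owner[[key]]
        if (is.null(prev)) node_owner[[key]] <- ai
        else uf[[find(ai)]] <- find(prev)
      }
    }
    roots <- vapply(seq_along(attractors), find, integer(1))
    cluster_ids <- match(roots, sort(unique(roots)))
    ## per-node flow into each merged cluster
    flow <- matrix(0, nrow = max(cluster_ids), ncol = n)
    for (r in seq_len(nrow(arows))) {
      ci <- cluster_ids[[match(arows$i[[r]], attractors)]]
      flow[ci, arows$j[[r]]] <- flow[ci, arows$j[[r]]] + arows$x[[r]]
    }
    clusters <- integer(n)
    for (j in seq_len(n)) {
      f <- flow[, j]
      clusters[[j]] <- if (all(f == 0)) 0L else which.max(f)
    }
  } else {
    clusters <- rep(0L, n)
  }
  ## leftover nodes (no attractor flow) become singletons
  nxt <- max(clusters, 0L)
  for (j in which(clusters == 0L)) {
    nxt <- nxt + 1L
    clusters[[j]] <- nxt
  }
  out <- split(nms, clusters)
  out <- out[order(vapply(out, function(v) min(match(v, nms)), integer(1)))]
  out <- lapply(unname(out), function(v) v[order(match(v, nms))])
  structure(out, converged = converged)
}

## --- G3 and induced subgraphs ---------------------------------------------

#' Build the mixed cluster/singleton graph G3
#'
#' Nodes are the G2 clusters plus the motifs present in G1 but not in G2.
#' For two nodes `u`, `v` the mean G1 edge weight over all member pairs,
#' `wbar(u, v) = sum(w_xy) / (|u| * |v|)`, defines an edge iff it exceeds
#' `alpha` strictly.
#'
#' @param g2_clusters clusters of G2 (list of motif-id vectors, from
#'   [mcl()]).
#' @param g1 the permissive similarity graph.
#' @param alpha the G1 cutoff.
#' @return list with `graph` (igraph over unit names `u1..uk`) and
#'   `units` (named list of member motif-id vectors).
#' @export
build_g3 <- function(g2_clusters, g1, alpha) {
  v1 <- igraph::V(g1)$name
  leftover <- setdiff(v1, unlist(g2_clusters))
  units <- c(g2_clusters, as.list(leftover))
  names(units) <- paste0("u", seq_along(units))
  k <- length(units)
  g <- igraph::make_empty_graph(k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(units))
  if (k >= 2L && igraph::ecount(g1) > 0L) {
    W <- igraph::as_adjacency_matrix(g1, attr = "weight", sparse = TRUE)
    B <- Matrix::sparseMatrix(
      i = rep(seq_len(k), lengths(units)),
      j = match(unlist(units), v1),
      x = 1, dims = c(k, length(v1)))
    num <- B %*% W %*% Matrix::t(B)
    sizes <- lengths(units)
    wbar <- as.matrix(num) / outer(sizes, sizes)
    hit <- which(upper.tri(wbar) & wbar > alpha, arr.ind = TRUE)
    if (nrow(hit) > 0L)
      g <- igraph::add_edges(g, as.vector(t(hit)), weight = wbar[hit])
  }
  list(graph = g, units = units)
}

#' Induce G1 subgraphs from G3 clusters
#'
#' Each G3 cluster is expanded to its underlying motif ids and the
#' corresponding induced subgraph of G1 is returned.
#'
#' @param g1 the permissive similarity graph.
#' @param g3_clusters clusters of G3-unit names.
#' @param units the unit membership list from [build_g3()].
#' @return list of igraph subgraphs.
#' @export
induce_subgraphs <- function(g1, g3_clusters, units) {
  lapply(g3_clusters, function(cl) {
    ids <- unlist(units[cl], use.names = FALSE)
    igraph::induced_subgraph(g1, intersect(igraph::V(g1)$name, ids))
  })
}

## --- quasi-cliques ---------------------------------------------------------

#' Find quasi-cliques in a weighted subgraph
#'
#' For every node a maximal clique is grown greedily from that node,
#' trying neighbours in order of decreasing edge weight; cliques sharing
#' strictly more than `majority` of the smaller one's nodes are merged
#' transitively.  The result is a cover of the subgraph's node set.
#'
#' @param s an `igraph` subgraph.
#' @param majority sharing fraction above which cliques merge (default
#'   0.5).
#' @return list of character vectors of vertex names.
#' @export
find_quasi_cliques <- function(s, majority = 0.5) {
  n <- igraph::vcount(s)
  if (n == 0L) return(list())
  nms <- igraph::V(s)$name
  adj <- igraph::as_adjacency_matrix(
    s, attr = if ("weight" %in% igraph::edge_attr_names(s)) "weight"
              else NULL, sparse = FALSE)
  cliques <- list()
  for (v in seq_len(n)) {
    cand <- order(-adj[v, ])
    cand <- cand[adj[v, cand] > 0]
    cl <- v
    compat <- adj[v, ] > 0
    for (u in cand)
      if (compat[[u]]) {
        cl <- c(cl, u)
        compat <- compat & adj[u, ] > 0
      }
    cliques[[length(cliques) + 1L]] <- sort(cl)
  }
  cliques <- unique(cliques)
  ## transitive merging via union-find
  k <- length(cliques)
  uf <- seq_len(k)
  find <- function(i) {
    while (uf[[i]] != i) i <- uf[[i]]
    i
  }
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (j > i) {
        ov <- length(intersect(cliques[[i]], cliques[[j]]))
        if (ov > majority * min(length(cliques[[i]]),
                                length(cliques[[j]])))
          uf[[find(j)]] <- find(i)
      }
  roots <- vapply(seq_len(k), find, integer(1))
  merged <- lapply(split(seq_len(k), roots), function(idx)
    sort(unique(unlist(cliques[idx]))))
  merged <- merged[order(vapply(merged, min, integer(1)))]
  lapply(unname(merged), function(ix) nms[ix])
}

## --- site surgery ----------------------------------------------------------

#' Merge overlapping sites
#'
#' Same-genome, same-strand sites whose intervals overlap by strictly more
#' than `min_overlap` bases are merged transitively into their union
#' interval; the merged sequence is re-extracted from the genome.  Exact
#' duplicate intervals are collapsed first.
#'
#' @param sites site data frame.
#' @param genomes named list of `pf_genome` objects.
#' @param min_overlap overlap threshold in bases (strictly greater than;
#'   default 8).
#' @return merged site data frame.
#' @export
merge_overlapping_sites <- function(sites, genomes, min_overlap = 8L) {
  if (nrow(sites) == 0L) return(sites)
  sites <- sites[!duplicated(sites[c("genome_id", "start", "end",
                                     "strand")]), , drop = FALSE]
  parts <- split(sites, paste(sites$genome_id, sites$strand))
  out <- lapply(parts, function(p) {
    p <- p[order(p$start, p$end), , drop = FALSE]
    grp <- integer(nrow(p))
    grp[[1L]] <- 1L
    run_end <- p$end[[1L]]
    for (i in seq_len(nrow(p))[-1L]) {
      if (min(run_end, p$end[[i]]) - p$start[[i]] > min_overlap) {
        grp[[i]] <- grp[[i - 1L]]
        run_end <- max(run_end, p$end[[i]])
      } else {
        grp[[i]] <- grp[[i - 1L]] + 1L
        run_end <- p$end[[i]]
      }
    }
    data.frame(genome_id = p$genome_id[[1L]],
               start = as.integer(tapply(p$start, grp, min)),
               end = as.integer(tapply(p$end, grp, max)),
               strand = p$strand[[1L]], seq = "", source = "merged",
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  refresh_site_seqs(merged, genomes)
}

## Redundancy rule for the final predicted site set of a cluster: the
## refinement motifs of different widths call overlapping windows of the
## same locus, so sites are grouped strand-agnostically whenever they
## overlap by at least half of the narrowest refinement width (> 3
## bases), and each group is collapsed to its union interval on the plus
## strand.
final_unique_sites <- function(sites, genomes, min_overlap = 3L) {
  if (nrow(sites) == 0L) return(sites)
  sites$strand <- "+"
  merge_overlapping_sites(sites, genomes, min_overlap)
}

## Extend sites by `pad` bases on both ends, clipped at the genome bounds.
extend_sites <- function(sites, genomes, pad = 10L) {
  if (nrow(sites) == 0L) return(sites)
  glen <- vapply(sites$genome_id, function(g) genomes[[g]]$length,
                 integer(1))
  sites$start <- pmax(0L, sites$start - pad)
  sites$end <- pmin(glen, sites$end + pad)
  refresh_site_seqs(sites, genomes)
}

## Run the stage finder on a merged site pool and map the best motif back
## to genomic coordinates.  Falls back to a passthrough motif built
## directly from the pooled sites when fewer than 3 usable sequences
## remain.
find_stage_motif <- function(sites, genomes, widths, seed, id, stage,
                             background = uniform_background(),
                             delta = 1.0) {
  if (nrow(sites) == 0L) return(NULL)
  usable <- sites[nchar(sites$seq) >= min(widths), , drop = FALSE]
  if (nrow(usable) < 3L) {
    w <- min(nchar(sites$seq))
    trimmed <- sites
    trimmed$seq <- substr(trimmed$seq, 1L, w)
    trimmed$end <- trimmed$start + w
    trimmed <- refresh_site_seqs(trimmed, genomes)
    return(new_motif(trimmed, id = id,
                     origin = list(stage = stage, degenerate = TRUE)))
  }
  if (length(widths) == 1L) {
    res <- builtin_sampler_find(usable$seq, widths, 1L, seed,
                                background = background, delta = delta)
    best <- if (length(res) > 0L) res[[1L]] else NULL
  } else {
    best <- best_motif_auto_width(usable$seq, widths, seed,
                                  background = background, delta = delta)
  }
  if (is.null(best)) return(NULL)
  gsites <- sites_from_windows(usable[best$sites$seq_index, ],
                               best$sites$offset, best$width,
                               best$sites$revcomp, source = stage)
  new_motif(gsites, id = id, origin = list(stage = stage))
}

#' Best motif of a quasi-clique
#'
#' Pools the sites of the quasi-clique's member motifs, merges overlaps,
#' and finds the single best fixed-width motif in the pooled sequences.
#'
#' @param qc character vector of member motif ids.
#' @param motifs named list of `pf_motif` objects.
#' @param genomes named list of `pf_genome` objects.
#' @param width motif width (default 16).
#' @param seed finder seed.
#' @param id motif id for the result.
#' @inheritParams clustering_config
#' @return a `pf_motif` tagged `"quasi-clique-specific"`.
#' @export
quasi_clique_motif <- function(qc, motifs, genomes, width = 16L, seed = 1L,
                               id = "qc", min_overlap = 8L,
                               background = uniform_background(),
                               delta = 1.0) {
  pooled <- do.call(rbind, lapply(motifs[qc], `[[`, "sites"))
  merged <- merge_overlapping_sites(pooled, genomes, min_overlap)
  find_stage_motif(merged, genomes, width, seed, id,
                   stage = "quasi-clique-specific",
                   background = background, delta = delta)
}

#' Extend merged sites and re-find a wider motif
#'
#' Merges overlapping sites, pads each merged site by `pad` bases on both
#' ends (clipped at the genome bounds) and finds the best motif of
#' `width` bases in the extended sequences -- recovering binding sites
#' only partially covered by the fixed-width input motifs.
#'
#' @param sites pooled site data frame of one cluster.
#' @inheritParams quasi_clique_motif
#' @inheritParams clustering_config
#' @return a `pf_motif` tagged `"extended"`.
#' @export
extend_and_refind <- function(sites, genomes, pad = 10L, width = 22L,
                              seed = 1L, id = "ext", min_overlap = 8L,
                              background = uniform_background(),
                              delta = 1.0) {
  merged <- merge_overlapping_sites(sites, genomes, min_overlap)
  ext <- extend_sites(merged, genomes, pad)
  find_stage_motif(ext, genomes, width, seed, id, stage = "extended",
                   background = background, delta = delta)
}

#' Partition cluster sites by genome and re-cluster per genome
#'
#' The pooled sites of every G5 cluster are split by genome into
#' genome-specific sequence sets; each set is merged and its best motif
#' found with length auto-detected over `gs_widths`.  Per genome, the
#' resulting motifs are connected at cutoff `gamma` and clustered with
#' MCL.
#'
#' @param g5_site_pools list of pooled site data frames (one per G5
#'   cluster).
#' @param genomes named list of `pf_genome` objects.
#' @param config a [clustering_config()].
#' @return named list (per genome) of clusters; each cluster is a list
#'   with `motifs` (member `pf_motif`s) and `sites` (their pooled sites).
#' @export
genome_specific_stage <- function(g5_site_pools, genomes, config) {
  per_genome <- list()
  for (k in seq_along(g5_site_pools)) {
    pool <- g5_site_pools[[k]]
    if (is.null(pool) || nrow(pool) == 0L) next
    for (gid in unique(pool$genome_id)) {
      sub <- pool[pool$genome_id == gid, , drop = FALSE]
      merged <- merge_overlapping_sites(sub, genomes, config$min_overlap)
      m <- find_stage_motif(
        merged, genomes, config$gs_widths,
        stable_seed(config$seed, "gs", k, gid),
        id = sprintf("gs_%03d_%s", k, gid), stage = "genome-specific",
        background = config$background, delta = config$delta)
      if (!is.null(m))
        per_genome[[gid]] <- c(per_genome[[gid]], list(m))
    }
  }
  out <- list()
  for (gid in names(per_genome)) {
    ms <- per_genome[[gid]]
    names(ms) <- vapply(ms, `[[`, character(1), "id")
    g <- build_similarity_graph(ms, config$gamma, keep_isolated = TRUE,
                                tau = config$tau,
                                background = config$background,
                                delta = config$delta)
    cls <- mcl(g, config$inflation, config$expansion, config$prune,
               config$max_iter)
    out[[gid]] <- lapply(cls, function(cl) {
      mm <- ms[cl]
      list(motifs = mm,
           sites = do.call(rbind, lapply(mm, `[[`, "sites")))
    })
  }
  out
}

#' Refine one per-genome cluster into its final motif
#'
#' Up to one motif per width in `widths` (at most `max_motifs`) is found
#' in the cluster's merged sequences; the union of their sites, merged
#' and deduplicated, is the final predicted motif.  The best single motif
#' supplies the matrices for [cluster_score()].
#'
#' @param cluster_sites pooled site data frame of the cluster.
#' @param genomes named list of `pf_genome` objects.
#' @param widths candidate widths (default 8:22).
#' @param max_motifs cap on the number of refinement motifs (default 15).
#' @param seed finder seed.
#' @inheritParams clustering_config
#' @return list with `final_sites`, `best_motif`, `n` (sites in the best
#'   motif), `L` (its width) and `N` (sequences in the cluster).
#' @export
refine_cluster <- function(cluster_sites, genomes, widths = 8:22,
                           max_motifs = 15L, seed = 1L, min_overlap = 8L,
                           background = uniform_background(),
                           delta = 1.0) {
  merged <- merge_overlapping_sites(cluster_sites, genomes, min_overlap)
  N <- nrow(merged)
  widths <- head(widths, max_motifs)
  ## degenerate clusters (< 3 usable sequences) yield one passthrough
  ## motif whatever the width, so the width scan is skipped
  if (sum(nchar(merged$seq) >= min(widths)) < 3L)
    widths <- widths[[1L]]
  found <- list()
  for (w in widths) {
    m <- find_stage_motif(merged, genomes, w,
                          seed = seed + w, id = sprintf("refine_w%02d", w),
                          stage = "refined", background = background,
                          delta = delta)
    if (!is.null(m)) found[[length(found) + 1L]] <- m
  }
  if (length(found) == 0L)
    found <- list(find_stage_motif(merged, genomes, min(nchar(merged$seq)),
                                   seed = seed, id = "refine_passthrough",
                                   stage = "refined",
                                   background = background, delta = delta))
  net <- vapply(found, function(m) {
    n <- nrow(m$sites)
    ic <- information_content(m, background, delta)
    n * (ic - m$width * 3 / (2 * n * log(2)))
  }, numeric(1))
  best <- found[[which.max(net)]]
  all_sites <- do.call(rbind, lapply(found, `[[`, "sites"))
  final_sites <- final_unique_sites(all_sites, genomes)
  list(final_sites = final_sites, best_motif = best,
       n = nrow(best$sites), L = best$width, N = N)
}

#' Cluster score
#'
#' `ClusterScore = (n / N) * sum_{i=1..L} [ sum_b p(b,i) * P(b,i) -
#' 3 / (2 n ln 2) ]`, floored at zero: the fraction of the cluster's
#' sequences covered by its best motif, times the motif's total
#' information content (bits) net of the finite-sample bias of the
#' information estimate (`E[IC] ~ 3 / (2 n ln 2)` bits per column for 3
#' free parameters).  The bias term keeps small clusters, whose raw
#' per-column information is strongly inflated, from outranking large
#' well-supported motifs; without it a 3-site alignment of random
#' sequences scores comparably to a conserved 30-site motif.
#'
#' @param best_motif the cluster's best `pf_motif`.
#' @param n sites in the best motif.
#' @param N sequences in the cluster.
#' @inheritParams frequency_matrix
#' @return numeric score, `>= 0`; 0 for any uninformative motif.
#' @export
cluster_score <- function(best_motif, n, N,
                          background = uniform_background(),
                          delta = 1.0) {
  stopifnot(N >= 1, n <= N)
  ic <- information_content(best_motif, background, delta)
  max(0, (n / N) * (ic - best_motif$width * 3 / (2 * n * log(2))))
}

#' Rank scored clusters
#'
#' Stable sort by score descending, ties by `N` descending, then by
#' cluster id.
#'
#' @param scored list of scored clusters (each with `score`, `N`, `id`).
#' @return the same list, ordered, with `rank` filled in.
#' @export
rank_clusters <- function(scored) {
  if (length(scored) == 0L) return(scored)
  sc <- vapply(scored, `[[`, numeric(1), "score")
  N <- vapply(scored, `[[`, numeric(1), "N")
  id <- vapply(scored, `[[`, character(1), "id")
  ord <- order(-sc, -N, id)
  out <- scored[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

## --- the full cascade ------------------------------------------------------

#' Run the full graph-clustering cascade
#'
#' Composes the stages in order: G1/G2 construction, MCL on G2, G3
#' recruitment and MCL, induced G1 subgraphs, quasi-cliques and their
#' motifs, G4 + MCL, extension to 22 bp motifs, G5 + MCL, genome-specific
#' partitioning and MCL, refinement, scoring, ranking.
#'
#' @param input_motifs list of `pf_motif` objects from
#'   [collect_input_motifs()].
#' @param genomes named list of `pf_genome` objects.
#' @param config a [clustering_config()].
#' @return list with `ranked` (named per-genome lists of scored clusters,
#'   see [rank_clusters()]), `stages` (checkpoint summaries incl. stage
#'   site pools) and `config`.
#' @export
run_clustering_pipeline <- function(input_motifs, genomes,
                                    config = clustering_config()) {
  empty <- list(ranked = list(), stages = list(), config = config)
  if (length(input_motifs) == 0L) return(empty)
  names(input_motifs) <- vapply(input_motifs, `[[`, character(1), "id")
  stages <- list()
  input_sites <- do.call(rbind, lapply(input_motifs, `[[`, "sites"))
  rownames(input_sites) <- NULL
  stages$input <- list(n_motifs = length(input_motifs),
                       sites = input_sites)

  ## (A) G1 / G2 and MCL on G2
  S <- similarity_matrix(input_motifs, config$tau, config$background,
                         config$delta)
  g1 <- graph_from_simmat(S, config$alpha)
  g2 <- graph_from_simmat(S, config$beta)
  stages$g1 <- list(n_nodes = igraph::vcount(g1),
                    n_edges = igraph::ecount(g1))
  stages$g2 <- list(n_nodes = igraph::vcount(g2),
                    n_edges = igraph::ecount(g2))
  if (igraph::vcount(g1) == 0L) return(empty)
  c2 <- mcl(g2, config$inflation, config$expansion, config$prune,
            config$max_iter)

  ## (B) G3 and its clusters; induced subgraphs of G1
  g3 <- build_g3(c2, g1, config$alpha)
  c3 <- mcl(g3$graph, config$inflation, config$expansion, config$prune,
            config$max_iter)
  subs <- induce_subgraphs(g1, c3, g3$units)
  stages$g3 <- list(n_units = length(g3$units), n_clusters = length(c3))

  ## (C) quasi-cliques and their motifs; G4
  qc_motifs <- list()
  for (si in seq_along(subs)) {
    qcs <- find_quasi_cliques(subs[[si]])
    for (qi in seq_along(qcs)) {
      m <- quasi_clique_motif(
        qcs[[qi]], input_motifs, genomes, width = 16L,
        seed = stable_seed(config$seed, "qc", si, qi),
        id = sprintf("qc_%03d_%02d", si, qi),
        min_overlap = config$min_overlap,
        background = config$background, delta = config$delta)
      if (!is.null(m)) qc_motifs[[length(qc_motifs) + 1L]] <- m
    }
  }
  names(qc_motifs) <- vapply(qc_motifs, `[[`, character(1), "id")
  stages$quasi_clique <- list(
    n_motifs = length(qc_motifs),
    sites = do.call(rbind, c(lapply(qc_motifs, `[[`, "sites"),
                             list(make.row.names = FALSE))))
  if (length(qc_motifs) == 0L) return(c(empty[1L], list(stages = stages),
                                        empty[3L]))
  g4 <- build_similarity_graph(qc_motifs, config$gamma,
                               keep_isolated = TRUE, tau = config$tau,
                               background = config$background,
                               delta = config$delta)
  c4 <- mcl(g4, config$inflation, config$expansion, config$prune,
            config$max_iter)

  ## (D) extended motifs; G5
  ext_motifs <- list()
  for (ci in seq_along(c4)) {
    pooled <- do.call(rbind, lapply(qc_motifs[c4[[ci]]], `[[`, "sites"))
    m <- extend_and_refind(
      pooled, genomes, pad = config$pad, width = config$extended_width,
      seed = stable_seed(config$seed, "ext", ci),
      id = sprintf("ext_%03d", ci), min_overlap = config$min_overlap,
      background = config$background, delta = config$delta)
    if (!is.null(m)) ext_motifs[[length(ext_motifs) + 1L]] <- m
  }
  names(ext_motifs) <- vapply(ext_motifs, `[[`, character(1), "id")
  stages$extended <- list(
    n_motifs = length(ext_motifs),
    sites = do.call(rbind, c(lapply(ext_motifs, `[[`, "sites"),
                             list(make.row.names = FALSE))))
  if (length(ext_motifs) == 0L) return(c(empty[1L], list(stages = stages),
                                         empty[3L]))
  g5 <- build_similarity_graph(ext_motifs, config$gamma,
                               keep_isolated = TRUE, tau = config$tau,
                               background = config$background,
                               delta = config$delta)
  c5 <- mcl(g5, config$inflation, config$expansion, config$prune,
            config$max_iter)

  ## (E) genome-specific partitioning
  pools5 <- lapply(c5, function(cl)
    do.call(rbind, lapply(ext_motifs[cl], `[[`, "sites")))
  per_genome <- genome_specific_stage(pools5, genomes, config)

  ## (F) refinement, scoring, ranking
  ranked <- list()
  for (gid in names(per_genome)) {
    scored <- list()
    for (ci in seq_along(per_genome[[gid]])) {
      cl <- per_genome[[gid]][[ci]]
      ref <- refine_cluster(
        cl$sites, genomes, widths = config$refine_widths,
        max_motifs = 15L,
        seed = stable_seed(config$seed, "refine", gid, ci),
        min_overlap = config$min_overlap,
        background = config$background, delta = config$delta)
      sc <- cluster_score(ref$best_motif, ref$n, ref$N,
                          config$background, config$delta)
      scored[[length(scored) + 1L]] <-
        list(id = sprintf("%s_c%03d", gid, ci), genome_id = gid,
             score = sc, n = ref$n, L = ref$L, N = ref$N,
             best_motif = ref$best_motif, sites = ref$final_sites)
    }
    ranked[[gid]] <- rank_clusters(scored)
  }
  final_sites <- do.call(rbind, c(unlist(lapply(ranked, function(rg)
    lapply(rg, `[[`, "sites")), recursive = FALSE),
    list(make.row.names = FALSE)))
  stages$final <- list(
    n_clusters = sum(lengths(ranked)),
    sites = final_sites)
  list(ranked = ranked, stages = stages, config = config)
}

#' Tabular report of ranked clusters
#'
#' @param result output of [run_clustering_pipeline()].
#' @return data frame with one row per (genome, cluster).
#' @export
ranked_report <- function(result) {
  rows <- list()
  for (gid in names(result$ranked)) {
    for (cl in result$ranked[[gid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, rank = cl$rank, cluster_id = cl$id,
        score = cl$score, n = cl$n, N = cl$N, L = cl$L,
        consensus = motif_consensus(cl$best_motif),
        n_unique_sites = nrow(cl$sites), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome_id = character(), rank = integer(),
                      cluster_id = character(), score = numeric(),
                      n = integer(), N = integer(), L = integer(),
                      consensus = character(), n_unique_sites = integer())
  out[order(out$genome_id, out$rank), , drop = FALSE]
}
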