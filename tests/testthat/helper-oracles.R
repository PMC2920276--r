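# Independent oracles and small builders shared across the test files.
# Everything here is deliberately written along a different code path than
# the implementation it checks (plain loops, dense matrices, union-find).

DNA <- c("A", "C", "G", "T")

rand_string <- function(w) paste0(sample(DNA, w, replace = TRUE),
                                  collapse = "")

rand_motif <- function(n = 5, w = 16, id = "m") {
  motif_from_seqs(replicate(n, rand_string(w)), id = id)
}

# n mutated copies of a consensus (a "sub-motif family")
family_motif <- function(consensus, n = 5, mut = 0.1, id = "fam") {
  w <- nchar(consensus)
  seqs <- replicate(n, {
    ch <- strsplit(consensus, "")[[1]]
    hit <- runif(w) < mut
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA, b), 1),
                      character(1))
    paste0(ch, collapse = "")
  })
  motif_from_seqs(seqs, id = id)
}

# --- union-find -------------------------------------------------------------

uf_membership <- function(n, edges) {
  if (length(edges) > 0) edges <- matrix(as.integer(edges), ncol = 2)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[[a]] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# --- dense reference MCL ----------------------------------------------------

ref_mcl_membership <- function(A, inflation = 2, expansion = 2,
                               max_iter = 200) {
  n <- nrow(A)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mn <- M
    for (e in seq_len(expansion - 1)) Mn <- Mn %*% M
    Mn <- Mn^inflation
    Mn <- sweep(Mn, 2, colSums(Mn), "/")
    Mn[Mn < 1e-12] <- 0
    cs <- colSums(Mn)
    cs[cs == 0] <- 1
    Mn <- sweep(Mn, 2, cs, "/")
    conv <- max(abs(Mn - M)) < 1e-6
    M <- Mn
    if (conv) break
  }
  B <- (M + t(M)) > 1e-6
  memb <- rep(0L, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (memb[[v]] > 0L) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      if (memb[[u]] > 0L) next
      memb[[u]] <- cid
      queue <- c(queue, which(B[u, ] & memb == 0L))
    }
  }
  memb
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

clusters_to_membership <- function(clusters, ids) {
  memb <- integer(length(ids))
  names(memb) <- ids
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  unname(memb)
}

# --- tiny genome/annotation builders ---------------------------------------

toy_genome <- function(id = "g1", len = 6000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_genome(id, paste0(sample(DNA, len, replace = TRUE), collapse = ""))
}

toy_annotation <- function(genome_id, starts, ends, strands,
                           prefix = "gene") {
  n <- length(starts)
  data.frame(gene_id = paste0(prefix, seq_len(n)), genome_id = genome_id,
             start = as.integer(starts), end = as.integer(ends),
             strand = strands,
             protein_id = paste0("p_", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# small ensemble used where full T = 40 would be needless compute
small_ensemble <- function(seed, ks = c(4L, 3L, 1L, 1L, 1L)) {
  slots <- lapply(seq_along(ks), function(i)
    list(adapter = builtin_adapter(paste0("gibbs", i)), k = ks[[i]]))
  ensemble_config(slots = slots, seed = seed)
}

# run the whole pipeline on a generated bundle; returns everything the
# evaluation needs
run_bundle <- function(bundle, seed, ens = small_ensemble(seed),
                       cfg = clustering_config(seed = seed)) {
  map <- build_ortholog_map(bundle$hit_tables, bundle$annotation)
  coors <- build_coors(bundle$operons, map)
  sets <- build_sequence_sets(coors, bundle$operons, bundle$genomes,
                              bundle$annotation)
  motifs <- collect_input_motifs(sets, ens)
  result <- run_clustering_pipeline(motifs, bundle$genomes, cfg)
  list(map = map, coors = coors, sets = sets, motifs = motifs,
       result = result)
}

top_sites <- function(result, k = 8) {
  do.call(rbind, unlist(lapply(result$ranked, function(rg)
    lapply(head(rg, k), `[[`, "sites")), recursive = FALSE))
}

# strand-agnostic recovery of each row of `known` by any row of `predicted`
recovered_vec <- function(predicted, known, min_overlap = 9) {
  vapply(seq_len(nrow(known)), function(i) {
    any(predicted$genome_id == known$genome_id[[i]] &
          pmin(predicted$end, known$end[[i]]) -
            pmax(predicted$start, known$start[[i]]) >= min_overlap)
  }, logical(1))
}
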