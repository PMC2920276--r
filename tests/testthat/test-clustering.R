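test_that("similarity graphs take edges strictly above the cutoff and
           match a brute-force oracle", {
  set.seed(19)
  trio <- lapply(1:3, function(i)
    motif_from_seqs(rep(strrep("A", 16), 6), id = paste0("id", i)))
  g <- build_similarity_graph(trio, 0.5)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 3L)  # triangle
  expect_equal(unique(igraph::E(g)$weight), 1.0)

  g1max <- build_similarity_graph(trio, 1.0)
  expect_equal(igraph::ecount(g1max), 0)

  pool <- c(replicate(12, rand_motif(), simplify = FALSE),
            replicate(8, family_motif(rand_string(16), mut = 0.08),
                      simplify = FALSE))
  for (i in seq_along(pool)) pool[[i]]$id <- paste0("m", i)
  cut <- 0.4
  g2 <- build_similarity_graph(pool, cut, keep_isolated = TRUE)
  # brute-force all-pairs oracle
  for (i in seq_along(pool))
    for (j in seq_along(pool))
      if (i < j) {
        s <- motif_similarity(pool[[i]], pool[[j]])
        expect_equal(
          igraph::are_adjacent(g2, paste0("m", i), paste0("m", j)),
          s > cut)
      }
})

test_that("graph density is edges over nodes", {
  tri <- igraph::make_ring(3)
  expect_equal(graph_density(tri), 1.0)
  path3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(graph_density(path3), 2 / 3)
  expect_equal(graph_density(igraph::make_empty_graph(4,
                                                      directed = FALSE)),
               0)
  expect_error(graph_density(igraph::make_empty_graph(0)), "no nodes")
})

test_that("cutoff auto-tuning bisects to an attainable density and falls
           back on degenerate pools", {
  set.seed(29)
  pool <- c(replicate(25, rand_motif(), simplify = FALSE),
            unlist(lapply(1:5, function(k)
              replicate(7, family_motif(rand_string(16), mut = 0.15),
                        simplify = FALSE)), recursive = FALSE))
  for (i in seq_along(pool)) pool[[i]]$id <- paste0("m", i)
  # measure the attainable density range with the package's own graph
  d_at <- function(cut) {
    g <- build_similarity_graph(pool, cut)
    if (igraph::vcount(g) == 0) 0 else graph_density(g)
  }
  targ_a <- mean(c(d_at(0.2), d_at(0.3)))
  targ_b <- mean(c(d_at(0.35), d_at(0.45)))
  cuts <- autotune_cutoffs(pool, target_g1 = targ_a,
                           target_g2 = c(targ_b, targ_b))
  expect_true(cuts$alpha >= 0.2 && cuts$alpha <= 0.3)
  expect_true(cuts$beta >= 0.35 && cuts$beta <= 0.45)
  expect_lt(abs(d_at(cuts$alpha) - targ_a), 0.2 * max(targ_a, 1))
  expect_lt(abs(d_at(cuts$beta) - targ_b), 0.2 * max(targ_b, 1))

  # density is monotone non-increasing in the cutoff (bisection validity)
  dens <- vapply(seq(0.1, 0.9, by = 0.1), d_at, numeric(1))
  expect_true(all(diff(dens) <= 1e-12))

  # degenerate pool: identical motifs, targets unreachable -> midpoints
  ident <- lapply(1:6, function(i)
    motif_from_seqs(rep(strrep("ACGT", 4), 5), id = paste0("d", i)))
  ws <- testthat::capture_warnings(
    fb <- autotune_cutoffs(ident, target_g1 = 500, target_g2 = c(15, 20)))
  expect_true(all(grepl("midpoint", ws)))
  expect_length(ws, 2L)
  expect_equal(fb$alpha, 0.25)
  expect_equal(fb$beta, 0.40)
})

test_that("MCL separates disjoint cliques, splits a barbell and keeps
           singletons", {
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  tri2 <- igraph::set_vertex_attr(tri2, "name",
                                  value = paste0("v", 1:6))
  cl <- mcl(tri2)
  expect_equal(length(cl), 2L)
  expect_setequal(lengths(cl), c(3L, 3L))
  expect_setequal(unlist(cl), paste0("v", 1:6))

  # barbell: two K5 joined by one edge
  barbell <- igraph::disjoint_union(igraph::make_full_graph(5),
                                    igraph::make_full_graph(5))
  barbell <- igraph::add_edges(barbell, c(1, 6))
  barbell <- igraph::set_vertex_attr(barbell, "name",
                                     value = paste0("b", 1:10))
  clb <- mcl(barbell)
  expect_equal(length(clb), 2L)
  expect_setequal(vapply(clb, function(x)
    paste(sort(x), collapse = ","), character(1)),
    c(paste(sort(paste0("b", 1:5)), collapse = ","),
      paste(sort(paste0("b", 6:10)), collapse = ",")))

  single <- igraph::make_empty_graph(1, directed = FALSE)
  single <- igraph::set_vertex_attr(single, "name", value = "only")
  expect_equal(mcl(single), list("only"), ignore_attr = TRUE)
})

test_that("MCL never merges graph components and always partitions the
           vertex set", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    g <- igraph::sample_gnp(n, 0.15)
    g <- igraph::set_vertex_attr(g, "name", value = paste0("n", 1:n))
    cl <- mcl(g)
    expect_setequal(unlist(cl), paste0("n", 1:n))
    expect_equal(sum(lengths(cl)), n)  # a partition: no node twice
    comp <- igraph::components(g)$membership
    for (cluster in cl)
      expect_equal(length(unique(comp[match(cluster,
                                            paste0("n", 1:n))])), 1L)
  }
})

test_that("G3 averages G1 edge weights over unit pairs with a strict
           cutoff", {
  g1 <- igraph::make_graph(~ a - c)
  g1 <- igraph::set_edge_attr(g1, "weight", value = 0.4)
  g1 <- igraph::add_vertices(g1, 1, name = "b")
  # u = {a, b}, v = {c}: wbar = 0.4 / (2*1) = 0.2, not > alpha = 0.2
  g3 <- build_g3(list(c("a", "b")), g1, alpha = 0.2)
  expect_equal(length(g3$units), 2L)  # cluster + leftover singleton {c}
  expect_equal(igraph::ecount(g3$graph), 0L)
  # just below the mean weight the edge appears with the averaged weight
  g3b <- build_g3(list(c("a", "b")), g1, alpha = 0.19)
  expect_equal(igraph::ecount(g3b$graph), 1L)
  expect_equal(igraph::E(g3b$graph)$weight, 0.2)

  # singleton-vs-singleton reduces to the G1 edge rule
  g1c <- igraph::make_graph(~ x - y)
  g1c <- igraph::set_edge_attr(g1c, "weight", value = 0.5)
  g3c <- build_g3(list(), g1c, alpha = 0.45)
  expect_equal(igraph::ecount(g3c$graph), 1L)
  expect_equal(igraph::E(g3c$graph)$weight, 0.5)
})

test_that("induced subgraphs expand units, conserve motifs and filter
           G1 edges exactly", {
  set.seed(47)
  pool <- c(replicate(6, family_motif("ACGTACGTACGTACGT", mut = 0.05),
                      simplify = FALSE),
            replicate(6, family_motif("TTTTGGGGCCCCAAAA", mut = 0.05),
                      simplify = FALSE))
  for (i in seq_along(pool)) pool[[i]]$id <- paste0("m", i)
  g1 <- build_similarity_graph(pool, 0.4, keep_isolated = TRUE)
  units <- list(paste0("m", 1:6), paste0("m", 7:12))
  names(units) <- c("u1", "u2")
  subs <- induce_subgraphs(g1, list("u1", "u2"), units)
  expect_equal(length(subs), 2L)
  expect_equal(sum(vapply(subs, igraph::vcount, numeric(1))), 12)
  # induced edges = brute-force filter of the G1 edge set
  for (k in 1:2) {
    el <- igraph::as_edgelist(subs[[k]])
    for (r in seq_len(nrow(el)))
      expect_true(igraph::are_adjacent(g1, el[r, 1], el[r, 2]))
    inside <- units[[k]]
    el1 <- igraph::as_edgelist(g1)
    both_in <- el1[, 1] %in% inside & el1[, 2] %in% inside
    expect_equal(nrow(el), sum(both_in))
  }
})

test_that("quasi-cliques grow greedily per node, merge on majority
           sharing and cover all nodes", {
  # two triangles sharing the edge b-c merge into one quasi-clique
  g <- igraph::make_graph(~ a - b, a - c, b - c, b - d, c - d)
  qcs <- find_quasi_cliques(g)
  expect_equal(length(qcs), 1L)
  expect_setequal(qcs[[1]], c("a", "b", "c", "d"))

  # two triangles sharing a single node stay apart (1 of 3 shared)
  g2 <- igraph::make_graph(~ a - b, a - c, b - c, c - d, c - e, d - e)
  qcs2 <- find_quasi_cliques(g2)
  expect_equal(length(qcs2), 2L)
  expect_setequal(unlist(qcs2), c("a", "b", "c", "d", "e"))  # cover

  # a graph that is one clique yields one quasi-clique with all nodes
  k4 <- igraph::make_full_graph(4)
  k4 <- igraph::set_vertex_attr(k4, "name", value = letters[1:4])
  expect_equal(find_quasi_cliques(k4), list(letters[1:4]))

  # cover property on random graphs
  set.seed(51)
  for (rep in 1:5) {
    gr <- igraph::sample_gnp(15, 0.3)
    gr <- igraph::set_vertex_attr(gr, "name", value = paste0("q", 1:15))
    expect_setequal(unlist(find_quasi_cliques(gr)), paste0("q", 1:15))
  }
})

test_that("site merging is transitive, strand-aware and strict about
           the 8-base rule", {
  set.seed(57)
  g <- toy_genome("g1", 2000)
  genomes <- list(g1 = g)
  mk <- function(s, e, strand = "+")
    new_site("g1", s, e, strand, genome_slice(g, s, e, strand), "t")
  # overlap exactly 8 -> NOT merged
  s8 <- rbind(mk(100, 116), mk(108, 124))
  expect_equal(nrow(merge_overlapping_sites(s8, genomes)), 2L)
  # overlap 9 -> merged to the union [100, 123)
  s9 <- rbind(mk(100, 116), mk(107, 123))
  m9 <- merge_overlapping_sites(s9, genomes)
  expect_equal(nrow(m9), 1L)
  expect_equal(c(m9$start, m9$end), c(100L, 123L))
  expect_equal(m9$seq, genome_slice(g, 100, 123))
  # disjoint sites unchanged; different strands never merge
  sd <- rbind(mk(100, 116), mk(300, 316), mk(105, 121, "-"))
  expect_equal(nrow(merge_overlapping_sites(sd, genomes)), 3L)
  # transitive chain a~b~c with a, c barely disjoint collapses to one
  ch <- rbind(mk(100, 116), mk(106, 122), mk(112, 128))
  mch <- merge_overlapping_sites(ch, genomes)
  expect_equal(nrow(mch), 1L)
  expect_equal(c(mch$start, mch$end), c(100L, 128L))
})

test_that("extension pads merged sites within genome bounds and
           recovers a planted 20-mer from its 16-mer fragments", {
  set.seed(59)
  core20 <- rand_string(20)
  host <- plant_site(rand_string(1500), core20, 700)
  host <- plant_site(host, core20, 200)
  host <- plant_site(host, core20, 1100)
  g <- new_genome("g1", host)
  genomes <- list(g1 = g)
  # 16-mer calls covering only part of the 20-mer at each locus
  frag <- function(s) new_site("g1", s, s + 16, "+",
                               genome_slice(g, s, s + 16), "frag")
  sites <- rbind(frag(200), frag(702), frag(1103))
  ext <- phylofoot:::extend_sites(sites, genomes, pad = 10)
  expect_equal(ext$start, c(190L, 692L, 1093L))
  expect_equal(ext$end, c(226L, 728L, 1129L))
  # clipping at the left genome edge
  near0 <- phylofoot:::extend_sites(frag(3), genomes, pad = 10)
  expect_equal(near0$start, 0L)

  m <- extend_and_refind(sites, genomes, pad = 10, width = 22, seed = 11,
                         id = "ext")
  expect_s3_class(m, "pf_motif")
  expect_equal(m$width, 22L)
  # every 22-base site fully contains the planted 20-mer
  expect_true(all(grepl(core20, m$sites$seq, fixed = TRUE) |
                    grepl(reverse_complement(core20), m$sites$seq,
                          fixed = TRUE)))
})

test_that("quasi-clique motifs pool member sites and are deterministic;
           tiny pools pass through", {
  set.seed(61)
  kmer <- rand_string(16)
  host <- rand_string(3000)
  pos <- seq(100, 2500, by = 240)[1:10]
  for (p in pos) host <- plant_site(host, kmer, p)
  g <- new_genome("g1", host)
  genomes <- list(g1 = g)
  mk_motif <- function(idx, id) new_motif(do.call(rbind, lapply(pos[idx],
    function(p) new_site("g1", p, p + 16, "+", genome_slice(g, p, p + 16),
                         "m"))), id = id)
  motifs <- list(a = mk_motif(1:5, "a"), b = mk_motif(6:10, "b"))
  qm <- quasi_clique_motif(c("a", "b"), motifs, genomes, seed = 3,
                           id = "qc1")
  expect_equal(qm$width, 16L)
  expect_true(all(qm$sites$seq %in% c(kmer, reverse_complement(kmer))))
  qm2 <- quasi_clique_motif(c("a", "b"), motifs, genomes, seed = 3,
                            id = "qc1")
  expect_identical(qm, qm2)

  # fewer than 3 pooled sequences: degenerate passthrough keeps the sites
  tiny <- list(t = mk_motif(1:2, "t"))
  qt <- quasi_clique_motif("t", tiny, genomes, seed = 3, id = "qct")
  expect_equal(nrow(qt$sites), 2L)
  expect_true(isTRUE(qt$origin$degenerate))
})

test_that("cluster scores weigh coverage against bias-corrected
           information", {
  # background-like motif scores 0 whatever the coverage
  set.seed(63)
  flat <- motif_from_seqs(c("ACGT", "CGTA", "GTAC", "TACG",
                            "ACGT", "CGTA", "GTAC", "TACG"))
  expect_equal(cluster_score(flat, 8, 8), 0)
  # near-hard motif: score approaches the oracle formula value
  hard <- motif_from_seqs(rep(strrep("A", 12), 40))
  ic <- information_content(hard)
  want <- (40 / 40) * (ic - 12 * 3 / (2 * 40 * log(2)))
  expect_equal(cluster_score(hard, 40, 40), want)
  expect_gt(want, 15)
  # halving coverage halves the score at fixed n-bias
  expect_equal(cluster_score(hard, 40, 80), want / 2)
  # a small cluster of the same hardness scores far lower per the bias
  hard3 <- motif_from_seqs(rep(strrep("A", 12), 3))
  expect_lt(cluster_score(hard3, 3, 3), cluster_score(hard, 40, 40) / 2)
  expect_error(cluster_score(hard, 10, 5))
})

test_that("ranking is stable with documented tie-breaks", {
  mk <- function(id, score, N) list(id = id, score = score, N = N)
  ranked <- rank_clusters(list(mk("c", 1, 5), mk("a", 3, 2),
                               mk("b", 1, 9), mk("d", 1, 5)))
  expect_equal(vapply(ranked, `[[`, character(1), "id"),
               c("a", "b", "c", "d"))
  expect_equal(vapply(ranked, `[[`, integer(1), "rank"), 1:4)
  expect_setequal(vapply(ranked, `[[`, character(1), "id"),
                  c("a", "b", "c", "d"))
})

test_that("the pipeline handles empty input and is deterministic under a
           fixed seed", {
  empty <- run_clustering_pipeline(list(), list())
  expect_equal(empty$ranked, list())

  b <- generate_group(fixture_config(n_genomes = 3, n_operons = 10,
                                     n_planted_motifs = 1, seed = 303))
  r1 <- run_bundle(b, seed = 9)
  r2 <- run_bundle(b, seed = 9)
  expect_identical(ranked_report(r1$result), ranked_report(r2$result))
  expect_identical(lapply(r1$result$ranked, function(rg)
    lapply(rg, `[[`, "sites")),
    lapply(r2$result$ranked, function(rg) lapply(rg, `[[`, "sites")))
})
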