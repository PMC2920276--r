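hit_row <- function(q, s, e, b = 100) {
  data.frame(query = q, subject = s, evalue = e, bitscore = b,
             stringsAsFactors = FALSE)
}

test_that("BDBH keeps mutual best hits under the E-value cutoff", {
  ab <- rbind(hit_row("a1", "b1", 1e-30), hit_row("a1", "b2", 1e-25),
              hit_row("a2", "b2", 1e-30), hit_row("a3", "b3", 1e-10))
  ba <- rbind(hit_row("b1", "a1", 1e-30), hit_row("b2", "a9", 1e-40),
              hit_row("b2", "a2", 1e-30), hit_row("b3", "a3", 1e-10))
  bd <- bdbh_orthologs(ab, ba)
  # a1<->b1 mutual best; a2's best is b2 but b2's best is a9 -> dropped;
  # a3<->b3 mutual but above the 1e-20 cutoff -> dropped
  expect_equal(bd$a, "a1")
  expect_equal(bd$b, "b1")

  # brute-force best-hit check on a random table
  set.seed(14)
  qs <- paste0("a", 1:6)
  ss <- paste0("b", 1:6)
  ab2 <- do.call(rbind, lapply(qs, function(q)
    do.call(rbind, lapply(sample(ss, 3), function(s)
      hit_row(q, s, 10^-sample(21:60, 1))))))
  ba2 <- do.call(rbind, lapply(ss, function(s)
    do.call(rbind, lapply(sample(qs, 3), function(q)
      hit_row(s, q, 10^-sample(21:60, 1))))))
  bd2 <- bdbh_orthologs(ab2, ba2)
  best <- function(h, q) {
    hh <- h[h$query == q & h$evalue <= 1e-20, ]
    hh <- hh[order(hh$evalue, -hh$bitscore, hh$subject), ]
    if (nrow(hh) == 0) NA_character_ else hh$subject[[1]]
  }
  for (q in qs) {
    expected <- !is.na(best(ab2, q)) && identical(best(ba2, best(ab2, q)), q)
    expect_equal(q %in% bd2$a, expected)
  }
  # one-to-one: no gene appears twice
  expect_false(anyDuplicated(bd2$a) > 0 || anyDuplicated(bd2$b) > 0)

  # symmetry: swapping the direction tables swaps the columns
  bd_rev <- bdbh_orthologs(ba2, ab2)
  expect_setequal(paste(bd2$a, bd2$b), paste(bd_rev$b, bd_rev$a))
})

test_that("SCOOR recruitment honours the at-least-half-the-genes rule", {
  # seed operon with 4 genes in g1; candidates in g2 share 3, 2, 1 genes
  ann <- rbind(
    toy_annotation("g1", (0:3) * 200 + 50, (0:3) * 200 + 150,
                   rep("+", 4), prefix = "x"),
    toy_annotation("g2", (0:7) * 200 + 50, (0:7) * 200 + 150,
                   rep("+", 8), prefix = "y"))
  ops <- make_operons(
    c("o_seed", "o_c3", "o_c2", "o_c1"),
    c("g1", "g2", "g2", "g2"),
    list(paste0("x", 1:4), paste0("y", 1:3), c("y4", "y5"), c("y6", "y7")),
    rep("+", 4), ann)
  pair_map <- function(pairs) {
    env <- new.env(parent = emptyenv())
    for (p in pairs) {
      assign(paste0(p[[1]], "\r", "g2"), p[[2]], envir = env)
      assign(paste0(p[[2]], "\r", "g1"), p[[1]], envir = env)
    }
    structure(list(env = env), class = "pf_ortholog_map")
  }
  # x1..x3 -> y1..y3 (3/4 >= 0.5): o_c3 recruited
  m3 <- pair_map(list(c("x1", "y1"), c("x2", "y2"), c("x3", "y3")))
  expect_setequal(build_scoor("o_seed", ops, m3)$members,
                  c("o_seed", "o_c3"))
  # exactly 2/4 still recruits ("at least 50%")
  m2 <- pair_map(list(c("x1", "y4"), c("x2", "y5")))
  expect_setequal(build_scoor("o_seed", ops, m2)$members,
                  c("o_seed", "o_c2"))
  # 1/4 does not
  m1 <- pair_map(list(c("x1", "y6")))
  expect_equal(build_scoor("o_seed", ops, m1)$members, "o_seed")
  # no orthologs at all: singleton SCOOR
  m0 <- pair_map(list())
  expect_equal(build_scoor("o_seed", ops, m0)$members, "o_seed")
})

test_that("SCOOR containment graph and COOR components follow the 70%
           rule", {
  scoors <- list(
    list(seed_operon = "o1", members = c("o1", "o2", "o3")),
    list(seed_operon = "o1", members = c("o1", "o2", "o3", "o4", "o5")),
    list(seed_operon = "o1", members = c("o1", "o6", "o9", "o10")),
    list(seed_operon = "o7", members = c("o7", "o8")))
  g <- scoor_graph(scoors)
  el <- igraph::as_edgelist(g)
  # s1 subset of s2: 3/3 >= 0.7 -> edge; s1 vs s3 share 1/3 -> none;
  # s4 disjoint -> none; s2 vs s3: share only o1 -> 1/4 < 0.7 -> none
  expect_equal(nrow(el), 1L)
  expect_setequal(el[1, ], c("s1", "s2"))

  coors <- coors_from_components(g, scoors)
  expect_equal(length(coors), 3L)
  sizes <- sort(lengths(lapply(coors, `[[`, "operons")))
  expect_equal(sizes, c(2L, 4L, 5L))
  # union of members for the merged component
  big <- coors[[which.max(lengths(lapply(coors, `[[`, "operons")))]]
  expect_setequal(big$operons, paste0("o", 1:5))
})

test_that("COOR components agree with a union-find oracle on random
           SCOOR graphs", {
  set.seed(77)
  for (rep in 1:20) {
    ns <- sample(5:30, 1)
    scoors <- lapply(seq_len(ns), function(i)
      list(seed_operon = paste0("o", i),
           members = unique(c(paste0("o", i),
                              paste0("o", sample(ns, sample(1:4, 1)))))))
    g <- scoor_graph(scoors, containment_frac = 0.7)
    coors <- coors_from_components(g, scoors)
    memb <- uf_membership(ns, igraph::as_edgelist(g, names = FALSE))
    expect_equal(length(coors), length(unique(memb)))
    # every SCOOR lands in exactly one COOR, matching its component
    owner <- integer(ns)
    for (k in seq_along(coors)) owner[coors[[k]]$member_scoors] <- k
    expect_true(all(owner > 0))
    expect_equal(length(unique(paste(memb, owner))),
                 length(unique(memb)))
  }
})

test_that("COOR sizes are monotone in the containment threshold", {
  set.seed(5)
  scoors <- lapply(1:15, function(i)
    list(seed_operon = paste0("o", i),
         members = unique(paste0("o", c(i, sample(15, 3))))))
  prev <- NULL
  for (cf in c(0.9, 0.7, 0.5, 0.3)) {
    coors <- coors_from_components(scoor_graph(scoors, cf), scoors)
    biggest <- max(lengths(lapply(coors, `[[`, "operons")))
    if (!is.null(prev)) expect_gte(biggest, prev)
    prev <- biggest
  }
})

test_that("upstream extraction is inter-operonic, truncated at 800 and
           strand-aware", {
  set.seed(8)
  g <- toy_genome("g1", 9000)
  ann <- toy_annotation("g1", c(1000, 2000, 5000, 8200),
                        c(1500, 2600, 5400, 8900),
                        c("+", "+", "-", "+"))
  ops <- make_operons(paste0("op", 1:4), rep("g1", 4),
                      list("gene1", "gene2", "gene3", "gene4"),
                      c("+", "+", "-", "+"), ann)
  # previous gene ends at 1500, operon starts at 2000 -> [1500, 2000)
  s2 <- extract_upstream(ops[2, ], g, ann)
  expect_equal(c(s2$start, s2$end), c(1500L, 2000L))
  expect_equal(s2$seq, genome_slice(g, 1500, 2000))

  # gap 5400..8200 = 2800 for the + operon at 8200: last 800 only
  s4 <- extract_upstream(ops[4, ], g, ann)
  expect_equal(c(s4$start, s4$end), c(7400L, 8200L))

  # minus-strand operon: downstream-in-genome window, reverse-complemented
  s3 <- extract_upstream(ops[3, ], g, ann)
  expect_equal(c(s3$start, s3$end), c(5400L, 6200L))
  expect_equal(s3$seq, reverse_complement(genome_slice(g, 5400, 6200)))

  # + operon flush at position 0 of a linear genome has no upstream
  ann0 <- toy_annotation("g1", 0, 300, "+")
  op0 <- make_operons("op0", "g1", list("gene1"), "+", ann0)
  expect_null(extract_upstream(op0[1, ], g, ann0))
})

test_that("sequence sets and COOR membership serialise to FASTA/TSV", {
  b <- generate_group(fixture_config(n_genomes = 3, n_operons = 4,
                                     n_planted_motifs = 1,
                                     motif_fraction = 0.25, seed = 71))
  map <- build_ortholog_map(b$hit_tables, b$annotation)
  coors <- build_coors(b$operons, map)
  sets <- build_sequence_sets(coors, b$operons, b$genomes, b$annotation)
  dir <- withr::local_tempdir()
  write_coor_table(coors, file.path(dir, "coors.tsv"))
  tab <- phylofoot:::read_hash_tsv(file.path(dir, "coors.tsv"))
  expect_equal(nrow(tab), length(coors))
  expect_equal(tab$n_operons, rep(3L, 4L))
  write_sequence_sets(sets, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir,
                                               paste0(sets[[1]]$coor_id,
                                                      ".fa")))
  expect_equal(length(fa), nrow(sets[[1]]$entries))
  expect_equal(unname(as.character(fa)), sets[[1]]$entries$seq)
  expect_match(names(fa)[[1]], "^g01\\|op_g01_t\\d+\\|\\d+-\\d+\\([+-]\\)$")
})

test_that("sequence sets require three non-empty upstream extracts", {
  set.seed(12)
  g <- toy_genome("g1", 8000)
  ann <- toy_annotation("g1", c(0, 1000, 3000, 5000),
                        c(400, 1400, 3400, 5400), rep("+", 4))
  ops <- make_operons(paste0("op", 1:4), rep("g1", 4),
                      as.list(paste0("gene", 1:4)), rep("+", 4), ann)
  coor_all <- list(id = "coorA", operons = paste0("op", 1:4))
  coor_two <- list(id = "coorB", operons = c("op2", "op3"))
  expect_message(
    sets <- build_sequence_sets(list(coor_all, coor_two), ops,
                                list(g1 = g), ann),
    "coorB")
  expect_equal(length(sets), 1L)
  # op1 starts at 0 -> empty upstream; op2..op4 contribute
  expect_equal(nrow(sets[[1]]$entries), 3L)
  expect_true(all(nchar(sets[[1]]$entries$seq) > 0 &
                    nchar(sets[[1]]$entries$seq) <= 800))
})
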