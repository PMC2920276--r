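## Orthology and orthologous-operon clustering.
##
## Bi-directional best hits (BDBH) define one-to-one orthology between
## genome pairs.  Each operon seeds a SCOOR (semi-cluster of operons with
## orthologous relationships) by recruiting, from every other genome, the
## operon sharing orthologs of at least half of the seed's genes.  SCOORs
## whose member sets are mutually contained are connected, and each
## connected component of that graph is a COOR -- the unit for which one
## upstream inter-operonic sequence set is extracted.

#' Bi-directional best-hit orthologs for one genome pair
#'
#' A pair `(a, b)` is kept iff `b` is `a`'s best hit (smallest E-value,
#' then largest bit score, then lexicographically smallest subject id) at
#' `E <= evalue_cutoff`, and symmetrically `a` is `b`'s best hit.
#'
#' @param hits_ab,hits_ba hit tables (see [read_hit_table()]) for the two
#'   search directions of the same genome pair.
#' @param evalue_cutoff E-value cut-off applied in both directions.
#' @return data frame with columns `a` and `b` (query-side and
#'   subject-side protein ids of `hits_ab`); possibly zero rows.
#' @export
bdbh_orthologs <- function(hits_ab, hits_ba, evalue_cutoff = 1e-20) {
  best_of <- function(h) {
    h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(h) == 0L)
      return(setNames(character(), character()))
    h <- h[order(h$query, h$evalue, -h$bitscore, h$subject), ]
    h <- h[!duplicated(h$query), ]
    setNames(h$subject, h$query)
  }
  fw <- best_of(hits_ab)
  bw <- best_of(hits_ba)
  a <- names(fw)
  keep <- !is.na(bw[fw]) & bw[fw] == a
  keep[is.na(keep)] <- FALSE
  data.frame(a = a[keep], b = unname(fw[keep]), stringsAsFactors = FALSE)
}

#' Build a cross-genome ortholog map from pairwise hit tables
#'
#' @param hit_tables named list of hit tables; names are
#'   `"<genomeA>|<genomeB>"` for the query-A-vs-subject-B direction.
#'   Both directions of a pair must be present for it to contribute.
#' @param annotation internal annotation data frame (maps `protein_id` to
#'   `gene_id`/`genome_id`).
#' @param evalue_cutoff E-value cut-off (both directions).
#' @return object of class `pf_ortholog_map`: a lookup of gene-level
#'   ortholog pairs, one-to-one within each genome pair.
#' @export
build_ortholog_map <- function(hit_tables, annotation,
                               evalue_cutoff = 1e-20) {
  prot2gene <- setNames(annotation$gene_id, annotation$protein_id)
  gene2genome <- setNames(annotation$genome_id, annotation$gene_id)
  env <- new.env(parent = emptyenv())
  pairs_seen <- character()
  for (nm in names(hit_tables)) {
    gg <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    rev_nm <- paste(gg[[2L]], gg[[1L]], sep = "|")
    key <- paste(sort(gg), collapse = "|")
    if (key %in% pairs_seen || !rev_nm %in% names(hit_tables)) next
    pairs_seen <- c(pairs_seen, key)
    bd <- bdbh_orthologs(hit_tables[[nm]], hit_tables[[rev_nm]],
                         evalue_cutoff)
    if (nrow(bd) == 0L) next
    ga <- unname(prot2gene[bd$a])
    gb <- unname(prot2gene[bd$b])
    if (anyNA(ga) || anyNA(gb))
      stop("hit table ", nm, " references proteins absent from annotation")
    for (i in seq_along(ga)) {
      assign(paste0(ga[[i]], "\r", gg[[2L]]), gb[[i]], envir = env)
      assign(paste0(gb[[i]], "\r", gg[[1L]]), ga[[i]], envir = env)
    }
  }
  structure(list(env = env, gene2genome = gene2genome),
            class = "pf_ortholog_map")
}

#' Look up the ortholog of a gene in another genome
#'
#' @param map a `pf_ortholog_map`.
#' @param gene_id gene identifier.
#' @param genome_id the other genome.
#' @return the ortholog's gene id, or `NA` if none.
#' @export
ortholog_of <- function(map, gene_id, genome_id) {
  v <- mget(paste0(gene_id, "\r", genome_id), envir = map$env,
            ifnotfound = NA_character_)[[1L]]
  v
}

## Longest run of consecutive seed genes whose orthologs are consecutive
## (in either direction) in the candidate operon; used only to break ties.
syntenic_run <- function(seed_genes, cand_genes, map, cand_genome) {
  pos <- vapply(seed_genes, function(g) {
    o <- ortholog_of(map, g, cand_genome)
    if (is.na(o)) NA_integer_ else match(o, cand_genes)
  }, integer(1))
  best <- 0L
  run <- 0L
  for (i in seq_along(pos)) {
    if (i > 1L && !is.na(pos[[i]]) && !is.na(pos[[i - 1L]]) &&
        abs(pos[[i]] - pos[[i - 1L]]) == 1L) {
      run <- run + 1L
    } else {
      run <- if (is.na(pos[[i]])) 0L else 1L
    }
    best <- max(best, run)
  }
  best
}

#' Build the SCOOR seeded by one operon
#'
#' For every other genome, the operon containing orthologs of at least
#' `min_frac` of the seed's genes and with the highest ortholog count is
#' recruited (ties: longest syntenic run with the seed, then smallest
#' operon id); at most one operon per genome.
#'
#' @param seed_id seed operon id.
#' @param operons operon data frame (see [read_operon_table()]).
#' @param map a `pf_ortholog_map`.
#' @param min_frac minimum fraction of seed genes with an ortholog in the
#'   recruited operon (default 0.5, inclusive).
#' @return list with `seed_operon` and `members` (operon ids, seed
#'   included).
#' @export
build_scoor <- function(seed_id, operons, map, min_frac = 0.5) {
  si <- match(seed_id, operons$operon_id)
  if (is.na(si)) stop("unknown operon: ", seed_id)
  seed <- operons[si, ]
  seed_genes <- seed$gene_ids[[1L]]
  members <- seed_id
  for (g in setdiff(unique(operons$genome_id), seed$genome_id)) {
    orth <- vapply(seed_genes, ortholog_of, character(1),
                   map = map, genome_id = g)
    orth <- orth[!is.na(orth)]
    if (length(orth) == 0L) next
    cand <- operons[operons$genome_id == g, , drop = FALSE]
    counts <- vapply(cand$gene_ids, function(gl)
      sum(orth %in% gl), integer(1))
    ok <- counts >= min_frac * length(seed_genes)
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    counts <- counts[ok]
    top <- counts == max(counts)
    cand <- cand[top, , drop = FALSE]
    if (nrow(cand) > 1L) {
      runs <- vapply(seq_len(nrow(cand)), function(i)
        syntenic_run(seed_genes, cand$gene_ids[[i]], map, g), integer(1))
      cand <- cand[order(-runs, cand$operon_id), , drop = FALSE]
    }
    members <- c(members, cand$operon_id[[1L]])
  }
  list(seed_operon = seed_id, members = members)
}

#' Containment graph over SCOORs
#'
#' SCOORs `S` and `T` are connected iff the larger one contains at least
#' `containment_frac` of the operons of the smaller one (sizes by member
#' count; at equal sizes either may play "smaller").
#'
#' @param scoors list of SCOORs (see [build_scoor()]).
#' @param containment_frac containment threshold (default 0.7, inclusive).
#' @return an `igraph` graph whose vertices are SCOOR indices (names
#'   `"s<i>"`).
#' @export
scoor_graph <- function(scoors, containment_frac = 0.7) {
  n <- length(scoors)
  edges <- integer()
  sets <- lapply(scoors, `[[`, "members")
  sizes <- lengths(sets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      if (inter >= containment_frac * min(sizes[[i]], sizes[[j]]))
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("s", seq_len(n)))
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  g
}

#' COORs from the connected components of the SCOOR graph
#'
#' One COOR per connected component; its operon set is the union of the
#' member SCOORs' members.  COOR ids are assigned deterministically from
#' the smallest member operon id.
#'
#' @param graph SCOOR containment graph (see [scoor_graph()]).
#' @param scoors the SCOOR list the graph was built from.
#' @return list of COORs: `list(id, operons, member_scoors)`.
#' @export
coors_from_components <- function(graph, scoors) {
  comp <- igraph::components(graph)
  out <- lapply(seq_len(comp$no), function(k) {
    idx <- which(comp$membership == k)
    ops <- sort(unique(unlist(lapply(scoors[idx], `[[`, "members"))))
    list(id = paste0("coor_", ops[[1L]]), operons = ops,
         member_scoors = idx)
  })
  out <- out[order(vapply(out, `[[`, character(1), "id"))]
  ids <- make.unique(vapply(out, `[[`, character(1), "id"), sep = "_")
  for (i in seq_along(out)) out[[i]]$id <- ids[[i]]
  out
}

#' Build COORs from operons and an ortholog map
#'
#' Convenience wrapper composing [build_scoor()] for every operon,
#' [scoor_graph()] and [coors_from_components()].
#'
#' @inheritParams build_scoor
#' @inheritParams scoor_graph
#' @export
build_coors <- function(operons, map, min_frac = 0.5,
                        containment_frac = 0.7) {
  scoors <- lapply(operons$operon_id, build_scoor,
                   operons = operons, map = map, min_frac = min_frac)
  coors_from_components(scoor_graph(scoors, containment_frac), scoors)
}

#' Extract the upstream inter-operonic sequence of an operon
#'
#' For a plus-strand operon, the region between the nearest annotated gene
#' boundary to its left and the operon start, truncated to the last
#' `max_len` bases; for a minus-strand operon the mirror-image region to
#' its right, reverse-complemented.  On circular genomes the region may
#' wrap the origin; on linear genomes it is clipped at the ends.
#'
#' @param operon one operon row.
#' @param genome the operon's `pf_genome`.
#' @param annotation internal annotation data frame.
#' @param max_len maximum upstream length (default 800).
#' @return a one-row site data frame, or `NULL` when the region is empty.
#' @export
extract_upstream <- function(operon, genome, annotation, max_len = 800L) {
  ann <- annotation[annotation$genome_id == operon$genome_id, ]
  glen <- genome$length
  own <- operon$gene_ids[[1L]]
  ann <- ann[!ann$gene_id %in% own, , drop = FALSE]
  if (operon$strand == "+") {
    prev <- ann$end[ann$end <= operon$start]
    bound <- if (length(prev) > 0L) max(prev)
             else if (genome$topology == "circular" && nrow(ann) > 0L)
               max(ann$end) - glen
             else 0L
    start <- max(bound, operon$start - max_len)
    end <- operon$start
  } else {
    nxt <- ann$start[ann$start >= operon$end]
    bound <- if (length(nxt) > 0L) min(nxt)
             else if (genome$topology == "circular" && nrow(ann) > 0L)
               min(ann$start) + glen
             else glen
    start <- operon$end
    end <- min(bound, operon$end + max_len)
  }
  if (end <= start) return(NULL)
  seq <- wrap_slice(genome, start, end)
  if (operon$strand == "-") seq <- reverse_complement(seq)
  ## store in-range coordinates (wrapping regions keep modular start)
  s0 <- ((start %% glen) + glen) %% glen
  site <- new_site(operon$genome_id, s0, s0 + (end - start), operon$strand,
                   seq, source = paste0("upstream:", operon$operon_id))
  site
}

## Slice that may run off either end of a circular genome.
wrap_slice <- function(genome, start, end) {
  glen <- genome$length
  if (start >= 0L && end <= glen)
    return(substr(genome$seq, start + 1L, end))
  idx <- (seq.int(start, end - 1L) %% glen) + 1L
  paste0(strsplit(genome$seq, "", fixed = TRUE)[[1L]][idx], collapse = "")
}

#' Write COOR membership to a TSV
#'
#' @param coors list of COORs (see [build_coors()]).
#' @param path output path.
#' @export
write_coor_table <- function(coors, path) {
  df <- data.frame(
    coor_id = vapply(coors, `[[`, character(1), "id"),
    operon_ids = vapply(coors, function(cc)
      paste(cc$operons, collapse = ","), character(1)),
    n_operons = lengths(lapply(coors, `[[`, "operons")),
    stringsAsFactors = FALSE)
  write_hash_tsv(df, path)
}

#' Write per-COOR upstream sequence sets as FASTA
#'
#' One `coor_<id>.fa` per sequence set; headers are
#' `<genome>|<operon>|<start>-<end>(<strand>)` with 0-based half-open
#' coordinates.
#'
#' @param sets sequence sets from [build_sequence_sets()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sets) {
    e <- s$entries
    ss <- Biostrings::DNAStringSet(e$seq)
    names(ss) <- sprintf("%s|%s|%d-%d(%s)", e$genome_id, e$operon_id,
                         e$start, e$end, e$strand)
    Biostrings::writeXStringSet(ss, file.path(dir,
                                              paste0(s$coor_id, ".fa")))
  }
  invisible(dir)
}

#' Build the upstream sequence set of every COOR
#'
#' One set per COOR whose non-empty upstream extracts number at least
#' `min_seqs`; smaller COORs are dropped with a message.
#'
#' @param coors list of COORs (see [build_coors()]).
#' @param operons operon data frame.
#' @param genomes named list of `pf_genome` objects.
#' @param annotation internal annotation data frame.
#' @param min_seqs minimum sequences per set (default 3).
#' @param max_len maximum upstream length (default 800).
#' @return list of sequence sets: `list(coor_id, entries)` where
#'   `entries` is a data frame of `operon_id` plus site columns.
#' @export
build_sequence_sets <- function(coors, operons, genomes, annotation,
                                min_seqs = 3L, max_len = 800L) {
  out <- list()
  for (coor in coors) {
    rows <- list()
    for (op_id in coor$operons) {
      op <- operons[match(op_id, operons$operon_id), ]
      site <- extract_upstream(op, genomes[[op$genome_id]], annotation,
                               max_len)
      if (!is.null(site))
        rows[[length(rows) + 1L]] <- cbind(operon_id = op_id, site)
    }
    if (length(rows) >= min_seqs) {
      out[[length(out) + 1L]] <-
        list(coor_id = coor$id, entries = do.call(rbind, rows))
    } else {
      message("dropping ", coor$id, ": only ", length(rows),
              " non-empty upstream sequences (need ", min_seqs, ")")
    }
  }
  out
}
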